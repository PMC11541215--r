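#' @include AllClasses.R pdb-io.R
NULL

#' Write a conformer library to disk
#'
#' The representatives go into one multi-model PDB (model 1 = G0, the
#' highest-populated conformer) and the weights, cluster ids and pipeline
#' provenance into a JSON sidecar.
#'
#' @param library a \linkS4class{ConformerLibrary}.
#' @param pdbFile output PDB path.
#' @param metaFile output JSON path (default: pdbFile + ".json").
#' @return Invisibly, the two paths.
#' @export
writeConformerLibrary <- function(library, pdbFile,
                                  metaFile = paste0(pdbFile, ".json")) {
  writeStructure(structures(library), file = pdbFile)
  meta <- list(glycanId = library@glycanId,
               weights = library@weights,
               clusterIds = library@clusterIds,
               metadata = library@metadata)
  jsonlite::write_json(meta, metaFile, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(pdb = pdbFile, meta = metaFile))
}

#' Read a conformer library written by \code{\link{writeConformerLibrary}}
#'
#' @param pdbFile multi-model PDB of representatives.
#' @param metaFile JSON sidecar with weights.
#' @return A \linkS4class{ConformerLibrary}.
#' @export
readConformerLibrary <- function(pdbFile,
                                 metaFile = paste0(pdbFile, ".json")) {
  models <- readStructure(pdbFile)
  meta <- jsonlite::read_json(metaFile, simplifyVector = TRUE)
  ConformerLibrary(models, weights = as.numeric(meta$weights),
                   clusterIds = as.integer(meta$clusterIds),
                   glycanId = meta$glycanId,
                   metadata = as.list(meta$metadata))
}
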