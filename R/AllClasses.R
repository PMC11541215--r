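#' @include AllGenerics.R
NULL

.ATOM_COLS <- c("serial", "name", "element", "resname", "chain", "resno",
                "insert", "x", "y", "z", "occupancy", "b", "type")

#' MolecularModel: one model of a molecular structure
#'
#' Holds an ordered atom table (PDB conventions: author residue numbering,
#' insertion codes and chain identifiers preserved verbatim) plus an optional
#' bond list. Bonds come from CONECT records or from covalent-radius distance
#' perception (see \code{\link{perceiveBonds}}).
#'
#' @slot atoms data.frame with columns \code{serial, name, element, resname,
#'   chain, resno, insert, x, y, z, occupancy, b, type}. The \code{b} column
#'   may carry pLDDT scores for predicted models.
#' @slot bonds integer two-column matrix of atom indices, each pair stored
#'   once with \code{bonds[,1] < bonds[,2]}.
#' @slot modelId integer model number.
#'
#' @examples
#' m <- makeToyGlycan()
#' nAtoms(m)
#' head(atoms(m))
#' @export
setClass("MolecularModel",
  representation(atoms = "data.frame", bonds = "matrix", modelId = "integer"),
  prototype(atoms = data.frame(), bonds = matrix(integer(0), ncol = 2),
            modelId = 1L))

setValidity("MolecularModel", function(object) {
  a <- object@atoms
  if (nrow(a) == 0L) return("model contains zero atoms")
  if (!all(.ATOM_COLS %in% names(a)))
    return(paste("atom table lacks columns:",
                 paste(setdiff(.ATOM_COLS, names(a)), collapse = ", ")))
  xyz <- as.matrix(a[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) return("non-finite coordinates")
  if (any(!nzchar(a$element))) return("empty element symbol")
  key <- paste(a$chain, a$resno, a$insert, a$name)
  if (anyDuplicated(key))
    return(paste("duplicate atom identity:", key[duplicated(key)][1]))
  b <- object@bonds
  if (length(b)) {
    if (ncol(b) != 2L) return("bond matrix must have two columns")
    if (any(b < 1L) || any(b > nrow(a))) return("bond index out of range")
    if (any(b[, 1] >= b[, 2])) return("bonds must be stored once with i < j")
    if (anyDuplicated(paste(b[, 1], b[, 2]))) return("duplicate bond")
  }
  TRUE
})

#' Construct a MolecularModel
#'
#' @param atoms atom data.frame (see \linkS4class{MolecularModel}).
#' @param bonds integer two-column matrix; pairs are canonicalized to
#'   \code{i < j} and deduplicated.
#' @param modelId integer model number.
#' @return A \linkS4class{MolecularModel}.
#' @export
MolecularModel <- function(atoms, bonds = matrix(integer(0), ncol = 2),
                           modelId = 1L) {
  atoms <- as.data.frame(atoms)
  rownames(atoms) <- NULL
  bonds <- canonicalBonds(bonds)
  new("MolecularModel", atoms = atoms, bonds = bonds,
      modelId = as.integer(modelId))
}

#' Canonicalize a bond list
#'
#' Orders each pair as \code{i < j}, drops self-bonds and duplicates, and
#' sorts rows lexicographically.
#'
#' @param bonds two-column matrix (or empty).
#' @return Integer two-column matrix.
#' @export
canonicalBonds <- function(bonds) {
  if (is.null(bonds) || length(bonds) == 0L)
    return(matrix(integer(0), ncol = 2))
  bonds <- matrix(as.integer(bonds), ncol = 2)
  bonds <- bonds[bonds[, 1] != bonds[, 2], , drop = FALSE]
  bonds <- cbind(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
  bonds <- unique(bonds)
  bonds[order(bonds[, 1], bonds[, 2]), , drop = FALSE]
}

#' @rdname atoms
#' @export
setMethod("atoms", "MolecularModel", function(x, ...) x@atoms)

#' @rdname coords
#' @export
setMethod("coords", "MolecularModel", function(x, ...) {
  m <- as.matrix(x@atoms[, c("x", "y", "z")])
  dimnames(m) <- list(x@atoms$name, c("x", "y", "z"))
  m
})

#' @rdname coords-set
#' @name coords<-
#' @aliases coords<-,MolecularModel-method
#' @export
setReplaceMethod("coords", "MolecularModel", function(x, value) {
  stopifnot(nrow(value) == nrow(x@atoms), ncol(value) == 3L)
  x@atoms$x <- value[, 1]; x@atoms$y <- value[, 2]; x@atoms$z <- value[, 3]
  x
})

#' @rdname bonds
#' @export
setMethod("bonds", "MolecularModel", function(x, ...) x@bonds)

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "MolecularModel", function(x) nrow(x@atoms))

setMethod("show", "MolecularModel", function(object) {
  a <- object@atoms
  cat("MolecularModel (model", object@modelId, "):", nrow(a), "atoms,",
      nrow(object@bonds), "bonds\n")
  cat("  chains:", paste(unique(a$chain), collapse = " "),
      "| residues:", length(unique(paste(a$chain, a$resno, a$insert))), "\n")
})

#' ConformationEnsemble: aligned multi-frame heavy-atom coordinates
#'
#' A stack of F frames of the same molecule, one 3-vector per heavy atom
#' per frame, with atom metadata shared across frames and the replica of
#' origin recorded per frame. Hydrogens are removed on construction.
#'
#' @slot frames numeric array F x N x 3 (Angstrom).
#' @slot atomMeta data.frame with columns \code{name, element, resname,
#'   resno, chain}; one row per atom, ordering shared by all frames.
#' @slot replicaOf integer vector, replica index (0-based) per frame.
#' @export
setClass("ConformationEnsemble",
  representation(frames = "array", atomMeta = "data.frame",
                 replicaOf = "integer"))

setValidity("ConformationEnsemble", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L || d[3] != 3L) return("frames must be F x N x 3")
  if (d[1] < 2L) return("an ensemble needs at least two frames")
  if (d[2] != nrow(object@atomMeta)) return("atomMeta rows != atom count")
  if (length(object@replicaOf) != d[1]) return("replicaOf length != F")
  if (any(toupper(object@atomMeta$element) == "H"))
    return("hydrogen atoms must be stripped from ensembles")
  if (!all(is.finite(object@frames))) return("non-finite frame coordinates")
  TRUE
})

#' @rdname nFrames
#' @export
setMethod("nFrames", "ConformationEnsemble", function(x) dim(x@frames)[1])

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "ConformationEnsemble", function(x) dim(x@frames)[2])

setMethod("show", "ConformationEnsemble", function(object) {
  cat("ConformationEnsemble:", nFrames(object), "frames x",
      nAtoms(object), "heavy atoms,",
      length(unique(object@replicaOf)), "replica(s)\n")
})

#' Extract one frame of an ensemble as a MolecularModel
#'
#' @param ensemble a \linkS4class{ConformationEnsemble}.
#' @param i frame index (1-based).
#' @return A \linkS4class{MolecularModel} (HETATM records, no bonds).
#' @export
ensembleFrame <- function(ensemble, i) {
  stopifnot(i >= 1, i <= nFrames(ensemble))
  meta <- ensemble@atomMeta
  atoms <- data.frame(
    serial = seq_len(nrow(meta)), name = meta$name, element = meta$element,
    resname = meta$resname, chain = meta$chain, resno = meta$resno,
    insert = "", x = ensemble@frames[i, , 1], y = ensemble@frames[i, , 2],
    z = ensemble@frames[i, , 3], occupancy = 1, b = 0, type = "HETATM",
    stringsAsFactors = FALSE)
  MolecularModel(atoms, modelId = i)
}

#' ConformerLibrary: ranked representative conformers with weights
#'
#' The product of the conformer-extraction pipeline: one representative 3D
#' structure per cluster with a normalized population weight (the fraction
#' of trajectory frames assigned to that cluster). Entries are ordered by
#' descending weight, so entry 1 is the highest-populated conformer G0.
#'
#' @slot structures list of \linkS4class{MolecularModel}, identical atom
#'   composition across entries.
#' @slot weights numeric, normalized to sum 1, non-increasing.
#' @slot clusterIds integer cluster label per entry.
#' @slot glycanId free-form identifier.
#' @slot metadata list (seed, silhouette by k, bandwidths, frame provenance).
#' @export
setClass("ConformerLibrary",
  representation(structures = "list", weights = "numeric",
                 clusterIds = "integer", glycanId = "character",
                 metadata = "list"),
  prototype(glycanId = "glycan", metadata = list()))

setValidity("ConformerLibrary", function(object) {
  n <- length(object@structures)
  if (n == 0L) return("library has no entries")
  if (length(object@weights) != n || length(object@clusterIds) != n)
    return("weights/clusterIds length mismatch")
  if (abs(sum(object@weights) - 1) > 1e-9) return("weights must sum to 1")
  if (any(diff(object@weights) > 1e-12))
    return("entries must be ordered by descending weight")
  nat <- vapply(object@structures, nAtoms, integer(1))
  if (length(unique(nat)) != 1L)
    return("entries differ in atom composition")
  TRUE
})

#' Construct a ConformerLibrary
#'
#' Entries are sorted by descending weight with ties broken by lower
#' cluster id; weights are renormalized to sum exactly 1.
#'
#' @param structures list of \linkS4class{MolecularModel}.
#' @param weights numeric population fractions.
#' @param clusterIds integer cluster labels (default \code{0:(n-1)}).
#' @param glycanId identifier string.
#' @param metadata provenance list.
#' @return A \linkS4class{ConformerLibrary}.
#' @export
ConformerLibrary <- function(structures, weights,
                             clusterIds = seq_along(structures) - 1L,
                             glycanId = "glycan", metadata = list()) {
  o <- order(-weights, clusterIds)
  w <- weights[o] / sum(weights)
  new("ConformerLibrary", structures = structures[o], weights = w,
      clusterIds = as.integer(clusterIds[o]), glycanId = glycanId,
      metadata = metadata)
}

#' @rdname nConformers
#' @export
setMethod("nConformers", "ConformerLibrary", function(x) length(x@structures))

#' @rdname structures
#' @export
setMethod("structures", "ConformerLibrary", function(x) x@structures)

#' Population weights of a conformer library
#'
#' @param object a \linkS4class{ConformerLibrary}.
#' @param ... ignored.
#' @return Numeric vector summing to 1, ordered G0, G1, ...
#' @export
setMethod("weights", "ConformerLibrary", function(object, ...) object@weights)

setMethod("show", "ConformerLibrary", function(object) {
  cat("ConformerLibrary '", object@glycanId, "': ", nConformers(object),
      " conformer(s), ", nAtoms(object@structures[[1]]), " atoms each\n",
      sep = "")
  cat("  weights:", paste(sprintf("G%d=%.3f",
      seq_len(nConformers(object)) - 1L, object@weights), collapse = " "),
      "\n")
})

#' LinkageSpec: geometry of one protein-glycan linkage type
#'
#' Defines the atoms and torsion ranges of the bond between the reducing
#' end of a glycan and the protein sidechain, using the five-atom naming
#' a-e: phi = a-b-c-d and psi = b-c-d-e, where a and b belong to the glycan
#' (e.g. O5 and C1) and c, d, e to the protein sidechain (e.g. ND2, CG, CB
#' for asparagine).
#'
#' @slot glycoType one of N-GlcNAc, O-GalNAc, O-GlcNAc, O-Fuc, O-Man,
#'   O-Glc, O-Xyl, C-Man.
#' @slot residues protein residue names this linkage applies to.
#' @slot phiAtoms character quadruple (a, b, c, d).
#' @slot psiAtoms character quadruple (b, c, d, e).
#' @slot phiRange,psiRange degree intervals within (-180, 180].
#' @slot bondLength b-c bond length, Angstrom.
#' @slot bondAngle b-c-d angle at the attachment atom, degrees.
#' @export
setClass("LinkageSpec",
  representation(glycoType = "character", residues = "character",
                 phiAtoms = "character", psiAtoms = "character",
                 phiRange = "numeric", psiRange = "numeric",
                 bondLength = "numeric", bondAngle = "numeric"))

.GLYCO_TYPES <- c("N-GlcNAc", "O-GalNAc", "O-GlcNAc", "O-Fuc", "O-Man",
                  "O-Glc", "O-Xyl", "C-Man")

setValidity("LinkageSpec", function(object) {
  if (!object@glycoType %in% .GLYCO_TYPES)
    return(paste("unsupported glycosylation type:", object@glycoType))
  if (length(object@phiAtoms) != 4L || length(object@psiAtoms) != 4L)
    return("phiAtoms and psiAtoms must each name four atoms")
  if (!identical(object@phiAtoms[2:4], object@psiAtoms[1:3]))
    return("phi and psi quartets must overlap in atoms b, c, d")
  rng <- c(object@phiRange, object@psiRange)
  if (length(object@phiRange) != 2L || length(object@psiRange) != 2L ||
      any(rng < -180) || any(rng > 180))
    return("torsion ranges must lie within (-180, 180]")
  if (object@phiRange[1] > object@phiRange[2] ||
      object@psiRange[1] > object@psiRange[2])
    return("torsion ranges must be ordered [min, max]")
  if (object@bondLength <= 0) return("bond length must be positive")
  TRUE
})

setMethod("show", "LinkageSpec", function(object) {
  cat("LinkageSpec", object@glycoType, "on",
      paste(object@residues, collapse = "/"), "\n")
  cat(sprintf("  phi %s-%s-%s-%s in [%g, %g], psi %s-%s-%s-%s in [%g, %g]\n",
      object@phiAtoms[1], object@phiAtoms[2], object@phiAtoms[3],
      object@phiAtoms[4], object@phiRange[1], object@phiRange[2],
      object@psiAtoms[1], object@psiAtoms[2], object@psiAtoms[3],
      object@psiAtoms[4], object@psiRange[1], object@psiRange[2]))
  cat(sprintf("  bond %s-%s %.2f A, angle %.1f deg\n", object@phiAtoms[2],
      object@phiAtoms[3], object@bondLength, object@bondAngle))
})

#' GraftResult: outcome of grafting one glycan onto one site
#'
#' @slot success logical; TRUE iff the final steric loss is exactly 0.
#' @slot pose list with the positioned glycan (\code{glycan}, a
#'   \linkS4class{MolecularModel}), the linkage bookkeeping and the final
#'   \code{phi}, \code{psi}, \code{fitness} and \code{clashes}.
#' @slot phase "ga" if a conformer passed during the cascade, "wiggle" if
#'   the stochastic refinement stage was reached.
#' @slot clusterId cluster id of the conformer in the returned pose.
#' @slot clustersTried integer cluster ids in the order attempted.
#' @slot clusterFitness best GA fitness per tried cluster.
#' @slot wiggleIterationsUsed 0-40.
#' @slot site site label (e.g. "A:45").
#' @export
setClass("GraftResult",
  representation(success = "logical", pose = "list", phase = "character",
                 clusterId = "integer", clustersTried = "integer",
                 clusterFitness = "numeric", wiggleIterationsUsed = "integer",
                 site = "character"))

setValidity("GraftResult", function(object) {
  if (object@success && object@pose$fitness != 0)
    return("success requires zero steric loss")
  if (!object@phase %in% c("ga", "wiggle")) return("phase must be ga/wiggle")
  TRUE
})

setMethod("show", "GraftResult", function(object) {
  cat(sprintf("GraftResult %s: %s (phase %s, conformer G%d, fitness %.4g",
      object@site, if (object@success) "success" else "failure",
      object@phase, object@clusterId, object@pose$fitness))
  if (object@phase == "wiggle")
    cat(",", object@wiggleIterationsUsed, "wiggle iterations")
  cat(")\n")
})

#' ScanReport: per-sequon occupancy predictions
#'
#' @slot entries data.frame with one row per sequon: \code{chain, resno,
#'   insert, motif, label, reason, cluster_used, fitness_best, phase}.
#' @slot proteinId identifier of the scanned structure.
#' @slot parameters list snapshot of scan parameters.
#' @export
setClass("ScanReport",
  representation(entries = "data.frame", proteinId = "character",
                 parameters = "list"))

setMethod("show", "ScanReport", function(object) {
  cat("ScanReport for", object@proteinId, "-", nrow(object@entries),
      "sequon(s)\n")
  if (nrow(object@entries))
    print(object@entries[, c("chain", "resno", "motif", "label")])
})

#' EnsembleResult: multi-frame fitting outcome at one site
#'
#' @slot accepted data.frame with columns \code{repeat_index, frame, phi,
#'   psi} for every clash-free pose.
#' @slot rejectedCount integer, frames rejected across all repeats.
#' @slot nFrames frames drawn per repeat.
#' @slot repeats number of repeats.
#' @slot sasaPerModel numeric, SASA (nm^2) of the complex per accepted
#'   model (empty unless SASA was requested).
#' @slot parameters list snapshot.
#' @export
setClass("EnsembleResult",
  representation(accepted = "data.frame", rejectedCount = "integer",
                 nFrames = "integer", repeats = "integer",
                 sasaPerModel = "numeric", parameters = "list"))

setMethod("show", "EnsembleResult", function(object) {
  tot <- object@nFrames * object@repeats
  cat(sprintf("EnsembleResult: %d/%d poses accepted (%.1f%%), %d repeats x %d frames\n",
      nrow(object@accepted), tot, 100 * nrow(object@accepted) / tot,
      object@repeats, object@nFrames))
})
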