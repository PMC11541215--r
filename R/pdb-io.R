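#' @include AllClasses.R utils.R
NULL

.pdbLines <- function(source) {
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source))
    return(readLines(source, warn = FALSE))
  unlist(strsplit(source, "\n", fixed = TRUE))
}

.checkAtomLines <- function(lines) {
  idx <- grep("^(ATOM  |HETATM)", lines)
  if (!length(idx)) stop("empty input: no ATOM/HETATM records found")
  for (i in idx) {
    ln <- lines[i]
    bad <- nchar(ln) < 54
    if (!bad) {
      xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                           substr(ln, 39, 46),
                                           substr(ln, 47, 54))))
      bad <- any(is.na(xyz))
    }
    if (bad)
      stop(sprintf("malformed ATOM/HETATM record at line %d: '%s'", i, ln))
  }
  invisible(idx)
}

# CONECT records -> bond pairs keyed on atom serial numbers.
.parseConect <- function(lines) {
  cl <- grep("^CONECT", lines, value = TRUE)
  if (!length(cl)) return(matrix(integer(0), ncol = 2))
  out <- list()
  for (ln in cl) {
    flds <- suppressWarnings(as.integer(
      substring(ln, seq(7, 27, by = 5), seq(11, 31, by = 5))))
    flds <- flds[!is.na(flds)]
    if (length(flds) >= 2L)
      out[[length(out) + 1L]] <- cbind(flds[1], flds[-1])
  }
  do.call(rbind, out)
}

#' Read a (possibly multi-model) PDB structure
#'
#' Parses ATOM/HETATM records through bio3d, preserving author residue
#' numbering, insertion codes and chain identifiers verbatim. CONECT
#' records are translated into the bond list of every returned model.
#'
#' @param source path to a PDB file, or PDB-format text.
#' @param modelSelect "all" or "first".
#' @return A list of \linkS4class{MolecularModel} objects (length 1 for a
#'   single-model file).
#' @examples
#' txt <- writeStructure(list(makeToyGlycan()))
#' mods <- readStructure(txt)
#' @export
readStructure <- function(source, modelSelect = c("all", "first")) {
  modelSelect <- match.arg(modelSelect)
  lines <- .pdbLines(source)
  .checkAtomLines(lines)
  f <- tempfile(fileext = ".pdb")
  on.exit(unlink(f))
  writeLines(lines, f)
  pdb <- bio3d::read.pdb(f, multi = TRUE, verbose = FALSE)
  a <- pdb$atom
  atomsDf <- data.frame(
    serial = a$eleno,
    name = a$elety,
    element = ifelse(is.na(a$elesy) | !nzchar(trimws(a$elesy)),
                     elementFromName(a$elety), trimws(a$elesy)),
    resname = a$resid,
    chain = ifelse(is.na(a$chain), "", a$chain),
    resno = a$resno,
    insert = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    b = ifelse(is.na(a$b), 0, a$b),
    type = a$type,
    stringsAsFactors = FALSE)
  conect <- .parseConect(lines)
  bondIdx <- matrix(integer(0), ncol = 2)
  if (length(conect)) {
    pos <- match(conect[, 1], atomsDf$serial)
    pos2 <- match(conect[, 2], atomsDf$serial)
    keep <- !is.na(pos) & !is.na(pos2)
    bondIdx <- canonicalBonds(cbind(pos[keep], pos2[keep]))
  }
  nModels <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  nModels <- if (modelSelect == "first") 1L else nModels
  lapply(seq_len(nModels), function(i) {
    ai <- atomsDf
    xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[i, ] else as.numeric(pdb$xyz)
    m <- matrix(xyz, ncol = 3, byrow = TRUE)
    ai$x <- m[, 1]; ai$y <- m[, 2]; ai$z <- m[, 3]
    MolecularModel(ai, bonds = bondIdx, modelId = i)
  })
}

.fmtAtomName <- function(name, element) {
  # PDB convention: 1-3 character names start in column 14 unless the
  # element symbol itself is two characters.
  if (nchar(name) >= 4L || nchar(element) == 2L)
    formatC(name, width = -4)
  else
    paste0(" ", formatC(name, width = -3))
}

.atomLine <- function(r) {
  sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          r$type, r$serial %% 100000L, .fmtAtomName(r$name, r$element), "",
          r$resname, r$chain, r$resno, r$insert,
          r$x, r$y, r$z, r$occupancy, r$b, toupper(r$element))
}

#' Write models as PDB-format text
#'
#' Multi-model input is wrapped in MODEL/ENDMDL blocks. Bonds of the first
#' model are emitted as CONECT records when \code{includeConect} is TRUE,
#' which keeps inter-residue protein-glycan links explicit. Round-tripping
#' through \code{\link{readStructure}} reproduces names, numbering and
#' coordinates to three decimals.
#'
#' @param models a \linkS4class{MolecularModel} or list thereof.
#' @param file optional path; when NULL the text is returned invisibly.
#' @param includeConect emit CONECT records for the stored bonds.
#' @return PDB text as a character vector of lines (invisibly when written
#'   to \code{file}).
#' @export
writeStructure <- function(models, file = NULL, includeConect = TRUE) {
  if (is(models, "MolecularModel")) models <- list(models)
  stopifnot(length(models) >= 1L)
  multi <- length(models) > 1L
  out <- character(0)
  for (i in seq_along(models)) {
    m <- models[[i]]
    a <- atoms(m)
    if (nrow(a) > 99999L)
      stop("serial overflow: more than 99999 atoms cannot be written")
    if (multi) out <- c(out, sprintf("MODEL     %4d", i))
    recs <- vapply(seq_len(nrow(a)),
                   function(j) .atomLine(as.list(a[j, ])), character(1))
    out <- c(out, recs, "TER")
    if (multi) out <- c(out, "ENDMDL")
  }
  if (includeConect) {
    b <- bonds(models[[1]])
    if (nrow(b)) {
      ser <- atoms(models[[1]])$serial
      out <- c(out, sprintf("CONECT%5d%5d", ser[b[, 1]], ser[b[, 2]]))
    }
  }
  out <- c(out, "END")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Perceive covalent bonds from interatomic distances
#'
#' Two atoms are bonded when their separation is below 1.3 times the sum of
#' their covalent radii (and above 0.4 A, rejecting coincident atoms).
#' Used when a structure carries no CONECT records.
#'
#' @param model a \linkS4class{MolecularModel}.
#' @param scale cutoff multiplier on the covalent-radius sum.
#' @return The model with its bond slot filled.
#' @export
perceiveBonds <- function(model, scale = 1.3) {
  xyz <- coords(model)
  n <- nrow(xyz)
  r <- covalentRadius(atoms(model)$element)
  d2 <- crossDist2(xyz, xyz)
  cut <- (scale * outer(r, r, "+"))^2
  hit <- which(d2 < cut & d2 > 0.16, arr.ind = TRUE)
  hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
  model@bonds <- canonicalBonds(hit)
  model
}
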