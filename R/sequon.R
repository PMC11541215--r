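#' @include AllClasses.R graft.R
NULL

# Per-chain residue table in author order (order of first appearance),
# with a consecutive flag that breaks on numbering gaps so missing
# residues never create spurious motifs.
.residueTable <- function(model) {
  a <- atoms(model)
  key <- paste(a$chain, a$resno, a$insert, sep = "\r")
  first <- !duplicated(key)
  data.frame(chain = a$chain[first], resno = a$resno[first],
             insert = a$insert[first], resname = a$resname[first],
             stringsAsFactors = FALSE)
}

.AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Find N-glycosylation sequons (N-X-S/T)
#'
#' Scans each chain's residue sequence in author order and reports every
#' Asn followed (two positions later, with no chain break) by Ser or Thr.
#' Author residue numbering, including offsets and insertion codes, is
#' reported verbatim. The literal N-X-S/T rule is applied by default;
#' \code{excludeProlineX} drops motifs whose X is proline, matching the
#' biological convention.
#'
#' @param protein a \linkS4class{MolecularModel}.
#' @param excludeProlineX drop N-P-S/T motifs.
#' @return data.frame with columns \code{chain, resno, insert, resname,
#'   motif} (one row per sequon Asn).
#' @examples
#' p <- makeSequonProtein("ANASA")
#' findSequons(p)   # sequon at residue 2
#' @export
findSequons <- function(protein, excludeProlineX = FALSE) {
  rt <- .residueTable(protein)
  out <- list()
  for (ch in unique(rt$chain)) {
    r <- rt[rt$chain == ch, , drop = FALSE]
    n <- nrow(r)
    if (n < 3L) next
    # author-order adjacency: consecutive rows with numbering step <= 1
    step <- diff(r$resno)
    adj <- step == 1L | (step == 0L & (r$insert[-n] != r$insert[-1]))
    for (i in seq_len(n - 2L)) {
      if (r$resname[i] != "ASN") next
      if (!adj[i] || !adj[i + 1L]) next
      if (!r$resname[i + 2L] %in% c("SER", "THR")) next
      if (excludeProlineX && r$resname[i + 1L] == "PRO") next
      m1 <- unname(.AA3TO1[r$resname[i + 0:2]])
      m1[is.na(m1)] <- "X"
      motif <- paste0(m1, collapse = "")
      out[[length(out) + 1L]] <- data.frame(
        chain = ch, resno = r$resno[i], insert = r$insert[i],
        resname = r$resname[i], motif = motif, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chain = character(0), resno = integer(0),
                      insert = character(0), resname = character(0),
                      motif = character(0)))
  do.call(rbind, out)
}

#' Swap the Asn sidechain amide oxygen and nitrogen
#'
#' Exchanges the coordinates of OD1 and ND2 of one asparagine, leaving
#' every other field untouched. The assignment of these two atoms is
#' largely arbitrary in X-ray structures, and an inverted assignment can
#' block grafting; the swap is an exact involution.
#'
#' @param protein a \linkS4class{MolecularModel}.
#' @param site site reference of an Asn residue.
#' @return The modified \linkS4class{MolecularModel}.
#' @export
swapAsnAmide <- function(protein, site) {
  rows <- .residueAtoms(protein, site)
  if (!length(rows)) stop("site ", siteLabel(site), " not found")
  a <- atoms(protein)
  if (a$resname[rows[1]] != "ASN")
    stop("site ", siteLabel(site), " is ", a$resname[rows[1]],
         ", not ASN; the amide swap only applies to asparagine")
  od1 <- rows[a$name[rows] == "OD1"]
  nd2 <- rows[a$name[rows] == "ND2"]
  if (length(od1) != 1L || length(nd2) != 1L)
    stop("site ", siteLabel(site), " lacks OD1 or ND2")
  xyz <- coords(protein)
  tmp <- xyz[od1, ]
  xyz[od1, ] <- xyz[nd2, ]
  xyz[nd2, ] <- tmp
  coords(protein) <- xyz
  protein
}

#' Predict sequon occupancy with a single-GlcNAc probe
#'
#' Attempts to graft a single GlcNAc monosaccharide into every N-X-S/T
#' sequon of the protein using the full cascade (genetic search, then
#' stochastic refinement). Each sequon is probed against the bare protein
#' independently -- a one-monosaccharide probe at another sequon should not
#' change local accessibility. A sequon is labelled "yes" iff the graft
#' ends clash-free; missing sidechain atoms yield "no" with reason
#' "sidechain-atom-missing" and a pointer to \code{\link{swapAsnAmide}}.
#'
#' @param protein a \linkS4class{MolecularModel}.
#' @param library single-GlcNAc \linkS4class{ConformerLibrary}; default
#'   the built-in probe.
#' @param linkage a \linkS4class{LinkageSpec}; default N-GlcNAc.
#' @param config a \code{\link{gaConfig}}.
#' @param seed master seed.
#' @param excludeProlineX drop N-P-S/T sequons.
#' @param proteinId identifier stored in the report.
#' @return A \linkS4class{ScanReport}.
#' @export
glcnacScan <- function(protein, library = glcnacProbeLibrary(),
                       linkage = NULL, config = gaConfig(), seed = 1L,
                       excludeProlineX = FALSE, proteinId = "protein") {
  if (is.null(linkage)) linkage <- getLinkage("N-GlcNAc")
  seqs <- findSequons(protein, excludeProlineX = excludeProlineX)
  entries <- data.frame(chain = character(0), resno = integer(0),
                        insert = character(0), motif = character(0),
                        label = character(0), reason = character(0),
                        cluster_used = integer(0),
                        fitness_best = numeric(0), phase = character(0),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(seqs))) {
    s <- seqs[i, ]
    lbl <- paste0(s$chain, ":", s$resno, s$insert)
    res <- tryCatch(
      graftSite(protein, lbl, library, linkage, config = config,
                seed = childSeed(seed, lbl)),
      glycograft_missing_sidechain = function(e) e,
      error = function(e) e)
    if (inherits(res, "glycograft_missing_sidechain")) {
      row <- data.frame(chain = s$chain, resno = s$resno,
                        insert = s$insert, motif = s$motif, label = "no",
                        reason = "sidechain-atom-missing",
                        cluster_used = NA_integer_,
                        fitness_best = NA_real_, phase = NA_character_)
    } else if (inherits(res, "error")) {
      row <- data.frame(chain = s$chain, resno = s$resno,
                        insert = s$insert, motif = s$motif, label = "no",
                        reason = conditionMessage(res),
                        cluster_used = NA_integer_,
                        fitness_best = NA_real_, phase = NA_character_)
    } else {
      row <- data.frame(chain = s$chain, resno = s$resno,
                        insert = s$insert, motif = s$motif,
                        label = if (res@success) "yes" else "no",
                        reason = "",
                        cluster_used = res@clusterId,
                        fitness_best = res@pose$fitness,
                        phase = res@phase)
    }
    entries <- rbind(entries, row)
  }
  new("ScanReport", entries = entries, proteinId = proteinId,
      parameters = list(seed = seed, excludeProlineX = excludeProlineX,
                        threshold = config$threshold,
                        populationSize = config$populationSize,
                        generations = config$generations,
                        wiggleMaxIter = config$wiggleMaxIter))
}
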