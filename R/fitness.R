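#' @include AllClasses.R utils.R
NULL

#' Steric loss between protein and glycan atom sets
#'
#' For every protein-glycan atom pair strictly closer than the threshold
#' (default 1.7 A, the van der Waals radius of carbon) the pair contributes
#' \code{200 * exp(d^2)}; pairs at or beyond the threshold contribute
#' nothing, as do excluded glycan atoms (the reducing-end atom that is
#' covalently bonded to the protein). A coincident pair therefore scores
#' exactly 200, and the loss is 0 iff no clash exists.
#'
#' @param protein numeric m x 3 matrix (or \linkS4class{MolecularModel}).
#' @param glycan numeric n x 3 matrix (or \linkS4class{MolecularModel}).
#' @param threshold clash distance, Angstrom.
#' @param exclude indices of glycan atoms exempt from the sum.
#' @return List with \code{fitness} (non-negative scalar) and
#'   \code{clashes} (data.frame \code{protein, glycan, distance}).
#' @examples
#' p <- matrix(c(0, 0, 0), 1)
#' stericFitness(p, p)$fitness          # 200
#' stericFitness(p, matrix(c(1.7, 0, 0), 1))$fitness  # 0: strict inequality
#' @export
stericFitness <- function(protein, glycan, threshold = 1.7,
                          exclude = integer(0)) {
  P <- if (is(protein, "MolecularModel")) coords(protein) else as.matrix(protein)
  G <- if (is(glycan, "MolecularModel")) coords(glycan) else as.matrix(glycan)
  empty <- data.frame(protein = integer(0), glycan = integer(0),
                      distance = numeric(0))
  gIdx <- setdiff(seq_len(nrow(G)), exclude)
  if (nrow(P) == 0L || length(gIdx) == 0L)
    return(list(fitness = 0, clashes = empty))
  if (!all(is.finite(P)) || !all(is.finite(G)))
    stop("non-finite coordinates in steric evaluation")
  d2 <- crossDist2(P, G[gIdx, , drop = FALSE])
  hit <- which(d2 < threshold^2, arr.ind = TRUE)
  if (!nrow(hit)) return(list(fitness = 0, clashes = empty))
  dd2 <- d2[hit]
  list(fitness = sum(200 * exp(dd2)),
       clashes = data.frame(protein = hit[, 1], glycan = gIdx[hit[, 2]],
                            distance = sqrt(dd2)))
}
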