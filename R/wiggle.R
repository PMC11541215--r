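#' @include AllClasses.R linkage.R ga.R fitness.R
NULL

# Rotatable torsions of a positioned glycan: the detected quartets of the
# glycan graph, with the rotating side chosen away from the anomeric
# anchor so the protein-glycan bond never moves.
glycanWiggleTorsions <- function(pose) {
  graph <- buildGraph(pose$glycan)
  tq <- detectTorsionPairs(graph)
  lapply(tq, function(q) {
    if (pose$bIdx %in% q$rotatingSet) {
      moving <- setdiff(seq_len(nAtoms(pose$glycan)),
                        union(q$rotatingSet, q$atoms[2:3]))
      list(atoms = q$atoms, rotatingSet = moving)
    } else q
  })
}

.evalPose <- function(pose, proteinXYZ, threshold) {
  r <- stericFitness(proteinXYZ, coords(pose$glycan), threshold = threshold,
                     exclude = pose$exclude)
  pose$fitness <- r$fitness
  pose$clashes <- r$clashes
  pose
}

#' Stochastic torsion refinement ("wiggle") of a graft pose
#'
#' Fallback used when no conformer passes the genetic search: starting
#' from the lowest-loss pose, every rotatable torsion of the glycan (the
#' detected quartets plus the linkage phi/psi) is perturbed per iteration
#' by an independent uniform draw within the move range (default 10
#' degrees, the low end of glycosidic-torsion fluctuations at room
#' temperature). The perturbations accumulate as a random walk, the loss
#' is re-evaluated after every move set, and the best pose encountered is
#' retained and returned. Stops early at zero loss; gives up after
#' \code{wiggleMaxIter} iterations (default 40). A greedy descent is
#' deliberately avoided: within the clash threshold the loss rewards
#' deeper overlap, so hill-descending from the best pose can trap a
#' shallow clash instead of releasing it.
#'
#' @param pose a graft pose (see \code{\link{attachReducingEnd}}).
#' @param protein protein coordinates (matrix) or
#'   \linkS4class{MolecularModel}.
#' @param config a \code{\link{gaConfig}}.
#' @param seed RNG seed.
#' @param instrument record every torsion move (for move-size audits).
#' @return List with \code{pose} (best found, fitness filled),
#'   \code{success}, \code{iterations} and, when instrumented,
#'   \code{moves} (matrix of per-iteration torsion deltas, degrees).
#' @export
wiggleRefine <- function(pose, protein, config = gaConfig(), seed = 1L,
                         instrument = FALSE) {
  P <- if (is(protein, "MolecularModel")) coords(protein) else as.matrix(protein)
  set.seed(seed)
  half <- if (config$wiggleStepMode == "half-width") config$wiggleStep
          else config$wiggleStep / 2
  best <- .evalPose(pose, P, config$threshold)
  if (best$fitness == 0)
    return(list(pose = best, success = TRUE, iterations = 0L,
                moves = if (instrument) matrix(numeric(0), 0, 0)))
  torsions <- glycanWiggleTorsions(pose)
  nT <- length(torsions) + 2L          # internal quartets + phi + psi
  moves <- if (instrument) matrix(NA_real_, config$wiggleMaxIter, nT)
  iterations <- 0L
  cur <- best                          # random-walk state; best kept aside
  for (it in seq_len(config$wiggleMaxIter)) {
    iterations <- it
    cand <- cur
    deltas <- stats::runif(nT, -half, half)
    xyz <- coords(cand$glycan)
    for (j in seq_along(torsions)) {
      q <- torsions[[j]]
      if (!length(q$rotatingSet)) next
      xyz[q$rotatingSet, ] <- rotateAboutAxis(
        xyz[q$rotatingSet, , drop = FALSE],
        xyz[q$atoms[3], ], xyz[q$atoms[3], ] - xyz[q$atoms[2], ],
        deltas[j])
    }
    coords(cand$glycan) <- xyz
    cand <- setLinkageTorsions(cand,
                               wrapAngle(cur$phi + deltas[nT - 1L]),
                               wrapAngle(cur$psi + deltas[nT]))
    cand <- .evalPose(cand, P, config$threshold)
    if (instrument) moves[it, ] <- deltas
    cur <- cand
    if (cand$fitness < best$fitness) best <- cand
    if (best$fitness == 0) break
  }
  list(pose = best, success = best$fitness == 0, iterations = iterations,
       moves = if (instrument) moves[seq_len(iterations), , drop = FALSE])
}
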