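#' @include AllClasses.R utils.R
NULL

#' Genetic-algorithm configuration
#'
#' Defaults follow the published protocol: a population of 128 torsion
#' pairs evolved over eight generations, the best half serving as parents,
#' gene-wise uniform crossover and per-gene mutation probability 0.2
#' (resampling the gene uniformly within its range). The best individual
#' always survives, and the search exits early once a clash-free
#' individual (fitness 0) appears, which cannot change the success set.
#'
#' @param populationSize individuals per generation.
#' @param generations maximum number of generations.
#' @param parentFraction fraction of lowest-fitness individuals kept as
#'   parents.
#' @param mutationRate per-gene mutation probability.
#' @param earlyExitOnZero stop as soon as fitness 0 is observed.
#' @param wiggleMaxIter iterations of the stochastic refinement fallback.
#' @param wiggleStep torsion move range, degrees.
#' @param wiggleStepMode "half-width" draws moves in [-step, step];
#'   "total-width" in [-step/2, step/2].
#' @param threshold clash distance, Angstrom.
#' @return A list of class "GAConfig".
#' @export
gaConfig <- function(populationSize = 128L, generations = 8L,
                     parentFraction = 0.5, mutationRate = 0.2,
                     earlyExitOnZero = TRUE, wiggleMaxIter = 40L,
                     wiggleStep = 10, wiggleStepMode = c("half-width",
                                                         "total-width"),
                     threshold = 1.7) {
  stopifnot(populationSize >= 2L, parentFraction > 0, parentFraction < 1,
            mutationRate >= 0, mutationRate <= 1)
  structure(list(populationSize = as.integer(populationSize),
                 generations = as.integer(generations),
                 parentFraction = parentFraction,
                 mutationRate = mutationRate,
                 earlyExitOnZero = earlyExitOnZero,
                 wiggleMaxIter = as.integer(wiggleMaxIter),
                 wiggleStep = wiggleStep,
                 wiggleStepMode = match.arg(wiggleStepMode),
                 threshold = threshold),
            class = "GAConfig")
}

#' Optimize the linkage torsions by a genetic algorithm
#'
#' Minimizes a steric-loss function over (phi, psi). The population is
#' randomly initialized within the ranges; each generation keeps the
#' lowest-fitness half as parents and replaces the rest with offspring
#' produced by gene-wise uniform crossover and range-bounded mutation.
#' The best fitness per generation is non-increasing by construction.
#'
#' @param fitnessFn function(phi, psi) returning a non-negative scalar.
#' @param phiRange,psiRange degree intervals.
#' @param config a \code{\link{gaConfig}}.
#' @param seed RNG seed.
#' @return List with \code{phi}, \code{psi}, \code{fitness},
#'   \code{history} (best fitness after each evaluated generation),
#'   \code{generationsRun} and \code{populationSize0}.
#' @export
gaOptimize <- function(fitnessFn, phiRange, psiRange, config = gaConfig(),
                       seed = 1L) {
  set.seed(seed)
  n <- config$populationSize
  pop <- cbind(phi = stats::runif(n, phiRange[1], phiRange[2]),
               psi = stats::runif(n, psiRange[1], psiRange[2]))
  fit <- vapply(seq_len(n), function(i) fitnessFn(pop[i, 1], pop[i, 2]),
                numeric(1))
  history <- min(fit)
  gens <- 0L
  ranges <- list(phiRange, psiRange)
  while (gens < config$generations &&
         !(config$earlyExitOnZero && min(fit) == 0)) {
    gens <- gens + 1L
    ord <- order(fit)
    nPar <- max(2L, ceiling(n * config$parentFraction))
    parents <- pop[ord[seq_len(nPar)], , drop = FALSE]
    nChild <- n - nPar
    childs <- matrix(NA_real_, nChild, 2)
    for (i in seq_len(nChild)) {
      pr <- parents[sample.int(nPar, 2, replace = TRUE), , drop = FALSE]
      gene <- ifelse(stats::runif(2) < 0.5, pr[1, ], pr[2, ])
      mut <- stats::runif(2) < config$mutationRate
      for (gidx in which(mut))
        gene[gidx] <- stats::runif(1, ranges[[gidx]][1], ranges[[gidx]][2])
      childs[i, ] <- gene
    }
    childFit <- vapply(seq_len(nChild),
                       function(i) fitnessFn(childs[i, 1], childs[i, 2]),
                       numeric(1))
    pop <- rbind(parents, childs)   # elite parent survives in row 1
    fit <- c(fit[ord[seq_len(nPar)]], childFit)
    history <- c(history, min(fit))
  }
  best <- which.min(fit)
  list(phi = unname(pop[best, 1]), psi = unname(pop[best, 2]),
       fitness = fit[best], history = history, generationsRun = gens,
       populationSize0 = n)
}
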