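#' @include AllClasses.R utils.R
NULL

# Scalar-bandwidth Gaussian kernel density in d dimensions.
# p(x) = 1/(n (h sqrt(2pi))^d) sum_i exp(-||x - x_i||^2 / (2 h^2))

#' Gaussian kernel
#'
#' The standard normal kernel K(u) = exp(-u^2/2) / sqrt(2*pi); at u = 0 it
#' evaluates to 1/sqrt(2*pi).
#'
#' @param u numeric.
#' @return Kernel values.
#' @export
gaussianKernel <- function(u) exp(-0.5 * u^2) / sqrt(2 * pi)

#' Evaluate a kernel density estimate
#'
#' @param x query points, m x d matrix (or a single d-vector).
#' @param X training points, n x d matrix.
#' @param h scalar bandwidth (> 0).
#' @return Numeric vector of densities at the query points.
#' @export
kdeDensity <- function(x, X, h) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  X <- as.matrix(X)
  stopifnot(h > 0, ncol(x) == ncol(X))
  d <- ncol(X)
  d2 <- crossDist2(as.matrix(x), X)
  rowSums(exp(-d2 / (2 * h^2))) / (nrow(X) * (h * sqrt(2 * pi))^d)
}

# Scott's-rule plug-in bandwidth (scalar): mean per-dimension sd scaled by
# n^(-1/(d+4)).
scottBandwidth <- function(X) {
  X <- as.matrix(X)
  s <- mean(apply(X, 2, stats::sd))
  if (s == 0) s <- 1e-3
  s * nrow(X)^(-1 / (ncol(X) + 4))
}

#' Select a KDE bandwidth by five-fold cross-validation
#'
#' The data are split into five folds; for each candidate bandwidth the
#' density is trained on four folds and scored on the fifth by negative
#' mean log-density, and the bandwidth minimizing the averaged validation
#' loss is returned. The default grid is 20 log-spaced values spanning
#' [0.1, 10] times the Scott's-rule plug-in estimate.
#'
#' @param X n x d training matrix.
#' @param grid candidate bandwidths; NULL for the default grid.
#' @param folds number of folds.
#' @param seed seed for the fold assignment.
#' @return List with \code{bandwidth}, \code{grid} and \code{loss}.
#' @export
cvBandwidth <- function(X, grid = NULL, folds = 5, seed = 42) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= folds)
  if (is.null(grid)) {
    h0 <- scottBandwidth(X)
    grid <- h0 * 10^seq(-1, 1, length.out = 20)
  }
  set.seed(seed)
  fold <- sample(rep_len(seq_len(folds), n))
  loss <- vapply(grid, function(h) {
    ll <- vapply(seq_len(folds), function(f) {
      dens <- kdeDensity(X[fold == f, , drop = FALSE],
                         X[fold != f, , drop = FALSE], h)
      -mean(log(pmax(dens, 1e-300)))
    }, numeric(1))
    mean(ll)
  }, numeric(1))
  list(bandwidth = grid[which.min(loss)], grid = grid, loss = loss)
}

#' Locate the density peak of one cluster
#'
#' Fits a cross-validated KDE to the cluster's embedding rows and minimizes
#' the negative density s(x) = -p(x) with L-BFGS-B under box bounds given
#' by the per-dimension minimum and maximum of the cluster's points, using
#' multiple restarts from the highest-density training points. Clusters
#' with fewer than 10 points fall back to the medoid (KDE cross-validation
#' is not meaningful at that size), with a warning.
#'
#' @param clusterPoints n x d matrix of embedding rows of one cluster.
#' @param seed seed for the CV fold assignment.
#' @param restarts number of optimizer restarts.
#' @param grid optional bandwidth grid passed to \code{\link{cvBandwidth}}.
#' @return A density model: list with \code{peak}, \code{bandwidth},
#'   \code{bounds}, \code{trainingPoints} and \code{method} ("kde" or
#'   "medoid").
#' @export
findDensityPeak <- function(clusterPoints, seed = 42, restarts = 8,
                            grid = NULL) {
  X <- as.matrix(clusterPoints)
  if (nrow(X) < 10L) {
    warning("cluster has fewer than 10 points; using the medoid instead of a KDE peak")
    d2 <- crossDist2(X, X)
    med <- which.min(rowSums(sqrt(d2)))
    return(list(peak = X[med, ], bandwidth = NA_real_,
                bounds = apply(X, 2, range), trainingPoints = X,
                method = "medoid"))
  }
  cv <- cvBandwidth(X, grid = grid, seed = seed)
  h <- cv$bandwidth
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  sx <- function(x) -kdeDensity(x, X, h)
  dens <- kdeDensity(X, X, h)
  starts <- X[order(-dens)[seq_len(min(restarts, nrow(X)))], , drop = FALSE]
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[i, ], sx, method = "L-BFGS-B",
                   lower = lo, upper = hi),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) stop("density-peak optimization failed for all restarts")
  peak <- pmin(pmax(best$par, lo), hi)
  list(peak = peak, bandwidth = h, bounds = rbind(lo, hi),
       trainingPoints = X, method = "kde", cv = cv)
}
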