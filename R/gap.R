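#' @include AllClasses.R kde.R geometry.R
#' @importFrom mclust Mclust mclustBIC
NULL

.stripHydrogens <- function(model) {
  keep <- toupper(atoms(model)$element) != "H"
  MolecularModel(atoms(model)[keep, , drop = FALSE], modelId = model@modelId)
}

.atomKey <- function(a) paste(a$chain, a$resno, a$insert, a$name, sep = "|")

#' Build a ConformationEnsemble from a list of models
#'
#' @param models list of \linkS4class{MolecularModel} (frames of one
#'   replica); hydrogens are stripped.
#' @param replica replica index recorded for every frame.
#' @return A \linkS4class{ConformationEnsemble}.
#' @export
ensembleFromModels <- function(models, replica = 0L) {
  models <- lapply(models, .stripHydrogens)
  ref <- atoms(models[[1]])
  frames <- array(NA_real_, c(length(models), nrow(ref), 3))
  refKey <- .atomKey(ref)
  for (i in seq_along(models)) {
    ai <- atoms(models[[i]])
    ord <- match(refKey, .atomKey(ai))
    if (anyNA(ord)) {
      miss <- refKey[which(is.na(ord))[1]]
      stop("replica frame ", i, " lacks atom ", miss)
    }
    frames[i, , ] <- coords(models[[i]])[ord, ]
  }
  meta <- ref[, c("name", "element", "resname", "resno", "chain")]
  rownames(meta) <- NULL
  new("ConformationEnsemble", frames = frames, atomMeta = meta,
      replicaOf = rep(as.integer(replica), length(models)))
}

#' Merge uncorrelated replicas into one ensemble
#'
#' Concatenates the frames of several replicas into a single dataset,
#' stripping all hydrogen atoms and recording the replica of origin per
#' frame. Replicas whose atoms are permuted but name-identical are
#' reordered to the first replica's atom ordering; any composition
#' mismatch is a hard error naming the first differing atom.
#'
#' @param trajectories list whose elements are
#'   \linkS4class{ConformationEnsemble} objects or lists of
#'   \linkS4class{MolecularModel} frames.
#' @return A merged \linkS4class{ConformationEnsemble}.
#' @export
mergeReplicas <- function(trajectories) {
  ens <- lapply(seq_along(trajectories), function(i) {
    tr <- trajectories[[i]]
    if (is(tr, "ConformationEnsemble")) tr
    else ensembleFromModels(tr, replica = i - 1L)
  })
  ref <- ens[[1]]@atomMeta
  refKey <- paste(ref$chain, ref$resno, ref$name, sep = "|")
  frames <- list()
  replicaOf <- integer(0)
  for (i in seq_along(ens)) {
    e <- ens[[i]]
    key <- paste(e@atomMeta$chain, e@atomMeta$resno, e@atomMeta$name,
                 sep = "|")
    ord <- match(refKey, key)
    if (anyNA(ord) || length(key) != length(refKey)) {
      bad <- if (anyNA(ord)) refKey[which(is.na(ord))[1]]
             else setdiff(key, refKey)[1]
      stop("replica ", i, " atom composition mismatch at atom ", bad)
    }
    frames[[i]] <- e@frames[, ord, , drop = FALSE]
    replicaOf <- c(replicaOf, rep(i - 1L, dim(e@frames)[1]))
  }
  all <- do.call(abind3, frames)
  new("ConformationEnsemble", frames = all, atomMeta = ref,
      replicaOf = replicaOf)
}

# rbind for F x N x 3 arrays along the frame axis
abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  out <- array(NA_real_, c(sum(vapply(parts, function(p) dim(p)[1],
                                      numeric(1))), d[2], d[3]))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

#' Flatten per-frame pairwise distance matrices
#'
#' For each frame, computes the Euclidean distance matrix over atoms and
#' flattens its lower triangle (excluding the diagonal) in column-major
#' order {g21, g31, ..., gn1, g32, ...}. The representation captures all
#' internal geometry and is exactly invariant under rigid-body motion of a
#' frame, so no superposition step is needed.
#'
#' @param ensemble a \linkS4class{ConformationEnsemble}.
#' @return F x p numeric matrix, p = N(N-1)/2, with attribute
#'   \code{flattenOrder}.
#' @export
flattenDistances <- function(ensemble) {
  fr <- ensemble@frames
  F_ <- dim(fr)[1]; N <- dim(fr)[2]
  stopifnot(N >= 2L)
  out <- matrix(NA_real_, F_, N * (N - 1) / 2)
  for (i in seq_len(F_)) {
    xyz <- fr[i, , ]
    if (!all(is.finite(xyz))) {
      bad <- which(!is.finite(xyz), arr.ind = TRUE)[1, 1]
      stop("non-finite coordinate in frame ", i, ", atom ", bad)
    }
    out[i, ] <- as.numeric(stats::dist(xyz))
  }
  attr(out, "flattenOrder") <- "column-major-lower-triangle"
  out
}

#' Reduce the distance representation by PCA
#'
#' Principal component analysis of the flattened-distance matrix (centered,
#' unscaled), keeping \code{dim} components. Three components retain the
#' geometry/efficiency balance used throughout the pipeline.
#'
#' @param flat F x p matrix from \code{\link{flattenDistances}}.
#' @param dim number of components.
#' @return List with \code{T} (F x dim scores), \code{components} (p x dim
#'   orthonormal loadings), \code{explainedVarianceRatio} and
#'   \code{cumulativeVariance}.
#' @export
reduceDimensionality <- function(flat, dim = 3) {
  stopifnot(nrow(flat) > dim)
  if (all(apply(flat, 2, stats::var) < 1e-18))
    stop("degenerate input: features have zero variance")
  pc <- stats::prcomp(flat, center = TRUE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  list(T = pc$x[, seq_len(dim), drop = FALSE],
       components = pc$rotation[, seq_len(dim), drop = FALSE],
       explainedVarianceRatio = evr[seq_len(dim)],
       cumulativeVariance = cumsum(evr)[seq_len(dim)])
}

#' Cluster the embedding with a Gaussian mixture, selecting k by silhouette
#'
#' Fits full-covariance Gaussian mixtures for every k in [kMin, kMax] and
#' returns the model with the maximal silhouette score (Euclidean metric on
#' the embedding); ties within 1e-6 go to the smaller k. Fits that fail are
#' skipped with a warning. With more than 50,000 frames the silhouette is
#' computed on a seeded subsample of 50,000.
#'
#' @param embedding list from \code{\link{reduceDimensionality}} or an
#'   F x dim matrix.
#' @param kMin,kMax search bounds (defaults 2 and 10).
#' @param seed RNG seed for reproducibility.
#' @return List with \code{nClusters}, \code{labels} (0-based),
#'   \code{means}, \code{covariances}, \code{mixtureWeights},
#'   \code{silhouetteByK} and \code{seed}.
#' @export
selectClusterCount <- function(embedding, kMin = 2, kMax = 10, seed = 42) {
  T_ <- if (is.list(embedding)) embedding$T else as.matrix(embedding)
  F_ <- nrow(T_)
  stopifnot(F_ >= kMax + 1)
  silIdx <- seq_len(F_)
  if (F_ > 50000L) {
    set.seed(childSeed(seed, "silhouette-subsample"))
    silIdx <- sort(sample.int(F_, 50000L))
    message("silhouette computed on a seeded subsample of 50000 frames")
  }
  dmat <- stats::dist(T_[silIdx, , drop = FALSE])
  fits <- list()
  silByK <- stats::setNames(rep(NA_real_, kMax - kMin + 1),
                            as.character(kMin:kMax))
  for (k in kMin:kMax) {
    set.seed(seed)
    fit <- tryCatch(
      Mclust(T_, G = k, modelNames = "VVV", verbose = FALSE),
      error = function(e) NULL)
    if (is.null(fit) || length(unique(fit$classification)) < 2L) {
      warning("Gaussian mixture fit failed or collapsed for k = ", k,
              "; skipped")
      next
    }
    sil <- cluster::silhouette(fit$classification[silIdx], dmat)
    silByK[as.character(k)] <- mean(sil[, "sil_width"])
    fits[[as.character(k)]] <- fit
  }
  if (!length(fits)) stop("all Gaussian mixture fits failed")
  best <- max(silByK, na.rm = TRUE)
  kBest <- min(as.integer(names(silByK)[!is.na(silByK) &
                                        silByK >= best - 1e-6]))
  fit <- fits[[as.character(kBest)]]
  list(nClusters = kBest,
       labels = as.integer(fit$classification) - 1L,
       means = t(fit$parameters$mean),
       covariances = fit$parameters$variance$sigma,
       mixtureWeights = fit$parameters$pro,
       silhouetteByK = silByK,
       seed = seed)
}

#' Assemble the conformer library
#'
#' For each cluster, the representative is the actual sampled frame whose
#' embedding row lies nearest (Euclidean) to the cluster's density peak --
#' not the centroid, which would average away conformational specificity.
#' Weights are cluster frame counts over the total frame count; empty
#' clusters are dropped with renormalization.
#'
#' @param ensemble the merged \linkS4class{ConformationEnsemble}.
#' @param embedding output of \code{\link{reduceDimensionality}}.
#' @param clusters output of \code{\link{selectClusterCount}}.
#' @param densityModels list of density models, one per cluster id in
#'   ascending order (see \code{\link{findDensityPeak}}).
#' @param glycanId identifier stored in the library.
#' @param metadata extra provenance merged into the library metadata.
#' @return A \linkS4class{ConformerLibrary}.
#' @export
buildConformerLibrary <- function(ensemble, embedding, clusters,
                                  densityModels, glycanId = "glycan",
                                  metadata = list()) {
  T_ <- if (is.list(embedding)) embedding$T else as.matrix(embedding)
  ids <- sort(unique(clusters$labels))
  stopifnot(length(densityModels) == length(ids))
  F_ <- nrow(T_)
  reps <- integer(0); ws <- numeric(0); cid <- integer(0)
  for (i in seq_along(ids)) {
    idx <- which(clusters$labels == ids[i])
    if (!length(idx)) {
      warning("cluster ", ids[i], " is empty; excluded")
      next
    }
    peak <- densityModels[[i]]$peak
    d2 <- rowSums(sweep(T_[idx, , drop = FALSE], 2, peak)^2)
    reps <- c(reps, idx[which.min(d2)])
    ws <- c(ws, length(idx) / F_)
    cid <- c(cid, ids[i])
  }
  structures <- lapply(reps, function(i) ensembleFrame(ensemble, i))
  meta <- c(list(frameIndex = reps,
                 replicaOf = ensemble@replicaOf[reps],
                 silhouetteByK = clusters$silhouetteByK,
                 seed = clusters$seed,
                 bandwidths = vapply(densityModels,
                                     function(d) d$bandwidth, numeric(1)),
                 clusterSizes = as.integer(round(ws * F_))),
            metadata)
  ConformerLibrary(structures, ws, clusterIds = cid, glycanId = glycanId,
                   metadata = meta)
}

#' Run the full conformer-extraction pipeline
#'
#' Merge replicas, flatten pairwise distances, reduce to a 3-D embedding,
#' cluster with silhouette-guided Gaussian mixtures, locate each cluster's
#' density peak and return the library of nearest-to-peak frames with
#' population weights. Deterministic given the input frames and seed.
#'
#' @param trajectories as in \code{\link{mergeReplicas}} (a single
#'   ensemble is also accepted).
#' @param dim embedding dimension.
#' @param kMin,kMax cluster-count search bounds.
#' @param seed RNG seed (default 42).
#' @param glycanId identifier stored in the library.
#' @return A \linkS4class{ConformerLibrary}.
#' @examples
#' \donttest{
#' pl <- makePlantedEnsemble(k = 2, nFrames = 120, seed = 7)
#' lib <- runConformerPipeline(pl$ensemble, seed = 42)
#' weights(lib)
#' }
#' @export
runConformerPipeline <- function(trajectories, dim = 3, kMin = 2, kMax = 10, seed = 42,
                   glycanId = "glycan") {
  ensemble <- if (is(trajectories, "ConformationEnsemble")) trajectories
              else mergeReplicas(trajectories)
  flat <- flattenDistances(ensemble)
  emb <- reduceDimensionality(flat, dim = dim)
  clusters <- selectClusterCount(emb, kMin = kMin, kMax = kMax, seed = seed)
  ids <- sort(unique(clusters$labels))
  dens <- lapply(ids, function(id)
    findDensityPeak(emb$T[clusters$labels == id, , drop = FALSE],
                    seed = childSeed(seed, paste0("kde", id))))
  buildConformerLibrary(ensemble, emb, clusters, dens, glycanId = glycanId,
                        metadata = list(
                          explainedVarianceRatio = emb$explainedVarianceRatio,
                          cumulativeVariance = emb$cumulativeVariance))
}

#' Per-frame torsion series and per-cluster circular histograms
#'
#' @param ensemble a \linkS4class{ConformationEnsemble}.
#' @param quartets list of integer 4-vectors (atom indices) or quartet
#'   objects from \code{\link{detectTorsionPairs}}.
#' @param labels optional cluster label per frame (0-based); histograms
#'   are computed per cluster when given.
#' @param binWidth histogram bin width, degrees (default 5).
#' @return List with \code{series} (F x Q matrix, NA for collinear
#'   geometry), \code{histograms} (per cluster, per quartet counts),
#'   \code{breaks} and \code{circularMeans}.
#' @export
torsionProfiles <- function(ensemble, quartets, labels = NULL, binWidth = 5) {
  qs <- lapply(quartets, function(q) if (is.list(q)) q$atoms else q)
  F_ <- nFrames(ensemble)
  series <- matrix(NA_real_, F_, length(qs))
  colnames(series) <- vapply(qs, paste, character(1), collapse = "-")
  for (i in seq_len(F_)) {
    xyz <- ensemble@frames[i, , ]
    for (j in seq_along(qs)) {
      series[i, j] <- tryCatch(measureDihedral(xyz[qs[[j]], ]),
                               error = function(e) NA_real_)
    }
  }
  breaks <- seq(-180, 180, by = binWidth)
  if (is.null(labels)) labels <- rep(0L, F_)
  hist <- lapply(sort(unique(labels)), function(l) {
    apply(series[labels == l, , drop = FALSE], 2, function(v)
      table(cut(v[!is.na(v)], breaks, include.lowest = TRUE)))
  })
  names(hist) <- paste0("cluster", sort(unique(labels)))
  cm <- apply(series, 2, circularMean)
  list(series = series, histograms = hist, breaks = breaks,
       circularMeans = cm, binWidth = binWidth)
}

#' Circular mean of angles in degrees
#'
#' @param deg numeric angles (NA dropped).
#' @return Mean direction in (-180, 180].
#' @export
circularMean <- function(deg) {
  deg <- deg[!is.na(deg)]
  if (!length(deg)) return(NA_real_)
  r <- deg * pi / 180
  wrapAngle(atan2(mean(sin(r)), mean(cos(r))) * 180 / pi)
}
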