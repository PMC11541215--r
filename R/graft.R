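#' @include AllClasses.R wiggle.R
NULL

# Protein atoms worth testing against a glycan anchored at cPos: everything
# within the glycan's maximal reach plus the clash threshold and a margin.
.nearbyProtein <- function(proteinXYZ, pose, threshold) {
  reach <- max(sqrt(rowSums(sweep(coords(pose$glycan), 2, pose$cPos)^2)))
  d2 <- rowSums(sweep(proteinXYZ, 2, pose$cPos)^2)
  # phi/psi rotations keep glycan-to-anchor distances fixed; the margin
  # covers the extra reach internal wiggle torsions can add
  proteinXYZ[d2 <= (reach + threshold + 8)^2, , drop = FALSE]
}

#' Graft one glycan library onto one site
#'
#' Runs the conformer cascade: conformers are tried in descending
#' population order (G0 first); for each, the linkage torsions are
#' optimized by the genetic algorithm, and the first clash-free result
#' wins. If every conformer retains clashes, the pose with the lowest
#' steric loss enters the stochastic torsion-refinement ("wiggle") phase.
#'
#' @param protein a \linkS4class{MolecularModel}.
#' @param site site reference ("A:45" or list).
#' @param library a \linkS4class{ConformerLibrary}.
#' @param linkage a \linkS4class{LinkageSpec} (default: the N-GlcNAc entry
#'   of the shipped table).
#' @param config a \code{\link{gaConfig}}.
#' @param seed master seed; per-cluster sub-seeds are derived from it.
#' @param extraProtein optional extra coordinates added to the protein
#'   atom set (e.g. previously grafted glycans).
#' @return A \linkS4class{GraftResult}.
#' @export
graftSite <- function(protein, site, library, linkage = NULL,
                      config = gaConfig(), seed = 1L, extraProtein = NULL) {
  if (is.null(linkage)) linkage <- getLinkage("N-GlcNAc")
  stopifnot(nConformers(library) >= 1L)
  proteinXYZ <- coords(protein)
  if (!is.null(extraProtein)) proteinXYZ <- rbind(proteinXYZ, extraProtein)
  tried <- integer(0)
  triedFit <- numeric(0)
  bestGA <- NULL
  for (e in seq_len(nConformers(library))) {
    cid <- library@clusterIds[e]
    pose0 <- attachReducingEnd(protein, site, structures(library)[[e]],
                               linkage)
    P <- .nearbyProtein(proteinXYZ, pose0, config$threshold)
    fitnessFn <- function(phi, psi) {
      stericFitness(P, coords(setLinkageTorsions(pose0, phi, psi)$glycan),
                    threshold = config$threshold,
                    exclude = pose0$exclude)$fitness
    }
    ga <- gaOptimize(fitnessFn, linkage@phiRange, linkage@psiRange,
                     config = config,
                     seed = childSeed(seed, paste0("ga", cid)))
    tried <- c(tried, cid)
    triedFit <- c(triedFit, ga$fitness)
    pose <- .evalPose(setLinkageTorsions(pose0, ga$phi, ga$psi), P,
                      config$threshold)
    if (is.null(bestGA) || pose$fitness < bestGA$pose$fitness)
      bestGA <- list(pose = pose, clusterId = cid, P = P)
    if (ga$fitness == 0) {
      return(new("GraftResult", success = TRUE, pose = pose, phase = "ga",
                 clusterId = cid, clustersTried = tried,
                 clusterFitness = triedFit, wiggleIterationsUsed = 0L,
                 site = siteLabel(site)))
    }
  }
  wr <- wiggleRefine(bestGA$pose, bestGA$P, config = config,
                     seed = childSeed(seed, "wiggle"))
  new("GraftResult", success = wr$success, pose = wr$pose,
      phase = "wiggle", clusterId = bestGA$clusterId,
      clustersTried = tried, clusterFitness = triedFit,
      wiggleIterationsUsed = wr$iterations, site = siteLabel(site))
}

# Append a grafted glycan to a protein model, renumbering the glycan
# residues past the current maximum and adding the covalent CONECT bond.
.appendGlycan <- function(protein, result) {
  g <- result@pose$glycan
  ga <- atoms(g)
  s <- parseSite(result@site)
  resKey <- paste(ga$chain, ga$resno, ga$insert)
  newNo <- max(atoms(protein)$resno) + as.integer(factor(resKey,
                                                  levels = unique(resKey)))
  ga$resno <- newNo
  ga$chain <- s$chain
  ga$insert <- ""
  off <- nAtoms(protein)
  gm <- MolecularModel(ga, bonds = bonds(g))
  linkBond <- cbind(result@pose$cProteinIdx, off + result@pose$bIdx)
  mergeModels(protein, gm, extraBonds = linkBond)
}

#' Graft glycans onto many sites of a protein
#'
#' Sites are processed in residue order. By default every successfully
#' grafted glycan joins the protein atom set for subsequent sites, so
#' later grafts cannot overlap earlier ones; disable with
#' \code{includeGrafted = FALSE}. In "one_shot" mode the same library is
#' used at every site; in "site_by_site" mode \code{sitePlan} maps each
#' site label to its own library (and optionally linkage).
#'
#' @param protein a \linkS4class{MolecularModel}.
#' @param sites character vector of site labels (one_shot mode).
#' @param library a \linkS4class{ConformerLibrary} (one_shot mode).
#' @param linkage a \linkS4class{LinkageSpec}; default N-GlcNAc.
#' @param mode "one_shot" or "site_by_site".
#' @param sitePlan named list (site label -> list(library, linkage)) for
#'   site_by_site mode.
#' @param config a \code{\link{gaConfig}}.
#' @param seed master seed; per-site sub-seeds are derived from it.
#' @param includeGrafted earlier glycans join the protein set.
#' @return List with \code{model} (the glycoprotein
#'   \linkS4class{MolecularModel}) and \code{results} (per-site
#'   \linkS4class{GraftResult} list, named by site).
#' @export
graftProtein <- function(protein, sites = NULL, library = NULL,
                         linkage = NULL,
                         mode = c("one_shot", "site_by_site"),
                         sitePlan = NULL, config = gaConfig(), seed = 1L,
                         includeGrafted = TRUE) {
  mode <- match.arg(mode)
  if (is.null(linkage)) linkage <- getLinkage("N-GlcNAc")
  if (mode == "one_shot") {
    stopifnot(!is.null(sites), !is.null(library))
    sitePlan <- stats::setNames(
      lapply(sites, function(s) list(library = library, linkage = linkage)),
      vapply(sites, siteLabel, character(1)))
  }
  if (!length(sitePlan))
    return(list(model = protein, results = list()))
  ord <- order(vapply(names(sitePlan),
                      function(s) parseSite(s)$resno, numeric(1)))
  sitePlan <- sitePlan[ord]
  current <- protein
  results <- list()
  for (lbl in names(sitePlan)) {
    plan <- sitePlan[[lbl]]
    lk <- if (is.null(plan$linkage)) linkage else plan$linkage
    res <- tryCatch(
      graftSite(current, lbl, plan$library, lk, config = config,
                seed = childSeed(seed, lbl)),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning("site ", lbl, " failed: ", conditionMessage(res))
      results[[lbl]] <- res
      next
    }
    results[[lbl]] <- res
    if (res@success && includeGrafted)
      current <- .appendGlycan(current, res)
  }
  if (!includeGrafted) {
    for (lbl in names(results)) {
      r <- results[[lbl]]
      if (is(r, "GraftResult") && r@success)
        current <- .appendGlycan(current, r)
    }
  }
  list(model = current, results = results)
}
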