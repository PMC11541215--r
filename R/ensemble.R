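#' @include AllClasses.R graft.R sasa.R
NULL

#' Fit multiple trajectory frames at one site (exclusion-volume sampling)
#'
#' Per repeat, \code{nFrames} frames are drawn from the free-glycan
#' trajectory (without replacement; with replacement plus a warning when
#' the trajectory is shorter), each is attached to the site with linkage
#' torsions drawn uniformly from the configured ranges, and the pose is
#' kept iff no protein-glycan atom pair is closer than the clash
#' threshold. The default protocol is 200 frames and 5 repeats.
#'
#' @param protein a \linkS4class{MolecularModel}.
#' @param site site reference.
#' @param trajectory a \linkS4class{ConformationEnsemble} of the free
#'   glycan.
#' @param linkage a \linkS4class{LinkageSpec}; default N-GlcNAc.
#' @param nFrames frames per repeat (default 200).
#' @param repeats number of repeats (default 5).
#' @param seed RNG seed.
#' @param threshold clash distance, Angstrom (default 1.7).
#' @param withSasa also compute per-model SASA of the accepted
#'   complexes (slower).
#' @param clashAtoms protein atom indices included in the clash test
#'   (default all); an empty integer vector simulates a site with no
#'   surrounding protein.
#' @param dotsPerSphere dots per sphere for the SASA stage.
#' @return An \linkS4class{EnsembleResult}.
#' @export
ensembleFit <- function(protein, site, trajectory, linkage = NULL,
                        nFrames = 200L, repeats = 5L, seed = 1L,
                        threshold = 1.7, withSasa = FALSE,
                        dotsPerSphere = 15, clashAtoms = NULL) {
  if (is.null(linkage)) linkage <- getLinkage("N-GlcNAc")
  F_ <- dim(trajectory@frames)[1]   # nFrames() is shadowed by the argument
  replace <- F_ < nFrames
  if (replace)
    warning("trajectory has ", F_, " < ", nFrames,
            " frames; drawing with replacement")
  proteinXYZ <- coords(protein)
  if (!is.null(clashAtoms))
    proteinXYZ <- proteinXYZ[clashAtoms, , drop = FALSE]
  accepted <- list()
  rejected <- 0L
  acceptedModels <- list()
  pose0 <- NULL
  for (rep_ in seq_len(repeats)) {
    set.seed(childSeed(seed, paste0("rep", rep_)))
    drawn <- if (replace) sample.int(F_, nFrames, replace = TRUE)
             else sample.int(F_, nFrames)
    phis <- stats::runif(nFrames, linkage@phiRange[1], linkage@phiRange[2])
    psis <- stats::runif(nFrames, linkage@psiRange[1], linkage@psiRange[2])
    for (i in seq_len(nFrames)) {
      frame <- ensembleFrame(trajectory, drawn[i])
      pose <- attachReducingEnd(protein, site, frame, linkage)
      if (is.null(pose0)) pose0 <- pose
      pose <- setLinkageTorsions(pose, phis[i], psis[i])
      fit <- stericFitness(proteinXYZ, coords(pose$glycan),
                           threshold = threshold,
                           exclude = pose$exclude)$fitness
      if (fit == 0) {
        accepted[[length(accepted) + 1L]] <- data.frame(
          repeat_index = rep_, frame = drawn[i], phi = phis[i],
          psi = psis[i])
        acceptedModels[[length(acceptedModels) + 1L]] <- pose$glycan
      } else rejected <- rejected + 1L
    }
  }
  acc <- if (length(accepted)) do.call(rbind, accepted)
         else data.frame(repeat_index = integer(0), frame = integer(0),
                         phi = numeric(0), psi = numeric(0))
  sasa <- numeric(0)
  if (withSasa && length(acceptedModels)) {
    complexes <- lapply(acceptedModels, function(g)
      mergeGlycanComplex(protein, g))
    sasa <- computeSasa(complexes, dotsPerSphere = dotsPerSphere)
  }
  new("EnsembleResult", accepted = acc, rejectedCount = rejected,
      nFrames = as.integer(nFrames), repeats = as.integer(repeats),
      sasaPerModel = sasa,
      parameters = list(seed = seed, threshold = threshold,
                        site = siteLabel(site),
                        glycoType = linkage@glycoType))
}

#' Merge a positioned glycan with a protein into one complex model
#'
#' @param protein a \linkS4class{MolecularModel}.
#' @param glycan a positioned glycan \linkS4class{MolecularModel}.
#' @return A merged \linkS4class{MolecularModel} (glycan residues
#'   renumbered past the protein's).
#' @export
mergeGlycanComplex <- function(protein, glycan) {
  ga <- atoms(glycan)
  resKey <- paste(ga$chain, ga$resno, ga$insert)
  ga$resno <- max(atoms(protein)$resno) +
    as.integer(factor(resKey, levels = unique(resKey)))
  ga$chain <- atoms(protein)$chain[1]
  ga$insert <- ""
  mergeModels(protein, MolecularModel(ga, bonds = bonds(glycan)))
}

#' Accepted ensemble poses as a multi-model complex
#'
#' @param protein the protein used in \code{\link{ensembleFit}}.
#' @param site the site reference.
#' @param trajectory the free-glycan trajectory.
#' @param result an \linkS4class{EnsembleResult}.
#' @param linkage linkage spec used for the fit.
#' @return List of complex \linkS4class{MolecularModel} objects, one per
#'   accepted pose (suitable for \code{\link{writeStructure}}).
#' @export
ensembleComplexes <- function(protein, site, trajectory, result,
                              linkage = NULL) {
  if (is.null(linkage)) linkage <- getLinkage("N-GlcNAc")
  acc <- result@accepted
  lapply(seq_len(nrow(acc)), function(i) {
    pose <- attachReducingEnd(protein, site,
                              ensembleFrame(trajectory, acc$frame[i]),
                              linkage)
    pose <- setLinkageTorsions(pose, acc$phi[i], acc$psi[i])
    mergeGlycanComplex(protein, pose$glycan)
  })
}
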