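#' @include AllClasses.R utils.R
NULL

# van der Waals radii (Angstrom) for SASA; overridable via radiiTable.
.VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                P = 1.80, F = 1.47, SE = 1.90, CL = 1.75, BR = 1.85)

# Deterministic quasi-uniform sphere points (golden-spiral lattice).
sphereDots <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley dot sampling)
#'
#' Each atom is inflated by the probe radius and sampled with a fixed
#' quasi-uniform dot lattice; a dot survives if it lies outside every
#' neighbouring inflated sphere, and the atom's accessible area is the
#' surviving fraction of its inflated-sphere area. Results are reported in
#' nm^2. The default probe parameter is 0.14 nm interpreted as the probe
#' radius (water); \code{probeMode = "diameter"} halves it for tools whose
#' 0.14 nm setting means the diameter.
#'
#' @param models a \linkS4class{MolecularModel} or list thereof (a
#'   multi-model complex).
#' @param probe probe size in nm (default 0.14).
#' @param dotsPerSphere dots per atom sphere (default 15; increase for
#'   tighter discretization).
#' @param radiiTable named vector of van der Waals radii in Angstrom,
#'   keyed by element symbol; unknown elements are an error.
#' @param probeMode interpret \code{probe} as "radius" or "diameter".
#' @return Numeric vector: SASA in nm^2 per model.
#' @examples
#' # isolated sphere: area approaches 4*pi*(r+p)^2 as dots increase
#' a <- data.frame(serial = 1, name = "C", element = "C", resname = "DUM",
#'                 chain = "A", resno = 1, insert = "", x = 0, y = 0, z = 0,
#'                 occupancy = 1, b = 0, type = "HETATM")
#' computeSasa(MolecularModel(a), dotsPerSphere = 960)
#' @export
computeSasa <- function(models, probe = 0.14, dotsPerSphere = 15,
                        radiiTable = NULL, probeMode = c("radius",
                                                         "diameter")) {
  probeMode <- match.arg(probeMode)
  if (is(models, "MolecularModel")) models <- list(models)
  tab <- if (is.null(radiiTable)) .VDW_RADII else radiiTable
  pr <- probe * 10                       # nm -> Angstrom
  if (probeMode == "diameter") pr <- pr / 2
  dots <- sphereDots(dotsPerSphere)
  vapply(models, function(m) {
    el <- toupper(atoms(m)$element)
    unknown <- setdiff(unique(el), names(tab))
    if (length(unknown))
      stop("no van der Waals radius for element: ",
           paste(unknown, collapse = ", "))
    r <- unname(tab[el]) + pr
    xyz <- coords(m)
    n <- nrow(xyz)
    total <- 0
    for (i in seq_len(n)) {
      d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
      nb <- which(d2 < (r + r[i])^2 & seq_len(n) != i)
      pts <- sweep(dots * r[i], 2, xyz[i, ], "+")
      if (length(nb)) {
        buried <- rep(FALSE, nrow(pts))
        for (j in nb)
          buried <- buried |
            rowSums(sweep(pts, 2, xyz[j, ])^2) < r[j]^2
        expo <- sum(!buried)
      } else expo <- nrow(pts)
      total <- total + 4 * pi * r[i]^2 * expo / nrow(pts)
    }
    total / 100                          # Angstrom^2 -> nm^2
  }, numeric(1))
}

#' Glycan occlusion of the protein surface
#'
#' Reports the exclusion effect of a fitted glycan ensemble as
#' Delta-SASA = SASA(protein alone) - mean over models of SASA(protein
#' within complex), in nm^2.
#'
#' @param protein a \linkS4class{MolecularModel}.
#' @param complexes list of complex models whose first
#'   \code{nAtoms(protein)} atoms are the protein.
#' @param ... passed to \code{\link{computeSasa}}.
#' @return List with \code{sasaProtein}, \code{sasaWithinComplex} (per
#'   model, protein contribution only) and \code{deltaSasa}.
#' @export
deltaSasa <- function(protein, complexes, ...) {
  base <- computeSasa(protein, ...)
  nP <- nAtoms(protein)
  within <- vapply(complexes, function(cm) {
    .proteinSasaInComplex(cm, nP, ...)
  }, numeric(1))
  list(sasaProtein = base, sasaWithinComplex = within,
       deltaSasa = base - mean(within))
}

.proteinSasaInComplex <- function(complexModel, nProtein, probe = 0.14,
                                  dotsPerSphere = 15, radiiTable = NULL,
                                  probeMode = "radius") {
  tab <- if (is.null(radiiTable)) .VDW_RADII else radiiTable
  pr <- probe * 10
  if (probeMode == "diameter") pr <- pr / 2
  dots <- sphereDots(dotsPerSphere)
  el <- toupper(atoms(complexModel)$element)
  r <- unname(tab[el]) + pr
  if (anyNA(r)) stop("no van der Waals radius for element: ",
                     paste(unique(el[is.na(r)]), collapse = ", "))
  xyz <- coords(complexModel)
  n <- nrow(xyz)
  total <- 0
  for (i in seq_len(nProtein)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (r + r[i])^2 & seq_len(n) != i)
    pts <- sweep(dots * r[i], 2, xyz[i, ], "+")
    buried <- rep(FALSE, nrow(pts))
    for (j in nb)
      buried <- buried | rowSums(sweep(pts, 2, xyz[j, ])^2) < r[j]^2
    total <- total + 4 * pi * r[i]^2 * sum(!buried) / nrow(pts)
  }
  total / 100
}
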