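#' @include AllClasses.R geometry.R graph.R linkage.R gap.R
NULL

# ---------------------------------------------------------------------------
# Deterministic generators for every input class the package needs in tests:
# an idealized GlcNAc-like monosaccharide, a linked disaccharide with planted
# torsional conformers, an extended-chain peptide with sequon sidechains, and
# a parametric spherical pocket with analytically known feasibility.
# ---------------------------------------------------------------------------

.hetAtomRow <- function(name, xyz, resname = "NAG", resno = 1L,
                        chain = "G", serial = 1L) {
  data.frame(serial = as.integer(serial), name = name,
             element = elementFromName(name), resname = resname,
             chain = chain, resno = as.integer(resno), insert = "",
             x = xyz[1], y = xyz[2], z = xyz[3],
             occupancy = 1, b = 0, type = "HETATM",
             stringsAsFactors = FALSE)
}

# Chair-like pyranose ring template: C1 C2 C3 C4 C5 O5, alternating pucker.
.ringTemplate <- function() {
  k <- 0:5
  r <- 1.43; z0 <- 0.25
  xyz <- cbind(r * cos(k * pi / 3), r * sin(k * pi / 3),
               z0 * (-1)^k)
  rownames(xyz) <- c("C1", "C2", "C3", "C4", "C5", "O5")
  xyz
}

# Substituent along the mean open direction of an sp3 ring atom.
.meanDirection <- function(xyz, at, neighbours, length) {
  dirs <- t(apply(xyz[neighbours, , drop = FALSE], 1,
                  function(p) vunit(p - xyz[at, ])))
  xyz[at, ] + length * vunit(-colSums(dirs))
}

#' Idealized GlcNAc-like monosaccharide
#'
#' A 15-heavy-atom pyranose with the topology of N-acetylglucosamine: the
#' C1-C5/O5 ring, the anomeric hydroxyl O1 (displaced on attachment), the
#' N-acetyl arm N2-C7(=O7)-C8, hydroxyls O3/O4 and the exocyclic C6-O6
#' arm. The geometry is idealized (no force field) but chemically
#' plausible, and the torsion-pair detector finds at least three rotatable
#' quartets on it. Used as the scanning probe and as the reducing-end
#' residue of the planted disaccharide.
#'
#' @param resno residue number (default 1).
#' @param chain chain identifier (default "G").
#' @return A \linkS4class{MolecularModel} with explicit bonds.
#' @export
makeToyGlycan <- function(resno = 1L, chain = "G") {
  ring <- .ringTemplate()
  names <- rownames(ring)
  xyz <- ring
  addAtom <- function(name, pos) {
    xyz <<- rbind(xyz, pos)
    names <<- c(names, name)
  }
  idx <- function(nm) match(nm, names)
  addAtom("O1", .meanDirection(xyz, idx("C1"), idx(c("C2", "O5")), 1.43))
  addAtom("N2", .meanDirection(xyz, idx("C2"), idx(c("C1", "C3")), 1.47))
  addAtom("O3", .meanDirection(xyz, idx("C3"), idx(c("C2", "C4")), 1.43))
  addAtom("O4", .meanDirection(xyz, idx("C4"), idx(c("C3", "C5")), 1.43))
  addAtom("C6", .meanDirection(xyz, idx("C5"), idx(c("C4", "O5")), 1.52))
  addAtom("C7", nerfPlace(xyz[idx("C1"), ], xyz[idx("C2"), ],
                          xyz[idx("N2"), ], 1.34, 122, 150))
  addAtom("O7", nerfPlace(xyz[idx("C2"), ], xyz[idx("N2"), ],
                          xyz[idx("C7"), ], 1.23, 122, 0))
  addAtom("C8", nerfPlace(xyz[idx("C2"), ], xyz[idx("N2"), ],
                          xyz[idx("C7"), ], 1.51, 116, 180))
  addAtom("O6", nerfPlace(xyz[idx("C4"), ], xyz[idx("C5"), ],
                          xyz[idx("C6"), ], 1.43, 109.5, 60))
  bondNames <- rbind(
    c("C1", "C2"), c("C2", "C3"), c("C3", "C4"), c("C4", "C5"),
    c("C5", "O5"), c("O5", "C1"), c("C1", "O1"), c("C2", "N2"),
    c("C3", "O3"), c("C4", "O4"), c("C5", "C6"), c("N2", "C7"),
    c("C7", "O7"), c("C7", "C8"), c("C6", "O6"))
  atomsDf <- do.call(rbind, lapply(seq_along(names), function(i)
    .hetAtomRow(names[i], xyz[i, ], resno = resno, chain = chain,
                serial = i)))
  MolecularModel(atomsDf,
                 bonds = cbind(match(bondNames[, 1], names),
                               match(bondNames[, 2], names)))
}

#' Single-GlcNAc probe library for occupancy scanning
#'
#' A one-entry \linkS4class{ConformerLibrary} holding the idealized
#' GlcNAc (weight 1, cluster 0).
#'
#' @return A \linkS4class{ConformerLibrary}.
#' @export
glcnacProbeLibrary <- function() {
  ConformerLibrary(list(makeToyGlycan()), weights = 1,
                   clusterIds = 0L, glycanId = "GlcNAc-probe",
                   metadata = list(kind = "single-GlcNAc probe"))
}

# 1->4 linked disaccharide of two toy pyranoses; ring B is anchored through
# the O4 of ring A. Returns the model plus the planted torsion quartets
# (phi-like, psi-like, omega-like) as atom-name quadruples.
.makeDisaccharide <- function() {
  m <- makeToyGlycan()
  names <- atoms(m)$name
  xyz <- coords(m)
  idx <- function(nm) match(nm, names)
  c1b <- nerfPlace(xyz[idx("C3"), ], xyz[idx("C4"), ], xyz[idx("O4"), ],
                   1.43, 117, -90)
  o5b <- nerfPlace(xyz[idx("C4"), ], xyz[idx("O4"), ], c1b, 1.43, 109.5, 60)
  c2b <- nerfPlace(xyz[idx("C4"), ], xyz[idx("O4"), ], c1b, 1.53, 109.5, 180)
  ring <- .ringTemplate()
  tr <- kabschTransform(ring[c("C1", "O5", "C2"), ], rbind(c1b, o5b, c2b))
  ringB <- tr(ring)
  aB <- do.call(rbind, lapply(seq_len(6), function(i)
    .hetAtomRow(rownames(ring)[i], ringB[i, ], resname = "BGC",
                resno = 2L, chain = "G", serial = nAtoms(m) + i)))
  bondsB <- cbind(nAtoms(m) + 1:6, nAtoms(m) + c(2:6, 1))
  linkBond <- cbind(idx("O4"), nAtoms(m) + 1L)
  model <- MolecularModel(rbind(atoms(m), aB),
                          bonds = rbind(bonds(m), bondsB, linkBond))
  list(model = model,
       torsions = list(
         phi = c("C4", "O4", "C1|2", "O5|2"),   # about the O4-C1' bond
         psi = c("C3", "C4", "O4", "C1|2"),     # about the C4-O4 bond
         omega = c("C4", "C5", "C6", "O6")))    # exocyclic arm of ring A
}

# Resolve "NAME" or "NAME|RESNO" atom references against a model.
.namedQuartet <- function(model, names4) {
  a <- atoms(model)
  vapply(names4, function(nm) {
    parts <- strsplit(nm, "|", fixed = TRUE)[[1]]
    rn <- if (length(parts) == 2L) as.integer(parts[2]) else 1L
    w <- which(a$name == parts[1] & a$resno == rn)
    if (!length(w)) stop("fixture atom not found: ", nm)
    w[1]
  }, integer(1), USE.NAMES = FALSE)
}

# Moving set when rotating about the j-k bond of a quartet: the component
# containing k (and l) after cutting the bond.
.movingSet <- function(graph, j, k) {
  g2 <- igraph::delete_edges(graph@graph,
                             igraph::get_edge_ids(graph@graph, c(j, k)))
  comp <- igraph::components(g2)$membership
  which(comp == comp[k])
}

#' Planted-conformer ensemble generator
#'
#' Builds a two-ring branched disaccharide and emits frames whose three
#' rotatable linkage torsions (phi-like and psi-like glycosidic torsions
#' plus the exocyclic omega arm) are Gaussian-perturbed around k planted
#' cluster centers. The generator's own labels are returned and serve as
#' the ground truth for parameter-recovery tests. Identical spec + seed
#' gives identical coordinate stacks.
#'
#' @param k number of planted conformers (<= 4 with default centers).
#' @param centers k x 3 matrix of torsion centers, degrees; defaults are
#'   gauche+/trans/gauche-/skew combinations separated by >= 120 degrees.
#' @param spread Gaussian torsion standard deviation, degrees (default 8;
#'   default centers are separated by more than 6 spreads, the
#'   "well-separated" regime).
#' @param proportions cluster proportions (sum 1); default uniform.
#' @param nFrames total frames.
#' @param nReplicas frames are split round-robin into this many replicas.
#' @param seed RNG seed.
#' @return List with \code{ensemble} (a
#'   \linkS4class{ConformationEnsemble}), \code{labels} (0-based planted
#'   label per frame), \code{centers}, \code{torsions} (planted per-frame
#'   angles) and \code{quartets} (atom-index quadruples of the varied
#'   torsions).
#' @export
makePlantedEnsemble <- function(k = 3, centers = NULL, spread = 8,
                                proportions = NULL, nFrames = 300,
                                nReplicas = 2, seed = 1L) {
  defaults <- rbind(c(60, 60, 60), c(180, 180, 180), c(-60, -60, -60),
                    c(60, 180, -60))
  if (is.null(centers)) {
    stopifnot(k <= nrow(defaults))
    centers <- defaults[seq_len(k), , drop = FALSE]
  }
  centers <- as.matrix(centers)
  stopifnot(nrow(centers) == k, ncol(centers) == 3)
  if (is.null(proportions)) proportions <- rep(1 / k, k)
  stopifnot(abs(sum(proportions) - 1) < 1e-9)
  dis <- .makeDisaccharide()
  base <- dis$model
  graph <- buildGraph(base)
  quartets <- lapply(dis$torsions, function(nm) .namedQuartet(base, nm))
  moving <- lapply(quartets, function(q) .movingSet(graph, q[2], q[3]))
  set.seed(seed)
  labels <- sample(seq_len(k) - 1L, nFrames, replace = TRUE,
                   prob = proportions)
  torsions <- centers[labels + 1L, , drop = FALSE] +
    matrix(stats::rnorm(nFrames * 3, 0, spread), nFrames, 3)
  frames <- array(NA_real_, c(nFrames, nAtoms(base), 3))
  for (f in seq_len(nFrames)) {
    m <- base
    for (t in 1:3)
      m <- setDihedral(m, quartets[[t]], wrapAngle(torsions[f, t]),
                       movingSet = moving[[t]])
    frames[f, , ] <- coords(m)
  }
  meta <- atoms(base)[, c("name", "element", "resname", "resno", "chain")]
  rownames(meta) <- NULL
  ens <- new("ConformationEnsemble", frames = frames, atomMeta = meta,
             replicaOf = as.integer((seq_len(nFrames) - 1L) %% nReplicas))
  list(ensemble = ens, labels = labels, centers = centers,
       torsions = torsions, quartets = quartets)
}

.AA1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

#' Extended-chain peptide with sequon-ready sidechains
#'
#' Builds an idealized fully extended backbone (N, CA, C, O per residue,
#' CB for non-glycine) from a one-letter sequence, with sidechain stubs
#' sufficient for sequon detection and glycan attachment: Asn carries
#' CG/OD1/ND2, Ser OG, Thr OG1/CG2, Trp CG/CD1. Author numbering starts at
#' 1 + \code{numberingOffset}.
#'
#' @param sequence one-letter amino-acid string.
#' @param numberingOffset added to every residue number.
#' @param chain chain identifier.
#' @return A \linkS4class{MolecularModel} (ATOM records, no bonds).
#' @examples
#' p <- makeSequonProtein("ANASA", numberingOffset = 3)
#' findSequons(p)$resno   # 5: numbering is sourced from the structure
#' @export
makeSequonProtein <- function(sequence, numberingOffset = 0L, chain = "A") {
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  if (any(!letters1 %in% names(.AA1TO3)))
    stop("unknown residue letter: ",
         letters1[!letters1 %in% names(.AA1TO3)][1])
  nRes <- length(letters1)
  rows <- list()
  addRow <- function(name, resname, resno, pos) {
    r <- .hetAtomRow(name, pos, resname = resname, resno = resno,
                     chain = chain, serial = length(rows) + 1L)
    r$type <- "ATOM"
    rows[[length(rows) + 1L]] <<- r
  }
  # backbone trace, fully extended (phi = psi = 180, omega = 180)
  N <- c(0, 0, 0); CA <- c(1.46, 0, 0)
  C <- nerfPlace(c(0, 1, 0), N, CA, 1.52, 111, -150)
  for (i in seq_len(nRes)) {
    resname <- .AA1TO3[[letters1[i]]]
    resno <- i + numberingOffset
    O <- nerfPlace(N, CA, C, 1.23, 121, 0)
    addRow("N", resname, resno, N)
    addRow("CA", resname, resno, CA)
    addRow("C", resname, resno, C)
    addRow("O", resname, resno, O)
    if (resname != "GLY") {
      CB <- nerfPlace(N, C, CA, 1.53, 110, -122)
      addRow("CB", resname, resno, CB)
      if (resname == "ASN") {
        CG <- nerfPlace(N, CA, CB, 1.52, 113, 180)
        OD1 <- nerfPlace(CA, CB, CG, 1.23, 121, -60)
        ND2 <- nerfPlace(CA, CB, CG, 1.33, 116, 120)
        addRow("CG", resname, resno, CG)
        addRow("OD1", resname, resno, OD1)
        addRow("ND2", resname, resno, ND2)
      } else if (resname == "SER") {
        addRow("OG", resname, resno, nerfPlace(N, CA, CB, 1.42, 111, 180))
      } else if (resname == "THR") {
        addRow("OG1", resname, resno, nerfPlace(N, CA, CB, 1.43, 110, 180))
        addRow("CG2", resname, resno, nerfPlace(N, CA, CB, 1.52, 111, -60))
      } else if (resname == "TRP") {
        CG <- nerfPlace(N, CA, CB, 1.50, 114, 180)
        addRow("CG", resname, resno, CG)
        addRow("CD1", resname, resno, nerfPlace(CA, CB, CG, 1.37, 127, 90))
      }
    }
    # next residue's backbone
    Nn <- nerfPlace(N, CA, C, 1.33, 116, 180)
    CAn <- nerfPlace(CA, C, Nn, 1.46, 122, 180)
    Cn <- nerfPlace(C, Nn, CAn, 1.52, 111, 180)
    N <- Nn; CA <- CAn; C <- Cn
  }
  MolecularModel(do.call(rbind, rows))
}

#' Parametric pocket protein with analytically known feasibility
#'
#' An extended-chain peptide with one N-X-S sequon whose Asn sidechain is
#' surrounded by a rigid spherical shell of carbon pseudo-atoms. The shell
#' is centered 3 A out along the amide attachment direction and has radius
#' \code{3 + clearance} A, so a single-GlcNAc probe fits iff every glycan
#' atom can stay more than the clash threshold (1.7 A) inside the shell:
#' feasibility is monotone in \code{clearance} with a single no-to-yes
#' transition. Carbon pseudo-atoms keep the 1.7 A threshold analysis
#' exact.
#'
#' @param clearance shell radius minus the 3 A base, Angstrom (>= 0).
#' @param seed unused (the fixture is deterministic); kept for interface
#'   uniformity.
#' @param dotSpacing approximate shell dot spacing, Angstrom.
#' @return List with \code{model} (protein + shell), \code{site} (the
#'   sequon label), \code{center} (shell center) and \code{radius}.
#' @export
makePocketProtein <- function(clearance, seed = 1L, dotSpacing = 0.8) {
  stopifnot(clearance >= 0)
  base <- makeSequonProtein("GNASG")
  a <- atoms(base)
  asn <- which(a$resname == "ASN")
  nd2 <- asn[a$name[asn] == "ND2"]
  cg <- asn[a$name[asn] == "CG"]
  xyz <- coords(base)
  v <- vunit(xyz[nd2, ] - xyz[cg, ])
  center <- xyz[nd2, ] + 3 * v
  radius <- 3 + clearance
  nDots <- max(12L, ceiling(4 * pi * radius^2 / dotSpacing^2))
  shell <- sweep(sphereDots(nDots) * radius, 2, center, "+")
  shellRows <- do.call(rbind, lapply(seq_len(nrow(shell)), function(i) {
    r <- .hetAtomRow("C", shell[i, ], resname = "DUM", resno = 1000L + i,
                     chain = "X", serial = nrow(a) + i)
    r
  }))
  model <- MolecularModel(rbind(a, shellRows))
  list(model = model, site = paste0(a$chain[asn[1]], ":", a$resno[asn[1]]),
       center = center, radius = radius)
}

#' Maximal envelope radius of an attached probe around a pocket center
#'
#' Distance from the pocket center to the farthest non-excluded glycan
#' atom of the default attached pose; with the spherical pocket fixture,
#' clearances of at least \code{envelope + 1.7 - 3} guarantee a "yes"
#' scan label.
#'
#' @param pocket output of \code{\link{makePocketProtein}}.
#' @param library probe library (default single GlcNAc).
#' @return Numeric scalar, Angstrom.
#' @export
glycanEnvelopeRadius <- function(pocket, library = glcnacProbeLibrary()) {
  pose <- attachReducingEnd(pocket$model, pocket$site,
                            structures(library)[[1]],
                            getLinkage("N-GlcNAc"))
  g <- coords(pose$glycan)
  keep <- setdiff(seq_len(nrow(g)), pose$exclude)
  max(sqrt(rowSums(sweep(g[keep, , drop = FALSE], 2, pocket$center)^2)))
}

#' Blocked-amide false-negative fixture
#'
#' An extended-chain sequon protein whose Asn amide direction is walled
#' off by a dense spherical cap of carbon pseudo-atoms: grafting a GlcNAc
#' onto ND2 as assigned is sterically impossible, but after exchanging
#' OD1 and ND2 (\code{\link{swapAsnAmide}}) the attachment points into
#' open space. Mirrors the false negatives caused by the arbitrary
#' crystallographic assignment of the Asn sidechain amide atoms.
#'
#' @param capAngle half-angle of the blocking cap, degrees.
#' @param capRadius cap radius around ND2, Angstrom.
#' @param dotSpacing cap dot spacing, Angstrom.
#' @return List with \code{model} and \code{site}.
#' @export
makeBlockedAmideProtein <- function(capAngle = 105, capRadius = 3.0,
                                    dotSpacing = 0.7) {
  base <- makeSequonProtein("GNASG")
  a <- atoms(base)
  asn <- which(a$resname == "ASN")
  nd2 <- asn[a$name[asn] == "ND2"]
  cg <- asn[a$name[asn] == "CG"]
  xyz <- coords(base)
  v <- vunit(xyz[nd2, ] - xyz[cg, ])
  nDots <- max(24L, ceiling(4 * pi * capRadius^2 / dotSpacing^2))
  dots <- sphereDots(nDots)
  keep <- dots %*% v >= cos(capAngle * pi / 180)
  cap <- sweep(dots[keep, , drop = FALSE] * capRadius, 2, xyz[nd2, ], "+")
  capRows <- do.call(rbind, lapply(seq_len(nrow(cap)), function(i)
    .hetAtomRow("C", cap[i, ], resname = "DUM", resno = 2000L + i,
                chain = "X", serial = nrow(a) + i)))
  model <- MolecularModel(rbind(a, capRows))
  list(model = model,
       site = paste0(a$chain[asn[1]], ":", a$resno[asn[1]]))
}
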