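#' @include AllClasses.R geometry.R graph.R
NULL

#' Load a linkage-geometry table
#'
#' Reads the configuration mapping each glycosylation type to the atom
#' quartets and torsion ranges of the protein-glycan bond. The shipped
#' defaults (inst/extdata/linkage_table.csv) use conventional glycosidic
#' torsion statistics and are meant to be edited or overridden; the column
#' layout is documented in the file header.
#'
#' @param path CSV path; default is the table shipped with the package.
#' @return Named list of \linkS4class{LinkageSpec} objects keyed by type.
#' @examples
#' tab <- defaultLinkageTable()
#' tab[["N-GlcNAc"]]
#' @export
defaultLinkageTable <- function(path = system.file("extdata",
                                                   "linkage_table.csv",
                                                   package = "glycograft")) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  specs <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    new("LinkageSpec",
        glycoType = r$glyco_type,
        residues = strsplit(r$residues, "/", fixed = TRUE)[[1]],
        phiAtoms = c(r$a, r$b, r$c, r$d),
        psiAtoms = c(r$b, r$c, r$d, r$e),
        phiRange = c(r$phi_min, r$phi_max),
        psiRange = c(r$psi_min, r$psi_max),
        bondLength = r$bond_length,
        bondAngle = r$bond_angle)
  })
  names(specs) <- df$glyco_type
  specs
}

#' Retrieve one linkage specification
#'
#' @param glycoType glycosylation type, e.g. "N-GlcNAc".
#' @param table optional table from \code{\link{defaultLinkageTable}}.
#' @return A \linkS4class{LinkageSpec}.
#' @export
getLinkage <- function(glycoType, table = defaultLinkageTable()) {
  if (!glycoType %in% names(table))
    stop("no linkage specification for glycosylation type: ", glycoType)
  table[[glycoType]]
}

#' Parse a site reference
#'
#' @param site a string "CHAIN:RESNO" (optionally "CHAIN:RESNO:ICODE"), or
#'   a list with elements chain, resno and optionally insert.
#' @return List with chain, resno, insert.
#' @export
parseSite <- function(site) {
  if (is.list(site))
    return(list(chain = site$chain, resno = as.integer(site$resno),
                insert = if (is.null(site$insert)) "" else site$insert))
  parts <- strsplit(site, ":", fixed = TRUE)[[1]]
  resno <- sub("^[A-Za-z]*", "", parts[2])  # tolerate "A:N45"
  list(chain = parts[1], resno = as.integer(resno),
       insert = if (length(parts) >= 3L) parts[3] else "")
}

siteLabel <- function(site) {
  s <- parseSite(site)
  paste0(s$chain, ":", s$resno, s$insert)
}

.residueAtoms <- function(model, site) {
  s <- parseSite(site)
  a <- atoms(model)
  which(a$chain == s$chain & a$resno == s$resno & a$insert == s$insert)
}

# Resolve an atom name (possibly a comma-separated preference list) within
# a set of atom-table rows; returns the model atom index or NA.
.resolveAtom <- function(model, rows, nameSpec) {
  for (nm in strsplit(nameSpec, ",", fixed = TRUE)[[1]]) {
    hit <- rows[atoms(model)$name[rows] == nm]
    if (length(hit)) return(hit[1])
  }
  NA_integer_
}

# Locate the reducing-end atoms a and b inside a glycan model. The
# reducing-end residue is the residue of the first atom named like b
# (anomeric carbon, usually C1) in file order.
.reducingEnd <- function(glycan, linkage) {
  a <- atoms(glycan)
  bName <- linkage@phiAtoms[2]
  aName <- linkage@phiAtoms[1]
  bIdx <- which(a$name == bName)[1]
  if (is.na(bIdx)) stop("glycan lacks anomeric atom ", bName)
  res <- which(a$chain == a$chain[bIdx] & a$resno == a$resno[bIdx] &
               a$insert == a$insert[bIdx])
  aIdx <- res[a$name[res] == aName][1]
  if (is.na(aIdx)) stop("glycan reducing end lacks atom ", aName)
  list(aIdx = aIdx, bIdx = bIdx, residue = res)
}

#' Attach a glycan's reducing end to a protein sidechain
#'
#' Places the glycan so that its anomeric carbon sits at the configured
#' bond length and angle from the sidechain attachment atom, with the
#' linkage torsions initialized to their range midpoints. The anomeric
#' substituent direction of the input conformer is preserved: if the glycan
#' carries a free anomeric hydroxyl (O1), the new bond replaces it
#' (condensation) and the anomeric configuration is untouched.
#'
#' @param protein a \linkS4class{MolecularModel}.
#' @param site site reference (see \code{\link{parseSite}}).
#' @param glycan a \linkS4class{MolecularModel} conformer.
#' @param linkage a \linkS4class{LinkageSpec}.
#' @return A graft pose: list with the positioned \code{glycan}, atom
#'   bookkeeping (\code{aIdx}, \code{bIdx}, \code{exclude}), protein anchor
#'   coordinates (\code{cPos}, \code{dPos}, \code{ePos}), the linkage, the
#'   current \code{phi}/\code{psi} and the protein atom index of the
#'   attachment atom (\code{cProteinIdx}).
#' @export
attachReducingEnd <- function(protein, site, glycan, linkage) {
  rows <- .residueAtoms(protein, site)
  if (!length(rows))
    stop("site ", siteLabel(site), " not found in protein")
  resname <- atoms(protein)$resname[rows[1]]
  if (!resname %in% linkage@residues)
    stop("site ", siteLabel(site), " is ", resname, ", not one of ",
         paste(linkage@residues, collapse = "/"))
  cIdx <- .resolveAtom(protein, rows, linkage@phiAtoms[3])
  dIdx <- .resolveAtom(protein, rows, linkage@phiAtoms[4])
  eIdx <- .resolveAtom(protein, rows, linkage@psiAtoms[4])
  if (is.na(cIdx))
    stop(missingSidechainError(site, linkage@phiAtoms[3], resname))
  if (is.na(dIdx) || is.na(eIdx))
    stop("site ", siteLabel(site), " lacks sidechain atom ",
         linkage@phiAtoms[4], " or ", linkage@psiAtoms[4])
  pXYZ <- coords(protein)
  cPos <- pXYZ[cIdx, ]; dPos <- pXYZ[dIdx, ]; ePos <- pXYZ[eIdx, ]

  re <- .reducingEnd(glycan, linkage)
  gXYZ <- coords(glycan)
  bPos <- gXYZ[re$bIdx, ]
  # direction the new bond must take over, seen from the glycan frame
  gGraph <- buildGraph(glycan)
  nb <- as.integer(igraph::neighbors(gGraph@graph, re$bIdx))
  o1 <- nb[atoms(glycan)$name[nb] == "O1" &
           seq_along(nb) > 0][1]
  if (!is.na(o1)) {
    u <- vunit(gXYZ[o1, ] - bPos)
  } else {
    dirs <- t(apply(gXYZ[nb, , drop = FALSE], 1, function(p) vunit(p - bPos)))
    u <- vunit(-colSums(dirs))
  }
  psi0 <- mean(linkage@psiRange)
  phi0 <- mean(linkage@phiRange)
  bTarget <- nerfPlace(ePos, dPos, cPos, linkage@bondLength,
                       linkage@bondAngle, psi0)
  w <- vunit(cPos - bTarget)
  # rotate the glycan about its anomeric carbon so u maps onto w
  cosang <- max(-1, min(1, sum(u * w)))
  if (cosang < 1 - 1e-12) {
    axis <- vcross(u, w)
    if (vnorm(axis) < 1e-9) axis <- .anyPerpendicular(u)
    gXYZ <- rotateAboutAxis(gXYZ, bPos, axis, acos(cosang) * 180 / pi)
  }
  gXYZ <- sweep(gXYZ, 2, bTarget - bPos, "+")
  # drop the displaced anomeric hydroxyl
  keep <- seq_len(nrow(gXYZ))
  if (!is.na(o1)) keep <- setdiff(keep, o1)
  aDf <- atoms(glycan)[keep, , drop = FALSE]
  aDf$x <- gXYZ[keep, 1]; aDf$y <- gXYZ[keep, 2]; aDf$z <- gXYZ[keep, 3]
  remap <- match(seq_len(nrow(atoms(glycan))), keep)
  b <- bonds(glycan)
  b <- cbind(remap[b[, 1]], remap[b[, 2]])
  b <- b[stats::complete.cases(b), , drop = FALSE]
  g2 <- MolecularModel(aDf, bonds = b)
  pose <- list(glycan = g2,
               aIdx = remap[re$aIdx], bIdx = remap[re$bIdx],
               exclude = remap[re$bIdx],
               cPos = cPos, dPos = dPos, ePos = ePos,
               cProteinIdx = cIdx, linkage = linkage,
               phi = NA_real_, psi = psi0,
               site = siteLabel(site), fitness = NA_real_)
  setLinkageTorsions(pose, phi0, psi0)
}

.anyPerpendicular <- function(u) {
  v <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  vunit(vcross(u, v))
}

missingSidechainError <- function(site, atom, resname) {
  structure(class = c("glycograft_missing_sidechain", "error", "condition"),
            list(message = paste0("site ", siteLabel(site), " (", resname,
                 ") lacks sidechain atom ", atom,
                 "; check the rotamer or use swapAsnAmide() if the amide ",
                 "O/N assignment may be inverted"), call = NULL))
}

#' Current linkage torsions of a pose
#'
#' @param pose a graft pose from \code{\link{attachReducingEnd}}.
#' @return Named numeric c(phi, psi) in degrees.
#' @export
measureLinkageTorsions <- function(pose) {
  g <- coords(pose$glycan)
  phi <- measureDihedral(rbind(g[pose$aIdx, ], g[pose$bIdx, ],
                               pose$cPos, pose$dPos))
  psi <- measureDihedral(rbind(g[pose$bIdx, ], pose$cPos, pose$dPos,
                               pose$ePos))
  c(phi = phi, psi = psi)
}

#' Set the linkage torsions of a pose
#'
#' Rigidly rotates the glycan about the psi axis (c-d) and then the phi
#' axis (b-c) so the measured torsions equal the request to 1e-6 degrees.
#' Glycan-internal distances are preserved exactly; protein atoms never
#' move.
#'
#' @param pose a graft pose.
#' @param phi,psi target angles, degrees.
#' @return The updated pose (fitness cleared).
#' @export
setLinkageTorsions <- function(pose, phi, psi) {
  g <- coords(pose$glycan)
  # psi = dihedral(b, c, d, e); the glycan sits on the b side, so rotate it
  # about the d->c axis (reversed quartet) by the needed increment
  cur <- measureDihedral(rbind(g[pose$bIdx, ], pose$cPos, pose$dPos,
                               pose$ePos))
  g <- rotateAboutAxis(g, pose$cPos, pose$cPos - pose$dPos,
                       wrapAngle(psi - cur))
  # phi = dihedral(a, b, c, d); rotate the glycan about the c->b axis
  cur <- measureDihedral(rbind(g[pose$aIdx, ], g[pose$bIdx, ], pose$cPos,
                               pose$dPos))
  g <- rotateAboutAxis(g, g[pose$bIdx, ], g[pose$bIdx, ] - pose$cPos,
                       wrapAngle(phi - cur))
  coords(pose$glycan) <- g
  pose$phi <- phi; pose$psi <- psi
  pose$fitness <- NA_real_
  got <- measureLinkageTorsions(pose)
  if (abs(wrapAngle(got["phi"] - phi)) > 1e-6 ||
      abs(wrapAngle(got["psi"] - psi)) > 1e-6)
    stop("linkage torsion setting failed to converge")
  pose
}
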