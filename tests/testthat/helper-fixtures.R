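# Shared fixture builders and independent brute-force oracles.

# Shallow single-atom clash released by an ~8 degree rotation of the
# exocyclic C5-C6-O6 arm: the obstacle sits 1.58 A from O6 along the arm's
# rotation tangent, so one wiggle move of the omega torsion clears it.
armClashFixture <- function() {
  lk <- getLinkage("N-GlcNAc")
  p <- makeSequonProtein("GNASG")
  pose <- attachReducingEnd(p, "A:2", makeToyGlycan(), lk)
  g <- coords(pose$glycan)
  nm <- atoms(pose$glycan)$name
  o6 <- which(nm == "O6"); c6 <- which(nm == "C6"); c5 <- which(nm == "C5")
  axis <- (g[c5, ] - g[c6, ]) / sqrt(sum((g[c5, ] - g[c6, ])^2))
  radial <- (g[o6, ] - g[c6, ]) - sum((g[o6, ] - g[c6, ]) * axis) * axis
  tang <- c(axis[2] * radial[3] - axis[3] * radial[2],
            axis[3] * radial[1] - axis[1] * radial[3],
            axis[1] * radial[2] - axis[2] * radial[1])
  tang <- tang / sqrt(sum(tang^2))
  obs <- g[o6, ] - 1.58 * tang
  oa <- data.frame(serial = nAtoms(p) + 1L, name = "C", element = "C",
                   resname = "DUM", chain = "X", resno = 999L, insert = "",
                   x = obs[1], y = obs[2], z = obs[3], occupancy = 1, b = 0,
                   type = "HETATM")
  list(pose = pose, protein = MolecularModel(rbind(atoms(p), oa)),
       obstacle = obs, armQuartet = c(o6, c6, c5))
}

# Two-conformer disaccharide library: G0 extended, G1 compact. A pocket of
# clearance ~5.5 A admits only the compact conformer, exercising the
# conformer cascade.
twoConformerLibrary <- function() {
  dis <- glycograft:::.makeDisaccharide()
  base <- dis$model
  graph <- buildGraph(base)
  qs <- lapply(dis$torsions, function(nm) glycograft:::.namedQuartet(base, nm))
  mv <- lapply(qs, function(q) glycograft:::.movingSet(graph, q[2], q[3]))
  conf <- function(t3) {
    m <- base
    for (t in 1:3) m <- setDihedral(m, qs[[t]], t3[t], movingSet = mv[[t]])
    m
  }
  ConformerLibrary(list(conf(c(90, -150, 60)), conf(c(-30, 30, 60))),
                   weights = c(0.7, 0.3), clusterIds = 0:1,
                   glycanId = "cascade-fixture")
}

# Independent ring detection: an atom lies on a cycle iff it has an
# incident non-bridge edge; bridges found by edge removal + hand-rolled BFS
# (no igraph).
bfRingAtoms <- function(n, bonds) {
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1]; j <- bonds[r, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  connected <- function(from, to, dropEdge) {
    seen <- rep(FALSE, n); queue <- from; seen[from] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if ((v == dropEdge[1] && w == dropEdge[2]) ||
            (v == dropEdge[2] && w == dropEdge[1])) next
        if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    seen[to]
  }
  ring <- rep(FALSE, n)
  for (r in seq_len(nrow(bonds))) {
    e <- bonds[r, ]
    if (connected(e[1], e[2], e)) ring[e] <- TRUE   # edge on a cycle
  }
  ring
}

# Brute-force steric loss: explicit double loop over all pairs.
bfFitness <- function(P, G, threshold = 1.7, exclude = integer(0)) {
  total <- 0
  for (i in seq_len(nrow(P))) {
    for (j in setdiff(seq_len(nrow(G)), exclude)) {
      d2 <- sum((P[i, ] - G[j, ])^2)
      if (d2 < threshold^2) total <- total + 200 * exp(d2)
    }
  }
  total
}

randomRigidMotion <- function() {
  ang <- stats::runif(3, -pi, pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])),
              c(0, sin(ang[1]), cos(ang[1])))
  Ry <- rbind(c(cos(ang[2]), 0, sin(ang[2])), c(0, 1, 0),
              c(-sin(ang[2]), 0, cos(ang[2])))
  Rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0),
              c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
  list(R = Rx %*% Ry %*% Rz, t = stats::runif(3, -20, 20))
}

applyRigid <- function(xyz, motion) {
  sweep(xyz %*% t(motion$R), 2, motion$t, "+")
}
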