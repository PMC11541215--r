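.chainModel <- function(n) {
  a <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(serial = i, name = paste0("C", i), element = "C",
               resname = "DUM", chain = "G", resno = 1L, insert = "",
               x = 1.5 * i, y = 0, z = 0, occupancy = 1, b = 0,
               type = "HETATM")))
  MolecularModel(a, bonds = cbind(seq_len(n - 1), 2:n))
}

test_that("ring membership matches brute-force bridge analysis", {
  for (model in list(makeToyGlycan(), glycograft:::.makeDisaccharide()$model,
                     .chainModel(4))) {
    g <- buildGraph(model)
    expect_equal(g@ringMembership,
                 bfRingAtoms(nAtoms(model), bonds(model)))
    expect_equal(g@degrees, as.integer(table(factor(as.vector(bonds(model)),
                 levels = seq_len(nAtoms(model))))))
  }
})

test_that("pyranose ring atoms are flagged, exocyclic atoms are not", {
  m <- makeToyGlycan()
  g <- buildGraph(m)
  ringNames <- atoms(m)$name[g@ringMembership]
  expect_setequal(ringNames, c("C1", "C2", "C3", "C4", "C5", "O5"))
  expect_false(g@ringMembership[match("O6", atoms(m)$name)])
  expect_equal(sum(g@ringMembership), 6L)
})

test_that("a plain chain has no ring atoms and one torsion quartet", {
  m <- .chainModel(4)
  g <- buildGraph(m)
  expect_equal(sum(g@ringMembership), 0L)
  tq <- detectTorsionPairs(g)
  # both degree-2 atoms anchor the same central bond: deduplicated to one
  expect_length(tq, 1L)
  expect_equal(sort(tq[[1]]$atoms), 1:4)
})

test_that("a bare ring yields no torsion quartets", {
  a <- do.call(rbind, lapply(1:6, function(i)
    data.frame(serial = i, name = paste0("C", i), element = "C",
               resname = "DUM", chain = "G", resno = 1L, insert = "",
               x = 1.5 * cos(i * pi / 3), y = 1.5 * sin(i * pi / 3), z = 0,
               occupancy = 1, b = 0, type = "HETATM")))
  ring <- MolecularModel(a, bonds = cbind(1:6, c(2:6, 1)))
  expect_length(detectTorsionPairs(buildGraph(ring)), 0L)
})

test_that("torsion detection matches exhaustive degree-2 enumeration", {
  for (model in list(makeToyGlycan(), glycograft:::.makeDisaccharide()$model)) {
    g <- buildGraph(model)
    tq <- detectTorsionPairs(g)
    # oracle: central bonds are exactly the bonds incident to a non-ring
    # degree-2 atom whose far end can extend
    deg <- g@degrees; ring <- g@ringMembership
    b <- bonds(model)
    expected <- character(0)
    for (r in seq_len(nrow(b))) {
      for (s in 1:2) {
        j <- b[r, s]; k <- b[r, 3 - s]
        if (deg[j] != 2L || ring[j]) next
        if (deg[k] < 2L) next   # far end cannot extend
        expected <- c(expected, paste(min(j, k), max(j, k)))
      }
    }
    got <- vapply(tq, function(q) paste(min(q$atoms[2:3]), max(q$atoms[2:3])),
                  character(1))
    expect_setequal(got, unique(expected))
    # rotating set and complement partition the molecule when the bond is cut
    for (q in tq) {
      expect_true(q$atoms[3] %in% q$rotatingSet)
      expect_false(q$atoms[2] %in% q$rotatingSet)
      expect_true(length(q$rotatingSet) < nAtoms(model))
    }
  }
})

test_that("glycosidic bridge oxygen yields the linkage torsion pairs", {
  dis <- glycograft:::.makeDisaccharide()$model
  g <- buildGraph(dis)
  tq <- detectTorsionPairs(g)
  a <- atoms(dis)
  o4 <- which(a$name == "O4" & a$resno == 1L)
  nWithO4 <- sum(vapply(tq, function(q) o4 %in% q$atoms[2:3], logical(1)))
  expect_equal(nWithO4, 2L)   # phi-like and psi-like axes through the bridge
})

test_that("disconnected graphs warn and are handled per component", {
  m <- makeToyGlycan()
  a2 <- atoms(m)
  a2$x <- a2$x + 30; a2$resno <- 2L
  both <- MolecularModel(rbind(atoms(m), a2),
                         bonds = rbind(bonds(m), bonds(m) + nAtoms(m)))
  expect_warning(g <- buildGraph(both), "disconnected")
  expect_equal(sum(g@ringMembership), 12L)
})
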