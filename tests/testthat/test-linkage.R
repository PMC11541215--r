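test_that("the shipped linkage table covers the supported chemistries", {
  tab <- defaultLinkageTable()
  expect_setequal(names(tab),
                  c("N-GlcNAc", "O-GalNAc", "O-GlcNAc", "O-Fuc", "O-Man",
                    "O-Glc", "O-Xyl", "C-Man"))
  for (lk in tab) {
    expect_s4_class(lk, "LinkageSpec")
    expect_identical(lk@phiAtoms[2:4], lk@psiAtoms[1:3])
    expect_true(all(c(lk@phiRange, lk@psiRange) >= -180))
    expect_true(all(c(lk@phiRange, lk@psiRange) <= 180))
  }
  expect_error(getLinkage("S-GlcNAc"), "unsupported|no linkage")
})

test_that("attachment hits the configured bond geometry at an Asn", {
  p <- makeSequonProtein("GNASG")
  lk <- getLinkage("N-GlcNAc")
  pose <- attachReducingEnd(p, "A:2", makeToyGlycan(), lk)
  g <- coords(pose$glycan)
  # bond formed at ND2 with the configured length
  expect_equal(sqrt(sum((g[pose$bIdx, ] - pose$cPos)^2)), lk@bondLength,
               tolerance = 1e-6)
  a <- atoms(p)
  nd2 <- which(a$resname == "ASN" & a$name == "ND2")
  expect_equal(pose$cProteinIdx, nd2)
  # angle at the attachment atom
  v1 <- g[pose$bIdx, ] - pose$cPos
  v2 <- pose$dPos - pose$cPos
  ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  expect_equal(ang, lk@bondAngle, tolerance = 1e-4)
  # torsions initialized to range midpoints
  t0 <- measureLinkageTorsions(pose)
  expect_equal(unname(t0["phi"]), mean(lk@phiRange), tolerance = 1e-6)
  expect_equal(unname(t0["psi"]), mean(lk@psiRange), tolerance = 1e-6)
  # anomeric hydroxyl is displaced by the new bond
  expect_false("O1" %in% atoms(pose$glycan)$name)
})

test_that("C-mannosylation attaches at the Trp indole C2 carbon", {
  p <- makeSequonProtein("GWG")
  lk <- getLinkage("C-Man")
  pose <- attachReducingEnd(p, "A:2", makeToyGlycan(), lk)
  a <- atoms(p)
  cd1 <- which(a$resname == "TRP" & a$name == "CD1")
  expect_equal(pose$cProteinIdx, cd1)
  expect_equal(sqrt(sum((coords(pose$glycan)[pose$bIdx, ] - pose$cPos)^2)),
               lk@bondLength, tolerance = 1e-6)
})

test_that("serine takes the O-linked attachment through OG", {
  p <- makeSequonProtein("GSG")
  lk <- getLinkage("O-GalNAc")
  pose <- attachReducingEnd(p, "A:2", makeToyGlycan(), lk)
  a <- atoms(p)
  expect_equal(pose$cProteinIdx, which(a$resname == "SER" & a$name == "OG"))
})

test_that("linkage torsions are set exactly, rigidly and reversibly", {
  p <- makeSequonProtein("GNASG")
  lk <- getLinkage("N-GlcNAc")
  pose <- attachReducingEnd(p, "A:2", makeToyGlycan(), lk)
  # identity request leaves coordinates untouched
  t0 <- measureLinkageTorsions(pose)
  same <- setLinkageTorsions(pose, t0["phi"], t0["psi"])
  expect_lt(max(abs(coords(same$glycan) - coords(pose$glycan))), 1e-9)
  # arbitrary request is reached to 1e-6 degrees
  pose2 <- setLinkageTorsions(pose, 60, -120)
  t2 <- measureLinkageTorsions(pose2)
  expect_equal(unname(t2), c(60, -120), tolerance = 1e-6)
  # glycan-internal distances preserved to 1e-9
  expect_lt(max(abs(dist(coords(pose$glycan)) - dist(coords(pose2$glycan)))),
            1e-9)
  # inverse restores coordinates
  back <- setLinkageTorsions(pose2, t0["phi"], t0["psi"])
  expect_lt(max(abs(coords(back$glycan) - coords(pose$glycan))), 1e-8)
})

test_that("missing sidechain atoms raise the actionable condition", {
  p <- makeSequonProtein("GNASG")
  a <- atoms(p)
  p2 <- MolecularModel(a[!(a$resname == "ASN" & a$name == "ND2"), ])
  expect_error(attachReducingEnd(p2, "A:2", makeToyGlycan(),
                                 getLinkage("N-GlcNAc")),
               class = "glycograft_missing_sidechain")
  err <- tryCatch(attachReducingEnd(p2, "A:2", makeToyGlycan(),
                                    getLinkage("N-GlcNAc")),
                  condition = function(e) e)
  expect_match(conditionMessage(err), "swapAsnAmide")
})
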