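test_that("an open surface succeeds with the top-weighted conformer", {
  p <- makeSequonProtein("GNASG")
  r <- graftSite(p, "A:2", glcnacProbeLibrary(), seed = 2)
  expect_true(r@success)
  expect_equal(r@phase, "ga")
  expect_equal(r@clusterId, 0L)
  expect_identical(r@pose$fitness, 0)
  expect_equal(r@clustersTried, 0L)
})

test_that("the cascade falls through to a conformer that fits the pocket", {
  lib <- twoConformerLibrary()
  pk <- makePocketProtein(5.5)
  r <- graftSite(pk$model, pk$site, lib, seed = 2)
  expect_true(r@success)
  expect_equal(r@clusterId, 1L)
  expect_equal(r@clustersTried, c(0L, 1L))
  expect_equal(r@phase, "ga")
  expect_gt(r@clusterFitness[1], 0)   # G0 could not be placed
})

test_that("a buried site fails through the wiggle phase", {
  pk <- makePocketProtein(0)
  r <- graftSite(pk$model, pk$site, glcnacProbeLibrary(), seed = 2)
  expect_false(r@success)
  expect_equal(r@phase, "wiggle")
  expect_equal(r@wiggleIterationsUsed, 40L)
  expect_gt(r@pose$fitness, 0)
})

test_that("graft success survives a PDB round trip at zero recomputed loss", {
  p <- makeSequonProtein("GNASG")
  out <- graftProtein(p, sites = "A:2", library = glcnacProbeLibrary(),
                      seed = 6)
  r <- out$results[["A:2"]]
  expect_true(r@success)
  cplx <- readStructure(paste(writeStructure(out$model),
                              collapse = "\n"))[[1]]
  a <- atoms(cplx)
  gl <- which(a$resname == "NAG")
  anomeric <- which(a$resname == "NAG" & a$name == "C1")
  refit <- stericFitness(coords(cplx)[-gl, , drop = FALSE],
                         coords(cplx)[gl, , drop = FALSE],
                         exclude = match(anomeric, gl))
  expect_identical(refit$fitness, 0)
})

test_that("multi-site one-shot grafting places one copy per open site", {
  p <- makeSequonProtein("GNASGGGGGGNAT")
  sq <- findSequons(p)
  out <- graftProtein(p, sites = paste0("A:", sq$resno),
                      library = glcnacProbeLibrary(), seed = 4)
  expect_true(all(vapply(out$results, function(r) r@success, logical(1))))
  a <- atoms(out$model)
  expect_equal(sum(a$resname == "NAG"), 2L * 14L)
  expect_equal(length(unique(a$resno[a$resname == "NAG"])), 2L)
})

test_that("earlier glycans join the protein set for later sites", {
  # adjacent sequons: the first graft must be visible to the second
  p <- makeSequonProtein("GNNSSG")
  sq <- findSequons(p)
  expect_equal(nrow(sq), 2L)
  out <- graftProtein(p, sites = paste0("A:", sq$resno),
                      library = glcnacProbeLibrary(), seed = 8,
                      includeGrafted = TRUE)
  a <- atoms(out$model)
  glyResnos <- unique(a$resno[a$resname == "NAG"])
  succ <- vapply(out$results, function(r) is(r, "GraftResult") && r@success,
                 logical(1))
  if (sum(succ) == 2L) {
    g1 <- coords(out$model)[a$resno == glyResnos[1] & a$resname == "NAG", ]
    g2 <- coords(out$model)[a$resno == glyResnos[2] & a$resname == "NAG", ]
    # no glycan-glycan overlap when both were placed
    expect_gte(min(sqrt(glycograft:::crossDist2(g1, g2))), 1.7)
  } else {
    # the occluded neighbour site is allowed to fail, never to overlap
    expect_gte(sum(succ), 1L)
  }
})

test_that("an empty site plan returns the protein unchanged", {
  p <- makeSequonProtein("GAAAG")
  out <- graftProtein(p, sitePlan = list(), mode = "site_by_site", seed = 1)
  expect_identical(out$model, p)
  expect_length(out$results, 0L)
})
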