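test_that("N-X-S/T motifs are found with author numbering", {
  expect_equal(findSequons(makeSequonProtein("ANASA"))$resno, 2L)
  expect_equal(findSequons(makeSequonProtein("ANASA", 3))$resno, 5L)
  # NXT counts too
  expect_equal(findSequons(makeSequonProtein("ANATA"))$motif, "NAT")
  expect_equal(nrow(findSequons(makeSequonProtein("AAAAA"))), 0L)
})

test_that("the proline rule is literal by default and optional", {
  p <- makeSequonProtein("ANPTA")
  expect_equal(nrow(findSequons(p)), 1L)
  expect_equal(findSequons(p)$motif, "NPT")
  expect_equal(nrow(findSequons(p, excludeProlineX = TRUE)), 0L)
})

test_that("terminal partial motifs and chain breaks are not sequons", {
  expect_equal(nrow(findSequons(makeSequonProtein("AAAN"))), 0L)
  expect_equal(nrow(findSequons(makeSequonProtein("AAANA"))), 0L)
  # numbering gap between Asn and Ser marks missing residues
  p <- makeSequonProtein("ANAS")
  a <- atoms(p)
  a$resno[a$resno >= 4] <- a$resno[a$resno >= 4] + 7L
  broken <- MolecularModel(a)
  expect_equal(nrow(findSequons(broken)), 0L)
})

test_that("the amide swap is an exact involution", {
  p <- makeSequonProtein("GNASG")
  sw <- swapAsnAmide(p, "A:2")
  a <- atoms(p)
  od1 <- which(a$resname == "ASN" & a$name == "OD1")
  nd2 <- which(a$resname == "ASN" & a$name == "ND2")
  expect_equal(coords(sw)[od1, ], coords(p)[nd2, ], ignore_attr = TRUE)
  expect_equal(coords(sw)[nd2, ], coords(p)[od1, ], ignore_attr = TRUE)
  expect_identical(coords(swapAsnAmide(sw, "A:2")), coords(p))
  # every other field untouched
  expect_identical(atoms(sw)$name, atoms(p)$name)
  # distances follow the exchanged coordinates
  ca <- which(a$name == "CA")[2]
  expect_equal(sqrt(sum((coords(sw)[nd2, ] - coords(sw)[ca, ])^2)),
               sqrt(sum((coords(p)[od1, ] - coords(p)[ca, ])^2)))
  expect_error(swapAsnAmide(p, "A:1"), "not ASN")
})

test_that("scanning labels track pocket clearance monotonically", {
  labels <- vapply(c(0, 3, 6, 9), function(cl) {
    pk <- makePocketProtein(cl)
    rep <- glcnacScan(pk$model, seed = 5)
    rep@entries$label[1]
  }, character(1))
  expect_equal(labels[1], "no")
  expect_equal(labels[4], "yes")
  # single no->yes transition along the ladder
  expect_equal(sum(labels[-1] != labels[-4]), 1L)
})

test_that("a clearance beyond the probe envelope guarantees occupancy", {
  pk <- makePocketProtein(8)
  env <- glycanEnvelopeRadius(pk)
  needed <- env + 1.7 - 3
  expect_lte(needed, 8)
  rep <- glcnacScan(pk$model, seed = 6)
  expect_equal(rep@entries$label[1], "yes")
})

test_that("a blocked amide scans no and flips to yes after the swap", {
  bl <- makeBlockedAmideProtein()
  r1 <- glcnacScan(bl$model, seed = 3)
  expect_equal(r1@entries$label, "no")
  sw <- swapAsnAmide(bl$model, bl$site)
  r2 <- glcnacScan(sw, seed = 3)
  expect_equal(r2@entries$label, "yes")
})

test_that("scan reports are deterministic and rigid-motion invariant", {
  pk <- makePocketProtein(4)
  r1 <- glcnacScan(pk$model, seed = 11)
  r2 <- glcnacScan(pk$model, seed = 11)
  expect_identical(r1@entries, r2@entries)
  set.seed(31)
  m <- randomRigidMotion()
  moved <- pk$model
  coords(moved) <- applyRigid(coords(pk$model), m)
  r3 <- glcnacScan(moved, seed = 11)
  expect_identical(r1@entries$label, r3@entries$label)
})

test_that("proteins without sequons give an empty report", {
  rep <- glcnacScan(makeSequonProtein("GAAAG"), seed = 1)
  expect_equal(nrow(rep@entries), 0L)
})

test_that("a missing amide nitrogen is reported, not crashed on", {
  p <- makeSequonProtein("GNASG")
  a <- atoms(p)
  p2 <- MolecularModel(a[!(a$resname == "ASN" & a$name == "ND2"), ])
  rep <- glcnacScan(p2, seed = 1)
  expect_equal(rep@entries$label, "no")
  expect_equal(rep@entries$reason, "sidechain-atom-missing")
})
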