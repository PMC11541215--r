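test_that("single-model files parse with verbatim author numbering", {
  txt <- c(
    "ATOM      1  N   ASN A   4       1.000   2.000   3.000  1.00 50.00           N",
    "ATOM      2  CA  ASN A   4       2.000   2.000   3.000  1.00 50.00           C",
    "ATOM      3  C   ASN A   4       3.000   2.000   3.000  1.00 50.00           C",
    "ATOM      4  O   ASN A   4       3.500   3.000   3.000  1.00 50.00           O",
    "ATOM      5  N   ALA A   5       3.700   1.000   3.000  1.00 42.50           N",
    "HETATM    6  C1  NAG B   1       0.500   0.250   0.125  1.00  0.00           C",
    "END")
  mods <- readStructure(paste(txt, collapse = "\n"))
  expect_length(mods, 1L)
  a <- atoms(mods[[1]])
  expect_equal(nrow(a), 6L)
  # numbering fidelity: first residue stays 4, not renumbered from 1
  expect_equal(a$resno[1], 4L)
  expect_equal(a$type[6], "HETATM")
  expect_equal(a$b[5], 42.5)   # B-factor column (pLDDT carrier) preserved
})

test_that("multi-model files keep atom ordering across models", {
  pl <- makePlantedEnsemble(k = 2, nFrames = 5, seed = 1)
  mods <- lapply(1:3, function(i) ensembleFrame(pl$ensemble, i))
  txt <- writeStructure(mods)
  expect_equal(sum(grepl("^MODEL", txt)), 3L)
  back <- readStructure(paste(txt, collapse = "\n"), modelSelect = "all")
  expect_length(back, 3L)
  for (m in back) expect_identical(atoms(m)$name, atoms(mods[[1]])$name)
  expect_length(readStructure(paste(txt, collapse = "\n"),
                              modelSelect = "first"), 1L)
})

test_that("read/write round-trip is lossless for emitted fields", {
  set.seed(7)
  for (model in list(makeToyGlycan(), makeSequonProtein("ANASA", 3))) {
    a <- atoms(model)
    a[, c("x", "y", "z")] <- round(a[, c("x", "y", "z")] +
                                   stats::runif(3 * nrow(a), -5, 5), 3)
    model <- MolecularModel(a, bonds = bonds(model))
    back <- readStructure(paste(writeStructure(model), collapse = "\n"))[[1]]
    expect_identical(atoms(back)$name, a$name)
    expect_identical(atoms(back)$resno, a$resno)
    expect_identical(atoms(back)$chain, a$chain)
    expect_identical(atoms(back)$resname, a$resname)
    expect_equal(coords(back), coords(model), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(bonds(back), bonds(model), ignore_attr = TRUE)
  }
})

test_that("CONECT records become bonds and are emitted for grafts", {
  g <- makeToyGlycan()
  back <- readStructure(paste(writeStructure(g), collapse = "\n"))[[1]]
  expect_equal(nrow(bonds(back)), nrow(bonds(g)))
  # grafted complex carries the sidechain-to-anomeric-carbon CONECT
  p <- makeSequonProtein("GNASG")
  out <- graftProtein(p, sites = "A:2", library = glcnacProbeLibrary(),
                      seed = 4)
  expect_true(out$results[["A:2"]]@success)
  txt <- writeStructure(out$model)
  cplx <- readStructure(paste(txt, collapse = "\n"))[[1]]
  a <- atoms(cplx)
  nd2 <- which(a$name == "ND2" & a$resname == "ASN")
  c1 <- which(a$name == "C1" & a$resname == "NAG")
  b <- bonds(cplx)
  expect_true(any((b[, 1] == nd2 & b[, 2] == c1) |
                  (b[, 1] == c1 & b[, 2] == nd2)))
})

test_that("malformed and empty inputs raise informative errors", {
  bad <- c("ATOM      1  N   ASN A   4       1.000   xxx     3.000",
           "END")
  expect_error(readStructure(paste(bad, collapse = "\n")),
               "malformed.*line 1")
  expect_error(readStructure("REMARK nothing here\nEND"), "empty input")
})

test_that("insertion codes survive the round trip", {
  txt <- c(
    "ATOM      1  N   ASN A  52A     1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  ASN A  52A     2.400   2.000   3.000  1.00  0.00           C",
    "END")
  m <- readStructure(paste(txt, collapse = "\n"))[[1]]
  expect_equal(atoms(m)$insert, c("A", "A"))
  back <- readStructure(paste(writeStructure(m), collapse = "\n"))[[1]]
  expect_equal(atoms(back)$insert, c("A", "A"))
  expect_equal(atoms(back)$resno, c(52L, 52L))
})

test_that("bond perception flags covalent contacts only", {
  m <- makeToyGlycan()
  m@bonds <- matrix(integer(0), ncol = 2)
  p <- perceiveBonds(m)
  expect_equal(nrow(bonds(p)), 15L)   # same topology as the explicit list
  expect_setequal(paste(bonds(p)[, 1], bonds(p)[, 2]),
                  paste(bonds(makeToyGlycan())[, 1],
                        bonds(makeToyGlycan())[, 2]))
})
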