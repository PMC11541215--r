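#' @include AllClasses.R
NULL

# Derive a reproducible child seed from a master seed and a label.
# Kept below 2^31 so it is always a valid R integer seed.
childSeed <- function(seed, label) {
  h <- sum(utf8ToInt(paste0(label)) * seq_along(utf8ToInt(paste0(label))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Element symbol from a PDB atom name (fallback when the element column is
# blank): strip digits/primes, first letter wins except two-letter symbols
# commonly seen in protein/glycan work.
elementFromName <- function(name) {
  nm <- gsub("[0-9']", "", trimws(name))
  two <- c("CL", "BR", "NA", "MG", "ZN", "FE", "MN", "SE")
  up <- toupper(nm)
  ifelse(up %in% two, substr(up, 1, 2), substr(up, 1, 1))
}

# Covalent radii (Angstrom) used for distance-based bond perception.
.COVALENT_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05,
                     P = 1.07, F = 0.57, SE = 1.20, CL = 1.02, BR = 1.20)

covalentRadius <- function(element) {
  r <- .COVALENT_RADII[toupper(element)]
  r[is.na(r)] <- 0.77  # unknown elements treated as carbon-like
  unname(r)
}

# Wrap degrees into (-180, 180].
wrapAngle <- function(a) {
  a <- (a + 180) %% 360 - 180
  a[a <= -180] <- a[a <= -180] + 360
  ifelse(abs(a + 180) < 1e-12, 180, a)
}

# Squared cross-distances between two coordinate matrices (rows = points).
crossDist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * (A %*% t(B))
  d2[d2 < 0] <- 0
  d2
}

# Merge two models into one (atoms concatenated, bonds reindexed).
mergeModels <- function(m1, m2, extraBonds = NULL) {
  off <- nAtoms(m1)
  a2 <- atoms(m2)
  a <- rbind(atoms(m1), a2)
  a$serial <- seq_len(nrow(a))
  b <- rbind(bonds(m1), bonds(m2) + off)
  if (!is.null(extraBonds)) b <- rbind(b, extraBonds)
  # de-duplicate atom identities from the glycan side by renaming chains is
  # the caller's job; here we only require the merged table to validate
  MolecularModel(a, bonds = b, modelId = m1@modelId)
}
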