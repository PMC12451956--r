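# Independent oracles used to cross-check the package's own implementations.
# They deliberately use different algorithms from the code under test.

# Optimal superposition RMSD via the quaternion (Horn) method: largest
# eigenvalue of the 4x4 profile matrix built from the cross-correlation of
# the centered point sets. No SVD, no rotation construction.
quaternion_rmsd <- function(a, b) {
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  M <- t(b) %*% a
  S <- matrix(0, 4, 4)
  S[1, 1] <- M[1, 1] + M[2, 2] + M[3, 3]
  S[1, 2] <- S[2, 1] <- M[2, 3] - M[3, 2]
  S[1, 3] <- S[3, 1] <- M[3, 1] - M[1, 3]
  S[1, 4] <- S[4, 1] <- M[1, 2] - M[2, 1]
  S[2, 2] <- M[1, 1] - M[2, 2] - M[3, 3]
  S[2, 3] <- S[3, 2] <- M[1, 2] + M[2, 1]
  S[2, 4] <- S[4, 2] <- M[1, 3] + M[3, 1]
  S[3, 3] <- -M[1, 1] + M[2, 2] - M[3, 3]
  S[3, 4] <- S[4, 3] <- M[2, 3] + M[3, 2]
  S[4, 4] <- -M[1, 1] - M[2, 2] + M[3, 3]
  lam <- max(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(a^2) + sum(b^2) - 2 * lam) / nrow(a)
  sqrt(max(msd, 0))
}

# Brute-force Needleman-Wunsch/Gotoh affine-gap global alignment score.
# Plain three-matrix dynamic program over the full table; a gap of length k
# costs open + k * extend (the Biostrings convention).
gotoh_score <- function(sa, sb, submat, open = 10, extend = 0.5) {
  a <- strsplit(sa, "")[[1]]; b <- strsplit(sb, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)  # ends in residue-residue column
  X <- matrix(NEG, n + 1, m + 1)  # ends in gap in b (a residue unmatched)
  Y <- matrix(NEG, n + 1, m + 1)  # ends in gap in a
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -open - extend * i
  for (j in seq_len(m)) Y[1, j + 1] <- -open - extend * j
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- submat[a[i], b[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - extend,
                             X[i, j + 1] - extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                             Y[i + 1, j] - extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})
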