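# Independent oracles used across the suite. These deliberately do not share
# code with the package implementation.

# Gotoh affine-gap global alignment score (gap of length L costs
# open + L * ext), scored with BLOSUM62. Small and slow; for short peptides.
oracle_nw_score <- function(a, b, open = 10, ext = 1) {
  B <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in b (vertical)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in a (horizontal)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -(open + (i - 1) * ext)
  for (j in 2:(m + 1)) Iy[1, j] <- -(open + (j - 1) * ext)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- B[av[i - 1], bv[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
      Ix[i, j] <- max(M[i - 1, j] - (open + ext), Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - (open + ext), Iy[i, j - 1] - ext)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# Enumerate the full Cartesian product of a compiled pattern (class list) as
# strings; assumes the product is small.
oracle_pattern_strings <- function(classes) {
  grid <- do.call(expand.grid, c(rev(classes), stringsAsFactors = FALSE))
  apply(grid[, rev(seq_along(classes)), drop = FALSE], 1, paste, collapse = "")
}

# Grid-scan isoelectric point: finest-grained pH whose net charge is closest
# to zero, using the same published pKa constants but an independent search.
oracle_pi_grid <- function(sequence, step = 0.001) {
  chars <- strsplit(sequence, "")[[1]]
  pka_pos <- c(K = 10.00, R = 12.00, H = 5.98)
  pka_neg <- c(D = 4.05, E = 4.45, C = 9.00, Y = 10.00)
  charge <- function(pH) {
    pos <- 1 / (1 + 10^(pH - 7.5)) +
      sum(vapply(names(pka_pos), function(r)
        sum(chars == r) / (1 + 10^(pH - pka_pos[[r]])), numeric(1)))
    neg <- 1 / (1 + 10^(3.55 - pH)) +
      sum(vapply(names(pka_neg), function(r)
        sum(chars == r) / (1 + 10^(pka_neg[[r]] - pH)), numeric(1)))
    pos - neg
  }
  grid <- seq(0, 14, by = step)
  grid[which.min(abs(vapply(grid, charge, numeric(1))))]
}

random_protein <- function(n, seed = NULL) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  paste(sample(aa, n, replace = TRUE), collapse = "")
}
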