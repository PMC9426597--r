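# Independent oracles and small generators used across the suite.
# Every oracle here is written from the definition, independent of the
# code path it checks.

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

AA_LETTERS <- rownames(blosum62)[1:20]

# brute-force affine-gap local alignment score (triple-matrix DP);
# gap of length L costs open + L * ext
brute_sw_score <- function(a, b, open = 11, ext = 1, mat = blosum62) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  M <- matrix(-Inf, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)
  Y <- matrix(-Inf, n + 1, m + 1)
  M[1, ] <- 0; M[, 1] <- 0
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      M[i, j] <- max(0, max(M[i - 1, j - 1], X[i - 1, j - 1],
                            Y[i - 1, j - 1]) + mat[a[i - 1], b[j - 1]])
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
      best <- max(best, M[i, j])
    }
  }
  best
}

# Spearman rho from the textbook definition: Pearson on midranks
brute_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# per-position identity of two equal-length ungapped sequences
hamming_identity <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  100 * mean(a == b)
}

random_protein_str <- function(len) {
  paste(sample(AA_LETTERS, len, replace = TRUE), collapse = "")
}

# three planted families of BaiE-scale proteins; ancestors derived from
# one root at `between` identity, members at `within`
planted_families <- function(seed, n_members = 6, within = 0.98,
                             between = 0.45, n_families = 3) {
  root <- random_protein(177, seed = seed)
  fams <- lapply(seq_len(n_families), function(i) {
    anc <- if (i == 1) root else
      mutate_family(family_spec(root, 1, between, seed + 100 * i))$seq
    mutate_family(family_spec(anc, n_members, within, seed + i),
                  prefix = paste0("f", i))
  })
  names(fams) <- paste0("f", seq_len(n_families))
  fams
}
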