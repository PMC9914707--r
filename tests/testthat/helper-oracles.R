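# Independent oracles, coded separately from the package implementations.

# Literal transcription of the classic ACE estimator.
ace_oracle <- function(counts, cutoff = 10) {
  counts <- counts[counts > 0]
  if (length(counts) == 0) return(0)
  S_abund <- sum(counts > cutoff)
  rare <- counts[counts <= cutoff]
  S_rare <- length(rare)
  if (S_rare == 0) return(S_abund)
  N_rare <- sum(rare)
  F1 <- sum(rare == 1)
  C_ace <- 1 - F1 / N_rare
  if (C_ace == 0) return(NA_real_)  # undefined; package falls back
  ssum <- 0
  for (i in 1:cutoff) ssum <- ssum + i * (i - 1) * sum(rare == i)
  gamma2 <- S_rare / C_ace * ssum / (N_rare * (N_rare - 1)) - 1
  gamma2 <- max(gamma2, 0)
  S_abund + S_rare / C_ace + (F1 / C_ace) * gamma2
}

# Brute-force two-sided exact Spearman permutation p: loop over every
# permutation of y, computing rho with cor() each time.
spearman_brute_p <- function(x, y) {
  n <- length(x)
  rho_obs <- cor(rank(x), rank(y))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  hits <- 0
  all_p <- perms(seq_len(n))
  for (p in all_p) {
    rho <- cor(rank(x), rank(y)[p])
    if (abs(rho) >= abs(rho_obs) - 1e-12) hits <- hits + 1
  }
  hits / length(all_p)
}

# Gotoh affine-gap local-alignment score (score only, quadratic DP).
# Gap of length L costs open + L * extend, matching the aligner.
sw_score_oracle <- function(a, b, match = 2, mismatch = -3,
                            open = 5, extend = 2) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)  # gap in a (deletion from b)
  F <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (a[i - 1] == b[j - 1]) match else mismatch
      E[i, j] <- max(H[i, j - 1] - open - extend, E[i, j - 1] - extend)
      F[i, j] <- max(H[i - 1, j] - open - extend, F[i - 1, j] - extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Uniform random distributions for JSD property tests.
random_distribution <- function(k) {
  x <- rexp(k)
  x / sum(x)
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Small annotation table fixture.
toy_annotations <- function() {
  data.frame(
    genome_id = rep(c("g1", "g2"), c(8, 4)),
    gene_id = paste0("gene", 1:12),
    category = c("A", "A", "A", "B", NA, NA, NA, NA,
                 "A", "A", "B", "B"),
    is_protein_coding = TRUE,
    is_cazyme = c(TRUE, rep(FALSE, 7), TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

read_matrix_tsv_for_test <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}
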