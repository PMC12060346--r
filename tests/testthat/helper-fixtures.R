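# Shared fixtures, built in code at test time.

# small deterministic count matrix with named dims
toy_counts <- function(values, n_mirna, n_sample,
                       mirnas = sprintf("miR-%d", seq_len(n_mirna)),
                       samples = sprintf("s%d", seq_len(n_sample))) {
  m <- matrix(values, nrow = n_mirna, ncol = n_sample,
              dimnames = list(mirnas, samples))
  mir_counts(m)
}

# random valid count matrix for property tests
random_counts <- function(n_mirna = 20, n_sample = 6, lambda = 50) {
  m <- matrix(rpois(n_mirna * n_sample, lambda) + 1L, nrow = n_mirna,
              dimnames = list(sprintf("miR-%d", seq_len(n_mirna)),
                              sprintf("s%d", seq_len(n_sample))))
  mir_counts(m)
}

# independent brute-force BH step-up oracle: for the k-th smallest p,
# adj = min(1, min over j >= k of m * p_(j) / j), mapped back to input order
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj_sorted <- numeric(m)
  for (k in seq_len(m)) {
    vals <- vapply(k:m, function(j) m * ps[j] / j, numeric(1))
    adj_sorted[k] <- min(1, min(vals))
  }
  out <- numeric(m)
  out[ord] <- adj_sorted
  out
}

# default config relaxed for small test matrices
small_config <- function(...) {
  pipeline_config(min_reads = 0L, min_samples_expressed = 0L, ...)
}

# a simple ratio table with all ten species
ratio_row <- function(id, ratios) {
  stopifnot(length(ratios) == 10)
  df <- data.frame(id = id, stringsAsFactors = FALSE)
  for (i in seq_along(FISH_SPECIES)) df[[FISH_SPECIES[i]]] <- ratios[i]
  df
}
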