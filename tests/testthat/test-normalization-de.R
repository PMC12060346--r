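test_that("cpm scales by library size and every column sums to one million", {
  x <- toy_counts(c(1, 1, 2, 0, 0, 4), 3, 2)
  out <- cpm(x)
  expect_equal(unname(out[, 1]), c(250000, 250000, 500000))

  set.seed(31)
  for (i in 1:10) {
    y <- random_counts(20, 6)
    expect_equal(unname(colSums(cpm(y))), rep(1e6, 6))
  }

  z <- matrix(c(1L, 2L, 0L, 0L), 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(cpm(z), "zero library size for sample 's2'")
})

test_that("size factors reproduce hand-computed medians of ratios", {
  # identical columns give unit factors
  x <- toy_counts(rep(c(5, 9, 2), 3), 3, 3)
  expect_equal(unname(size_factors(x)), c(1, 1, 1))

  # rows (2,4) and (4,8): geometric means sqrt(8) and sqrt(32)
  y <- toy_counts(c(2, 4, 4, 8), 2, 2)
  expect_equal(unname(size_factors(y)), c(1 / sqrt(2), sqrt(2)))

  # doubling one column doubles its factor relative to the other
  # (closed form: geomeans gain sqrt(2), so (1/sqrt2, sqrt2) -> (1/2, 2))
  z2 <- toy_counts(c(2, 4, 8, 16), 2, 2)
  expect_equal(unname(size_factors(z2)), c(0.5, 2))

  w <- matrix(c(0L, 1L, 1L, 0L), 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(size_factors(w), "no reference features")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(33)
  # an odd number of zero-free rows makes the median a single element, so
  # the ratio-scale and log-scale medians coincide exactly
  for (i in 1:5) {
    x <- random_counts(31, 5, lambda = 80)
    expect_equal(unname(size_factors(x)),
                 unname(DESeq2::estimateSizeFactorsForMatrix(x$counts)),
                 tolerance = 1e-12)
  }
})

test_that("size factors are invariant to a common count rescaling", {
  # ratios to the geometric mean are scale-free, so a common factor cancels
  set.seed(34)
  x <- random_counts(25, 4, lambda = 40)
  expect_equal(size_factors(x$counts * 3L), size_factors(x))
})

test_that("the low-count filter keeps miRNAs expressed in enough samples", {
  # 14 samples; row A has >=10 reads in exactly 10, row B in 9
  m <- matrix(0L, 2, 14, dimnames = list(c("A", "B"), sprintf("s%d", 1:14)))
  m["A", 1:10] <- 10L
  m["B", 1:9] <- 50L
  m[, 14] <- m[, 14] + 1L  # avoid zero libraries
  out <- filter_low_counts(m, min_reads = 10, min_samples_expressed = 10)
  expect_identical(out$kept, "A")
  expect_identical(out$dropped, "B")

  all_kept <- filter_low_counts(m, min_reads = 0, min_samples_expressed = 10)
  expect_setequal(all_kept$kept, c("A", "B"))

  expect_error(filter_low_counts(m, 10, 15), "exceeds the number of samples")
})

test_that("BH adjustment equals a brute-force step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  # exhaustive grids of length <= 8
  grid_vals <- c(0.013, 0.1, 0.5, 0.9)
  for (n in 1:6) {
    combos <- as.matrix(expand.grid(rep(list(grid_vals), n)))
    for (i in seq_len(nrow(combos))) {
      p <- unname(combos[i, ])
      expect_equal(bh_adjust(p), bh_oracle(p))
    }
  }
  for (n in 7:8) {
    combos <- as.matrix(expand.grid(rep(list(c(0.02, 0.6)), n)))
    for (i in seq_len(nrow(combos))) {
      p <- unname(combos[i, ])
      expect_equal(bh_adjust(p), bh_oracle(p))
    }
  }

  # random cases: output dominates input and is permutation-equivariant
  set.seed(41)
  for (i in 1:20) {
    p <- runif(sample(2:12, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p))
    expect_true(all(adj >= p))
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), adj[perm])
  }
})

test_that("ddCt fold change matches a per-sample oracle", {
  ct_t <- c(a = 25, b = 26, c = 20, d = 21)
  ct_r <- c(a = 20, b = 21, c = 16, d = 17)
  # treated dCt == control dCt -> fold change 1
  expect_equal(ddct_fold_change(ct_t, ct_r, c("a", "b"), c("c", "d")),
               2^(-(mean(c(4, 4)) - mean(c(5, 5)))))
  expect_equal(ddct_fold_change(c(a = 20, b = 19), c(a = 15, b = 15),
                                "a", "b"), 2)  # ddCt = -1

  set.seed(51)
  for (i in 1:10) {
    ids <- sprintf("s%d", 1:6)
    tt <- setNames(runif(6, 18, 30), ids)
    rr <- setNames(runif(6, 15, 22), ids)
    ctrl <- ids[1:3]; trt <- ids[4:6]
    oracle <- 2^(-(mean(tt[trt] - rr[trt]) - mean(tt[ctrl] - rr[ctrl])))
    expect_equal(ddct_fold_change(tt, rr, ctrl, trt), oracle)
  }
  expect_error(ddct_fold_change(ct_t, ct_r, character(0), "a"), "non-empty")
})

test_that("the NB-Wald test is null on identical groups and group-antisymmetric", {
  m <- matrix(50L, 5, 8, dimnames = list(sprintf("m%d", 1:5),
                                         sprintf("s%d", 1:8)))
  res <- nb_wald_de(m, sprintf("s%d", 1:4), sprintf("s%d", 5:8),
                    small_config())
  expect_equal(res$log2fc, rep(0, 5))
  expect_equal(res$wald_z, rep(0, 5))
  expect_equal(res$p, rep(1, 5))

  set.seed(61)
  x <- random_counts(40, 8, lambda = 100)
  a <- sprintf("s%d", 1:4); b <- sprintf("s%d", 5:8)
  fwd <- nb_wald_de(x, a, b, small_config())
  rev <- nb_wald_de(x, b, a, small_config())
  expect_equal(rev$log2fc, -fwd$log2fc)
  expect_equal(rev$p, fwd$p)
  expect_equal(rev$adj_p, fwd$adj_p)

  expect_error(nb_wald_de(x, a, c("s4", "s5")), "overlap")
  expect_error(nb_wald_de(x, "s1", b), "at least 2")
})

test_that("untested miRNAs carry no statistics and significance honours the cutoff", {
  set.seed(62)
  x <- random_counts(30, 8, lambda = 60)
  x$counts[1:5, ] <- 0L
  x$counts[1:5, 1] <- 1L  # low-count rows
  res <- nb_wald_de(mir_counts(x$counts), sprintf("s%d", 1:4),
                    sprintf("s%d", 5:8),
                    pipeline_config(min_reads = 10,
                                    min_samples_expressed = 6))
  low <- res$mirna %in% sprintf("miR-%d", 1:5)
  expect_true(all(!res$tested[low]))
  expect_true(all(is.na(res$p[low])))
  expect_true(all(!res$significant[low]))
  ok <- res$tested
  expect_true(all(res$adj_p[ok] >= res$p[ok]))
  expect_identical(res$significant, res$tested & !is.na(res$adj_p) &
                     res$adj_p < 0.05)
})

test_that("planted fold changes are recovered without bias at moderate depth", {
  set.seed(63)
  n0 <- 300; n1 <- 100
  muA <- rep(200, n0 + n1); muB <- c(rep(200, n0), rep(800, n1))
  mA <- matrix(rnbinom((n0 + n1) * 4, size = 5, mu = muA), ncol = 4)
  mB <- matrix(rnbinom((n0 + n1) * 4, size = 5, mu = muB), ncol = 4)
  m <- cbind(mA, mB)
  dimnames(m) <- list(sprintf("m%d", seq_len(n0 + n1)), sprintf("s%d", 1:8))
  res <- nb_wald_de(m, sprintf("s%d", 1:4), sprintf("s%d", 5:8),
                    small_config())
  est <- res$log2fc[(n0 + 1):(n0 + n1)]
  expect_lt(abs(median(est) - 2), 0.5)
})
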