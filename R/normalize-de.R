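# Normalization and differential expression: CPM, median-of-ratios size
# factors, the low-count filter, a moment-dispersion NB-Wald two-group test
# with BH correction, and the qPCR 2^-ddCt fold change.

#' Counts per million
#'
#' Scales every count by its sample's library size times 1e6.
#'
#' @param x a [mir_counts] object or count matrix.
#' @return numeric matrix of CPM values; every column sums to 1e6.
#' @export
cpm <- function(x) {
  m <- as_count_matrix(x)
  libs <- colSums(m)
  if (any(libs == 0)) {
    stop(sprintf("zero library size for sample '%s'",
                 colnames(m)[libs == 0][1L]))
  }
  t(t(m) / libs) * 1e6
}

#' Median-of-ratios size factors
#'
#' For each sample j, the size factor is the median over reference miRNAs i
#' of count_ij / geometric-mean_i, where reference miRNAs are the rows with
#' no zero count (the estimator DESeq-style normalization is built on).
#'
#' @param x a [mir_counts] object or count matrix.
#' @return named numeric vector of per-sample size factors.
#' @export
size_factors <- function(x) {
  m <- as_count_matrix(x)
  ref <- rowSums(m == 0) == 0L
  if (!any(ref)) stop("no reference features: every miRNA has a zero count")
  r <- m[ref, , drop = FALSE]
  geo <- exp(rowMeans(log(r)))
  apply(r / geo, 2L, stats::median)
}

#' Low-count filter
#'
#' Keeps a miRNA iff at least `min_samples_expressed` samples of the full
#' matrix carry at least `min_reads` counts. Applied once globally on all
#' samples, before any subsetting into contrasts.
#'
#' @param x a [mir_counts] object or count matrix.
#' @param min_reads per-sample read threshold (default 10).
#' @param min_samples_expressed required number of samples at or above the
#'   threshold (default 10).
#' @return list with character vectors `kept` and `dropped`.
#' @export
filter_low_counts <- function(x, min_reads = 10L, min_samples_expressed = 10L) {
  m <- as_count_matrix(x)
  stopifnot(min_reads >= 0, min_samples_expressed >= 0)
  if (min_samples_expressed > ncol(m)) {
    stop(sprintf("min_samples_expressed (%d) exceeds the number of samples (%d)",
                 min_samples_expressed, ncol(m)))
  }
  keep <- rowSums(m >= min_reads) >= min_samples_expressed
  list(kept = rownames(m)[keep], dropped = rownames(m)[!keep])
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity, capped
#' at 1. Inputs outside `[0, 1]` are rejected.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must be numeric in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Relative quantification fold change (2^-ddCt)
#'
#' Per sample, dCt = Ct(target) - Ct(reference); ddCt is the mean dCt of the
#' treated group minus the mean dCt of the control group; the fold change is
#' 2^-ddCt.
#'
#' @param ct_target,ct_reference named numeric vectors of threshold cycles,
#'   indexed by sample id.
#' @param control_ids,treated_ids sample ids of the two groups (non-empty).
#' @return the fold change of the treated group relative to control.
#' @export
ddct_fold_change <- function(ct_target, ct_reference, control_ids,
                             treated_ids) {
  if (length(control_ids) == 0L || length(treated_ids) == 0L) {
    stop("both the control and the treated group must be non-empty")
  }
  all_ids <- c(control_ids, treated_ids)
  if (!all(all_ids %in% names(ct_target)) ||
      !all(all_ids %in% names(ct_reference))) {
    stop("every sample id must index both Ct vectors")
  }
  dct <- ct_target[all_ids] - ct_reference[all_ids]
  if (any(!is.finite(dct))) stop("all Ct values must be finite")
  ddct <- mean(dct[treated_ids]) - mean(dct[control_ids])
  2^(-ddct)
}

row_vars <- function(m) {
  n <- ncol(m)
  if (n < 2L) return(rep(NA_real_, nrow(m)))
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

#' Negative-binomial Wald test for a two-group contrast
#'
#' A documented approximation of the shrinkage-free NB generalized linear
#' model route: counts are divided by median-of-ratios size factors
#' (computed on the two contrasted groups' samples), group means `m_A` and
#' `m_B` are formed, and
#' `log2fc = log2((m_B + 0.5) / (m_A + 0.5))` (contrast B over A, the 0.5
#' pseudo-mean avoiding log of zero). A per-miRNA moment dispersion
#' `alpha = max(0, (pooled var - pooled mean) / pooled mean^2)` (clamped at
#' 1e-8) yields the delta-method standard error
#' `SE^2 = [(1/m_A + alpha)/n_A + (1/m_B + alpha)/n_B] / ln(2)^2`, a Wald
#' `z = (log2fc - lfc_null) / SE`, a two-sided normal p-value, and BH
#' adjustment across the miRNAs that survive the low-count filter (which is
#' evaluated on the full supplied matrix before subsetting). No dispersion
#' shrinkage, outlier refitting or independent filtering is performed.
#'
#' @param x a [mir_counts] object or count matrix containing (at least) the
#'   two groups' samples.
#' @param group_a,group_b disjoint character vectors of sample ids (>= 2
#'   each); the reported fold change is B over A.
#' @param config a [pipeline_config()] supplying `min_reads`,
#'   `min_samples_expressed`, `adj_p_cutoff` and `lfc_null`.
#' @return data.frame with one row per miRNA: `mirna`, `base_mean`,
#'   `log2fc`, `wald_z`, `p`, `adj_p`, `tested`, `significant`. Filtered
#'   miRNAs carry `tested = FALSE` and NA statistics.
#' @export
nb_wald_de <- function(x, group_a, group_b, config = pipeline_config()) {
  m <- as_count_matrix(x)
  if (length(intersect(group_a, group_b))) {
    stop("groups overlap: ", paste(intersect(group_a, group_b), collapse = ", "))
  }
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("both groups need at least 2 samples")
  }
  missing_ids <- setdiff(c(group_a, group_b), colnames(m))
  if (length(missing_ids)) {
    stop("sample id(s) not in the count matrix: ",
         paste(missing_ids, collapse = ", "))
  }

  keep <- filter_low_counts(m, config$min_reads,
                            config$min_samples_expressed)$kept
  tested <- rownames(m) %in% keep

  sub <- m[, c(group_a, group_b), drop = FALSE]
  sf <- size_factors(sub)
  q <- t(t(sub) / sf)
  qa <- q[, group_a, drop = FALSE]
  qb <- q[, group_b, drop = FALSE]
  na <- length(group_a)
  nb <- length(group_b)
  ma <- rowMeans(qa)
  mb <- rowMeans(qb)
  base_mean <- rowMeans(q)
  log2fc <- log2((mb + 0.5) / (ma + 0.5))

  pooled_var <- ((na - 1) * row_vars(qa) + (nb - 1) * row_vars(qb)) /
    (na + nb - 2)
  pooled_mean <- (na * ma + nb * mb) / (na + nb)
  alpha <- (pooled_var - pooled_mean) / pooled_mean^2
  alpha[!is.finite(alpha)] <- 0
  alpha <- pmax(alpha, 1e-8)

  se2 <- ((1 / ma + alpha) / na + (1 / mb + alpha) / nb) / log(2)^2
  se <- sqrt(se2)
  z <- ifelse(is.finite(se), (log2fc - config$lfc_null) / se, 0)
  p <- 2 * stats::pnorm(-abs(z))

  res <- data.frame(mirna = rownames(m), base_mean = base_mean,
                    log2fc = log2fc, wald_z = z, p = p,
                    adj_p = NA_real_, tested = tested,
                    significant = FALSE, stringsAsFactors = FALSE)
  res$log2fc[!tested] <- NA_real_
  res$wald_z[!tested] <- NA_real_
  res$p[!tested] <- NA_real_
  if (any(tested)) {
    res$adj_p[tested] <- bh_adjust(res$p[tested])
  }
  res$significant <- res$tested & !is.na(res$adj_p) &
    res$adj_p < config$adj_p_cutoff
  rownames(res) <- NULL
  res
}
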