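#' @title Cohort statistics: Pearson correlation and exact Wilcoxon signed rank
#' @description
#' The small cohorts of a first-in-human dosimetry study (a handful of
#' kidneys and lesions) call for exact small-sample inference. The Wilcoxon
#' signed-rank p-value is computed from the exact permutation null — the
#' distribution of the positive-rank sum over all 2^n sign assignments —
#' rather than a large-sample approximation; with 8 one-signed pairs this
#' gives the exact two-sided p = 2/256 ~ 0.0078. Pearson's r is tested with
#' the t transform on n - 2 degrees of freedom.
#' @name cohort_stats
NULL

#' Pearson product-moment correlation with two-sided p-value
#'
#' @param x,y equal-length numeric vectors (n >= 3, nonzero variance).
#' @return list `r`, `p_value`, `n`, `df`, `statistic` (the t value).
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    abort_acdosim("need equal-length vectors with n >= 3", "acdosim_invalid_input")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort_acdosim("values must be finite", "acdosim_invalid_input")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_acdosim("zero variance in one of the variables", "acdosim_degenerate_input")
  }
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  if (abs(r) >= 1) {
    p <- 0
    tstat <- sign(r) * Inf
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p_value = p, n = n, df = n - 2, statistic = tstat)
}

# Exact null distribution of the positive-rank sum, on doubled ranks so that
# mid-ranks of ties stay integral. Dynamic-programming convolution over the
# rank polynomial prod(1 + z^r_i): coefficient k is the number of sign
# assignments with doubled rank sum k. Identical to enumerating all 2^n
# assignments, in O(n * sum(r)) time.
.signrank_null <- function(doubled_ranks) {
  total <- sum(doubled_ranks)
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (r in doubled_ranks) {
    shifted <- c(numeric(r), f[seq_len(total + 1L - r)])
    f <- f + shifted
  }
  f # counts over doubled sums 0..total
}

#' Exact Wilcoxon signed-rank test
#'
#' Paired two-sided test of symmetric differences about zero. Zero differences
#' are dropped (their count is reported); tied absolute differences receive
#' mid-ranks. For `n <= exact_max_n` (default 25) the p-value is exact, from
#' the full sign-assignment null distribution; above that a normal
#' approximation with continuity and tie correction is used. The two-sided
#' p is `2 * min(P(W <= w), P(W >= w))`, capped at 1.
#'
#' @param x,y paired measurements; or differences in `x` with `y` omitted.
#' @param exact_max_n largest n for which the exact null is enumerated.
#' @return list `statistic` (W, the positive-rank sum), `p_value`, `n_used`,
#'   `n_zero_dropped`, `method`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max_n = 25L) {
  d <- if (is.null(y)) x else x - y
  if (any(!is.finite(d))) abort_acdosim("differences must be finite",
                                        "acdosim_invalid_input")
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    abort_acdosim("all differences are zero", "acdosim_degenerate_input")
  }
  ranks <- rank(abs(d))
  w <- sum(ranks[d > 0])
  if (n <= exact_max_n) {
    d2 <- as.integer(round(2 * ranks))
    f <- .signrank_null(d2)
    total <- sum(d2)
    w2 <- as.integer(round(2 * w))
    denom <- 2^n
    p_le <- sum(f[seq_len(w2 + 1L)]) / denom
    p_ge <- sum(f[seq.int(w2 + 1L, total + 1L)]) / denom
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(ranks)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- (w - mu - 0.5 * sign(w - mu)) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approximation"
  }
  list(statistic = w, p_value = p, n_used = n, n_zero_dropped = n_zero,
       method = method)
}

#' All kidney-lesion pairs within patients
#'
#' Builds the cross-pairing used to compare kidney and lesion doses when no
#' natural one-to-one pairing exists: within each patient, every kidney VOI
#' is paired with every lesion VOI, in the order the VOIs are listed.
#'
#' @param voi_table data.frame with columns `patient`, `voi`, `value` and a
#'   logical column `is_lesion`.
#' @return data.frame with columns `patient`, `kidney_voi`, `lesion_voi`,
#'   `kidney_value`, `lesion_value`.
#' @export
kidney_lesion_pairs <- function(voi_table) {
  out <- list()
  for (p in unique(voi_table$patient)) {
    sub <- voi_table[voi_table$patient == p, ]
    kid <- sub[!sub$is_lesion, ]
    les <- sub[sub$is_lesion, ]
    if (nrow(kid) == 0 || nrow(les) == 0) next
    grid <- expand.grid(k = seq_len(nrow(kid)), l = seq_len(nrow(les)))
    grid <- grid[order(grid$k, grid$l), ]
    out[[length(out) + 1L]] <- data.frame(
      patient = p,
      kidney_voi = kid$voi[grid$k], lesion_voi = les$voi[grid$l],
      kidney_value = kid$value[grid$k], lesion_value = les$value[grid$l])
  }
  if (!length(out)) {
    abort_acdosim("no kidney-lesion pairs available", "acdosim_pairing_error")
  }
  do.call(rbind, out)
}
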