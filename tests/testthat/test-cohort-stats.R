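test_that("pearson r and p follow the t transform", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_test(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_test(x, -3 * x + 10)$r, -1)
  set.seed(9)
  for (i in 1:20) {
    n <- sample(4:15, 1)
    a <- rnorm(n); b <- 0.8 * a + rnorm(n)
    ours <- pearson_test(a, b)
    ref <- stats::cor.test(a, b)   # independent cross-check
    expect_equal(ours$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
  # r = 0.96 with 9 pairs is significant below 1e-4
  r <- 0.96; n <- 9
  t <- r * sqrt((n - 2) / (1 - r^2))
  expect_lt(2 * pt(-t, n - 2), 1e-4)
  expect_error(pearson_test(c(1, 1, 1), c(1, 2, 3)),
               class = "acdosim_degenerate_input")
  expect_error(pearson_test(1:2, 2:3), class = "acdosim_invalid_input")
})

test_that("pearson r is invariant under positive affine transforms", {
  set.seed(21)
  a <- rnorm(10); b <- rnorm(10)
  r0 <- pearson_test(a, b)$r
  expect_equal(pearson_test(3 * a + 2, b)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_test(a, 0.1 * b - 5)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_test(-a, b)$r, -r0, tolerance = 1e-12)
})

test_that("eight one-signed pairs give the exact two-sided p of 2/256", {
  w <- wilcoxon_signed_rank(rnorm(8, mean = 5, sd = 0.5))
  expect_equal(w$p_value, 2 / 256)
  expect_equal(round(w$p_value, 4), 0.0078)
  expect_equal(w$statistic, 36)    # all positive: W is the full rank sum
  expect_identical(w$method, "exact")
})

test_that("wilcoxon edge cases: single pair, symmetric pair, zero differences", {
  expect_equal(wilcoxon_signed_rank(3.2)$p_value, 1.0)
  expect_equal(wilcoxon_signed_rank(c(4, -4))$p_value, 1.0)
  w <- wilcoxon_signed_rank(c(0, 0, 1, 2, 3))
  expect_equal(w$n_zero_dropped, 2L)
  expect_equal(w$n_used, 3L)
  expect_error(wilcoxon_signed_rank(c(0, 0, 0)), class = "acdosim_degenerate_input")
})

test_that("exact p matches brute-force sign enumeration up to n = 12", {
  set.seed(33)
  for (i in 1:40) {
    n <- sample(2:12, 1)
    d <- round(rnorm(n), sample(0:1, 1))  # rounding induces ties and zeros
    d <- d[d != 0]
    if (length(d) < 2) next
    expect_equal(wilcoxon_signed_rank(d)$p_value, brute_force_signrank_p(d),
                 tolerance = 1e-12)
  }
  # and against the standard exact implementation when there are no ties
  for (i in 1:20) {
    d <- rnorm(sample(5:20, 1))
    ref <- stats::wilcox.test(d, exact = TRUE)$p.value
    expect_equal(wilcoxon_signed_rank(d)$p_value, ref, tolerance = 1e-12)
  }
})

test_that("large-sample branch approximates the exact p", {
  set.seed(14)
  d <- rnorm(30, mean = 0.3)
  approx <- wilcoxon_signed_rank(d, exact_max_n = 25)
  exact <- wilcoxon_signed_rank(d, exact_max_n = 40)
  expect_identical(approx$method, "normal_approximation")
  expect_identical(exact$method, "exact")
  expect_equal(approx$p_value, exact$p_value, tolerance = 0.15)
})

test_that("type-I error at alpha = 0.05 matches the discrete exact level", {
  n <- 10
  # exact attainable level: P(p <= 0.05) under the null, computable from the
  # null distribution itself (no ties with continuous data)
  ranks <- 1:n
  w_all <- vapply(0:(2^n - 1), function(b) {
    sum(ranks[bitwAnd(b, 2^(0:(n - 1))) > 0])
  }, 0)
  p_of_w <- function(w) {
    min(1, 2 * min(mean(w_all <= w), mean(w_all >= w)))
  }
  exact_level <- mean(vapply(w_all, p_of_w, 0) <= 0.05)
  set.seed(99)
  rejections <- mean(vapply(1:2000, function(i) {
    wilcoxon_signed_rank(rnorm(n))$p_value <= 0.05
  }, TRUE))
  se <- sqrt(exact_level * (1 - exact_level) / 2000)
  expect_lt(abs(rejections - exact_level), 4 * se)
})

test_that("kidney-lesion cross-pairing enumerates all within-patient pairs", {
  tab <- data.frame(
    patient = c("p2", "p2", "p2", "p2", "p3", "p3", "p3"),
    voi = c("kidney_left", "kidney_right", "lesion_1", "lesion_2",
            "kidney_left", "kidney_right", "lesion_1"),
    is_lesion = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE),
    value = c(0.15, 0.18, 0.35, 0.4, 0.2, 0.17, 0.3))
  pairs <- kidney_lesion_pairs(tab)
  expect_equal(nrow(pairs), 2 * 2 + 2 * 1)
  expect_true(all(pairs$lesion_value > pairs$kidney_value))
  expect_error(kidney_lesion_pairs(tab[tab$is_lesion, ]),
               class = "acdosim_pairing_error")
})
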