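test_that("WHO T-score allocation uses the inclusive band edges", {
  expect_equal(as.character(allocate_group(c(-6.5, -2.7, -2.5))),
               rep("osteoporotic", 3))
  expect_equal(as.character(allocate_group(c(-0.9, -1.0, 0, 1.6))),
               rep("normal", 4))
  expect_equal(as.character(allocate_group(c(-1.8, -2.49, -1.01))),
               rep("osteopenia", 3))
  expect_error(allocate_group(NA_real_), "finite")
  expect_error(allocate_group(Inf), "finite")
})

test_that("bonferroni is min(1, m p)", {
  expect_equal(bonferroni(0.02, 3), 0.06)
  expect_equal(bonferroni(0.5, 3), 1)
  expect_equal(bonferroni(0.123, 1), 0.123)
  ps <- seq(0, 1, by = 0.01)
  for (m in c(1, 2, 7, 19)) expect_equal(bonferroni(ps, m), pmin(1, m * ps))
  expect_error(bonferroni(1.2, 2), "\\[0, 1\\]")
  expect_error(bonferroni(0.5, 0), "count")
})

test_that("the Shapiro-Wilk gate has its nominal operating characteristics", {
  expect_error(normality_gate(c(1, 2)), "at least 3")
  flat <- normality_gate(rep(2.5, 10))
  expect_false(flat$normal)                      # degenerate routed nonparametric

  set.seed(2201)
  pass_normal <- mean(replicate(1000, normality_gate(rnorm(30))$normal))
  expect_gte(pass_normal, 0.90)                  # level ~0.05 on normal data

  set.seed(2202)
  reject_exp <- mean(!replicate(500, normality_gate(rexp(50))$normal))
  expect_gte(reject_exp, 0.80)                   # power against exponential
})

test_that("signed-rank p-values match exhaustive sign enumeration", {
  # the canonical all-positive case: one-sided 1/64 at n = 6
  d <- c(1, 2, 3, 4, 5, 6)
  expect_equal(enumerate_signed_rank_p(d, "greater"), 1 / 64)
  expect_equal(humerometry:::signed_rank_p(d + 10, rep(10, 6)),
               enumerate_signed_rank_p(d))

  set.seed(99)
  for (n in c(5, 7, 8, 10)) {
    for (rep in 1:5) {
      x <- round(rnorm(n, 0, 5), 3)
      y <- round(rnorm(n, 1, 5), 3)
      d <- x - y
      if (any(d == 0) || any(duplicated(abs(d)))) next
      expect_equal(humerometry:::signed_rank_p(x, y), enumerate_signed_rank_p(d),
                   tolerance = 1e-12)
    }
  }
})

test_that("within-group comparison routes by the gate and handles nulls", {
  # identical values across regions: degenerate, nothing significant
  vals <- data.frame(h = rep(20, 6), m1 = rep(20, 6), m2 = rep(20, 6))
  ct <- compare_regions_within_group(vals)
  expect_equal(ct$raw_p, rep(1, 3))
  expect_false(any(ct$significant))

  # clean gaussian data takes the parametric path with paired contrasts
  set.seed(31)
  vals2 <- data.frame(h = rnorm(6, 25, 1), m1 = rnorm(6, 20, 1), m2 = rnorm(6, 20, 1))
  ct2 <- compare_regions_within_group(vals2)
  expect_true(all(ct2$test_used == "repeated_measures_parametric"))
  expect_equal(ct2$n_comparisons, rep(3, 3))
  expect_equal(ct2$adjusted_p, pmin(1, 3 * ct2$raw_p))
  expect_false(is.na(attr(ct2, "anova_p")))

  # a grossly non-normal region routes the whole family to signed-rank
  vals3 <- vals2
  vals3$m2 <- c(1, 1.01, 1.02, 1.03, 1.04, 90)
  ct3 <- compare_regions_within_group(vals3)
  expect_true(all(ct3$test_used == "wilcoxon_signed_rank"))

  expect_error(compare_regions_within_group(vals2[1:2, ]), "3 complete donors")
  expect_error(compare_regions_within_group(vals2[, 1, drop = FALSE]), "2 regions")
})

test_that("within-group results do not depend on donor order", {
  set.seed(77)
  vals <- data.frame(h = rnorm(8, 25, 2), sc1 = rnorm(8, 18, 2), sc2 = rnorm(8, 20, 2))
  ct_a <- compare_regions_within_group(vals)
  ct_b <- compare_regions_within_group(vals[sample(8), ])
  expect_equal(tibble::as_tibble(ct_a), tibble::as_tibble(ct_b))
})

test_that("between-group comparison: Welch t against the closed form", {
  x <- c(24.1, 25.3, 26.0, 24.8, 25.5, 23.9)
  y <- c(18.2, 19.1, 17.5, 18.8, 19.4, 18.0)
  ct <- compare_groups(x, y)
  expect_equal(ct$test_used, "t_test")

  # independent closed-form Welch computation
  s1 <- var(x) / length(x); s2 <- var(y) / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(s1 + s2)
  df <- (s1 + s2)^2 / (s1^2 / (length(x) - 1) + s2^2 / (length(y) - 1))
  p_oracle <- 2 * stats::pt(-abs(tstat), df)
  expect_equal(ct$raw_p, p_oracle, tolerance = 1e-10)

  ct_id <- compare_groups(x, x)
  expect_equal(ct_id$raw_p, 1)

  expect_error(compare_groups(x[1:2], y), "at least 3")
})

test_that("a 13-percentage-point effect at n = 6 is almost always detected", {
  set.seed(41)
  hits <- replicate(500, {
    compare_groups(rnorm(6, 25, 2), rnorm(6, 12, 2))$significant
  })
  expect_gte(mean(hits), 0.95)
})

test_that("tidy and glance summarize comparison tables", {
  set.seed(5)
  vals <- data.frame(a = rnorm(6, 10), b = rnorm(6, 11), c = rnorm(6, 12))
  ct <- compare_regions_within_group(vals)
  td <- tidy(ct)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("comparison", "test_used", "raw_p", "adjusted_p",
                     "n_comparisons", "significant"))
  gl <- glance(ct)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_comparisons, 3)
})
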