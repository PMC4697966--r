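#' Bonferroni correction
#'
#' @param raw_p Probability (or vector of probabilities) in `[0, 1]`.
#' @param m Number of comparisons in the family (>= 1).
#' @return `min(1, m * raw_p)`, elementwise.
#' @export
bonferroni <- function(raw_p, m) {
  if (any(!is.finite(raw_p)) || any(raw_p < 0) || any(raw_p > 1)) {
    stop("raw_p must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(m) || length(m) != 1L || m < 1) {
    stop("m must be a single count >= 1", call. = FALSE)
  }
  pmin(1, m * raw_p)
}

#' Shapiro-Wilk normality gate
#'
#' The test-selection gate of the comparison workflow: a sample is treated as
#' normally distributed iff the Shapiro-Wilk p-value exceeds `alpha_gate`.
#' Samples with no variance cannot be tested and are routed to the
#' nonparametric path (`normal = FALSE`, `W = NA`).
#'
#' @param x Numeric sample, 3 <= n <= 5000.
#' @param alpha_gate Gate level (default 0.05).
#' @return List with `normal` (logical), `W` statistic and `p_value`.
#' @export
normality_gate <- function(x, alpha_gate = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 3L) stop("normality gate needs at least 3 values", call. = FALSE)
  if (length(x) > 5000L) stop("normality gate supports at most 5000 values", call. = FALSE)
  if (stats::sd(x) < .Machine$double.eps) {
    return(list(normal = FALSE, W = NA_real_, p_value = NA_real_))
  }
  sw <- stats::shapiro.test(x)
  list(normal = sw$p.value > alpha_gate, W = unname(sw$statistic), p_value = sw$p.value)
}

new_comparison_table <- function(df) {
  class(df) <- c("comparison_table", class(df))
  df
}

# paired signed-rank p-value: exact for n <= exact_max without ties/zeros,
# else normal approximation with continuity correction (wilcox.test defaults)
signed_rank_p <- function(x, y, exact_max = 25) {
  d <- x - y
  use_exact <- length(d) <= exact_max && all(d != 0) && !any(duplicated(abs(d)))
  suppressWarnings(
    stats::wilcox.test(x, y, paired = TRUE, exact = use_exact, correct = TRUE)$p.value
  )
}

#' Compare regions within one donor group
#'
#' The within-group leg of the workflow: per-region values from the same
#' donors are compared across regions. Every region's sample is put through
#' the [normality_gate()]; if all pass, the family takes the parametric path
#' (one-way repeated-measures ANOVA with donor as the error stratum, plus
#' pairwise paired t contrasts), otherwise every pairwise contrast uses the
#' related-samples Wilcoxon signed-rank test. All pairwise p-values are
#' Bonferroni-adjusted with m = number of region pairs. Donors with a missing
#' value in any region are dropped (and counted in `n_dropped`).
#'
#' @param values Data frame or matrix, donors in rows, one column per region
#'   (column names are the region labels); or a long tibble with columns
#'   `donor_id`, `region`, `value`.
#' @param alpha Significance level (default 0.05).
#' @param alpha_gate Normality-gate level.
#' @return A `comparison_table` tibble: one row per region pair with
#'   `comparison`, `test_used`, `raw_p`, `adjusted_p`, `n_comparisons`,
#'   `significant`. Attributes: `gate` (per-region gate results),
#'   `anova_p` (overall repeated-measures p, parametric path only),
#'   `n_donors`, `n_dropped`.
#' @export
compare_regions_within_group <- function(values, alpha = 0.05, alpha_gate = 0.05) {
  if (is.data.frame(values) && all(c("donor_id", "region", "value") %in% names(values))) {
    values <- tidyr::pivot_wider(values[c("donor_id", "region", "value")],
                                 names_from = "region", values_from = "value")
    values <- as.data.frame(values[-1], row.names = values$donor_id)
  }
  values <- as.data.frame(values)
  if (ncol(values) < 2L) stop("need at least 2 regions to compare", call. = FALSE)
  complete <- stats::complete.cases(values)
  n_dropped <- sum(!complete)
  values <- values[complete, , drop = FALSE]
  n <- nrow(values)
  if (n < 3L) stop("fewer than 3 complete donors; cannot compare regions", call. = FALSE)

  gate <- purrr::map(values, normality_gate, alpha_gate = alpha_gate)
  all_normal <- all(vapply(gate, `[[`, TRUE, "normal"))

  pairs <- utils::combn(names(values), 2, simplify = FALSE)
  m <- length(pairs)

  anova_p <- NA_real_
  if (all_normal) {
    long <- data.frame(
      value = unlist(values, use.names = FALSE),
      region = factor(rep(names(values), each = n)),
      donor = factor(rep(seq_len(n), times = ncol(values)))
    )
    fit <- stats::aov(value ~ region + Error(donor), data = long)
    smry <- summary(fit)
    within <- smry[["Error: Within"]][[1]]
    anova_p <- within[["Pr(>F)"]][1]
  }

  rows <- purrr::map(pairs, function(pr) {
    x <- values[[pr[1]]]; y <- values[[pr[2]]]
    if (isTRUE(all.equal(x, y))) {
      raw_p <- 1                      # degenerate identical samples: no evidence
      test <- if (all_normal) "repeated_measures_parametric" else "wilcoxon_signed_rank"
    } else if (all_normal) {
      raw_p <- stats::t.test(x, y, paired = TRUE)$p.value
      test <- "repeated_measures_parametric"
    } else {
      raw_p <- signed_rank_p(x, y)
      test <- "wilcoxon_signed_rank"
    }
    if (!is.finite(raw_p)) raw_p <- 1
    tibble::tibble(
      comparison = paste(pr, collapse = " vs "),
      test_used = test,
      raw_p = raw_p,
      adjusted_p = bonferroni(raw_p, m),
      n_comparisons = m,
      significant = bonferroni(raw_p, m) <= alpha
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "gate") <- gate
  attr(out, "anova_p") <- anova_p
  attr(out, "n_donors") <- n
  attr(out, "n_dropped") <- n_dropped
  attr(out, "alpha") <- alpha
  new_comparison_table(out)
}

#' Compare one variable between two donor groups
#'
#' The between-group leg: both samples are put through the
#' [normality_gate()]; if both pass, a two-sided Welch t-test is used,
#' otherwise a two-sided independent-samples Wilcoxon rank-sum test. (The
#' independent-samples rank test is the coherent nonparametric counterpart
#' for unpaired groups.)
#'
#' @param values_g1,values_g2 Numeric samples, each n >= 3.
#' @param alpha Significance level.
#' @param alpha_gate Normality-gate level.
#' @param m Family size for Bonferroni adjustment (default 1: report raw).
#' @param comparison Label for the output row.
#' @return One-row `comparison_table` tibble.
#' @export
compare_groups <- function(values_g1, values_g2, alpha = 0.05, alpha_gate = 0.05,
                           m = 1, comparison = "group 1 vs group 2") {
  values_g1 <- values_g1[is.finite(values_g1)]
  values_g2 <- values_g2[is.finite(values_g2)]
  if (length(values_g1) < 3L || length(values_g2) < 3L) {
    stop("both groups need at least 3 values", call. = FALSE)
  }
  g1 <- normality_gate(values_g1, alpha_gate)
  g2 <- normality_gate(values_g2, alpha_gate)
  if (isTRUE(all.equal(sort(values_g1), sort(values_g2)))) {
    raw_p <- 1
    test <- if (g1$normal && g2$normal) "t_test" else "rank_sum"
  } else if (g1$normal && g2$normal) {
    raw_p <- stats::t.test(values_g1, values_g2, var.equal = FALSE)$p.value
    test <- "t_test"
  } else {
    use_exact <- !any(duplicated(c(values_g1, values_g2)))
    raw_p <- suppressWarnings(
      stats::wilcox.test(values_g1, values_g2, exact = use_exact, correct = TRUE)$p.value
    )
    test <- "rank_sum"
  }
  if (!is.finite(raw_p)) raw_p <- 1
  out <- tibble::tibble(
    comparison = comparison,
    test_used = test,
    raw_p = raw_p,
    adjusted_p = bonferroni(raw_p, m),
    n_comparisons = m,
    significant = bonferroni(raw_p, m) <= alpha
  )
  attr(out, "gate") <- list(g1 = g1, g2 = g2)
  attr(out, "alpha") <- alpha
  new_comparison_table(out)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy comparison_table
#' @export
tidy.comparison_table <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @method glance comparison_table
#' @export
glance.comparison_table <- function(x, ...) {
  tibble::tibble(
    n_comparisons = x$n_comparisons[1],
    test_used = paste(unique(x$test_used), collapse = "+"),
    n_significant = sum(x$significant),
    min_adjusted_p = min(x$adjusted_p),
    anova_p = if (is.null(attr(x, "anova_p"))) NA_real_ else attr(x, "anova_p"),
    alpha = if (is.null(attr(x, "alpha"))) 0.05 else attr(x, "alpha")
  )
}
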