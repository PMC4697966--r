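#' Pipeline run configuration
#'
#' Bundles every tunable of the measurement chain with its default, and a
#' stable hash that is embedded in all result files so two runs can be
#' checked for configuration identity.
#'
#' @param calibration mm per pixel of the input rasters.
#' @param angular_step Plate-ray spacing in degrees (divisor of 180).
#' @param n_segments Head-height segments for cortical levels.
#' @param plate_min_run Minimum bone run (px) accepted as the subchondral
#'   plate when terminating line e.
#' @param m_strip_len Distal extent of m1/m2 in units of s1.
#' @param shaft_fraction Distal envelope fraction used to fit line a.
#' @param alpha Significance level of all tests.
#' @param alpha_gate Shapiro-Wilk gate level.
#' @param seed Integer seed for anything stochastic downstream.
#' @return A list of class `run_config` with a `config_hash` element.
#' @export
run_config <- function(calibration = 0.025, angular_step = 10, n_segments = 8,
                       plate_min_run = 3, m_strip_len = 2, shaft_fraction = 0.35,
                       alpha = 0.05, alpha_gate = 0.05, seed = 1L) {
  cfg <- list(
    calibration = calibration, angular_step = angular_step,
    n_segments = n_segments, plate_min_run = plate_min_run,
    m_strip_len = m_strip_len, shaft_fraction = shaft_fraction,
    alpha = alpha, alpha_gate = alpha_gate, seed = as.integer(seed)
  )
  if (180 %% angular_step != 0) stop("angular_step must divide 180", call. = FALSE)
  if (alpha <= 0 || alpha >= 1 || alpha_gate <= 0 || alpha_gate >= 1) {
    stop("alpha and alpha_gate must lie in (0, 1)", call. = FALSE)
  }
  cfg$config_hash <- rlang::hash(cfg)
  structure(cfg, class = "run_config")
}

#' Run the full geometric and morphometric chain on one section
#'
#' Convenience composition: fits line a, constructs the landmark system,
#' partitions the regions, builds the measurement sites and measures the
#' section.
#'
#' @param section A [section_image()].
#' @param ann An [annotation()].
#' @param config A [run_config()].
#' @return List with `landmarks`, `regions`, `sites`, `result`.
#' @export
analyze_section <- function(section, ann, config = run_config()) {
  validate_annotation(ann, section)
  env <- tissue_envelope(section$bone_mask, section$cartilage_mask)
  bnd <- mask_boundary(env)
  line_a <- fit_long_axis(section, ann, shaft_fraction = config$shaft_fraction, env = env)
  lm <- construct_landmarks(section, ann, line_a, plate_min_run = config$plate_min_run,
                            env = env, boundary = bnd)
  regions <- partition_regions(section, lm, m_strip_len = config$m_strip_len, env = env,
                               boundary = bnd)
  sites <- build_thickness_sites(lm, angular_step = config$angular_step,
                                 n_segments = config$n_segments)
  result <- measure_section(section, regions, sites, env = env, boundary = bnd)
  list(landmarks = lm, regions = regions, sites = sites, result = result)
}

log_line <- function(con, msg) {
  line <- sprintf("%s %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), msg)
  if (!is.null(con)) writeLines(line, con)
  invisible(line)
}

#' Measure a set of donors and write per-donor result files
#'
#' Accepts either a materialized [generate_cohort()] tibble (list-columns
#' `section` and `annotation`, or `section_spec` when not materialized) or a
#' tibble of file paths (`donor_id`, `bone_path`, `cartilage_path`,
#' `annotation_path`). Per-donor failures are logged and skipped; the run
#' errors only if every donor fails.
#'
#' @param config A [run_config()].
#' @param donors Input tibble as described above.
#' @param out_dir Output directory; per-donor CSVs go to
#'   `out_dir/<donor_id>/`, the run log to `out_dir/run.log`. Every CSV
#'   starts with a `# config_hash:` comment line.
#' @return Tibble with `donor_id`, `ok`, `message`, and the combined result
#'   tibbles (`bvtv`, `plate`, `cortical`) of the successful donors as
#'   attribute `results`.
#' @export
run_measure <- function(config, donors, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  logc <- file(file.path(out_dir, "run.log"), open = "a")
  on.exit(close(logc), add = TRUE)
  log_line(logc, sprintf("run_measure start, config %s", config$config_hash))

  status <- purrr::map(seq_len(nrow(donors)), function(i) {
    id <- donors$donor_id[i]
    t0 <- Sys.time()
    res <- tryCatch({
      if ("section" %in% names(donors) && !is.null(donors$section[[i]])) {
        section <- donors$section[[i]]
        ann <- donors$annotation[[i]]
      } else if ("section_spec" %in% names(donors)) {
        gen <- generate_section(donors$section_spec[[i]])
        section <- gen$section
        ann <- gen$annotation
      } else {
        section <- read_section(donors$bone_path[i], donors$cartilage_path[i],
                                config$calibration, donors$medial_side[i], id)
        ann <- read_annotation(donors$annotation_path[i])
      }
      out <- analyze_section(section, ann, config)$result
      ddir <- file.path(out_dir, id)
      write_results(out, ddir, header = sprintf("# config_hash: %s", config$config_hash))
      log_line(logc, sprintf("donor %s ok (%.1f s)", id,
                             as.numeric(difftime(Sys.time(), t0, units = "secs"))))
      list(ok = TRUE, message = "ok", result = out)
    }, error = function(e) {
      log_line(logc, sprintf("donor %s FAILED: %s", id, conditionMessage(e)))
      list(ok = FALSE, message = conditionMessage(e), result = NULL)
    })
    res
  })
  ok <- vapply(status, `[[`, TRUE, "ok")
  if (!any(ok)) stop("all donors failed in run_measure; see run.log", call. = FALSE)
  results <- list(
    bvtv = dplyr::bind_rows(purrr::map(status[ok], ~ .x$result$bvtv)),
    plate = dplyr::bind_rows(purrr::map(status[ok], ~ .x$result$plate)),
    cortical = dplyr::bind_rows(purrr::map(status[ok], ~ .x$result$cortical))
  )
  out <- tibble::tibble(
    donor_id = donors$donor_id,
    ok = ok,
    message = vapply(status, `[[`, "", "message")
  )
  attr(out, "results") <- results
  out
}

#' Run the two-group comparison study
#'
#' Executes the full comparison workflow over measured results: within each
#' group, region families are compared with the normality-gated repeated
#' measures / signed-rank path; between groups, every region and measurement
#' site is compared with the gated Welch-t / rank-sum path. Bonferroni
#' correction is applied within each comparison family (e.g. the region pairs
#' of one within-group family, or the 7 regions of the between-group BV/TV
#' family), not across families. Donors in the osteopenia band are excluded
#' with a warning.
#'
#' @param results List of tibbles `bvtv`, `plate`, `cortical` (attribute
#'   `results` of [run_measure()], or [read_results()] output bound over
#'   donors).
#' @param donors Donor tibble with `donor_id` and `t_score` (and/or `group`).
#' @param config A [run_config()].
#' @param out_dir Optional directory for `comparisons.csv` + `summary.csv`.
#' @return A `comparison_table` tibble with columns `family`, `group`,
#'   `comparison`, `test_used`, `raw_p`, `adjusted_p`, `n_comparisons`,
#'   `significant`; the per-family summary is attribute `summary`.
#' @export
run_study <- function(results, donors, config = run_config(), out_dir = NULL) {
  if (!"group" %in% names(donors)) donors$group <- allocate_group(donors$t_score)
  n_pen <- sum(donors$group == "osteopenia")
  if (n_pen > 0) {
    warning(sprintf("excluding %d donor(s) in the osteopenia band from the two-group comparison", n_pen))
    donors <- donors[donors$group != "osteopenia", ]
  }
  donors$group <- droplevels(factor(donors$group))
  if (any(table(donors$group) < 3) || length(unique(donors$group)) < 2) {
    stop("need at least 3 donors in each of the two groups", call. = FALSE)
  }
  alpha <- config$alpha; agate <- config$alpha_gate

  bv <- dplyr::inner_join(results$bvtv, donors[c("donor_id", "group")], by = "donor_id")
  rows <- list()

  # between-group BV/TV, one family over the regions
  regions <- unique(bv$region)
  m <- length(regions)
  rows$between_bvtv <- dplyr::bind_rows(purrr::map(regions, function(rg) {
    d <- bv[bv$region == rg, ]
    ct <- compare_groups(d$bvtv[d$group == "normal"], d$bvtv[d$group == "osteoporotic"],
                         alpha = alpha, alpha_gate = agate, m = m,
                         comparison = sprintf("%s: normal vs osteoporotic", rg))
    ct$family <- "between_group_bvtv"; ct$group <- NA_character_
    ct
  }))

  # between-group thickness families, per site
  site_family <- function(df, key_cols, fam) {
    df <- dplyr::inner_join(df, donors[c("donor_id", "group")], by = "donor_id")
    keys <- dplyr::distinct(df[key_cols])
    m <- nrow(keys)
    dplyr::bind_rows(purrr::map(seq_len(m), function(i) {
      sel <- rep(TRUE, nrow(df))
      for (kc in key_cols) sel <- sel & df[[kc]] == keys[[kc]][i]
      d <- df[sel & is.finite(df$thickness_mm), ]
      lab <- paste(unlist(keys[i, ]), collapse = ", ")
      ct <- tryCatch(
        compare_groups(d$thickness_mm[d$group == "normal"],
                       d$thickness_mm[d$group == "osteoporotic"],
                       alpha = alpha, alpha_gate = agate, m = m,
                       comparison = sprintf("%s: normal vs osteoporotic", lab)),
        error = function(e) tibble::tibble(
          comparison = sprintf("%s: normal vs osteoporotic", lab),
          test_used = NA_character_, raw_p = NA_real_, adjusted_p = NA_real_,
          n_comparisons = m, significant = NA
        )
      )
      ct$family <- fam; ct$group <- NA_character_
      ct
    }))
  }
  rows$between_plate <- site_family(results$plate, "angle", "between_group_plate")
  rows$between_cortical <- site_family(results$cortical, c("side", "level"),
                                       "between_group_cortical")

  # within-group region families
  fams <- list(
    head_subcapital = c("h", "sc1", "sc2"),
    head_metaphyseal = c("h", "m1", "m2"),
    subchondral_inner = c("subchondral", "inner")
  )
  for (grp in levels(donors$group)) {
    for (fam in names(fams)) {
      sub <- bv[bv$group == grp & bv$region %in% fams[[fam]], ]
      wide <- tidyr::pivot_wider(sub[c("donor_id", "region", "bvtv")],
                                 names_from = "region", values_from = "bvtv")
      ct <- compare_regions_within_group(as.data.frame(wide[-1]),
                                         alpha = alpha, alpha_gate = agate)
      ct2 <- tibble::as_tibble(ct)
      ct2$family <- paste0("within_", fam)
      ct2$group <- grp
      rows[[paste(grp, fam, sep = "_")]] <- ct2
    }
  }

  comparisons <- dplyr::bind_rows(rows)
  comparisons <- comparisons[c("family", "group", "comparison", "test_used",
                               "raw_p", "adjusted_p", "n_comparisons", "significant")]
  summary <- dplyr::summarise(
    dplyr::group_by(comparisons, .data$family, .data$group),
    test_path = paste(unique(stats::na.omit(.data$test_used)), collapse = "+"),
    n_comparisons = dplyr::first(.data$n_comparisons),
    n_significant = sum(.data$significant, na.rm = TRUE),
    .groups = "drop"
  )
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    hdr <- sprintf("# config_hash: %s", config$config_hash)
    writeLines(hdr, file.path(out_dir, "comparisons.csv"))
    readr::write_csv(comparisons, file.path(out_dir, "comparisons.csv"),
                     append = TRUE, col_names = TRUE)
    writeLines(hdr, file.path(out_dir, "summary.csv"))
    readr::write_csv(summary, file.path(out_dir, "summary.csv"),
                     append = TRUE, col_names = TRUE)
  }
  attr(comparisons, "summary") <- summary
  attr(comparisons, "alpha") <- alpha
  new_comparison_table(comparisons)
}
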