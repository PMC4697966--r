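#' Specification of a two-group synthetic cohort
#'
#' Emulates a donor cohort of normal and osteoporotic individuals: per group,
#' `n_per_group` donors whose section targets jitter around a group template.
#' The osteoporotic-like template is the normal-like template with per-region
#' multiplicative BV/TV reductions (`effect_map`), strongest in the first
#' subcapital band and the medial metaphysis; subchondral plate thickness is
#' held equal across groups. T-scores are drawn from group distributions
#' truncated to the WHO band of the group label.
#'
#' @param n_per_group Donors per group (>= 3; statistics need at least 3).
#' @param base A [section_spec()] used as the normal-like template.
#' @param effect_map Named multiplicative BV/TV reductions applied to the
#'   normal-like targets for the osteoporotic-like group.
#' @param jitter_logit_sd Per-donor Gaussian jitter of each region target on
#'   the logit of the bone-area fraction (keeps targets inside (0, 1)).
#' @param t_score_normal,t_score_osteo `c(mean, sd)` of the group T-score
#'   distributions; the normal mean must be >= -1, the osteoporotic <= -2.5.
#' @param osteo_cortical Cortical profile list for the osteoporotic-like
#'   group (default: thinner distal medial cortex, lateral unchanged).
#' @param seed Integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 6,
                        base = section_spec(),
                        effect_map = c(h = 0.75, subchondral = 0.78, inner = 0.72,
                                       sc1 = 0.55, sc2 = 0.65,
                                       m1 = 0.60, m2 = 0.65, rest = 0.70),
                        jitter_logit_sd = 0.06,
                        t_score_normal = c(0.3, 0.8),
                        t_score_osteo = c(-4.0, 1.0),
                        osteo_cortical = list(medial = c(0.8, 2.2),
                                              lateral = c(0.8, 2.5)),
                        seed = 1L) {
  if (!is.numeric(n_per_group) || n_per_group < 3) {
    stop("n_per_group must be >= 3 (the comparison workflow needs 3 donors)", call. = FALSE)
  }
  stopifnot(inherits(base, "section_spec"))
  if (t_score_normal[1] < -1.0) {
    stop("normal-like T-score template mean must be >= -1.0", call. = FALSE)
  }
  if (t_score_osteo[1] > -2.5) {
    stop("osteoporotic-like T-score template mean must be <= -2.5", call. = FALSE)
  }
  if (any(!is.finite(effect_map)) || any(effect_map <= 0) || any(effect_map > 1)) {
    stop("effect_map entries must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(n_per_group = as.integer(n_per_group), base = base,
         effect_map = effect_map, jitter_logit_sd = jitter_logit_sd,
         t_score_normal = t_score_normal, t_score_osteo = t_score_osteo,
         osteo_cortical = osteo_cortical, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- stats::rnorm(1, mean, sd)
      if (x >= lower && x <= upper) break
    }
    out[i] <- x
  }
  out
}

jitter_targets <- function(targets, sd) {
  p <- targets / 100
  100 * stats::plogis(stats::qlogis(p) + stats::rnorm(length(p), 0, sd))
}

#' Generate a synthetic two-group cohort
#'
#' @param spec A [cohort_spec()].
#' @param materialize If `TRUE` (default) every donor's section is rasterized
#'   immediately; if `FALSE` only the per-donor [section_spec()]s are built
#'   (call [generate_section()] on them one at a time to bound memory).
#' @return A tibble with one row per donor: `donor_id`, `group`, `age`,
#'   `sex`, `t_score`, `targets` (list of jittered ground-truth targets),
#'   `section_spec` (list), and, when materialized, `section`, `annotation`,
#'   `ground_truth` list-columns.
#' @export
generate_cohort <- function(spec, materialize = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(spec$seed)

  n <- spec$n_per_group
  base <- spec$base
  base_targets <- expand_targets(base$region_bvtv_targets)

  rows <- purrr::map(seq_len(2 * n), function(i) {
    grp <- if (i <= n) "normal" else "osteoporotic"
    tmpl <- base_targets
    if (grp == "osteoporotic") {
      em <- spec$effect_map[names(tmpl)]
      em[is.na(em)] <- spec$effect_map["h"] %||% 1
      tmpl <- tmpl * em
    }
    tg <- jitter_targets(tmpl, spec$jitter_logit_sd)
    t_score <- if (grp == "normal") {
      rtrunc_norm(1, spec$t_score_normal[1], spec$t_score_normal[2], lower = -1.0)
    } else {
      rtrunc_norm(1, spec$t_score_osteo[1], spec$t_score_osteo[2], upper = -2.5)
    }
    age <- if (grp == "normal") round(rtrunc_norm(1, 59, 25, 19, 90))
           else round(rtrunc_norm(1, 79, 9, 60, 95))
    donor_seed <- (spec$seed %% 100000L) * 10000L + i
    sspec <- section_spec(
      head_radius = base$head_radius, shaft_width = base$shaft_width,
      cartilage_thickness = base$cartilage_thickness,
      plate_thickness = base$plate_thickness,
      cortical_thickness = if (grp == "osteoporotic") spec$osteo_cortical
                           else base$cortical_thickness,
      rim_thickness = base$rim_thickness,
      region_bvtv_targets = tg,
      trabecular_width = base$trabecular_width,
      neck_tilt_deg = base$neck_tilt_deg,
      head_offset = base$head_offset,
      mm_per_pixel = base$mm_per_pixel,
      medial_side = base$medial_side,
      donor_id = sprintf("S%02d", i),
      seed = donor_seed
    )
    tibble::tibble(
      donor_id = sspec$donor_id,
      group = grp,
      age = age,
      sex = sample(c("M", "F"), 1),
      t_score = t_score,
      targets = list(tg),
      section_spec = list(sspec)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$group <- factor(out$group, levels = c("normal", "osteoporotic"))

  if (materialize) {
    gen <- purrr::map(out$section_spec, generate_section)
    out$section <- purrr::map(gen, "section")
    out$annotation <- purrr::map(gen, "annotation")
    out$ground_truth <- purrr::map(gen, "ground_truth")
  }
  class(out) <- c("synthetic_cohort", class(out))
  out
}

# resolve h vs subchondral/inner fallbacks into the full 7-key target vector
expand_targets <- function(tg) {
  c(
    subchondral = unname(tg["subchondral"] %||% tg["h"]),
    inner = unname(tg["inner"] %||% tg["h"]),
    sc1 = unname(tg["sc1"]), sc2 = unname(tg["sc2"]),
    m1 = unname(tg["m1"]), m2 = unname(tg["m2"]),
    rest = unname(tg["rest"] %||% 20)
  )
}
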