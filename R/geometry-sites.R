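#' Build the thickness measurement sites
#'
#' Two site families are derived from the landmarks:
#'
#' * Subchondral plate rays: rays from the head center (midpoint of line b)
#'   across the articular semicircle at `angular_step` degree intervals,
#'   inclusive of both endpoints, so the default 10 degree step yields 19
#'   rays. Angle 0 points along line b toward its caudal end, 90 toward the
#'   articular apex (line e), 180 toward the cranial end.
#' * Cortical levels: `n_segments + 1` levels per side (medial and lateral),
#'   starting at the level of line c and proceeding distally along line a in
#'   steps of head height / `n_segments`; the default 8 segments give the 9
#'   measuring points per side.
#'
#' @param lm A [construct_landmarks()] result.
#' @param angular_step Ray spacing in degrees; must divide 180.
#' @param n_segments Number of equal head-height segments (>= 1).
#' @return A list of class `thickness_sites` with tibbles `plate_rays`
#'   (`angle`, `dir_x`, `dir_y`) and `cortical_levels` (`side`, `level`, `x`,
#'   `y`), plus the geometry needed by the thickness operators.
#' @export
build_thickness_sites <- function(lm, angular_step = 10, n_segments = 8) {
  if (!is.numeric(angular_step) || angular_step <= 0 || 180 %% angular_step != 0) {
    stop("angular_step must be a positive divisor of 180", call. = FALSE)
  }
  if (!is.numeric(n_segments) || n_segments < 1) {
    stop("n_segments must be >= 1", call. = FALSE)
  }
  angles <- seq(0, 180, by = angular_step)
  th <- deg2rad(angles)
  dirs <- cbind(
    cos(th) * (-lm$b_hat[1]) + sin(th) * lm$e_hat[1],
    cos(th) * (-lm$b_hat[2]) + sin(th) * lm$e_hat[2]
  )
  plate_rays <- tibble::tibble(angle = angles, dir_x = dirs[, 1], dir_y = dirs[, 2])

  a_hat <- lm$a_hat
  ca <- lm$line_b$caudal
  A0 <- lm$line_a$point + vdot(ca - lm$line_a$point, a_hat) * a_hat
  spacing <- lm$head_height / n_segments
  lv <- 0:n_segments
  centers <- cbind(A0[1] - lv * spacing * a_hat[1], A0[2] - lv * spacing * a_hat[2])
  cortical_levels <- tibble::tibble(
    side = rep(c("medial", "lateral"), each = length(lv)),
    level = rep(lv, times = 2),
    x = rep(centers[, 1], times = 2),
    y = rep(centers[, 2], times = 2)
  )

  structure(
    list(
      plate_rays = plate_rays,
      cortical_levels = cortical_levels,
      head_center = lm$head_center,
      a_hat = a_hat,
      medial_hat = lm$medial_hat,
      level_spacing = spacing,
      angular_step = angular_step,
      n_segments = n_segments
    ),
    class = "thickness_sites"
  )
}
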