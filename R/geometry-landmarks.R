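#' Fit the humeral long axis (line a)
#'
#' The central long axis of the humerus anchors the whole landmark system. If
#' the annotation carries a `shaft_axis_override`, the line through those two
#' points is returned unchanged. Otherwise the axis is the principal
#' second-moment axis of the most distal `shaft_fraction` of the tissue
#' envelope (bone plus cartilage, holes filled), which on a frontal section is
#' the parallel-sided shaft. The returned line is oriented distal to proximal
#' (toward the articular cartilage).
#'
#' @param section A [section_image()].
#' @param ann An [annotation()], or `NULL` when no override is available.
#' @param shaft_fraction Fraction (0, 0.6] of the envelope, taken from the
#'   distal end along a preliminary whole-bone axis, used for the moment fit.
#' @param env Optional precomputed tissue envelope (logical matrix), to avoid
#'   recomputing it across pipeline stages.
#' @return A line: `list(point, direction)` with a unit direction vector.
#' @export
fit_long_axis <- function(section, ann = NULL, shaft_fraction = 0.35, env = NULL) {
  stride <- 2L  # moment fits are insensitive to 2x subsampling of the envelope
  if (!is.numeric(shaft_fraction) || shaft_fraction <= 0 || shaft_fraction > 0.6) {
    stop("shaft_fraction must lie in (0, 0.6]", call. = FALSE)
  }
  if (!is.null(ann) && !is.null(ann$shaft_axis_override)) {
    p1 <- ann$shaft_axis_override[[1]]
    p2 <- ann$shaft_axis_override[[2]]
    dir <- vunit(p2 - p1)
    return(new_line(p1, orient_proximal(dir, p1, section)))
  }
  if (is.null(env)) env <- tissue_envelope(section$bone_mask, section$cartilage_mask)
  if (sum(env) < 100L) stop("degenerate mask: tissue envelope under 100 px", call. = FALSE)
  sub <- env
  if (nrow(env) * ncol(env) > 4e5) {
    keep_i <- seq(1L, nrow(env), by = stride); keep_j <- seq(1L, ncol(env), by = stride)
    sub <- matrix(FALSE, nrow(env), ncol(env))
    sub[keep_i, keep_j] <- env[keep_i, keep_j]
  }
  xy <- mask_coords(sub)
  pre <- principal_axis(xy)
  a_hat <- orient_proximal(pre$direction, pre$center, section)
  # second-moment PCA alone is unstable when the distal block is nearly
  # square; refine by regressing the cross-axis offset centroid of slim
  # slices on the along-axis position (exact for a parallel-sided shaft),
  # iterating so the distal selection itself converges
  center <- pre$center
  for (it in 1:3) {
    proj <- (xy[, 1] - center[1]) * a_hat[1] + (xy[, 2] - center[2]) * a_hat[2]
    cut <- stats::quantile(proj, shaft_fraction)
    sel <- proj <= cut
    distal <- xy[sel, , drop = FALSE]
    t <- proj[sel]
    u <- (distal[, 1] - center[1]) * vperp(a_hat)[1] +
         (distal[, 2] - center[2]) * vperp(a_hat)[2]
    bins <- cut(t, breaks = 22)
    tc <- tapply(t, bins, mean); uc <- tapply(u, bins, mean)
    ok <- is.finite(tc) & is.finite(uc)
    # drop the end slices, which straddle the oblique selection boundary
    ok[c(1, 2, length(ok) - 1, length(ok))] <- FALSE
    slope <- stats::coef(stats::lm(uc[ok] ~ tc[ok]))[[2]]
    dir <- vunit(a_hat + slope * vperp(a_hat))
    if (vdot(dir, a_hat) < 0) dir <- -dir
    a_hat <- dir
    center <- c(mean(distal[, 1]), mean(distal[, 2]))
  }
  new_line(center, a_hat)
}

# orient a direction so it points proximally: toward the cartilage centroid
# when cartilage exists, else toward the image top
orient_proximal <- function(dir, from, section) {
  if (any(section$cartilage_mask)) {
    ref <- mask_centroid(section$cartilage_mask) - from
  } else {
    ref <- c(0, -1)
  }
  if (vdot(dir, ref) < 0) -dir else dir
}

# unit vector perpendicular to a_hat pointing to the anatomically medial side
medial_unit <- function(a_hat, medial_side) {
  m <- vperp(a_hat)
  if (abs(m[1]) < 1e-12) stop("long axis is horizontal; medial direction undefined", call. = FALSE)
  want <- if (medial_side == "left") -1 else 1
  if (sign(m[1]) != want) m <- -m
  m
}

#' Construct the landmark system (lines a-e, s1, s2, head height)
#'
#' From the fitted long axis and the two annotated cartilage endpoints this
#' builds the full construction-line system on which every region and
#' measurement site rests:
#'
#' * line b — chord from the cranial to the caudal end of the articular
#'   cartilage; its course approximates the anatomical neck, its midpoint is
#'   the head center.
#' * line c — perpendicular to line a through the caudal end of line b.
#' * line d — parallel to line a, tangent to the medial periosteal contour
#'   within the distal third of the section (ties resolved to the more distal
#'   point); it splits line c into a medial and a lateral segment.
#' * line e — from the midpoint of line b, perpendicular to it, toward the
#'   articular surface, ending at the inner surface of the subchondral plate.
#'   The plate is detected as the contiguous bone run attached to the inner
#'   cartilage boundary along the search ray; the run must be at least
#'   `plate_min_run` px thick, otherwise an error names the search path.
#' * s1 — one third of the medial segment of line c; s2 — one third of line e.
#' * head height — distance along line a from line c to the most proximal
#'   point of the articular cartilage, the reference distance for the cortical
#'   measurement levels.
#'
#' @param section A [section_image()].
#' @param ann An [annotation()] with valid cartilage endpoints.
#' @param line_a Oriented long axis from [fit_long_axis()].
#' @param plate_min_run Minimum contiguous bone run (px) accepted as the
#'   subchondral plate when terminating line e.
#' @param env Optional precomputed tissue envelope.
#' @param boundary Optional precomputed envelope boundary mask.
#' @return An object of class `landmark_set`.
#' @export
construct_landmarks <- function(section, ann, line_a, plate_min_run = 3, env = NULL,
                                boundary = NULL) {
  a_hat <- line_a$direction
  cr <- ann$cranial_cartilage_end
  ca <- ann$caudal_cartilage_end
  b_hat <- vunit(cr - ca)
  m <- (cr + ca) / 2
  b_half <- vnorm(cr - ca) / 2

  cart <- section$cartilage_mask
  if (!any(cart)) stop("section has no cartilage; landmark system undefined", call. = FALSE)
  cart_ctr <- mask_centroid(cart)
  e_hat <- vperp(b_hat)
  if (vdot(e_hat, cart_ctr - m) < 0) e_hat <- -e_hat

  m_hat <- medial_unit(a_hat, section$medial_side)
  line_c <- new_line(ca, m_hat)

  if (is.null(env)) env <- tissue_envelope(section$bone_mask, cart)
  if (is.null(boundary)) boundary <- mask_boundary(env)
  bxy <- mask_coords(boundary)
  proj_a <- (bxy[, 1] - line_a$point[1]) * a_hat[1] + (bxy[, 2] - line_a$point[2]) * a_hat[2]
  lo <- min(proj_a); hi <- max(proj_a)
  distal_third <- proj_a <= lo + (hi - lo) / 3
  if (!any(distal_third)) stop("medial periosteal tangent not found: no distal boundary", call. = FALSE)
  dxy <- bxy[distal_third, , drop = FALSE]
  u <- (dxy[, 1] - m[1]) * m_hat[1] + (dxy[, 2] - m[2]) * m_hat[2]
  umax <- max(u)
  cand <- which(u > umax - 0.5)            # medial-most within half a pixel
  pa <- proj_a[distal_third][cand]
  tangent_pt <- dxy[cand[which.min(pa)], ] # tie-break: more distal
  line_d <- new_line(tangent_pt, a_hat)

  # medial segment of line c: from the line d intersection to the medial end
  # of line c. The medial end is the caudal cartilage end itself — line c is
  # constructed through it, and the cartilage margin sits on the medial
  # periosteal surface — so the annotated point anchors the segment exactly.
  X_d <- lines_intersect(line_c, line_d)
  P_med <- ca
  med_seg <- vnorm(P_med - X_d)
  if (med_seg < 3) {
    stop("medial segment of line c is degenerate (line d passes through the caudal cartilage end)",
         call. = FALSE)
  }
  s1 <- med_seg / 3

  # line e: search ray from the head center toward the articular surface
  es <- ray_samples(m, e_hat, 2.5 * b_half, step = 0.25)
  e_cart <- mask_at(cart, es)
  if (!any(e_cart)) {
    stop("line e found no articular cartilage along its search path from the head center", call. = FALSE)
  }
  runs <- split(which(e_cart), cumsum(c(1, diff(which(e_cart)) != 1)))
  outer_run <- runs[[which.max(vapply(runs, max, 0))]]
  i_in <- min(outer_run)
  e_bone <- mask_at(section$bone_mask, es)
  k <- i_in - 1L
  gap <- 0L
  while (k >= 1L && !e_bone[k] && gap < 2L) { k <- k - 1L; gap <- gap + 1L }
  run_len <- 0L
  while (k - run_len >= 1L && e_bone[k - run_len]) run_len <- run_len + 1L
  if (run_len * 0.25 < plate_min_run) {
    stop(sprintf(
      "line e found no subchondral plate (bone run %.2f px < %g px) walking inward from the cartilage along direction (%.3f, %.3f) from (%.1f, %.1f)",
      run_len * 0.25, plate_min_run, e_hat[1], e_hat[2], m[1], m[2]
    ), call. = FALSE)
  }
  j_end <- k - run_len + 1L              # innermost plate sample
  L_e <- (j_end - 1L) * 0.25
  E <- es[j_end, ]
  s2 <- L_e / 3

  cart_xy <- mask_coords(cart)
  proj_cart <- (cart_xy[, 1] - ca[1]) * a_hat[1] + (cart_xy[, 2] - ca[2]) * a_hat[2]
  head_height <- max(proj_cart)

  structure(
    list(
      line_a = line_a,
      line_b = list(point = ca, direction = b_hat, cranial = cr, caudal = ca),
      line_c = line_c,
      line_d = line_d,
      line_e = list(point = m, direction = e_hat, end = E, length = L_e),
      s1_length = s1,
      s2_length = s2,
      head_center = m,
      head_height = head_height,
      b_half = b_half,
      a_hat = a_hat,
      b_hat = b_hat,
      e_hat = e_hat,
      medial_hat = m_hat,
      medial_c_end = P_med,
      line_cd_intersection = X_d,
      medial_segment_length = med_seg
    ),
    class = "landmark_set"
  )
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf(
    "<landmark_set> head center (%.1f, %.1f) px; |line e| %.1f px; s1 %.2f px; s2 %.2f px; head height %.1f px\n",
    x$head_center[1], x$head_center[2], x$line_e$length, x$s1_length, x$s2_length, x$head_height
  ))
  invisible(x)
}
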