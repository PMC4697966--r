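#' Trabecular bone area fraction (BV/TV) within a region
#'
#' BV/TV is the counting estimate used throughout 2D histomorphometry:
#' 100 x (bone pixels inside the region) / (all pixels inside the region).
#' Regions are given either as integer pixel indices (the representation
#' produced by [partition_regions()]) or as a simple polygon, in which case
#' pixels are assigned by the pixel-center rule with no partial-pixel
#' weighting.
#'
#' @param section A [section_image()].
#' @param region Integer vector of image indices, or a polygon as a
#'   data frame / matrix with columns `x`, `y` (continuous px coordinates).
#' @return BV/TV as a percentage in `[0, 100]`.
#' @export
bv_tv <- function(section, region) {
  idx <- region_pixel_indices(region, dim(section$bone_mask))
  if (length(idx) == 0L) stop("zero-area region: no pixel centers inside", call. = FALSE)
  100 * sum(section$bone_mask[idx]) / length(idx)
}

region_pixel_indices <- function(region, dims) {
  if (is.numeric(region) && is.null(dim(region)) && !is.data.frame(region)) {
    return(as.integer(region))
  }
  poly <- as.matrix(as.data.frame(region)[, c("x", "y")])
  if (nrow(poly) < 3L) stop("polygon needs at least 3 vertices", call. = FALSE)
  j0 <- max(1L, floor(min(poly[, 1]))); j1 <- min(dims[2], ceiling(max(poly[, 1])))
  i0 <- max(1L, floor(min(poly[, 2]))); i1 <- min(dims[1], ceiling(max(poly[, 2])))
  if (j1 < j0 || i1 < i0) return(integer(0))
  jj <- j0:j1; ii <- i0:i1
  px <- rep(jj, each = length(ii)); py <- rep(ii, times = length(jj))
  inside <- points_in_polygon(px, py, poly)
  as.integer((px[inside] - 1L) * dims[1] + py[inside])
}

# periosteal (non-articular) envelope boundary: boundary pixels of the filled
# tissue envelope that are not on or next to articular cartilage — the
# cortex is subperiosteal, so the subchondral margin never serves as a
# cortical measurement contour
periosteal_boundary_xy <- function(section, env = NULL, boundary = NULL) {
  if (is.null(env)) env <- tissue_envelope(section$bone_mask, section$cartilage_mask)
  bnd <- if (is.null(boundary)) mask_boundary(env) else boundary
  cart_dil <- EBImage::dilate(EBImage::Image(section$cartilage_mask * 1),
                              EBImage::makeBrush(5, shape = "box"))
  mask_coords(bnd & !(matrix(as.numeric(cart_dil), nrow = nrow(env)) > 0.5))
}

# even-odd crossing test, vectorized over points
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  xs <- poly[, 1]; ys <- poly[, 2]
  jprev <- n
  for (i in seq_len(n)) {
    x1 <- xs[jprev]; y1 <- ys[jprev]; x2 <- xs[i]; y2 <- ys[i]
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      flip <- crosses & (px < xint)
      inside[flip] <- !inside[flip]
    }
    jprev <- i
  }
  inside
}

#' Subchondral plate thickness along one radial ray
#'
#' Walks outward from the head center, finds the outermost run of articular
#' cartilage crossed by the ray, and measures the contiguous bone run
#' attached to the cartilage's inner edge walking back inward: the distance
#' from the end of the cartilage to the beginning of the marrow cavity. The
#' outward-then-inward walk makes the measurement robust to trabeculae lying
#' further along the path. Rays that cross no cartilage return `NA` — missing
#' is a value here, not an error, and is excluded from statistics rather than
#' zero-filled.
#'
#' @param section A [section_image()].
#' @param origin Ray origin (head center), `c(x, y)` px.
#' @param direction Outward unit direction `c(x, y)`.
#' @param step Sampling step along the ray in px.
#' @return Thickness in mm, or `NA_real_` if the ray misses the cartilage.
#' @export
plate_thickness <- function(section, origin, direction, step = 0.25) {
  direction <- vunit(direction)
  max_len <- vnorm(dim(section$bone_mask))
  s <- ray_samples(origin, direction, max_len, step = step)
  on_cart <- mask_at(section$cartilage_mask, s)
  if (!any(on_cart)) return(NA_real_)
  idx <- which(on_cart)
  runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
  outer_run <- runs[[which.max(vapply(runs, max, 0))]]
  i_in <- min(outer_run)                       # inner cartilage edge = end of cartilage
  on_bone <- mask_at(section$bone_mask, s)
  k <- i_in - 1L
  gap <- 0L
  while (k >= 1L && !on_bone[k] && gap < 2L) { k <- k - 1L; gap <- gap + 1L }
  if (k < 1L || !on_bone[k]) return(0)         # no plate bone at all under the cartilage
  run_len <- 0L
  while (k - run_len >= 1L && on_bone[k - run_len]) run_len <- run_len + 1L
  j_marrow <- k - run_len                      # first marrow sample inward of the plate
  (i_in - 1L - j_marrow) * step * section$mm_per_pixel
}

#' Cortical thickness at one periosteal level
#'
#' Locates the periosteal contour point nearest the requested level on the
#' requested side, estimates the local contour tangent from neighbouring
#' boundary pixels, and measures the contiguous bone run along the inward
#' periosteal normal. If the local tangent is undefined (too few contour
#' pixels), the measurement falls back to a horizontal chord and flags it.
#'
#' @param section A [section_image()].
#' @param side `"medial"` or `"lateral"`.
#' @param level_point `c(x, y)` px center of the measurement level on line a.
#' @param a_hat Unit direction of line a (distal to proximal).
#' @param medial_hat Unit vector from line a toward the medial side.
#' @param boundary_xy Optional precomputed envelope boundary coordinates
#'   (n x 2), to avoid recomputing across levels.
#' @param band_px Half-width of the level band used to pick the contour point.
#' @return List with `thickness_mm` and `method` (`"normal"` or `"chord"`).
#' @export
cortical_thickness <- function(section, side, level_point, a_hat, medial_hat,
                               boundary_xy = NULL, band_px = 3) {
  if (is.null(boundary_xy)) {
    boundary_xy <- periosteal_boundary_xy(section)
  }
  s_hat <- if (side == "medial") medial_hat else -medial_hat
  t <- (boundary_xy[, 1] - level_point[1]) * a_hat[1] +
       (boundary_xy[, 2] - level_point[2]) * a_hat[2]
  u <- (boundary_xy[, 1] - level_point[1]) * s_hat[1] +
       (boundary_xy[, 2] - level_point[2]) * s_hat[2]
  # widen the band if needed: at the first level the contour point sits just
  # distal of the cartilage margin rather than exactly at line c
  in_band <- abs(t) <= band_px & u > 0
  for (widen in c(2, 4)) {
    if (any(in_band)) break
    in_band <- abs(t) <= widen * band_px & u > 0
  }
  if (!any(in_band)) {
    stop(sprintf("no periosteal contour at level (%.1f, %.1f), %s side",
                 level_point[1], level_point[2], side), call. = FALSE)
  }
  Q <- boundary_xy[in_band, , drop = FALSE][which.max(u[in_band]), ]

  # local tangent from the outermost boundary pixel in each nearby level row
  near <- abs(t) <= 2 * band_px & u > 0
  nb <- boundary_xy[near, , drop = FALSE]
  tn <- t[near]; un <- u[near]
  rows <- round(tn)
  outer_per_row <- vapply(split(seq_along(rows), rows),
                          function(ix) ix[which.max(un[ix])], 0L)
  pts <- nb[outer_per_row, , drop = FALSE]
  if (nrow(pts) >= 3L) {
    tangent <- principal_axis(pts)$direction
    n_in <- vperp(tangent)
    if (vdot(n_in, s_hat) > 0) n_in <- -n_in
    method <- "normal"
  } else {
    n_in <- -s_hat
    method <- "chord"
  }
  max_px <- 20 / section$mm_per_pixel
  s <- ray_samples(Q - 1.5 * n_in, n_in, max_px, step = 0.25)
  on_bone <- mask_at(section$bone_mask, s)
  i_first <- which(on_bone)[1]
  if (is.na(i_first)) {
    stop(sprintf("no cortical bone found at level (%.1f, %.1f), %s side",
                 level_point[1], level_point[2], side), call. = FALSE)
  }
  run_len <- 0L
  while (i_first + run_len <= length(on_bone) && on_bone[i_first + run_len]) {
    run_len <- run_len + 1L
  }
  list(thickness_mm = run_len * 0.25 * section$mm_per_pixel, method = method)
}

#' Measure one section: BV/TV, plate profile, cortical profile
#'
#' Composes the three measurement operators over a region partition and a
#' site set, returning a fully populated, deterministic result. Cortical
#' levels without a measurable contour are reported with `NA` thickness and a
#' note rather than dropped silently.
#'
#' @param section A [section_image()].
#' @param regions A [partition_regions()] result.
#' @param sites A [build_thickness_sites()] result.
#' @param env Optional precomputed tissue envelope.
#' @param boundary Optional precomputed envelope boundary mask.
#' @return A `morphometry_result`: list of tibbles `bvtv` (donor x region),
#'   `plate` (donor x angle, mm), `cortical` (donor x side x level, mm) plus
#'   the echoed `params`.
#' @export
measure_section <- function(section, regions, sites, env = NULL, boundary = NULL) {
  bvtv <- tibble::tibble(
    donor_id = section$donor_id,
    region = regions$region,
    bvtv = vapply(regions$pixels, function(px) bv_tv(section, px), 0)
  )

  origin <- sites$head_center
  plate <- sites$plate_rays
  plate$thickness_mm <- vapply(seq_len(nrow(plate)), function(i) {
    plate_thickness(section, origin, c(plate$dir_x[i], plate$dir_y[i]))
  }, 0)
  plate <- tibble::tibble(
    donor_id = section$donor_id,
    angle = plate$angle,
    thickness_mm = plate$thickness_mm
  )

  bxy <- periosteal_boundary_xy(section, env, boundary)
  cl <- sites$cortical_levels
  ct <- purrr::map(seq_len(nrow(cl)), function(i) {
    res <- tryCatch(
      cortical_thickness(section, cl$side[i], c(cl$x[i], cl$y[i]),
                         sites$a_hat, sites$medial_hat, boundary_xy = bxy),
      error = function(e) list(thickness_mm = NA_real_, method = conditionMessage(e))
    )
    tibble::tibble(
      donor_id = section$donor_id, side = cl$side[i], level = cl$level[i],
      thickness_mm = res$thickness_mm, method = res$method
    )
  })
  cortical <- dplyr::bind_rows(ct)

  structure(
    list(
      bvtv = bvtv,
      plate = plate,
      cortical = cortical,
      params = list(
        mm_per_pixel = section$mm_per_pixel,
        medial_side = section$medial_side,
        angular_step = sites$angular_step,
        n_segments = sites$n_segments,
        m_strip_len = attr(regions, "m_strip_len")
      )
    ),
    class = "morphometry_result"
  )
}

#' @export
print.morphometry_result <- function(x, ...) {
  cat(sprintf("<morphometry_result> donor %s\n", x$bvtv$donor_id[1]))
  cat("BV/TV (%):\n")
  print(stats::setNames(round(x$bvtv$bvtv, 1), x$bvtv$region))
  cat(sprintf("plate thickness: %d rays, median %.2f mm; cortical: %d sites\n",
              nrow(x$plate), stats::median(x$plate$thickness_mm, na.rm = TRUE),
              nrow(x$cortical)))
  invisible(x)
}
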