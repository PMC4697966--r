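# Synthetic frontal proximal-humerus sections with known ground truth.
#
# The generator draws, in an idealized medial-left frame: a circular humeral
# head carrying an articular cartilage band and a subchondral plate over its
# proximal-medial semicircle, a flaring metaphysis joining a parallel-sided
# shaft, cortical shells whose thickness follows a per-side level profile, and
# a trabecular interior produced by a seeded dead-leaves process of oriented
# ellipses, filled independently per ground-truth region until each region's
# bone-area fraction reaches its target within 0.5 percentage points.

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Specification of one synthetic section
#'
#' All lengths in mm. Profiles may be single numbers (constant), length-2
#' vectors (linear from proximal to distal / across the arc), or functions.
#'
#' @param head_radius Humeral head radius.
#' @param shaft_width Outer shaft width.
#' @param cartilage_thickness Articular cartilage band thickness.
#' @param plate_thickness Subchondral plate profile over the articular arc:
#'   constant, or a function of the arc angle in degrees (0 = caudal end).
#' @param cortical_thickness Named list `medial`, `lateral`; each a constant,
#'   a `c(proximal, distal)` pair interpolated linearly over the cortical
#'   levels, or a function of the normalized level in `[0, 1]`.
#' @param rim_thickness Thin compact rim along the non-articular periosteum.
#' @param region_bvtv_targets Named percentages for `sc1`, `sc2`, `m1`, `m2`,
#'   `rest`, and either `h` or the pair `subchondral`/`inner`. Targets must
#'   lie in (0, 95].
#' @param trabecular_width `c(mean, sd)` of the trabecular strut width in mm.
#' @param neck_tilt_deg Tilt of the anatomical neck normal from the shaft
#'   axis (45 approximates a 135 degree neck-shaft angle).
#' @param head_offset Medial offset of the head center from the shaft axis.
#' @param mm_per_pixel Raster calibration.
#' @param medial_side Which image side is medial in the emitted rasters.
#' @param donor_id Donor identifier.
#' @param seed Integer seed; a fixed seed makes the output bit-identical.
#' @return A validated list of class `section_spec`.
#' @export
section_spec <- function(head_radius = 20, shaft_width = 24,
                         cartilage_thickness = 1.0,
                         plate_thickness = 0.5,
                         cortical_thickness = list(medial = c(0.8, 3.0),
                                                   lateral = c(0.8, 2.5)),
                         rim_thickness = 0.8,
                         region_bvtv_targets = c(h = 25, sc1 = 18, sc2 = 20,
                                                 m1 = 24.5, m2 = 24.5, rest = 20),
                         trabecular_width = c(0.15, 0.04),
                         neck_tilt_deg = 45,
                         head_offset = 4,
                         mm_per_pixel = 0.025,
                         medial_side = c("left", "right"),
                         donor_id = "synthetic",
                         seed = 1L) {
  medial_side <- match.arg(medial_side)
  lens <- c(head_radius = head_radius, shaft_width = shaft_width,
            cartilage_thickness = cartilage_thickness, rim_thickness = rim_thickness,
            head_offset = head_offset, mm_per_pixel = mm_per_pixel)
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    stop("all lengths in a section_spec must be positive", call. = FALSE)
  }
  tg <- region_bvtv_targets
  if (is.null(names(tg)) || any(!is.finite(tg)) || any(tg <= 0) || any(tg > 100)) {
    stop("region_bvtv_targets must be named percentages in (0, 100]", call. = FALSE)
  }
  if (any(tg > 95)) {
    stop(sprintf("unreachable BV/TV target(s) above 95%%: %s",
                 paste(names(tg)[tg > 95], collapse = ", ")), call. = FALSE)
  }
  needed <- c("sc1", "sc2", "m1", "m2")
  if (!all(needed %in% names(tg)) || !("h" %in% names(tg) ||
        all(c("subchondral", "inner") %in% names(tg)))) {
    stop("region_bvtv_targets needs sc1, sc2, m1, m2 and h (or subchondral + inner)",
         call. = FALSE)
  }
  structure(
    list(
      head_radius = head_radius, shaft_width = shaft_width,
      cartilage_thickness = cartilage_thickness,
      plate_thickness = plate_thickness,
      cortical_thickness = cortical_thickness,
      rim_thickness = rim_thickness,
      region_bvtv_targets = tg,
      trabecular_width = trabecular_width,
      neck_tilt_deg = neck_tilt_deg,
      head_offset = head_offset,
      mm_per_pixel = mm_per_pixel,
      medial_side = medial_side,
      donor_id = donor_id,
      seed = as.integer(seed)
    ),
    class = "section_spec"
  )
}

as_profile_fn <- function(p) {
  if (is.function(p)) return(p)
  p <- as.numeric(p)
  if (length(p) == 1L) return(function(l) rep(p, length(l)))
  function(l) p[1] + (p[2] - p[1]) * pmin(pmax(l, 0), 1)
}

# scanline fill of a simple polygon into a logical matrix
polygon_fill_mask <- function(poly, nr, nc) {
  mask <- matrix(FALSE, nr, nc)
  xs <- poly[, 1]; ys <- poly[, 2]
  n <- nrow(poly)
  x2 <- c(xs[-1], xs[1]); y2 <- c(ys[-1], ys[1])
  cross <- vector("list", nr)
  for (e in seq_len(n)) {
    ylo <- min(ys[e], y2[e]); yhi <- max(ys[e], y2[e])
    rows <- seq.int(max(1L, ceiling(ylo)), min(nr, floor(yhi)))
    rows <- rows[(ys[e] > rows) != (y2[e] > rows)]
    if (length(rows) == 0L) next
    xint <- xs[e] + (rows - ys[e]) * (x2[e] - xs[e]) / (y2[e] - ys[e])
    for (k in seq_along(rows)) {
      r <- rows[k]
      cross[[r]] <- c(cross[[r]], xint[k])
    }
  }
  for (r in seq_len(nr)) {
    cx <- cross[[r]]
    if (is.null(cx) || length(cx) < 2L) next
    cx <- sort(cx)
    for (s in seq(1, length(cx) - 1, by = 2)) {
      a <- max(1L, ceiling(cx[s])); b <- min(nc, floor(cx[s + 1]))
      if (b >= a) mask[r, a:b] <- TRUE
    }
  }
  mask
}

cubic_bezier <- function(p0, c1, c2, p3, n = 40) {
  t <- seq(0, 1, length.out = n)
  bx <- (1 - t)^3 * p0[1] + 3 * (1 - t)^2 * t * c1[1] + 3 * (1 - t) * t^2 * c2[1] + t^3 * p3[1]
  by <- (1 - t)^3 * p0[2] + 3 * (1 - t)^2 * t * c1[2] + 3 * (1 - t) * t^2 * c2[2] + t^3 * p3[2]
  cbind(bx, by)
}

distmap_px <- function(mask) {
  d <- EBImage::distmap(EBImage::Image(mask * 1))
  matrix(as.numeric(d), nrow = nrow(mask))
}

#' Generate a synthetic section with ground truth
#'
#' @param spec A [section_spec()].
#' @return A list of class `synthetic_section` with elements `section`
#'   (a [section_image()]), `annotation` (exact cartilage endpoints, px) and
#'   `ground_truth`: region stencil pixel indices, achieved per-region BV/TV,
#'   true landmark quantities (head center, |line e|, s1, s2, head height, in
#'   px), and the thickness profiles the rasters were drawn from.
#' @export
generate_section <- function(spec) {
  stopifnot(inherits(spec, "section_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(spec$seed)

  mmpp <- spec$mm_per_pixel
  px <- function(mm) mm / mmpp
  R <- px(spec$head_radius)
  cart_th <- px(spec$cartilage_thickness)
  W <- px(spec$shaft_width)
  e_off <- px(spec$head_offset)
  margin <- px(2)
  tau <- deg2rad(spec$neck_tilt_deg)

  cx <- margin + R
  cy <- margin + R
  x0 <- cx + e_off
  y_c <- cy + R * sin(tau)
  head_height <- R * (1 + sin(tau))
  nr <- ceiling(y_c + head_height + px(4))
  nc <- ceiling(max(cx + R, x0 + W / 2) + margin)

  n_hat <- c(-sin(tau), -cos(tau))                 # articular apex direction
  b_hat <- c(cos(tau), -sin(tau))                  # caudal -> cranial
  caudal <- c(cx, cy) + R * c(-cos(tau), sin(tau))
  cranial <- c(cx, cy) + R * c(cos(tau), -sin(tau))

  plate_fn <- as_profile_fn(spec$plate_thickness)
  t_med_fn <- as_profile_fn(spec$cortical_thickness$medial)
  t_lat_fn <- as_profile_fn(spec$cortical_thickness$lateral)
  rim <- px(spec$rim_thickness)

  # ---- envelope -----------------------------------------------------------
  # the medial flare ends above the distal third of the section so line d's
  # periosteal tangent lands on the parallel-sided shaft wall
  flare_med <- px(12); flare_lat <- px(20)
  M1 <- caudal
  L1 <- c(cx + R, cy)
  med_wall <- x0 - W / 2; lat_wall <- x0 + W / 2
  y_mt <- y_c + flare_med; y_lt <- cy + flare_lat
  med_curve <- cubic_bezier(M1, c(M1[1], M1[2] + 0.6 * (y_mt - M1[2])),
                            c(med_wall, y_mt - 0.4 * (y_mt - M1[2])), c(med_wall, y_mt))
  lat_curve <- cubic_bezier(c(lat_wall, y_lt), c(lat_wall, y_lt - 0.4 * (y_lt - L1[2])),
                            c(L1[1], L1[2] + 0.6 * (y_lt - L1[2])), L1)
  poly <- rbind(c(cx, cy), M1, med_curve,
                c(med_wall, nr - 2), c(lat_wall, nr - 2),
                lat_curve, L1)
  env <- polygon_fill_mask(poly, nr, nc)

  ii <- seq_len(nr); jj <- seq_len(nc)
  # head disc and radial fields on its bounding box
  hj <- max(1L, floor(cx - R - 2)):min(nc, ceiling(cx + R + 2))
  hi <- max(1L, floor(cy - R - 2)):min(nr, ceiling(cy + R + 2))
  hdx <- rep(hj - cx, each = length(hi))
  hdy <- rep(hi - cy, times = length(hj))
  hr <- sqrt(hdx^2 + hdy^2)
  h_idx <- as.integer(outer(hi, (hj - 1L) * nr, "+"))
  env[h_idx[hr <= R]] <- TRUE

  # ---- cartilage and plate over the articular arc ------------------------
  d_n <- hdx * n_hat[1] + hdy * n_hat[2]
  arc_side <- d_n >= 0
  # the drawn cartilage/plate arc overshoots the nominal endpoints by 2 px so
  # that rays sampled exactly at the endpoint angles still cross them
  arc_draw <- d_n >= -2
  cart <- matrix(FALSE, nr, nc)
  cart[h_idx[arc_draw & hr <= R & hr > R - cart_th]] <- TRUE

  d_b <- hdx * b_hat[1] + hdy * b_hat[2]
  # plate thickness varies over the arc: evaluate the profile on the ring only
  max_plate <- px(max(plate_fn(seq(0, 180, by = 5)))) + 1
  ring_sel <- which(arc_draw & hr <= R - cart_th & hr > R - cart_th - max_plate)
  theta <- atan2(pmax(d_n[ring_sel], 0), -d_b[ring_sel]) * 180 / pi  # 0 caudal, 180 cranial
  plate_th_ring <- px(plate_fn(theta))
  plate_sel <- ring_sel[hr[ring_sel] > R - cart_th - plate_th_ring]
  bone <- matrix(FALSE, nr, nc)
  bone[h_idx[plate_sel]] <- TRUE
  r_i_apex <- R - cart_th - px(plate_fn(90))       # |line e| ground truth

  # ---- cortical shells via the envelope distance map ---------------------
  dmap_env <- distmap_px(env)
  lvl <- pmin(pmax((ii - y_c) / head_height, 0), 1)
  t_row_med <- pmax(px(t_med_fn(lvl)), rim)
  t_row_lat <- pmax(px(t_lat_fn(lvl)), rim)
  t_px <- matrix(0, nr, nc)
  med_cols <- jj < x0
  t_px[, med_cols] <- t_row_med
  t_px[, !med_cols] <- t_row_lat
  shell <- env & dmap_env <= t_px & !cart
  # keep the shell out of the cancellous space under the plate: the articular
  # cover is the separately drawn plate
  min_plate <- px(min(plate_fn(seq(0, 180, by = 5))))
  shell[h_idx[arc_side & hr <= R - cart_th - min_plate]] <- FALSE
  bone <- bone | shell

  compact <- bone
  domain <- env & !cart & !compact

  # ---- ground-truth region stencils --------------------------------------
  L_e <- r_i_apex
  s2 <- L_e / 3
  s1 <- (med_wall - M1[1]) / 3
  strip_len <- 2 * s1

  lab <- matrix(0L, nr, nc)
  # the subcapital bands reach beyond the head disc: use a wider box
  rhalf <- sqrt(R^2 + (2 * s2)^2) + 2
  rj <- max(1L, floor(cx - rhalf)):min(nc, ceiling(cx + rhalf))
  ri <- max(1L, floor(cy - rhalf)):min(nr, ceiling(cy + rhalf))
  rdx <- rep(rj - cx, each = length(ri))
  rdy <- rep(ri - cy, times = length(rj))
  rr <- sqrt(rdx^2 + rdy^2)
  r_n <- rdx * n_hat[1] + rdy * n_hat[2]
  r_b <- rdx * b_hat[1] + rdy * b_hat[2]
  r_idx <- as.integer(outer(ri, (rj - 1L) * nr, "+"))
  in_dom <- domain[r_idx]
  col_sel <- abs(r_b) <= R
  lab[r_idx[in_dom & r_n >= 0 & rr <= L_e & rr >= L_e - s2]] <- 1L
  lab[r_idx[in_dom & r_n >= 0 & rr < L_e - s2]] <- 2L
  lab[r_idx[in_dom & col_sel & r_n < 0 & r_n >= -s2]] <- 3L
  lab[r_idx[in_dom & col_sel & r_n < -s2 & r_n >= -2 * s2]] <- 4L

  mj <- max(1L, floor(M1[1])):min(nc, ceiling(M1[1] + 2 * s1))
  mi <- max(1L, floor(y_c)):min(nr, ceiling(y_c + strip_len))
  m_idx <- as.integer(outer(mi, (mj - 1L) * nr, "+"))
  su <- rep(mj - M1[1], each = length(mi))
  sv <- rep(mi - y_c, times = length(mj))
  ok_m <- domain[m_idx] & lab[m_idx] == 0L & sv >= 0 & sv <= strip_len
  lab[m_idx[ok_m & su >= 0 & su <= s1]] <- 5L
  lab[m_idx[ok_m & su > s1 & su <= 2 * s1]] <- 6L
  lab[domain & lab == 0L] <- 7L

  labels <- c("subchondral", "inner", "sc1", "sc2", "m1", "m2", "rest")

  # ---- dead-leaves trabecular fill ---------------------------------------
  tg <- spec$region_bvtv_targets
  targets <- c(
    subchondral = unname(tg["subchondral"] %||% tg["h"]),
    inner = unname(tg["inner"] %||% tg["h"]),
    sc1 = unname(tg["sc1"]), sc2 = unname(tg["sc2"]),
    m1 = unname(tg["m1"]), m2 = unname(tg["m2"]),
    rest = unname(tg["rest"] %||% 20)
  )
  # trabeculae must keep clear of the compact bone so connected-component
  # labelling can separate them from the shell; a box erosion of the domain
  # is a cheap conservative stand-in for a full distance map
  gap <- 2
  core <- EBImage::erode(EBImage::Image(domain * 1), EBImage::makeBrush(5, "box"))
  dmap_dom <- matrix(ifelse(as.numeric(core) > 0.5, gap, 0), nrow = nr)
  w_mean <- px(spec$trabecular_width[1])
  w_sd <- px(spec$trabecular_width[2])

  for (k in seq_along(labels)) {
    st_idx <- which(lab == k)
    n_tot <- length(st_idx)
    if (n_tot == 0L) next
    seed_idx <- st_idx[dmap_dom[st_idx] >= gap]
    if (length(seed_idx) == 0L) next
    f <- targets[[labels[k]]] / 100
    target_px <- round(f * n_tot)
    n_bone <- 0L
    mean_area <- pi * (w_mean / 2) * (w_mean * 3.5 / 2)
    iter <- 0L
    repeat {
      deficit <- target_px - n_bone
      if (deficit <= 0L || iter > 3000L) break
      iter <- iter + 1L
      kdraw <- max(1L, min(2000L, floor(deficit / (mean_area * 1.3))))
      small <- deficit < 3 * mean_area
      ctr_idx <- seed_idx[sample.int(length(seed_idx), kdraw, replace = TRUE)]
      ci <- ((ctr_idx - 1L) %% nr) + 1L
      cj <- ((ctr_idx - 1L) %/% nr) + 1L
      for (q in seq_len(kdraw)) {
        w <- max(2, stats::rnorm(1, w_mean, w_sd))
        if (small) w <- max(2, w * 0.6)
        len <- w * stats::runif(1, 2.5, 5)
        if (small) len <- w * 2
        phi <- stats::runif(1, 0, pi)
        a <- len / 2; b2 <- w / 2
        half <- ceiling(a)
        pj <- max(1L, cj[q] - half):min(nc, cj[q] + half)
        pi_ <- max(1L, ci[q] - half):min(nr, ci[q] + half)
        ddx <- rep(pj - cj[q], each = length(pi_))
        ddy <- rep(pi_ - ci[q], times = length(pj))
        u <- ddx * cos(phi) + ddy * sin(phi)
        v <- -ddx * sin(phi) + ddy * cos(phi)
        inside <- (u / a)^2 + (v / b2)^2 <= 1
        p_idx <- as.integer(outer(pi_, (pj - 1L) * nr, "+"))[inside]
        p_idx <- p_idx[lab[p_idx] == k & !bone[p_idx] & dmap_dom[p_idx] >= gap]
        need <- target_px - n_bone
        if (length(p_idx) > need) p_idx <- p_idx[seq_len(need)]  # exact landing
        bone[p_idx] <- TRUE
        n_bone <- n_bone + length(p_idx)
        if (n_bone >= target_px) break
      }
    }
  }

  # ---- orientation and packaging -----------------------------------------
  flip <- spec$medial_side == "right"
  if (flip) {
    bone <- bone[, nc:1]
    cart <- cart[, nc:1]
    lab <- lab[, nc:1]
    fx <- function(p) c(nc + 1 - p[1], p[2])
    caudal <- fx(caudal); cranial <- fx(cranial)
    C_px <- fx(c(cx, cy))
    apex_dir <- c(-n_hat[1], n_hat[2])
  } else {
    C_px <- c(cx, cy)
    apex_dir <- n_hat
  }

  section <- section_image(bone, cart, mmpp, spec$medial_side, spec$donor_id)
  ann <- annotation(cranial, caudal)

  stencils <- lapply(seq_along(labels), function(k) which(lab == k))
  names(stencils) <- labels
  stencils$h <- sort(c(stencils$subchondral, stencils$inner))
  achieved <- vapply(stencils, function(ix) 100 * sum(bone[ix]) / length(ix), 0)

  lvl9 <- seq(0, 1, length.out = 9)
  gt <- list(
    head_center = C_px,
    apex_dir = apex_dir,
    cranial = cranial,
    caudal = caudal,
    line_e_length = L_e,
    s1_length = s1,
    s2_length = s2,
    head_height = head_height,
    y_line_c = y_c,
    targets = targets,
    achieved_bvtv = achieved,
    stencils = stencils,
    plate_profile_mm = function(angle_deg) plate_fn(angle_deg),
    cortical_profile_mm = tibble::tibble(
      side = rep(c("medial", "lateral"), each = 9),
      level = rep(0:8, 2),
      thickness_mm = c(pmax(t_med_fn(lvl9), spec$rim_thickness),
                       pmax(t_lat_fn(lvl9), spec$rim_thickness))
    ),
    spec = spec
  )
  structure(list(section = section, annotation = ann, ground_truth = gt),
            class = "synthetic_section")
}
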