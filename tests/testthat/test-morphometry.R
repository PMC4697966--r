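test_that("BV/TV is exact pixel counting under the pixel-center rule", {
  set.seed(3)
  b <- matrix(runif(100 * 100) < 0.37, 100, 100)
  s <- section_image(b, matrix(FALSE, 100, 100), 0.05, "left")

  idx <- which(matrix(TRUE, 100, 100))
  expect_identical(bv_tv(s, idx), 100 * sum(b) / 1e4)

  # polygon spanning pixel centers 21..60 x 11..40: oracle by direct count
  poly <- data.frame(x = c(20.5, 60.5, 60.5, 20.5), y = c(10.5, 10.5, 40.5, 40.5))
  expect_identical(bv_tv(s, poly), 100 * sum(b[11:40, 21:60]) / (40 * 30))

  full <- section_image(matrix(TRUE, 10, 10), matrix(FALSE, 10, 10), 1, "left")
  expect_equal(bv_tv(full, which(matrix(TRUE, 10, 10))), 100)
  none <- section_image(matrix(FALSE, 10, 10), matrix(FALSE, 10, 10), 1, "left")
  expect_equal(bv_tv(none, which(matrix(TRUE, 10, 10))), 0)

  b2 <- matrix(FALSE, 100, 100); b2[which(matrix(TRUE, 100, 100))[1:5000]] <- TRUE
  s2 <- section_image(b2, matrix(FALSE, 100, 100), 1, "left")
  expect_equal(bv_tv(s2, which(matrix(TRUE, 100, 100))), 50)

  expect_error(bv_tv(s, data.frame(x = c(-10, -5, -5), y = c(-10, -10, -5))), "zero-area")
})

test_that("BV/TV is monotone in added bone and additive over partitions", {
  an <- cached_analysis()
  g <- cached_section()
  s <- g$section
  px <- setNames(an$regions$pixels, an$regions$region)

  # additivity: h equals the area-weighted mean over the subchondral/inner split
  w <- c(length(px$subchondral), length(px$inner))
  lhs <- bv_tv(s, sort(c(px$subchondral, px$inner)))
  rhs <- sum(w * c(bv_tv(s, px$subchondral), bv_tv(s, px$inner))) / sum(w)
  expect_equal(lhs, rhs, tolerance = 1e-12)

  # adding a marrow->bone pixel inside the region raises BV/TV, outside leaves it
  inner_marrow <- px$inner[!s$bone_mask[px$inner]][1]
  s_mod <- s; s_mod$bone_mask[inner_marrow] <- TRUE
  expect_gt(bv_tv(s_mod, px$inner), bv_tv(s, px$inner))
  expect_identical(bv_tv(s_mod, px$sc1), bv_tv(s, px$sc1))
})

test_that("plate thickness on a strip phantom measures the bone band", {
  ph <- strip_phantom(cart_px = 10, plate_px = 6, mm_per_pixel = 0.1)
  # upward ray from the marrow interior: crosses plate (rows 51..56) then
  # cartilage (41..50), mimicking a radial ray from the head center
  th <- plate_thickness(ph, origin = c(30, 110), direction = c(0, -1))
  expect_lt(abs(th - 0.6), 0.1)                     # within 1 px
  # ray that never meets cartilage
  expect_true(is.na(plate_thickness(ph, origin = c(30, 110), direction = c(0, 1))))
})

test_that("thickness operators are invariant under translation and 90-degree rotation", {
  ph <- strip_phantom()
  th0 <- plate_thickness(ph, c(30, 110), c(0, -1))
  expect_lt(abs(th0 - 0.6), 0.1)

  shift <- function(m, pad = 13L) {
    out <- matrix(FALSE, nrow(m) + pad, ncol(m) + pad)
    out[(pad + 1):(pad + nrow(m)), (pad + 1):(pad + ncol(m))] <- m
    out
  }
  ph_t <- section_image(shift(ph$bone_mask), shift(ph$cartilage_mask), 0.1, "left")
  expect_equal(plate_thickness(ph_t, c(43, 123), c(0, -1)), th0, tolerance = 1e-12)

  # 90 deg counter-clockwise: (x, y) -> (nrow + 1 - y, x)
  rot <- function(m) t(m)[, nrow(m):1, drop = FALSE]
  ph_r <- section_image(rot(ph$bone_mask), rot(ph$cartilage_mask), 0.1, "left")
  nr0 <- nrow(ph$bone_mask)
  th_r <- plate_thickness(ph_r, c(nr0 + 1 - 110, 30), c(1, 0))
  expect_equal(th_r, th0, tolerance = 1e-12)
})

test_that("cortical thickness on an annulus matches the analytic width", {
  ph <- annulus_phantom(outer_r = 100, inner_r = 90, mm_per_pixel = 0.05)
  ctr <- (nrow(ph$bone_mask) + 1) / 2
  bxy <- humerometry:::periosteal_boundary_xy(ph)
  for (lv in c(-60, -30, 0, 30, 60)) {
    for (side in c("medial", "lateral")) {
      res <- cortical_thickness(ph, side, c(ctr, ctr + lv), c(0, -1), c(-1, 0),
                                boundary_xy = bxy)
      expect_lt(abs(res$thickness_mm / 0.05 - 10), 1.1)   # 10 px within ~1 px
    }
  }
})

test_that("generated cortical taper is recovered along the shaft", {
  g <- cached_section(seed = 21, mm_per_pixel = 0.1)
  an <- cached_analysis(seed = 21, mm_per_pixel = 0.1)
  truth <- g$ground_truth$cortical_profile_mm
  mm <- merge(an$result$cortical, truth, by = c("side", "level"))
  med <- mm[mm$side == "medial", ]
  fit_meas <- stats::coef(stats::lm(thickness_mm.x ~ level, med))[[2]]
  fit_true <- stats::coef(stats::lm(thickness_mm.y ~ level, med))[[2]]
  expect_lt(abs(fit_meas - fit_true) / fit_true, 0.10)
})

test_that("measure_section has full cardinality and is deterministic", {
  g <- cached_section()
  an <- cached_analysis()
  res <- an$result
  expect_equal(nrow(res$bvtv), 7)
  expect_equal(nrow(res$plate), 19)
  expect_equal(nrow(res$cortical), 18)
  expect_true(all(res$bvtv$bvtv >= 0 & res$bvtv$bvtv <= 100))
  expect_true(all(res$cortical$thickness_mm >= 0, na.rm = TRUE))

  res2 <- measure_section(g$section, an$regions, an$sites)
  expect_identical(res$bvtv, res2$bvtv)
  expect_identical(res$plate, res2$plate)
  expect_identical(res$cortical, res2$cortical)
})

test_that("halving the pixel size under 2x supersampling barely moves the measures", {
  # operator-level consistency: the same physical region and ray, measured on
  # a 2x supersampled raster at half the calibration
  g <- cached_section()
  s <- g$section
  up <- function(m) m[rep(seq_len(nrow(m)), each = 2), rep(seq_len(ncol(m)), each = 2)]
  s2 <- section_image(up(s$bone_mask), up(s$cartilage_mask),
                      s$mm_per_pixel / 2, s$medial_side, s$donor_id)

  lm <- cached_analysis()$landmarks
  poly1 <- humerometry:::region_outline("h", lm)
  poly2 <- poly1 * 2 - 0.5                       # same physical polygon, fine grid
  expect_lt(abs(bv_tv(s, poly1) - bv_tv(s2, poly2)), 0.5)

  ctr1 <- lm$head_center
  dir <- lm$e_hat
  th1 <- plate_thickness(s, ctr1, dir)
  th2 <- plate_thickness(s2, ctr1 * 2 - 0.5, dir)
  expect_lt(abs(th1 - th2), s$mm_per_pixel)
})
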