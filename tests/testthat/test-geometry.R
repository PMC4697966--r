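test_that("long-axis fit matches the second-moment oracle", {
  # axis-aligned rectangle: vertical line through the x-centroid
  b <- matrix(FALSE, 260, 120); b[30:230, 41:80] <- TRUE
  s <- section_image(b, matrix(FALSE, 260, 120), 0.1, "left")
  ax <- fit_long_axis(s)
  expect_lt(abs(ax$direction[1]), 1e-6)
  expect_equal(ax$point[1], 60.5, tolerance = 0.5)

  # rotated rectangle: direction within 0.5 degrees of the covariance
  # eigenvector computed independently on the same pixel set
  th <- 30 * pi / 180
  n <- 400
  ii <- seq_len(n)
  xc <- rep(ii, each = n) - n / 2
  yc <- rep(ii, times = n) - n / 2
  u <- xc * cos(th) + yc * sin(th)
  v <- -xc * sin(th) + yc * cos(th)
  rot <- matrix(abs(u) <= 20 & abs(v) <= 100, n, n)
  s2 <- section_image(rot, matrix(FALSE, n, n), 0.1, "left")
  ax2 <- fit_long_axis(s2, shaft_fraction = 0.5)
  xy <- which(rot, arr.ind = TRUE)
  pts <- cbind(xy[, 2], xy[, 1])
  ev <- eigen(stats::cov(pts))$vectors[, 1]
  ang <- function(d) atan2(d[2], d[1]) %% pi
  expect_lt(abs(ang(ax2$direction) - ang(ev)) %% pi, 0.5 * pi / 180)

  # override short-circuits the fit
  ov <- annotation(c(1, 1), c(2, 2), shaft_axis_override = list(c(10, 0), c(10, 100)))
  ax3 <- fit_long_axis(s, ov)
  expect_equal(abs(ax3$direction), c(0, 1))
  expect_equal(ax3$point[1], 10)

  tiny <- section_image(matrix(FALSE, 20, 20), matrix(FALSE, 20, 20), 0.1, "left")
  expect_error(fit_long_axis(tiny), "degenerate")
  expect_error(fit_long_axis(s, shaft_fraction = 0.7), "shaft_fraction")
})

test_that("landmark construction satisfies its geometric invariants", {
  an <- cached_analysis()
  lm <- an$landmarks
  expect_lt(abs(vdot(lm$line_c$direction, lm$a_hat)), 1e-9)      # c perp a
  expect_lt(abs(vcross(lm$line_d$direction, lm$a_hat)), 1e-9)    # d parallel a
  expect_lt(abs(vdot(lm$line_e$direction, lm$b_hat)), 1e-9)      # e perp b
  mid_b <- (lm$line_b$cranial + lm$line_b$caudal) / 2
  expect_lt(vnorm(lm$line_e$point - mid_b), 0.5)                 # e through midpoint of b
  expect_lt(abs(3 * lm$s1_length - lm$medial_segment_length), 0.5)
  expect_lt(abs(3 * lm$s2_length - lm$line_e$length), 0.5)
})

test_that("landmarks and regions recover generator ground truth across random sections", {
  seeds <- 101:110
  for (sd in seeds) {
    tilt <- 38 + (sd %% 5) * 3
    g <- generate_section(section_spec(mm_per_pixel = 0.12, seed = sd,
                                       neck_tilt_deg = tilt,
                                       medial_side = if (sd %% 2) "left" else "right"))
    an <- analyze_section(g$section, g$annotation, run_config(calibration = 0.12))
    lm <- an$landmarks; gt <- g$ground_truth

    expect_lt(abs(vdot(lm$line_c$direction, lm$a_hat)), 1e-9)
    expect_lt(abs(vcross(lm$line_d$direction, lm$a_hat)), 1e-9)
    expect_lt(abs(vdot(lm$line_e$direction, lm$b_hat)), 1e-9)
    expect_lt(abs(3 * lm$s2_length - lm$line_e$length), 0.5)
    expect_lt(abs(lm$line_e$length - gt$line_e_length), 2)       # plate found at true depth
    expect_lt(abs(lm$head_height - gt$head_height), 2)

    expect_setequal(an$regions$region,
                    c("h", "sc1", "sc2", "m1", "m2", "subchondral", "inner"))
    for (r in an$regions$region) {
      i <- which(an$regions$region == r)
      expect_gte(region_jaccard(an$regions$pixels[[i]], gt$stencils[[r]]), 0.90)
    }
  }
})

test_that("region partition is a clean tiling of cancellous bone", {
  g <- cached_section()
  an <- cached_analysis()
  rg <- an$regions
  px <- setNames(rg$pixels, rg$region)

  # subchondral + inner tile h with < 0.1% area discrepancy
  expect_lt(abs(length(px$h) - length(px$subchondral) - length(px$inner)) /
              length(px$h), 0.001)
  expect_length(intersect(px$subchondral, px$inner), 0)

  # sc1, sc2, m1, m2, subchondral, inner pairwise interior-disjoint
  parts <- px[c("sc1", "sc2", "m1", "m2", "subchondral", "inner")]
  for (a in seq_along(parts)) for (b in seq_along(parts)) {
    if (a < b) expect_length(intersect(parts[[a]], parts[[b]]), 0)
  }

  # no region pixel lies on cartilage or on the peripheral compact bone
  cart_idx <- which(g$section$cartilage_mask)
  dom <- humerometry:::cancellous_domain(g$section)
  for (r in names(px)) {
    expect_length(intersect(px[[r]], cart_idx), 0)
    expect_true(all(dom[px[[r]]]))
  }
})

test_that("partitioning is deterministic and translation/mirror invariant", {
  g <- cached_section()
  an <- cached_analysis()
  cfg <- run_config(calibration = 0.1)

  an2 <- analyze_section(g$section, g$annotation, cfg)
  expect_identical(an$regions$pixels, an2$regions$pixels)

  # translation: pad 15 px on top/left shifts indices but not areas
  pad <- 15L
  shift <- function(m) {
    out <- matrix(FALSE, nrow(m) + pad, ncol(m) + pad)
    out[(pad + 1):(pad + nrow(m)), (pad + 1):(pad + ncol(m))] <- m
    out
  }
  s_sh <- section_image(shift(g$section$bone_mask), shift(g$section$cartilage_mask),
                        g$section$mm_per_pixel, g$section$medial_side)
  ann_sh <- annotation(g$annotation$cranial_cartilage_end + pad,
                       g$annotation$caudal_cartilage_end + pad)
  an_sh <- analyze_section(s_sh, ann_sh, cfg)
  expect_equal(an_sh$regions$n_px, an$regions$n_px, tolerance = 0.02)

  # mirroring with flipped medial_side metadata preserves region areas
  g_r <- generate_section(coarse_spec(seed = 7, medial_side = "right"))
  an_r <- analyze_section(g_r$section, g_r$annotation, cfg)
  expect_equal(an_r$regions$n_px[order(an_r$regions$region)],
               an$regions$n_px[order(an$regions$region)], tolerance = 0.02)
})

test_that("shrinking s2 strictly shrinks the subchondral band", {
  g <- cached_section()
  an <- cached_analysis()
  lm2 <- an$landmarks
  lm2$s2_length <- lm2$s2_length * 0.6
  rg2 <- partition_regions(g$section, lm2)
  a1 <- an$regions$n_px[an$regions$region == "subchondral"]
  a2 <- rg2$n_px[rg2$region == "subchondral"]
  expect_lt(a2, a1)
})

test_that("thickness sites follow the inclusive 10-degree and head-height/8 scheme", {
  lm <- cached_analysis()$landmarks
  st <- build_thickness_sites(lm, angular_step = 10, n_segments = 8)
  expect_equal(nrow(st$plate_rays), 19)
  expect_equal(st$plate_rays$angle, seq(0, 180, by = 10))
  expect_equal(sum(st$cortical_levels$side == "medial"), 9)
  expect_equal(sum(st$cortical_levels$side == "lateral"), 9)
  med <- st$cortical_levels[st$cortical_levels$side == "medial", ]
  gaps <- sqrt(diff(med$x)^2 + diff(med$y)^2)
  expect_true(all(abs(gaps - lm$head_height / 8) < 0.5))

  expect_equal(nrow(build_thickness_sites(lm, angular_step = 90)$plate_rays), 3)
  expect_error(build_thickness_sites(lm, angular_step = 70), "divisor")

  st9 <- build_thickness_sites(lm, n_segments = 4)
  expect_equal(sum(st9$cortical_levels$side == "medial"), 5)
})
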