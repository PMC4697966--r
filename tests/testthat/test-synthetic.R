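test_that("generation is bit-identical under a fixed seed", {
  g1 <- generate_section(coarse_spec(seed = 5))
  g2 <- generate_section(coarse_spec(seed = 5))
  expect_identical(g1$section$bone_mask, g2$section$bone_mask)
  expect_identical(g1$section$cartilage_mask, g2$section$cartilage_mask)
  expect_identical(g1$ground_truth$achieved_bvtv, g2$ground_truth$achieved_bvtv)
})

test_that("achieved bone fractions land within 0.5 pp of their targets", {
  g <- cached_section()
  gt <- g$ground_truth
  for (r in names(gt$targets)) {
    expect_lt(abs(gt$achieved_bvtv[[r]] - gt$targets[[r]]), 0.5)
  }
  # declared achieved values are literally direct pixel counts
  for (r in c("h", "sc1", "m1")) {
    ix <- gt$stencils[[r]]
    expect_identical(gt$achieved_bvtv[[r]],
                     100 * sum(g$section$bone_mask[ix]) / length(ix))
  }
})

test_that("a single head target drives both subchondral and inner fills", {
  g <- generate_section(coarse_spec(
    seed = 9, region_bvtv_targets = c(h = 30, sc1 = 18, sc2 = 20, m1 = 22, m2 = 22, rest = 18)
  ))
  gt <- g$ground_truth
  expect_equal(gt$targets[["subchondral"]], 30)
  expect_equal(gt$targets[["inner"]], 30)
  expect_lt(abs(gt$achieved_bvtv[["h"]] - 30), 0.5)
})

test_that("impossible specs are rejected", {
  expect_error(section_spec(region_bvtv_targets = c(h = 97, sc1 = 18, sc2 = 20,
                                                    m1 = 22, m2 = 22)),
               "unreachable")
  expect_error(section_spec(head_radius = -1), "positive")
  expect_error(section_spec(region_bvtv_targets = c(h = 25)), "needs sc1")
})

test_that("the drawn plate band has the prescribed width by a distance-map oracle", {
  g <- cached_section()
  gt <- g$ground_truth
  mmpp <- g$section$mm_per_pixel
  ctr <- gt$head_center
  nrr <- nrow(g$section$bone_mask)
  idx <- which(g$section$bone_mask)
  ri <- ((idx - 1L) %% nrr) + 1L
  rj <- ((idx - 1L) %/% nrr) + 1L
  rr <- sqrt((rj - ctr[1])^2 + (ri - ctr[2])^2)
  d_n <- (rj - ctr[1]) * gt$apex_dir[1] + (ri - ctr[2]) * gt$apex_dir[2]
  plate <- matrix(FALSE, nrr, ncol(g$section$bone_mask))
  plate[idx[rr > gt$line_e_length - 0.5 & d_n > 5]] <- TRUE
  # half the band width = the deepest interior distance of the band
  dm <- matrix(as.numeric(EBImage::distmap(EBImage::Image(plate * 1))), nrow = nrr)
  half_width_px <- max(dm)
  expect_lt(abs(2 * half_width_px * mmpp - 0.5), 2 * mmpp)
})

test_that("cohorts mirror the two-group design", {
  cs <- cohort_spec(seed = 3)
  ch <- generate_cohort(cs, materialize = FALSE)
  expect_equal(nrow(ch), 12)
  expect_equal(sum(ch$group == "normal"), 6)
  expect_equal(sum(ch$group == "osteoporotic"), 6)
  # labels consistent with the WHO rule applied to the drawn T-scores
  expect_equal(as.character(allocate_group(ch$t_score)), as.character(ch$group))

  tg <- do.call(rbind, ch$targets)
  worst <- colMeans(tg[ch$group == "osteoporotic", ]) / colMeans(tg[ch$group == "normal", ])
  expect_lt(worst[["sc1"]], worst[["sc2"]])       # strongest loss in sc1
  expect_lt(worst[["m1"]], worst[["subchondral"]])  # medial metaphysis below head
  expect_true(all(worst[c("subchondral", "inner", "sc1", "sc2", "m1", "m2")] < 0.9))

  # identity effect + no jitter: the two groups' targets coincide
  ch0 <- generate_cohort(cohort_spec(seed = 3, jitter_logit_sd = 1e-9,
                                     effect_map = c(h = 1, subchondral = 1, inner = 1,
                                                    sc1 = 1, sc2 = 1, m1 = 1, m2 = 1,
                                                    rest = 1)),
                         materialize = FALSE)
  t_norm <- colMeans(do.call(rbind, ch0$targets[ch0$group == "normal"]))
  t_ost <- colMeans(do.call(rbind, ch0$targets[ch0$group == "osteoporotic"]))
  expect_equal(t_norm, t_ost, tolerance = 1e-6)

  expect_error(cohort_spec(n_per_group = 2), ">= 3")
  expect_error(cohort_spec(t_score_normal = c(-2, 1)), ">= -1.0")
  expect_error(cohort_spec(t_score_osteo = c(-1, 1)), "<= -2.5")
})

test_that("materialized cohort donors carry sections and ground truth", {
  ch <- generate_cohort(cohort_spec(seed = 4, n_per_group = 3,
                                    base = coarse_spec()), materialize = TRUE)
  expect_equal(nrow(ch), 6)
  expect_s3_class(ch$section[[1]], "section_image")
  expect_true(all(vapply(ch$ground_truth, function(g) length(g$stencils) == 8, TRUE)))
  # donor seeds differ, so sections differ
  expect_false(identical(ch$section[[1]]$bone_mask, ch$section[[2]]$bone_mask))
})
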