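# Shared fixtures: coarse synthetic sections (fast), simple phantoms, and the
# brute-force signed-rank oracle used to cross-check the nonparametric path.

coarse_spec <- function(seed = 7, ...) {
  section_spec(mm_per_pixel = 0.1, seed = seed, ...)
}

# cache generated sections across tests within one run
.section_cache <- new.env(parent = emptyenv())

cached_section <- function(seed = 7, mm_per_pixel = 0.1, ...) {
  key <- paste0("s", seed, "_", mm_per_pixel)
  if (is.null(.section_cache[[key]])) {
    .section_cache[[key]] <- generate_section(
      section_spec(mm_per_pixel = mm_per_pixel, seed = seed, ...)
    )
  }
  .section_cache[[key]]
}

cached_analysis <- function(seed = 7, mm_per_pixel = 0.1) {
  key <- paste0("a", seed, "_", mm_per_pixel)
  if (is.null(.section_cache[[key]])) {
    g <- cached_section(seed, mm_per_pixel)
    .section_cache[[key]] <- analyze_section(g$section, g$annotation,
                                             run_config(calibration = mm_per_pixel))
  }
  .section_cache[[key]]
}

# horizontal strip phantom: marrow | plate bone | cartilage | background,
# stacked along +y so a downward ray from the top crosses cartilage then bone
strip_phantom <- function(cart_px = 10, plate_px = 6, mm_per_pixel = 0.1) {
  nr <- 120; nc <- 60
  bone <- matrix(FALSE, nr, nc)
  cart <- matrix(FALSE, nr, nc)
  # rows 1..40 marrow-side bone lattice absent; plate below cartilage
  cart[41:(40 + cart_px), ] <- TRUE
  bone[(41 + cart_px):(40 + cart_px + plate_px), ] <- TRUE
  # distal filler bone so the envelope is simply connected
  bone[(60 + cart_px + plate_px):nr, ] <- TRUE
  section_image(bone, cart, mm_per_pixel, "left", "phantom")
}

annulus_phantom <- function(outer_r = 100, inner_r = 90, mm_per_pixel = 0.05) {
  n <- 2 * outer_r + 21
  ctr <- (n + 1) / 2
  ii <- seq_len(n)
  d2 <- outer((ii - ctr)^2, (ii - ctr)^2, "+")   # [row, col] squared radius
  bone <- d2 <= outer_r^2 & d2 >= inner_r^2
  section_image(bone, matrix(FALSE, n, n), mm_per_pixel, "left", "annulus")
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
enumerate_signed_rank_p <- function(d, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 12, !any(duplicated(abs(d))))
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% rk)
  if (alternative == "greater") {
    mean(v_all >= v_obs)
  } else {
    min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
  }
}
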