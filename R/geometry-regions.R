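# Cancellous domain: tissue envelope minus cartilage and minus the peripheral
# compact bone (cortical shells, head rim and subchondral plate), identified
# as the connected bone component(s) touching the envelope boundary.
cancellous_domain <- function(section, env = NULL, boundary = NULL) {
  bone <- section$bone_mask
  if (is.null(env)) env <- tissue_envelope(bone, section$cartilage_mask)
  lab <- EBImage::bwlabel(EBImage::Image(bone * 1))
  lab <- matrix(as.integer(lab), nrow = nrow(bone))
  ring <- if (is.null(boundary)) mask_boundary(env) else boundary
  ring_labels <- setdiff(unique(lab[ring]), 0L)
  compact <- lab %in% ring_labels
  dim(compact) <- dim(bone)
  env & !section$cartilage_mask & !compact
}

#' Partition a section into the cancellous regions of interest
#'
#' Uses the landmark system to cut the cancellous bone into the seven regions
#' on which BV/TV is measured:
#'
#' * `h` — cancellous bone of the humeral head: the articular side of line b
#'   within the inner surface of the subchondral plate (radius |line e| around
#'   the head center).
#' * `subchondral` / `inner` — split of `h` at distance s2 from the plate's
#'   inner surface; together they tile `h` exactly.
#' * `sc1`, `sc2` — two s2-thick subcapital bands parallel to line b on its
#'   distal side (sc1 adjacent to the anatomical neck), spanning the column
#'   beneath the articular chord.
#' * `m1`, `m2` — two medial metaphyseal strips of width s1 running distally
#'   from line c, m1 medial-most; their long boundaries are the s1
#'   subdivisions of the medial segment of line c. Any residual overlap with
#'   the subcapital bands is removed from the strips, so the regions are
#'   pairwise interior-disjoint.
#'
#' Every region is clipped to the cancellous domain: tissue envelope minus
#' cartilage minus the peripheral compact bone (cortical lamellae, head rim
#' and subchondral plate), so cortical bone never enters a cancellous region.
#'
#' @param section A [section_image()].
#' @param lm A [construct_landmarks()] result.
#' @param m_strip_len Distal extent of the m1/m2 strips from line c, in units
#'   of s1 (default 2, i.e. strips of length 2 s1).
#' @param env Optional precomputed tissue envelope.
#' @param boundary Optional precomputed envelope boundary mask.
#' @return A tibble of class `region_set` with one row per region: `region`,
#'   `pixels` (integer image indices), `n_px`, `area_mm2`, and the clipped
#'   region `outline` polygon for plotting. The landmark set is attached as
#'   attribute `landmarks`.
#' @export
partition_regions <- function(section, lm, m_strip_len = 2, env = NULL,
                              boundary = NULL) {
  if (is.null(env)) env <- tissue_envelope(section$bone_mask, section$cartilage_mask)
  domain <- cancellous_domain(section, env, boundary)
  nr <- nrow(domain); nc <- ncol(domain)

  m <- lm$head_center
  e_hat <- lm$e_hat; b_hat <- lm$b_hat; a_hat <- lm$a_hat
  L_e <- lm$line_e$length
  s1 <- lm$s1_length; s2 <- lm$s2_length
  R_b <- lm$b_half

  # tight bounding box: head circle, subcapital slab corners, m-strip corners
  P0 <- lm$medial_c_end
  corners <- rbind(
    m + c(L_e, L_e), m - c(L_e, L_e),
    t(vapply(list(c(-R_b, 0), c(R_b, 0), c(-R_b, -2 * s2), c(R_b, -2 * s2)),
             function(k) m + k[1] * b_hat + k[2] * e_hat, numeric(2))),
    P0, P0 - 2 * s1 * lm$medial_hat, P0 - m_strip_len * s1 * a_hat,
    P0 - 2 * s1 * lm$medial_hat - m_strip_len * s1 * a_hat
  )
  j0 <- max(1L, floor(min(corners[, 1]) - 2)); j1 <- min(nc, ceiling(max(corners[, 1]) + 2))
  i0 <- max(1L, floor(min(corners[, 2]) - 2)); i1 <- min(nr, ceiling(max(corners[, 2]) + 2))
  jj <- j0:j1; ii <- i0:i1
  dx <- rep(jj - m[1], each = length(ii))
  dy <- rep(ii - m[2], times = length(jj))
  d_e <- dx * e_hat[1] + dy * e_hat[2]
  d_b <- dx * b_hat[1] + dy * b_hat[2]
  r <- sqrt(dx * dx + dy * dy)
  box_idx <- as.integer(outer(ii, (jj - 1L) * nr, "+"))  # image indices of box pixels
  dom_box <- domain[box_idx]

  sub_m <- dom_box & d_e >= 0 & r <= L_e & r >= L_e - s2
  inn_m <- dom_box & d_e >= 0 & r < L_e - s2
  in_col <- abs(d_b) <= R_b
  sc1_m <- dom_box & in_col & d_e < 0 & d_e >= -s2
  sc2_m <- dom_box & in_col & d_e < -s2 & d_e >= -2 * s2

  # medial metaphyseal strips in their own (smaller) frame
  P <- lm$medial_c_end
  t_hat <- -lm$medial_hat                 # lateral-ward along line c
  d_hat <- -a_hat                         # distal-ward
  strip_len <- m_strip_len * s1
  u <- dx + (m[1] - P[1]); v <- dy + (m[2] - P[2])  # relative to P_med
  su <- u * t_hat[1] + v * t_hat[2]
  sv <- u * d_hat[1] + v * d_hat[2]
  in_strip <- dom_box & sv >= 0 & sv <= strip_len & !sc1_m & !sc2_m
  m1_m <- in_strip & su >= 0 & su <= s1
  m2_m <- in_strip & su > s1 & su <= 2 * s1

  h_px <- box_idx[sub_m | inn_m]
  masks <- list(
    h = h_px,
    sc1 = box_idx[sc1_m],
    sc2 = box_idx[sc2_m],
    m1 = box_idx[m1_m],
    m2 = box_idx[m2_m],
    subchondral = box_idx[sub_m],
    inner = box_idx[inn_m]
  )
  empty <- names(masks)[vapply(masks, length, 0L) == 0L]
  if (length(empty) > 0L) {
    stop(sprintf("empty region(s) after clipping to cancellous bone: %s",
                 paste(empty, collapse = ", ")), call. = FALSE)
  }

  mmpp <- section$mm_per_pixel
  out <- tibble::tibble(
    region = names(masks),
    pixels = unname(masks),
    n_px = vapply(masks, length, 0L),
    area_mm2 = vapply(masks, length, 0L) * mmpp^2,
    outline = unname(lapply(names(masks), function(lbl) region_outline(lbl, lm, m_strip_len)))
  )
  attr(out, "landmarks") <- lm
  attr(out, "m_strip_len") <- m_strip_len
  class(out) <- c("region_set", class(out))
  out
}

# analytic construction outline of a region (pre-clipping), for plotting
region_outline <- function(label, lm, m_strip_len = 2) {
  m <- lm$head_center; e_hat <- lm$e_hat; b_hat <- lm$b_hat
  L_e <- lm$line_e$length; s1 <- lm$s1_length; s2 <- lm$s2_length
  R_b <- lm$b_half
  arc <- function(radius, from = 0, to = pi) {
    th <- seq(from, to, length.out = 90)
    cbind(m[1] + radius * (cos(th) * (-b_hat[1]) + sin(th) * e_hat[1]),
          m[2] + radius * (cos(th) * (-b_hat[2]) + sin(th) * e_hat[2]))
  }
  band <- function(d0, d1, halfwidth) {
    corner <- function(db, de) m + db * b_hat + de * e_hat
    rbind(corner(-halfwidth, -d0), corner(halfwidth, -d0),
          corner(halfwidth, -d1), corner(-halfwidth, -d1))
  }
  pts <- switch(label,
    h = arc(L_e),
    subchondral = rbind(arc(L_e), arc(L_e - s2, pi, 0)),
    inner = arc(L_e - s2),
    sc1 = band(0, s2, R_b),
    sc2 = band(s2, 2 * s2, R_b),
    m1 = ,
    m2 = {
      P <- lm$medial_c_end; t_hat <- -lm$medial_hat; d_hat <- -lm$a_hat
      o <- if (label == "m1") 0 else s1
      len <- m_strip_len * s1
      rbind(P + o * t_hat, P + (o + s1) * t_hat,
            P + (o + s1) * t_hat + len * d_hat, P + o * t_hat + len * d_hat)
    }
  )
  tibble::tibble(x = pts[, 1], y = pts[, 2])
}

#' Jaccard overlap of two pixel-index sets
#'
#' @param a,b Integer vectors of image indices (e.g. `pixels` entries of a
#'   [partition_regions()] result and a generator ground-truth stencil).
#' @return Intersection over union in `[0, 1]`.
#' @export
region_jaccard <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}
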