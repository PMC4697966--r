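# Small 2D vector helpers. Points are numeric length-2 c(x, y) in continuous
# pixel coordinates: pixel (row i, col j) of a mask matrix has its center at
# (x = j, y = i); x grows rightward (columns), y grows downward (rows).

vnorm <- function(v) sqrt(sum(v^2))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector", call. = FALSE)
  v / n
}

# perpendicular, rotated +90 degrees in image coords (x right, y down)
vperp <- function(v) c(-v[2], v[1])

vdot <- function(a, b) sum(a * b)

# z-component of the 2D cross product
vcross <- function(a, b) a[1] * b[2] - a[2] * b[1]

deg2rad <- function(deg) deg * pi / 180

#' @noRd
new_line <- function(point, direction) {
  list(point = as.numeric(point), direction = vunit(as.numeric(direction)))
}

# signed distance of points (n x 2 matrix) from line along a unit normal
line_offset <- function(line, pts) {
  nrm <- vperp(line$direction)
  (pts[, 1] - line$point[1]) * nrm[1] + (pts[, 2] - line$point[2]) * nrm[2]
}

# projection of points onto the line direction, relative to line$point
line_proj <- function(line, pts) {
  d <- line$direction
  (pts[, 1] - line$point[1]) * d[1] + (pts[, 2] - line$point[2]) * d[2]
}

lines_intersect <- function(l1, l2) {
  d1 <- l1$direction; d2 <- l2$direction
  denom <- vcross(d1, d2)
  if (abs(denom) < 1e-12) stop("lines are parallel; no intersection", call. = FALSE)
  dp <- l2$point - l1$point
  t1 <- vcross(dp, d2) / denom
  l1$point + t1 * d1
}

# sample a ray at fixed step; returns matrix of (x, y) positions
ray_samples <- function(origin, direction, max_len, step = 0.25) {
  t <- seq(0, max_len, by = step)
  cbind(origin[1] + t * direction[1], origin[2] + t * direction[2])
}

# nearest-pixel lookup of a logical matrix at continuous (x, y) positions;
# positions outside the matrix return FALSE
mask_at <- function(mask, pts) {
  i <- round(pts[, 2])
  j <- round(pts[, 1])
  ok <- i >= 1 & i <= nrow(mask) & j >= 1 & j <= ncol(mask)
  out <- logical(nrow(pts))
  out[ok] <- mask[cbind(i[ok], j[ok])]
  out
}

# coordinates (x, y) of TRUE pixels of a mask, as an n x 2 matrix
mask_coords <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0L) return(matrix(numeric(0), ncol = 2))
  i <- ((idx - 1L) %% nrow(mask)) + 1L
  j <- ((idx - 1L) %/% nrow(mask)) + 1L
  cbind(x = as.numeric(j), y = as.numeric(i))
}

mask_centroid <- function(mask) {
  xy <- mask_coords(mask)
  if (nrow(xy) == 0L) stop("empty mask has no centroid", call. = FALSE)
  colMeans(xy)
}

# principal axis (unit vector) of a point cloud via the 2x2 covariance eigenvector
principal_axis <- function(pts) {
  ctr <- colMeans(pts)
  x <- pts[, 1] - ctr[1]; y <- pts[, 2] - ctr[2]
  cv <- matrix(c(mean(x * x), mean(x * y), mean(x * y), mean(y * y)), 2, 2)
  ev <- eigen(cv, symmetric = TRUE)
  list(center = ctr, direction = vunit(ev$vectors[, 1]))
}

# filled boolean envelope of the section tissue (bone + cartilage, holes filled)
tissue_envelope <- function(bone, cartilage) {
  tissue <- bone | cartilage
  env <- EBImage::fillHull(EBImage::Image(tissue * 1))
  matrix(as.numeric(env) > 0.5, nrow = nrow(bone))
}

# boundary pixels of a filled mask (TRUE pixels with a FALSE 4-neighbour or on
# the image edge)
mask_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  up <- rbind(mask[-1, , drop = FALSE], FALSE)
  dn <- rbind(FALSE, mask[-nr, , drop = FALSE])
  lf <- cbind(mask[, -1, drop = FALSE], FALSE)
  rt <- cbind(FALSE, mask[, -nc, drop = FALSE])
  mask & !(up & dn & lf & rt)
}
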