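#' Calibrated two-mask model of a frontal bone section
#'
#' A `section_image` bundles the two aligned binary rasters that stand in for
#' a stained frontal section of a proximal humerus: a mineralized-bone mask
#' and a hyaline-cartilage mask, together with the length calibration and the
#' anatomical orientation of the image.
#'
#' Masks are logical matrices indexed `[row, col]` with row 1 at the top of
#' the image; the pixel in row i, column j has its center at continuous
#' coordinates (x = j, y = i). All geometry runs in pixel units and is
#' converted to millimetres only when results are reported, via
#' `mm_per_pixel`.
#'
#' @param bone_mask Logical matrix, `TRUE` where mineralized bone is present.
#' @param cartilage_mask Logical matrix of identical dimensions, `TRUE` where
#'   hyaline articular cartilage is present. A pixel may be bone or cartilage,
#'   never both.
#' @param mm_per_pixel Positive length calibration in mm per pixel.
#' @param medial_side Which image side is anatomically medial: `"left"` or
#'   `"right"`. Frontal sections can be mounted mirrored, so this is explicit
#'   metadata, never inferred.
#' @param donor_id Opaque donor identifier carried through to results.
#'
#' @return An object of class `section_image`.
#' @export
section_image <- function(bone_mask, cartilage_mask, mm_per_pixel,
                          medial_side = c("left", "right"), donor_id = "donor") {
  medial_side <- match.arg(medial_side)
  if (!is.matrix(bone_mask) || !is.matrix(cartilage_mask)) {
    stop("bone_mask and cartilage_mask must be matrices", call. = FALSE)
  }
  bone_mask <- bone_mask & TRUE        # coerce numeric 0/1 to logical
  cartilage_mask <- cartilage_mask & TRUE
  if (!identical(dim(bone_mask), dim(cartilage_mask))) {
    stop(sprintf(
      "mask dimension mismatch: bone is %dx%d, cartilage is %dx%d",
      nrow(bone_mask), ncol(bone_mask), nrow(cartilage_mask), ncol(cartilage_mask)
    ), call. = FALSE)
  }
  n_overlap <- sum(bone_mask & cartilage_mask)
  if (n_overlap > 0L) {
    stop(sprintf(
      "bone and cartilage masks overlap on %d pixel(s); a pixel is bone or cartilage, never both",
      n_overlap
    ), call. = FALSE)
  }
  if (!is.numeric(mm_per_pixel) || length(mm_per_pixel) != 1L ||
      !is.finite(mm_per_pixel) || mm_per_pixel <= 0) {
    stop("mm_per_pixel must be a single positive number", call. = FALSE)
  }
  structure(
    list(
      bone_mask = bone_mask,
      cartilage_mask = cartilage_mask,
      mm_per_pixel = as.numeric(mm_per_pixel),
      medial_side = medial_side,
      donor_id = as.character(donor_id)
    ),
    class = "section_image"
  )
}

#' @export
print.section_image <- function(x, ...) {
  cat(sprintf(
    "<section_image> donor %s: %d x %d px @ %.4g mm/px, medial side %s\n  bone %.1f%%, cartilage %.1f%% of frame\n",
    x$donor_id, nrow(x$bone_mask), ncol(x$bone_mask), x$mm_per_pixel, x$medial_side,
    100 * mean(x$bone_mask), 100 * mean(x$cartilage_mask)
  ))
  invisible(x)
}

read_raster_mask <- function(path) {
  if (!file.exists(path)) stop(sprintf("raster file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported raster format '%s' (use PNG or TIFF)", ext), call. = FALSE)
  )
  if (length(dim(img)) == 3L) img <- img[, , 1]   # collapse channels; masks are single-plane
  img > 0                                          # nonzero = mask-true
}

#' Read a calibrated section from two mask rasters
#'
#' Reads aligned bone and cartilage masks (8-bit PNG or TIFF; any nonzero
#' pixel is mask-true) and returns a validated [section_image()].
#'
#' @param bone_path,cartilage_path Paths to the bone and cartilage rasters.
#' @param calibration Length scale in mm per pixel (required; overview-scan
#'   resolution is never assumed).
#' @param medial_side `"left"` or `"right"`; see [section_image()].
#' @param donor_id Donor identifier.
#'
#' @return A `section_image`.
#' @export
read_section <- function(bone_path, cartilage_path, calibration,
                         medial_side = c("left", "right"), donor_id = "donor") {
  bone <- read_raster_mask(bone_path)
  cart <- read_raster_mask(cartilage_path)
  section_image(bone, cart, calibration, medial_side, donor_id)
}

#' Write a section's masks to PNG files
#'
#' @param section A `section_image`.
#' @param bone_path,cartilage_path Output PNG paths.
#' @return Invisibly, the two paths.
#' @export
write_section <- function(section, bone_path, cartilage_path) {
  png::writePNG(section$bone_mask * 1, bone_path)
  png::writePNG(section$cartilage_mask * 1, cartilage_path)
  invisible(c(bone_path, cartilage_path))
}

#' Landmark annotation for a section
#'
#' Records the two cartilage endpoints that anchor the anatomical-neck chord,
#' plus an optional manual override for the humeral long axis. Points are
#' continuous pixel coordinates `c(x, y)`.
#'
#' @param cranial_cartilage_end,caudal_cartilage_end Numeric `c(x, y)` points;
#'   must be distinct and lie on or within 2 px of the cartilage boundary of
#'   the section they annotate (validated in [validate_annotation()]).
#' @param shaft_axis_override Optional list of two `c(x, y)` points through
#'   which the long axis is forced.
#' @param notes Free text.
#' @return An object of class `annotation`.
#' @export
annotation <- function(cranial_cartilage_end, caudal_cartilage_end,
                       shaft_axis_override = NULL, notes = "") {
  cr <- as.numeric(cranial_cartilage_end)
  ca <- as.numeric(caudal_cartilage_end)
  if (length(cr) != 2L || length(ca) != 2L || !all(is.finite(c(cr, ca)))) {
    stop("cartilage endpoints must be finite (x, y) points", call. = FALSE)
  }
  if (vnorm(cr - ca) < 1e-9) {
    stop("cranial and caudal cartilage endpoints must be distinct", call. = FALSE)
  }
  if (!is.null(shaft_axis_override)) {
    shaft_axis_override <- lapply(shaft_axis_override, as.numeric)
    if (length(shaft_axis_override) != 2L ||
        any(!vapply(shaft_axis_override, function(p) length(p) == 2L && all(is.finite(p)), TRUE))) {
      stop("shaft_axis_override must be a list of two (x, y) points", call. = FALSE)
    }
  }
  structure(
    list(
      cranial_cartilage_end = cr,
      caudal_cartilage_end = ca,
      shaft_axis_override = shaft_axis_override,
      notes = as.character(notes)
    ),
    class = "annotation"
  )
}

#' Check that annotation endpoints sit on the cartilage boundary
#'
#' @param ann An [annotation()].
#' @param section The `section_image` it annotates.
#' @param tol_px Maximum allowed distance (px) from the cartilage boundary.
#' @return `ann`, invisibly; errors if an endpoint is too far from cartilage.
#' @export
validate_annotation <- function(ann, section, tol_px = 2) {
  bxy <- mask_coords(mask_boundary(section$cartilage_mask))
  if (nrow(bxy) == 0L) stop("section has no cartilage to annotate", call. = FALSE)
  for (nm in c("cranial_cartilage_end", "caudal_cartilage_end")) {
    p <- ann[[nm]]
    d <- sqrt(min((bxy[, 1] - p[1])^2 + (bxy[, 2] - p[2])^2))
    if (d > tol_px) {
      stop(sprintf("%s is %.1f px from the cartilage boundary (tolerance %g px)", nm, d, tol_px),
           call. = FALSE)
    }
  }
  invisible(ann)
}

#' Read / write annotation JSON
#'
#' JSON keys: `cranial_cartilage_end`, `caudal_cartilage_end`,
#' `shaft_axis_override` (optional), `notes` — all coordinates in px.
#'
#' @param path JSON file path.
#' @return [read_annotation()] returns an `annotation`.
#' @export
read_annotation <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  ov <- j$shaft_axis_override
  if (!is.null(ov)) {
    if (is.matrix(ov)) ov <- list(ov[1, ], ov[2, ])
    if (is.data.frame(ov)) ov <- list(unlist(ov[1, ]), unlist(ov[2, ]))
  }
  annotation(j$cranial_cartilage_end, j$caudal_cartilage_end, ov,
             notes = if (is.null(j$notes)) "" else j$notes)
}

#' @rdname read_annotation
#' @param ann An `annotation` to serialize.
#' @export
write_annotation <- function(ann, path) {
  jsonlite::write_json(
    list(
      cranial_cartilage_end = ann$cranial_cartilage_end,
      caudal_cartilage_end = ann$caudal_cartilage_end,
      shaft_axis_override = ann$shaft_axis_override,
      notes = ann$notes
    ),
    path, auto_unbox = FALSE, digits = NA, null = "null"
  )
  invisible(path)
}
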