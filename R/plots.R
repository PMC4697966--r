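#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a measured section result
#'
#' BV/TV by region, the subchondral plate profile over the articular arc, and
#' the cortical thickness profiles by level, faceted into one figure.
#'
#' @param object A `morphometry_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot morphometry_result
#' @export
autoplot.morphometry_result <- function(object, ...) {
  bv <- dplyr::mutate(object$bvtv, panel = "BV/TV (%)",
                      x = .data$region, value = .data$bvtv, grp = "bvtv")
  pl <- dplyr::mutate(object$plate, panel = "plate thickness (mm)",
                      x = as.character(.data$angle), value = .data$thickness_mm,
                      grp = "plate")
  ct <- dplyr::mutate(object$cortical, panel = "cortical thickness (mm)",
                      x = as.character(.data$level), value = .data$thickness_mm,
                      grp = .data$side)
  df <- dplyr::bind_rows(bv[c("panel", "x", "value", "grp")],
                         pl[c("panel", "x", "value", "grp")],
                         ct[c("panel", "x", "value", "grp")])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$value,
                                   group = .data$grp, colour = .data$grp)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = df[df$panel != "BV/TV (%)", ]) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the comparison workflow output
#'
#' Adjusted p-values per comparison, faceted by family, with the significance
#' threshold marked.
#'
#' @param object A `comparison_table` (e.g. from [run_study()]).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot comparison_table
#' @export
autoplot.comparison_table <- function(object, ...) {
  alpha <- attr(object, "alpha")
  if (is.null(alpha)) alpha <- 0.05
  df <- tibble::as_tibble(object)
  if (!"family" %in% names(df)) df$family <- "comparisons"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$comparison, y = .data$adjusted_p,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = alpha, linetype = 2) +
    ggplot2::facet_wrap(~family, scales = "free_y") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Bonferroni-adjusted p", fill = "significant") +
    ggplot2::theme_minimal()
}

#' Overlay the region partition on a section
#'
#' Downsamples the masks for display and draws the construction outlines of
#' the cancellous regions on top.
#'
#' @param section A [section_image()].
#' @param regions A [partition_regions()] result.
#' @param downsample Integer pixel stride for the raster underlay.
#' @return A ggplot.
#' @export
plot_section <- function(section, regions = NULL, downsample = 4) {
  b <- section$bone_mask; cmask <- section$cartilage_mask
  ii <- seq(1, nrow(b), by = downsample)
  jj <- seq(1, ncol(b), by = downsample)
  tissue <- matrix("background", length(ii), length(jj))
  tissue[b[ii, jj]] <- "bone"
  tissue[cmask[ii, jj]] <- "cartilage"
  df <- tibble::tibble(
    x = rep(jj, each = length(ii)),
    y = rep(ii, times = length(jj)),
    tissue = as.vector(tissue)
  )
  p <- ggplot2::ggplot(df[df$tissue != "background", ],
                       ggplot2::aes(x = .data$x, y = .data$y, fill = .data$tissue)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(bone = "grey20", cartilage = "steelblue")) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(regions)) {
    out <- dplyr::bind_rows(purrr::map2(regions$region, regions$outline,
                                        ~ dplyr::mutate(.y, region = .x)))
    p <- p + ggplot2::geom_path(
      data = out,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$region),
      inherit.aes = FALSE
    )
  }
  p
}
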