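#' Plot a raster (HSI, resistance, current) with ggplot2
#'
#' @param object an [eco_raster].
#' @param ... unused.
#' @param trans scale transform for the fill (e.g. `"log10"` for current
#'   maps); default identity.
#' @return A ggplot object.
#' @export
autoplot.eco_raster <- function(object, ..., trans = "identity") {
  m <- object$values
  df <- tibble::tibble(
    x_km = (rep(seq_len(ncol(m)) - 0.5, each = nrow(m))) * object$cell_km,
    y_km = (rep(rev(seq_len(nrow(m))) - 0.5, times = ncol(m))) *
      object$cell_km,
    value = as.vector(m[rev(seq_len(nrow(m))), ])
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x_km, .data$y_km,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90", trans = trans) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Dose-response plot: study-area HSI band with lek-proportion bars
#'
#' Mean HSI over study-area cells (line) with a +/- 1 SD band, bars for the
#' proportion of leks per bin, and a dashed line at the lek-coverage HSI
#' threshold when available.
#'
#' @param object an `eco_dose_response` from [dose_response()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.eco_dose_response <- function(object, ...) {
  thr <- attr(object, "hsi_threshold")
  gg <- ggplot2::ggplot(object, ggplot2::aes(x = .data$mid)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$lek_prop),
                      fill = "grey70", width = diff(object$mid[1:2])) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = pmax(.data$mean_hsi - .data$sd_hsi, 0),
      ymax = pmin(.data$mean_hsi + .data$sd_hsi, 1)),
      alpha = 0.2, na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_hsi), na.rm = TRUE) +
    ggplot2::labs(x = attr(object, "variable"),
                  y = "HSI / proportion of leks") +
    ggplot2::theme_minimal()
  if (is.finite(thr)) {
    gg <- gg + ggplot2::geom_hline(yintercept = thr, linetype = "dashed")
  }
  gg
}

#' Eigenvalue ladder of a partition model
#'
#' Eigenvalues by partition rank with the selected minimum-variance tail
#' highlighted and the unity threshold marked.
#'
#' @param model an `eco_partition_model`.
#' @return A ggplot object.
#' @export
plot_eigenvalue_ladder <- function(model) {
  td <- tidy(model)
  if (all(is.na(td$in_tail))) td$in_tail <- FALSE
  ggplot2::ggplot(td, ggplot2::aes(.data$partition, .data$eigval,
                                   colour = .data$in_tail)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey30", `TRUE` = "firebrick"),
      labels = c(`FALSE` = "dominant", `TRUE` = "minimum tail"),
      name = NULL) +
    ggplot2::labs(x = "partition (k)", y = "eigenvalue") +
    ggplot2::theme_minimal()
}
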