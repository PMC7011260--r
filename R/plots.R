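#' Plot a credibility grid
#'
#' Scatter of FPRP against BFDP for every record of a profile, faceted by
#' prior and detection odds ratio, with the noteworthiness thresholds drawn
#' as dashed lines. Values span many orders of magnitude, so both axes are
#' log-scaled; undefined FPRP cells are omitted.
#'
#' @param profile A long profile from [credibility_profile()].
#' @param fprp_threshold,bfdp_threshold Threshold lines; defaults `0.2` and
#'   `0.8`.
#' @return A ggplot object.
#' @export
plot_credibility <- function(profile, fprp_threshold = 0.2,
                             bfdp_threshold = 0.8) {
  df <- dplyr::filter(profile, !is.na(.data$fprp), .data$fprp > 0,
                      .data$bfdp > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fprp, y = .data$bfdp,
                                   colour = .data$noteworthy_any)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = fprp_threshold, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = bfdp_threshold, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_grid(prior ~ detection_or,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "FPRP", y = "BFDP", colour = "noteworthy") +
    ggplot2::theme_bw()
}

#' @exportS3Method ggplot2::autoplot
autoplot.reanalysis <- function(object, ...) {
  if (is.null(object$profile)) {
    stop("empty report: nothing to plot", call. = FALSE)
  }
  plot_credibility(object$profile,
                   fprp_threshold = object$config$fprp_threshold,
                   bfdp_threshold = object$config$bfdp_threshold)
}

#' Plot an attributable-risk table
#'
#' Horizontal bars of per-variant attributable risk (percent), ordered by
#' size, annotated with the joint summary under both combination
#' conventions.
#'
#' @param x A [par_table()].
#' @return A ggplot object.
#' @export
plot_par <- function(x) {
  stopifnot(inherits(x, "par_table"))
  df <- dplyr::mutate(x$per_snp,
                      variant = stats::reorder(.data$variant,
                                               .data$par_percent))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$par_percent,
                                   y = .data$variant)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "population attributable risk (%)", y = NULL,
      subtitle = sprintf(
        "joint: prod(1-PAR) = %.1f%%, 1 - prod(1-PAR) = %.1f%%",
        x$joint$complement_product_percent,
        x$joint$one_minus_product_percent)) +
    ggplot2::theme_bw()
}

#' @exportS3Method ggplot2::autoplot
autoplot.par_table <- function(object, ...) plot_par(object)
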