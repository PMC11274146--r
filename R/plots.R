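#' Convergence plot of Monte Carlo statistics
#'
#' Running mean and variance per traced output against sample size, the
#' standard visual check that the surrogate-assisted estimates have settled.
#'
#' @param object An `mc_statistics` with a nonempty trace.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mc_statistics <- function(object, ...) {
  tr <- object$trace
  if (nrow(tr) == 0) stop("no convergence trace recorded (trace_outputs was empty)")
  long <- tidyr::pivot_longer(tr, c("mean", "variance"),
                              names_to = "statistic", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n, y = .data$value,
                                     colour = factor(.data$output))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = "MC samples", y = NULL, colour = "output",
                  title = "Monte Carlo convergence")
}

#' Histogram of per-voxel relative errors
#'
#' @param object An `error_report`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.error_report <- function(object, bins = 40, ...) {
  ggplot2::ggplot(tidy.error_report(object),
                  ggplot2::aes(x = 100 * .data$err)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::geom_vline(xintercept = 100 * object$err_ave, linetype = 2) +
    ggplot2::labs(x = "per-voxel relative error (%)", y = "voxels",
                  title = sprintf("err_ave = %.3f%%, err_max = %.3f%%",
                                  100 * object$err_ave, 100 * object$err_max))
}

#' Bar chart of tissue-averaged Sobol indices
#'
#' One panel per tissue, bars over the twelve dielectric inputs - the
#' at-a-glance answer to "whose permittivity/conductivity drives the SAR
#' variance in this tissue".
#'
#' @param object A `sensitivity_table` from [tissue_averaged_sobol()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sensitivity_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = factor(.data$input, levels = unique(.data$input)),
    y = .data$sobol)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~tissue) +
    ggplot2::labs(x = NULL, y = "tissue-averaged Sobol index") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Raster plot of one slice of a SAR volume
#'
#' @param sar A `sar_volume`.
#' @param slice Slice index along `axis`.
#' @param axis 1, 2 or 3.
#' @return A ggplot.
#' @export
plot_sar_slice <- function(sar, slice = NULL, axis = 3) {
  d <- dim(sar$values)
  if (is.null(slice)) slice <- (d[axis] + 1) %/% 2
  sl <- switch(axis,
               sar$values[slice, , ],
               sar$values[, slice, ],
               sar$values[, , slice])
  df <- tidyr::expand_grid(i = seq_len(nrow(sl)), j = seq_len(ncol(sl)))
  df$sar <- sl[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j, fill = .data$sar)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(na.value = "grey80") +
    ggplot2::labs(fill = "W/kg",
                  title = paste0(sar$provenance, " (slice ", slice, ")"))
}
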