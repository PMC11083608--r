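#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_abline geom_raster labs theme_minimal scale_fill_manual
#'   geom_vline facet_wrap
#' @export
ggplot2::autoplot

#' Plot an RR tachogram
#'
#' @param rr An [rr_series()].
#' @return A ggplot: interval length (ms) against beat time (s).
#' @export
plot_tachogram <- function(rr) {
  validate_rr_series(rr)
  ggplot(rr, aes(x = .data$time, y = .data$rr)) +
    geom_line(color = "grey40") +
    geom_point(size = 0.5) +
    labs(x = "beat time [s]", y = "RR interval [ms]",
         title = "RR tachogram") +
    theme_minimal()
}

#' @export
autoplot.rr_histogram <- function(object, ...) {
  df <- tibble::tibble(mid = object$mids, count = object$counts)
  ggplot(df, aes(x = .data$mid, y = .data$count)) +
    geom_col(width = object$bin_width, fill = "steelblue") +
    labs(x = "RR interval [ms]", y = "count", title = "RR histogram") +
    theme_minimal()
}

#' @export
autoplot.hrv_spectrum <- function(object, ...) {
  df <- object$psd
  ggplot(df, aes(x = .data$freq, y = .data$psd)) +
    geom_line() +
    geom_vline(xintercept = c(0.003, 0.04, 0.15, 0.4),
               linetype = "dashed", color = "grey60") +
    labs(x = "frequency [Hz]", y = expression(PSD ~ "[" * ms^2 / Hz * "]"),
         title = "Welch periodogram (VLF | LF | HF)") +
    theme_minimal()
}

#' @export
autoplot.hrv_poincare <- function(object, ...) {
  ggplot(object$points, aes(x = .data$rr_n, y = .data$rr_next)) +
    geom_point(alpha = 0.4, size = 0.8) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                color = "grey50") +
    labs(x = "RR(n) [ms]", y = "RR(n+1) [ms]",
         title = sprintf("Poincare plot (SD1 = %.1f, SD2 = %.1f ms)",
                         object$sd1, object$sd2)) +
    theme_minimal()
}

#' Plot a recurrence matrix
#'
#' @param rm Logical recurrence matrix from [recurrence_matrix()].
#' @return A ggplot raster of the recurrent points.
#' @export
plot_recurrence <- function(rm) {
  rm <- as.matrix(rm) != 0
  df <- tidyr::expand_grid(i = seq_len(nrow(rm)), j = seq_len(ncol(rm)))
  df$recurrent <- as.vector(rm)
  ggplot(df[df$recurrent, ], aes(x = .data$i, y = .data$j)) +
    geom_raster(fill = "black") +
    labs(x = "i", y = "j", title = "Recurrence plot") +
    theme_minimal()
}

#' @export
autoplot.hrv_embedding <- function(object, ...) {
  df <- tidy.hrv_embedding(object)
  ggplot(df, aes(x = .data$index, y = .data$value)) +
    geom_line() +
    geom_point(size = 0.8) +
    facet_wrap(~.data$diagnostic, scales = "free") +
    labs(x = "lag tau / dimension m", y = "AMI [nats] / FNN [%]",
         title = sprintf("Embedding diagnostics (tau_opt = %d, m_opt = %s)",
                         object$tau_opt,
                         if (is.na(object$m_opt)) "NA" else object$m_opt)) +
    theme_minimal()
}

#' @importFrom rlang .data
NULL
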