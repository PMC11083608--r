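#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.hrv_time_report <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(unclass(x)),
                      dplyr::everything(),
                      names_to = "parameter", values_to = "value")
}

#' @export
glance.hrv_time_report <- function(x, ...) tibble::as_tibble(unclass(x))

#' @export
tidy.hrv_spectrum <- function(x, ...) tibble::as_tibble(x$psd)

#' @export
glance.hrv_spectrum <- function(x, ...) tibble::as_tibble(unclass(x$bands))

#' @export
tidy.hrv_poincare <- function(x, ...) x$points

#' @export
glance.hrv_poincare <- function(x, ...) {
  tibble::tibble(sd1 = x$sd1, sd2 = x$sd2, ratio = x$ratio,
                 n_points = nrow(x$points))
}

#' @export
tidy.hrv_rqa <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$diag_hist, direction = "diagonal"),
    dplyr::mutate(x$vert_hist, direction = "vertical")
  )
}

#' @export
glance.hrv_rqa <- function(x, ...) {
  tibble::tibble(rec = x$rec, det = x$det, lam = x$lam, entr = x$entr,
                 n_points = x$n_points,
                 m = x$settings$m %||% NA, tau = x$settings$tau %||% NA,
                 epsilon = x$settings$epsilon %||% NA)
}

#' @export
tidy.hrv_embedding <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(diagnostic = "ami", index = x$ami_curve$tau,
                   value = x$ami_curve$ami),
    tibble::tibble(diagnostic = "fnn", index = x$fnn_curve$m,
                   value = x$fnn_curve$fnn_pct)
  )
}

#' @export
glance.hrv_embedding <- function(x, ...) {
  tibble::tibble(tau_opt = x$tau_opt, m_opt = x$m_opt,
                 n_attractor = nrow(x$attractor))
}

#' @export
tidy.group_comparison <- function(x, ...) x$groups

#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(parameter = x$parameter, reference = x$reference,
                 n_groups = nrow(x$groups), p_anova = x$p_anova)
}
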