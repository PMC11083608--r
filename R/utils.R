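#' @importFrom rlang abort warn %||%
#' @importFrom stats sd var median fft filter runmed splinefun t.test aov
#' @importFrom stats rnorm runif complete.cases setNames
#' @importFrom utils head tail
NULL

# Validation helper: abort with a consistent class so callers can condition on it.
stop_hrv <- function(msg, class = "hrv_validation_error") {
  abort(msg, class = c(class, "hrv_error"))
}

assert_that <- function(ok, msg, class = "hrv_validation_error") {
  if (!isTRUE(ok)) stop_hrv(msg, class = class)
  invisible(TRUE)
}

# Trapezoidal integral of y over x (x increasing).
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Population (divide-by-n) variance and sd.
pop_var <- function(x) mean((x - mean(x))^2)
pop_sd <- function(x) sqrt(pop_var(x))

# Linear interpolation of y at x0 given grid (x, y); x0 must lie within range.
interp_at <- function(x, y, x0) {
  stats::approx(x, y, xout = x0, rule = 1)$y
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Run all lengths of maximal runs of TRUE in a logical vector.
run_lengths_true <- function(v) {
  if (!length(v)) return(integer(0))
  r <- rle(v)
  r$lengths[r$values]
}
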