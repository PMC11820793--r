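# Zero-phase Butterworth filtering and numerical differentiation. The drift
# of the small horizontal plate forces is removed with a 0.1 Hz high-pass;
# estimated COM and COP traces are smoothed with a 3 Hz low-pass. Filters are
# run forward and backward so the output carries no phase lag.

#' Filter specification
#'
#' @param kind `"lowpass"` or `"highpass"`.
#' @param cutoff Pass frequency in Hz; must satisfy `0 < cutoff < fs/2` for
#'   the sampling rate the filter is applied at.
#' @param order Butterworth order of the one-way filter (the forward-backward
#'   pass doubles the effective order).
#' @param zero_phase Apply forward and backward (no phase distortion).
#'
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("lowpass", "highpass"), cutoff, order = 4L,
                        zero_phase = TRUE) {
  kind <- match.arg(kind)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0) {
    stop("'cutoff' must be a positive frequency [Hz]", call. = FALSE)
  }
  if (order < 1L) stop("'order' must be >= 1", call. = FALSE)
  structure(list(kind = kind, cutoff = cutoff, order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Zero-phase Butterworth filter
#'
#' Applies a Butterworth filter forward and backward over the series so the
#' net phase response is zero. Edge transients are controlled by odd
#' (point-symmetric) reflection padding of up to two filter warm-up lengths
#' (one warm-up length is taken as one period of the cutoff frequency) before
#' filtering; the padding is discarded afterwards.
#'
#' @param x Numeric vector, or matrix filtered column-wise.
#' @param spec A [filter_spec()].
#' @param fs Sampling rate in Hz.
#'
#' @return Filtered series, same shape as `x`.
#' @export
zero_phase_filter <- function(x, spec, fs) {
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$cutoff >= fs / 2) {
    stop(sprintf("cutoff %.3g Hz must be below the Nyquist frequency %.3g Hz",
                 spec$cutoff, fs / 2), call. = FALSE)
  }
  if (is.matrix(x)) {
    out <- x
    for (j in seq_len(ncol(x))) out[, j] <- zero_phase_filter(x[, j], spec, fs)
    return(out)
  }
  n <- length(x)
  nmin <- 3L * (spec$order + 1L)
  if (n < nmin) {
    stop(sprintf("series too short for filtering: %d samples, need >= %d",
                 n, nmin), call. = FALSE)
  }
  bt <- signal::butter(spec$order, spec$cutoff / (fs / 2),
                       type = if (spec$kind == "lowpass") "low" else "high")
  npad <- min(n - 1L, max(3L * spec$order, ceiling(2 * fs / spec$cutoff)))
  # odd reflection about the end points, preserving series continuity
  pre <- 2 * x[1L] - x[(npad + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - npad)]
  xp <- c(pre, x, post)
  # steady-state initial history (DC-consistent), so a constant input
  # produces its steady response immediately instead of a step transient
  dc <- sum(bt$b) / sum(bt$a)
  run <- function(v) {
    as.numeric(signal::filter(bt$b, bt$a, v,
                              init.x = rep(v[1L], length(bt$b) - 1L),
                              init.y = rep(v[1L] * dc, length(bt$a) - 1L)))
  }
  y <- run(xp)
  if (spec$zero_phase) y <- rev(run(rev(y)))
  y[(npad + 1L):(npad + n)]
}

#' Numerical differentiation at a uniform rate
#'
#' Central differences at interior samples, first-order one-sided differences
#' at the two ends. Matrices are differentiated column-wise.
#'
#' @param x Numeric vector or matrix.
#' @param fs Sampling rate in Hz.
#'
#' @return Series of the same shape holding `dx/dt`.
#' @export
differentiate <- function(x, fs) {
  if (is.matrix(x)) {
    out <- x
    for (j in seq_len(ncol(x))) out[, j] <- differentiate(x[, j], fs)
    return(out)
  }
  n <- length(x)
  if (n < 3L) stop("need at least 3 samples to differentiate", call. = FALSE)
  d <- numeric(n)
  d[1L] <- (x[2L] - x[1L]) * fs
  d[n] <- (x[n] - x[n - 1L]) * fs
  d[2L:(n - 1L)] <- (x[3L:n] - x[1L:(n - 2L)]) * (fs / 2)
  d
}
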