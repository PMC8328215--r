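#' Design a Butterworth filter in second-order sections
#'
#' Builds the digital Butterworth filter of the requested order by bilinear
#' transform of the analytic analog prototype, returned as cascaded biquads.
#' The SOS form keeps high orders at low normalized cutoffs (e.g. 10th order
#' at 4 Hz on 100-Hz data) numerically stable where the expanded
#' transfer-function polynomial is fragile.
#'
#' @param order filter order (single-pass); must be >= 1
#' @param cutoff cutoff frequency in Hz (-3 dB point of the single pass)
#' @param rate sampling rate in Hz
#' @param kind `"lowpass"` or `"highpass"`
#' @return object of class `butter_sos`: list with `sos` (n_sections x 6
#'   matrix, columns b0 b1 b2 a0 a1 a2), `order`, `cutoff`, `rate`, `kind`
#' @export
butter_design <- function(order, cutoff, rate, kind = c("lowpass", "highpass")) {
  kind <- match.arg(kind)
  stopifnot(order >= 1, rate > 0)
  if (!(cutoff > 0 && cutoff < rate / 2)) {
    stop("cutoff must lie strictly between 0 and the Nyquist frequency (",
         rate / 2, " Hz)")
  }
  n <- as.integer(order)
  # analog prototype poles on the unit circle, left half plane
  k <- seq_len(n)
  theta <- pi * (2 * k - 1) / (2 * n) + pi / 2
  p <- complex(modulus = 1, argument = theta)
  wc <- tan(pi * cutoff / rate)            # bilinear prewarp, T = 2
  if (kind == "lowpass") s_poles <- wc * p else s_poles <- wc / p
  z_poles <- (1 + s_poles) / (1 - s_poles)

  # pair complex-conjugate poles into biquads (poles come in conjugate pairs
  # ordered symmetrically; take those with positive imaginary part plus the
  # real pole for odd orders)
  imag_pos <- z_poles[Im(z_poles) > 1e-12]
  real_p <- Re(z_poles[abs(Im(z_poles)) <= 1e-12])
  n_sec <- ceiling(n / 2)
  sos <- matrix(0, n_sec, 6)
  colnames(sos) <- c("b0", "b1", "b2", "a0", "a1", "a2")
  zsign <- if (kind == "lowpass") 1 else -1
  i <- 0L
  for (zp in imag_pos) {
    i <- i + 1L
    a <- c(1, -2 * Re(zp), Mod(zp)^2)
    b <- c(1, 2 * zsign, 1)
    g <- .biquad_gain(b, a, kind)
    sos[i, ] <- c(b / g, a)
  }
  for (rp in real_p) {
    i <- i + 1L
    a <- c(1, -rp, 0)
    b <- c(1, zsign, 0)
    g <- .biquad_gain(b, a, kind)
    sos[i, ] <- c(b / g, a)
  }
  structure(list(sos = sos, order = n, cutoff = cutoff, rate = rate,
                 kind = kind),
            class = "butter_sos")
}

# gain of a biquad at the reference point (DC for lowpass, Nyquist for highpass)
.biquad_gain <- function(b, a, kind) {
  z <- if (kind == "lowpass") 1 else -1
  zz <- c(1, z, z^2)
  abs(sum(b * zz) / sum(a * zz))
}

#' @export
print.butter_sos <- function(x, ...) {
  cat(sprintf("Butterworth %s filter: order %d, cutoff %g Hz at %g Hz (%d biquads)\n",
              x$kind, x$order, x$cutoff, x$rate, nrow(x$sos)))
  invisible(x)
}

.sos_filter <- function(x, sos) {
  .sos_filter_cpp(x, sos)
}

#' Zero-phase (forward-backward) filtering of a signal matrix
#'
#' Applies the filter along columns, forward then backward, so the net phase
#' response is zero and the amplitude response is the single-pass response
#' squared. Edges are handled by odd-reflection padding scaled to the
#' filter's impulse-response length (roughly `3 * rate / cutoff` samples,
#' capped at the signal length).
#'
#' @param x numeric vector or samples x channels matrix
#' @param design `butter_sos` object from [butter_design()]
#' @return filtered data, same shape as `x`
#' @export
sos_filtfilt <- function(x, design) {
  stopifnot(inherits(design, "butter_sos"))
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  if (anyNA(x)) stop("input contains NA")
  n <- nrow(x)
  if (n <= 3 * design$order) {
    stop("signal too short for order-", design$order, " filtering (", n,
         " samples)")
  }
  npad <- min(n - 1, max(3 * (2 * nrow(design$sos) + 1),
                         ceiling(3 * design$rate / design$cutoff)))
  # remove the column mean before filtering: with zero initial conditions a
  # DC offset excites a long start-up transient; a lowpass passes the mean
  # unchanged (added back), a highpass removes it anyway
  mu <- colMeans(x)
  x <- sweep(x, 2, mu)
  pre <- 2 * x[rep(1, npad), , drop = FALSE] - x[(npad + 1):2, , drop = FALSE]
  post <- 2 * x[rep(n, npad), , drop = FALSE] -
    x[(n - 1):(n - npad), , drop = FALSE]
  xp <- rbind(pre, x, post)
  y <- .sos_filter(xp, design$sos)
  y <- y[nrow(y):1, , drop = FALSE]
  y <- .sos_filter(y, design$sos)
  y <- y[nrow(y):1, , drop = FALSE]
  out <- y[(npad + 1):(npad + n), , drop = FALSE]
  if (design$kind == "lowpass") out <- sweep(out, 2, mu, "+")
  if (!all(is.finite(out))) stop("filter produced non-finite output; the ",
                                 "design is unstable for this cutoff/rate")
  if (vec) out[, 1] else out
}

#' Zero-phase Butterworth filtering of recordings or epochs
#'
#' Two-pass (forward-backward) application of an order-`order` Butterworth
#' filter, the standard way to low-pass EEG ahead of phase estimation
#' (e.g. a 4-Hz two-pass 10th-order lowpass before the Hilbert transform)
#' or to high-pass it ahead of ERP analysis (1-Hz two-pass 6th-order).
#'
#' @param data [continuous_recording()], [eeg_epochs()] object, numeric
#'   vector, or samples x channels matrix
#' @param cutoff cutoff frequency, Hz
#' @param order single-pass filter order
#' @param kind `"lowpass"` or `"highpass"`
#' @param rate sampling rate in Hz; taken from `data` when it carries one
#' @return object of the same type, filtered
#' @export
butterworth_zero_phase <- function(data, cutoff, order,
                                   kind = c("lowpass", "highpass"),
                                   rate = NULL) {
  kind <- match.arg(kind)
  UseMethod("butterworth_zero_phase")
}

#' @export
butterworth_zero_phase.default <- function(data, cutoff, order,
                                           kind = c("lowpass", "highpass"),
                                           rate = NULL) {
  kind <- match.arg(kind)
  if (is.null(rate)) stop("rate must be given for bare numeric data")
  des <- butter_design(order, cutoff, rate, kind)
  sos_filtfilt(data, des)
}

#' @export
butterworth_zero_phase.continuous_recording <- function(data, cutoff, order,
                                                        kind = c("lowpass", "highpass"),
                                                        rate = NULL) {
  kind <- match.arg(kind)
  des <- butter_design(order, cutoff, data$rate, kind)
  data$data <- t(sos_filtfilt(t(data$data), des))
  data
}

#' @export
butterworth_zero_phase.eeg_epochs <- function(data, cutoff, order,
                                              kind = c("lowpass", "highpass"),
                                              rate = NULL) {
  kind <- match.arg(kind)
  des <- butter_design(order, cutoff, data$rate, kind)
  d <- data$data
  dm <- dim(d)
  # samples on dim 3; flatten trials x channels into columns
  flat <- t(matrix(d, dm[1] * dm[2], dm[3]))
  flat <- sos_filtfilt(flat, des)
  data$data <- array(t(flat), dm)
  data
}

#' Resample a signal to a lower rate
#'
#' Applies a zero-phase anti-alias lowpass at 0.4 x the target rate, then
#' decimates exactly for integer rate ratios and interpolates with a cubic
#' spline otherwise (documented behavior for non-integer ratios, e.g.
#' 250 to 100 Hz). Event latencies stored in seconds are unaffected.
#'
#' @param data [continuous_recording()], [eeg_epochs()], vector, or
#'   samples x channels matrix
#' @param target_rate new sampling rate in Hz (must not exceed current rate)
#' @param rate current rate for bare numeric data
#' @return resampled data of the same type
#' @export
resample_to <- function(data, target_rate, rate = NULL) {
  UseMethod("resample_to")
}

.resample_matrix <- function(x, rate, target_rate) {
  if (target_rate == rate) return(x)
  if (target_rate > rate) stop("target_rate exceeds the current rate")
  des <- butter_design(8, 0.4 * target_rate, rate, "lowpass")
  y <- sos_filtfilt(x, des)
  n <- nrow(y)
  ratio <- rate / target_rate
  if (abs(ratio - round(ratio)) < 1e-9) {
    idx <- seq(1, n, by = round(ratio))
    return(y[idx, , drop = FALSE])
  }
  t_old <- (seq_len(n) - 1) / rate
  t_new <- seq(0, t_old[n], by = 1 / target_rate)
  out <- matrix(0, length(t_new), ncol(y))
  for (j in seq_len(ncol(y))) {
    out[, j] <- stats::spline(t_old, y[, j], xout = t_new)$y
  }
  out
}

#' @export
resample_to.default <- function(data, target_rate, rate = NULL) {
  if (is.null(rate)) stop("rate must be given for bare numeric data")
  vec <- is.null(dim(data))
  if (vec) data <- matrix(data, ncol = 1)
  out <- .resample_matrix(data, rate, target_rate)
  if (vec) out[, 1] else out
}

#' @export
resample_to.continuous_recording <- function(data, target_rate, rate = NULL) {
  data$data <- t(.resample_matrix(t(data$data), data$rate, target_rate))
  data$rate <- target_rate
  data
}

#' Analytic signal via the frequency domain
#'
#' Returns the analytic signal x + i H\[x\] computed by zeroing negative
#' frequencies of the FFT (doubling positive ones), columnwise.
#'
#' @param x numeric vector or samples x signals matrix
#' @return complex data of the same shape
#' @export
analytic_signal <- function(x) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  if (anyNA(x)) stop("input contains NA")
  n <- nrow(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  X <- stats::mvfft(x) * h
  out <- stats::mvfft(X, inverse = TRUE) / n
  if (vec) out[, 1] else out
}

#' Extend a signal by autoregressive extrapolation
#'
#' Fits an AR(`order`) model (Burg) and extrapolates `npad` samples beyond
#' both ends. Used to suppress the spectral leakage a finite epoch imposes
#' on the FFT analytic signal: an AR model continues a slow oscillation
#' coherently (an AR(2) continues a pure sinusoid exactly), so the
#' implicit periodic boundary falls on extrapolated samples instead of a
#' discontinuity inside the data.
#'
#' @param x numeric vector
#' @param npad samples to add on each side
#' @param order AR model order (capped at `length(x) - 2`); 3 by default: two
#'   poles continue the dominant oscillation, one absorbs residual offset
#' @return numeric vector of length `length(x) + 2 * npad`
#' @export
ar_extend <- function(x, npad, order = 3) {
  n <- length(x)
  order <- min(order, n - 2)
  if (order < 1 || stats::sd(x) == 0) {
    return(c(rep(x[1], npad), x, rep(x[n], npad)))
  }
  m <- mean(x)
  xc <- x - m
  lim <- 5 * max(abs(xc))
  extend_with <- function(coefs) {
    p <- length(coefs)
    fwd <- .ar_predict_cpp(xc[(n - p + 1):n], coefs, npad)
    bwd <- .ar_predict_cpp(rev(xc)[(n - p + 1):n], coefs, npad)
    list(fwd = fwd, bwd = bwd,
         ok = all(is.finite(fwd)) && all(is.finite(bwd)) &&
           max(abs(fwd)) <= lim && max(abs(bwd)) <= lim)
  }
  # surplus poles of a high-order fit can sit marginally outside the unit
  # circle and blow up over a long extrapolation; fall back to lower orders
  # (an AR(2) already continues a single oscillation exactly), then to
  # damped poles (phase-coherent, decaying amplitude), then to constants
  ext <- NULL
  for (p in unique(pmax(2, c(order, order %/% 2, 2)))) {
    ext <- extend_with(.ar_burg_cpp(xc, p))
    if (ext$ok) break
  }
  if (!ext$ok) {
    a2 <- .ar_burg_cpp(xc, 2)
    for (rho in c(0.999, 0.99, 0.95)) {
      ext <- extend_with(a2 * rho^seq_along(a2))
      if (ext$ok) break
    }
  }
  if (!ext$ok) {
    return(c(rep(x[1], npad), x, rep(x[n], npad)))
  }
  c(rev(ext$bwd) + m, x, ext$fwd + m)
}

#' Instantaneous phase of epoched data
#'
#' Computes the analytic (Hilbert) phase per trial and channel, wrapped to
#' (-pi, pi] under the cosine convention: a pure cosine has phase 0 at its
#' peaks and phase increases with time. Each trace is AR-extended
#' ([ar_extend()]) by one epoch length before the transform and cropped
#' back afterwards, which keeps the phase of slow oscillations accurate
#' even when the epoch covers a non-integer number of cycles. Input is
#' expected to be low-passed within the delta band already.
#'
#' @param epochs [eeg_epochs()] object
#' @param ar_order AR order of the boundary extension (0 disables it)
#' @return object of class `phase_map`: same shape array of phase angles,
#'   with `times`, `rate`, `channels`, `trials` copied from the input
#' @export
hilbert_phase <- function(epochs, ar_order = 3) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- epochs$data
  dm <- dim(d)
  flat <- t(matrix(d, dm[1] * dm[2], dm[3]))     # samples x (trial, channel)
  ns <- dm[3]
  if (ar_order > 0 && ns >= 16) {
    npad <- ns
    ext <- apply(flat, 2, ar_extend, npad = npad, order = ar_order)
    ph <- Arg(analytic_signal(ext))[(npad + 1):(npad + ns), , drop = FALSE]
  } else {
    ph <- Arg(analytic_signal(flat))
  }
  # Arg returns (-pi, pi]; map -pi (possible from rounding) to pi
  ph[ph <= -pi] <- pi
  structure(list(phase = array(t(ph), dm), times = epochs$times,
                 rate = epochs$rate, channels = epochs$channels,
                 trials = epochs$trials),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  dm <- dim(x$phase)
  cat(sprintf("phase_map: %d trials x %d channels x %d samples @ %g Hz, t = [%.3f, %.3f] s\n",
              dm[1], dm[2], dm[3], x$rate, x$times[1], x$times[length(x$times)]))
  invisible(x)
}
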