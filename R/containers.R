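#' Continuous multi-channel recording
#'
#' The container continuous EEG arrives in: a channels x samples voltage
#' matrix with a sampling rate, channel names, and an event table giving
#' within-recording latencies (in seconds; converted to samples only at
#' use, rounding to the nearest sample).
#'
#' @param data channels x samples numeric matrix (microvolts)
#' @param rate sampling rate, Hz
#' @param channels character vector of channel names, one per row
#' @param events tibble/data.frame with at least `label` (character) and
#'   `time` (seconds from recording start); extra columns (trial ids,
#'   condition labels) are carried into epochs
#' @return object of class `continuous_recording`
#' @export
continuous_recording <- function(data, rate, channels, events) {
  stopifnot(is.matrix(data), nrow(data) == length(channels), rate > 0)
  if (anyNA(data)) stop("recording contains NaN/NA")
  events <- tibble::as_tibble(events)
  stopifnot(all(c("label", "time") %in% names(events)))
  dur <- ncol(data) / rate
  if (nrow(events) && any(events$time < 0 | events$time > dur)) {
    stop("event latencies outside the recording duration")
  }
  structure(list(data = data, rate = rate, channels = channels,
                 events = events),
            class = "continuous_recording")
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("continuous_recording: %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate,
              nrow(x$events)))
  invisible(x)
}

#' Epoched EEG data
#'
#' Trials x channels x samples voltage array with a shared time axis
#' relative to the locking event. The universal container passed between
#' pipeline stages.
#'
#' @param data trials x channels x samples numeric array (microvolts)
#' @param rate sampling rate, Hz
#' @param times numeric time axis (seconds, relative to the locking event),
#'   strictly increasing with uniform step `1/rate`
#' @param channels channel names
#' @param trials tibble of per-trial labels (participant, trial, RATE,
#'   BOUNDARY, ...); one row per trial
#' @param locked_to name of the locking event
#' @return object of class `eeg_epochs`
#' @export
eeg_epochs <- function(data, rate, times, channels, trials,
                       locked_to = "event") {
  stopifnot(length(dim(data)) == 3, dim(data)[2] == length(channels),
            dim(data)[3] == length(times))
  trials <- tibble::as_tibble(trials)
  stopifnot(nrow(trials) == dim(data)[1])
  if (length(times) > 1) {
    step <- diff(times)
    if (any(step <= 0) || max(abs(step - 1 / rate)) > 1e-6 / rate) {
      stop("time axis must be strictly increasing with uniform step 1/rate")
    }
  }
  structure(list(data = data, rate = rate, times = times,
                 channels = channels, trials = trials,
                 locked_to = locked_to),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  dm <- dim(x$data)
  cat(sprintf("eeg_epochs: %d trials x %d channels x %d samples @ %g Hz, locked to '%s', t = [%.3f, %.3f] s\n",
              dm[1], dm[2], dm[3], x$rate, x$locked_to,
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Cut epochs around events of a continuous recording
#'
#' One trial per matching event. Windows follow the half-open convention
#' `[tmin, tmax)` at sample resolution: sample indices run from
#' `round(t_event * rate) + round(tmin * rate)` for
#' `round((tmax - tmin) * rate)` samples, so a -0.5..1.5 s epoch at 250 Hz
#' has exactly 500 samples and sample 0 of the time axis sits at `tmin`.
#'
#' @param recording [continuous_recording()]
#' @param event_label label of the locking event
#' @param tmin,tmax epoch window in seconds relative to the event
#' @return [eeg_epochs()]; zero-trial epochs (with intact metadata) when no
#'   event matches
#' @export
epoch_data <- function(recording, event_label, tmin, tmax) {
  stopifnot(inherits(recording, "continuous_recording"), tmax > tmin)
  ev <- recording$events[recording$events$label == event_label, ]
  rate <- recording$rate
  n_samp <- round((tmax - tmin) * rate)
  rel <- round(tmin * rate)
  times <- (rel + seq_len(n_samp) - 1) / rate
  nch <- nrow(recording$data)
  if (nrow(ev) == 0) {
    return(eeg_epochs(array(0, c(0, nch, n_samp)), rate, times,
                      recording$channels,
                      ev[, setdiff(names(ev), c("label", "time"))],
                      locked_to = event_label))
  }
  i0 <- round(ev$time * rate) + 1L + rel
  i1 <- i0 + n_samp - 1L
  bad <- i0 < 1 | i1 > ncol(recording$data)
  if (any(bad)) {
    stop("epoch window [", tmin, ", ", tmax, ") exceeds the recording for ",
         sum(bad), " event(s) at t = ",
         paste(signif(ev$time[bad], 4), collapse = ", "))
  }
  out <- array(0, c(nrow(ev), nch, n_samp))
  for (i in seq_len(nrow(ev))) {
    out[i, , ] <- recording$data[, i0[i]:i1[i]]
  }
  eeg_epochs(out, rate, times, recording$channels,
             ev[, setdiff(names(ev), c("label", "time"))],
             locked_to = event_label)
}

#' Crop epochs to a time window
#'
#' Keeps samples with `tmin <= t < tmax` (same half-open convention as
#' [epoch_data()]).
#'
#' @param epochs [eeg_epochs()]
#' @param tmin,tmax window in seconds
#' @return cropped [eeg_epochs()]
#' @export
crop_epochs <- function(epochs, tmin, tmax) {
  keep <- which(epochs$times >= tmin - 1e-9 & epochs$times < tmax - 1e-9)
  if (!length(keep)) stop("crop window contains no samples")
  epochs$data <- epochs$data[, , keep, drop = FALSE]
  epochs$times <- epochs$times[keep]
  epochs
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the baseline window
#' `[t0, t1]` (inclusive at sample resolution). After correction the mean
#' over the window is zero to float tolerance.
#'
#' @param epochs [eeg_epochs()]
#' @param t0,t1 baseline window in seconds (`t1 > t0`), within the epoch
#' @return corrected [eeg_epochs()]
#' @export
baseline_correct <- function(epochs, t0, t1) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (t1 <= t0) stop("baseline window requires t1 > t0")
  if (t0 < epochs$times[1] - 0.5 / epochs$rate ||
      t1 > epochs$times[length(epochs$times)] + 0.5 / epochs$rate) {
    stop("baseline window [", t0, ", ", t1, "] lies outside the epoch")
  }
  # nearest-sample endpoints, inclusive
  idx <- which.min(abs(epochs$times - t0)):which.min(abs(epochs$times - t1))
  bl <- apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(bl)  # recycles over samples (dim 3)
  epochs
}

#' Re-reference to the common average
#'
#' Subtracts the across-channel mean at every sample, per trial. A linear
#' projection: idempotent, and it commutes with baseline correction.
#'
#' @param data [continuous_recording()] or [eeg_epochs()]
#' @return same type, average-referenced (channel mean 0 at every sample)
#' @export
rereference_average <- function(data) {
  UseMethod("rereference_average")
}

#' @export
rereference_average.continuous_recording <- function(data) {
  if (nrow(data$data) < 2) stop("average reference requires >= 2 channels")
  data$data <- sweep(data$data, 2, colMeans(data$data))
  data
}

#' @export
rereference_average.eeg_epochs <- function(data) {
  dm <- dim(data$data)
  if (dm[2] < 2) stop("average reference requires >= 2 channels")
  m <- apply(data$data, c(1, 3), mean)                # trials x samples
  data$data <- data$data - aperm(array(m, c(dm[1], dm[3], dm[2])), c(1, 3, 2))
  data
}
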