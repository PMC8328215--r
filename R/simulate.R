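#' Configuration for the synthetic phase-coupled EEG generator
#'
#' Bundles and validates every knob of the simulation: design sizes, the
#' ongoing delta oscillation, the phase-coupled downstream positivity, the
#' uncoupled later negativity, noise, per-condition event timing, and the
#' prosodic-envelope proxy. Defaults emulate the study conditions the
#' pipeline is built for: a slow (SLOW) speech rate whose segmentation point
#' falls at 2.7 s — one cycle of a 0.37-Hz delta oscillation — versus a
#' time-compressed (FAST) rate (compression factor 0.66) whose
#' disambiguating verb arrives before 2.7 s; a centro-parietal positivity
#' 0.456 s after verb onset whose single-trial amplitude is cosine-coupled
#' to delta phase at the segmentation point; and a later broad negativity
#' with no coupling.
#'
#' @param n_participants number of simulated participants
#' @param n_trials_per_condition trials per cell of the RATE x BOUNDARY design
#' @param n_channels sensors in the layout (see [make_layout()])
#' @param sampling_rate Hz; must comfortably oversample the delta frequency
#'   (`>= 40 * delta_freq`)
#' @param delta_freq delta oscillation frequency, Hz (< 4; default 0.37,
#'   i.e. one cycle of about 2.7 s)
#' @param delta_amplitude delta oscillation amplitude at the map center, uV
#' @param coupling_strength kappa: cosine phase-to-amplitude coupling, uV
#' @param preferred_phase phi0: delta phase (radians, cosine convention)
#'   at which the evoked positivity is largest
#' @param rate_effect FAST-minus-SLOW evoked amplitude difference, uV
#' @param baseline_amplitude beta0: evoked amplitude common to all trials, uV
#' @param p600_latency,p600_width positivity bump center (s after verb
#'   onset) and full width (s) of its Hanning window
#' @param neg_latency,neg_width,neg_amplitude later negativity bump center
#'   (s after verb onset), full width (s), and amplitude (uV, negative)
#' @param event_times named list `FAST`/`SLOW`, each with `sentence_onset`,
#'   `segmentation_point`, `verb_onset`, `sentence_end` (s from trial-local 0);
#'   must be ordered onset < segmentation point < verb
#' @param noise_exponent alpha of the 1/f^alpha background (>= 0)
#' @param noise_sd standard deviation of the 1/f background per channel, uV
#' @param sensor_noise_sd white sensor noise SD, uV
#' @param amp_noise_sd trial-to-trial evoked-amplitude noise SD, uV
#' @param boundary_pause_s named vector `FAST`/`SLOW`: envelope pause length
#'   (s) at the segmentation point for BOUNDARY = PRESENT trials
#' @param phase_reset `"none"` (per-trial uniform random delta phase, the
#'   default, which makes the surrogate null exactly exchangeable) or
#'   `"onset"` (phase re-set to `phi0` at sentence onset, for realism
#'   experiments)
#' @param map_centers,map_widths named lists (`delta`, `p600`, `neg`) of 2-D
#'   Gaussian weight-map centers (x/y on the unit disc) and widths
#' @param snap_maps snap each map center to the nearest sensor of the
#'   layout (default `TRUE`), so every component peaks exactly at an
#'   electrode, the way scalp ERP peaks are reported
#' @param syllable_rate,envelope_floor envelope proxy: syllable modulation
#'   rate of the SLOW speech (Hz of the uncompressed profile) and the small
#'   positive level outside the sentence
#' @param seed integer master seed
#' @return validated list of class `simulation_config`
#' @export
simulation_config <- function(n_participants = 8,
                              n_trials_per_condition = 40,
                              n_channels = 16,
                              sampling_rate = 250,
                              delta_freq = 0.37,
                              delta_amplitude = 12,
                              coupling_strength = 4,
                              preferred_phase = pi / 4,
                              rate_effect = 4,
                              baseline_amplitude = 6,
                              p600_latency = 0.456,
                              p600_width = 0.15,
                              neg_latency = 0.856,
                              neg_width = 0.26,
                              neg_amplitude = -5,
                              event_times = list(
                                SLOW = list(sentence_onset = 0,
                                            segmentation_point = 2.7,
                                            verb_onset = 3.5,
                                            sentence_end = 4.5),
                                FAST = list(sentence_onset = 0,
                                            segmentation_point = 1.782,
                                            verb_onset = 2.31,
                                            sentence_end = 2.97)),
                              noise_exponent = 1,
                              noise_sd = 6,
                              sensor_noise_sd = 2,
                              amp_noise_sd = 1.5,
                              boundary_pause_s = c(FAST = 0.214, SLOW = 0.342),
                              phase_reset = c("none", "onset"),
                              map_centers = list(delta = c(0, -0.3),
                                                 p600 = c(0, -0.3),
                                                 neg = c(0, -0.55)),
                              map_widths = list(delta = 0.5, p600 = 0.5,
                                                neg = 0.6),
                              snap_maps = TRUE,
                              syllable_rate = 4,
                              envelope_floor = 0.05,
                              seed = 1) {
  phase_reset <- match.arg(phase_reset)
  cfg <- as.list(environment())
  stopifnot(n_participants >= 1, n_trials_per_condition >= 1, n_channels >= 2)
  if (delta_freq >= 4) stop("delta_freq must stay below the 4-Hz analysis lowpass")
  if (sampling_rate < 4 * delta_freq * 10) {
    stop("sampling_rate must be >= 40 x delta_freq for comfortable oversampling")
  }
  if (noise_exponent < 0) stop("noise_exponent must be >= 0")
  for (rt in c("FAST", "SLOW")) {
    ev <- event_times[[rt]]
    if (is.null(ev)) stop("event_times must name FAST and SLOW conditions")
    with(ev, {
      if (!(sentence_onset < segmentation_point &&
            segmentation_point < verb_onset && verb_onset < sentence_end)) {
        stop("event_times for ", rt, " must satisfy onset < segmentation ",
             "point < verb onset < sentence end")
      }
    })
    if (boundary_pause_s[[rt]] < 0 ||
        boundary_pause_s[[rt]] > ev$verb_onset - ev$segmentation_point) {
      stop("boundary pause for ", rt,
           " exceeds the segmentation-point-to-verb gap")
    }
  }
  stopifnot(p600_width > 0, neg_width > 0, p600_latency > 0, neg_latency > 0)
  # trial-local signal span: wide enough for -3..3 s epochs around the
  # segmentation point and -0.5..1.5 s around the verb, plus filter padding
  pad <- 0.5
  t0 <- min(vapply(event_times, function(e)
    min(e$sentence_onset, e$segmentation_point - 3), 0)) - pad
  t1 <- max(vapply(event_times, function(e)
    max(e$verb_onset + 1.5, e$segmentation_point + 3, e$sentence_end), 0)) + pad
  cfg$span <- c(round(t0 * sampling_rate) / sampling_rate,
                round(t1 * sampling_rate) / sampling_rate)
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0(
    "simulation_config: %d participants x %d trials/condition, %d channels @ %g Hz\n",
    "  delta %g Hz x %g uV; coupling kappa = %g uV at phi0 = %.3f rad; ",
    "rate effect %g uV\n"),
    x$n_participants, x$n_trials_per_condition, x$n_channels,
    x$sampling_rate, x$delta_freq, x$delta_amplitude, x$coupling_strength,
    x$preferred_phase, x$rate_effect))
  invisible(x)
}

#' Gaussian spatial weight map on a layout
#'
#' @param layout [make_layout()] result
#' @param center length-2 numeric (x, y)
#' @param width Gaussian SD in layout units
#' @return numeric weights in (0, 1], one per channel (max at the channel
#'   nearest the center is < 1 unless a sensor sits exactly on it)
#' @export
gaussian_weight_map <- function(layout, center, width) {
  d2 <- (layout$pos[, 1] - center[1])^2 + (layout$pos[, 2] - center[2])^2
  w <- exp(-d2 / (2 * width^2))
  names(w) <- layout$channels
  w
}

#' 1/f^alpha (pink-like) background noise
#'
#' Spectrally shaped Gaussian noise: the FFT of white noise is scaled by
#' `f^(-alpha/2)` (DC removed) and inverted, then standardized to zero mean
#' and unit SD. `exponent = 0` reduces to white noise.
#'
#' @param n_samples signal length (>= 2)
#' @param exponent spectral exponent alpha (>= 0)
#' @param rate sampling rate, Hz (sets the frequency axis only)
#' @param seed optional integer seed
#' @return numeric vector, zero mean, unit SD
#' @export
make_pink_noise <- function(n_samples, exponent, rate, seed = NULL) {
  if (n_samples < 2) stop("n_samples must be >= 2")
  if (exponent < 0) stop("exponent must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  .pink_matrix(n_samples, 1L, exponent, rate)[, 1]
}

# matrix of independent 1/f^alpha columns (n x k), standardized per column
.pink_matrix <- function(n, k, exponent, rate) {
  w <- matrix(stats::rnorm(n * k), n, k)
  if (exponent == 0) {
    w <- sweep(w, 2, colMeans(w))
    return(sweep(w, 2, apply(w, 2, stats::sd), "/"))
  }
  j <- seq_len(n) - 1
  f <- pmin(j, n - j) * rate / n   # symmetric frequency axis keeps FFT Hermitian
  s <- c(0, f[-1]^(-exponent / 2))
  x <- Re(stats::mvfft(stats::mvfft(w) * s, inverse = TRUE)) / n
  x <- sweep(x, 2, colMeans(x))
  sweep(x, 2, apply(x, 2, stats::sd), "/")
}

#' Per-trial prosodic envelope proxy
#'
#' A nonnegative low-frequency signal standing in for the pitch/intensity
#' envelope of one spoken sentence: a strictly positive syllable-rate
#' modulation between sentence onset and end (time-compressed for FAST
#' speech relative to the reference SLOW duration), a small positive floor
#' outside the sentence, and — for BOUNDARY = PRESENT — a contiguous
#' zero-valued pause of `pause_s` starting at the segmentation point.
#'
#' @param event_times list with `sentence_onset`, `segmentation_point`,
#'   `verb_onset`, `sentence_end` (trial-local seconds)
#' @param pause_s pause duration in seconds (0 for BOUNDARY = ABSENT)
#' @param rate sampling rate, Hz
#' @param t_start,t_end trial-local span of the returned signal
#' @param ref_duration duration (s) of the uncompressed reference sentence;
#'   the profile is compressed by `duration / ref_duration`. `NULL` uses the
#'   sentence's own duration (no compression).
#' @param syllable_rate modulation rate of the reference profile, Hz
#' @param floor positive envelope level outside the sentence
#' @return numeric envelope vector sampled at `rate` over `[t_start, t_end)`
#' @export
make_envelope <- function(event_times, pause_s, rate, t_start, t_end,
                          ref_duration = NULL, syllable_rate = 4,
                          floor = 0.05) {
  ev <- event_times
  dur <- ev$sentence_end - ev$sentence_onset
  if (is.null(ref_duration)) ref_duration <- dur
  if (pause_s < 0 || pause_s > ev$verb_onset - ev$segmentation_point) {
    stop("pause longer than the segmentation-point-to-verb gap")
  }
  n <- round((t_end - t_start) * rate)
  t <- t_start + (seq_len(n) - 1) / rate
  env <- rep(floor, n)
  inside <- t >= ev$sentence_onset & t < ev$sentence_end
  u <- (t[inside] - ev$sentence_onset) * (ref_duration / dur)
  env[inside] <- 0.6 + 0.4 * sin(2 * pi * syllable_rate * u - pi / 2)
  if (pause_s > 0) {
    env[t >= ev$segmentation_point & t < ev$segmentation_point + pause_s] <- 0
  }
  env
}

#' Draw the trial-level ground truth for one participant
#'
#' Samples the per-trial delta phase at the segmentation point (uniform on
#' (-pi, pi] unless `phase_reset = "onset"`) and the resulting true evoked
#' amplitude `beta0 + beta_rate * 1[FAST] + kappa * cos(phase - phi0) +
#' noise`, reproducibly from the seed.
#'
#' @param config [simulation_config()]
#' @param participant participant id (integer)
#' @param seed integer seed for this participant's draw
#' @return tibble: `participant`, `trial`, `RATE`, `BOUNDARY`,
#'   `true_phase_at_segpoint`, `amp_noise`, `neg_amp`,
#'   `true_evoked_amplitude`, `kappa`, `phi0`
#' @export
draw_ground_truth <- function(config, participant = 1L, seed = config$seed) {
  set.seed(seed)
  n_pc <- config$n_trials_per_condition
  cond <- expand.grid(RATE = c("FAST", "SLOW"),
                      BOUNDARY = c("PRESENT", "ABSENT"),
                      rep = seq_len(n_pc), stringsAsFactors = FALSE)
  n <- nrow(cond)
  f <- config$delta_freq
  if (config$phase_reset == "none") {
    psi <- stats::runif(n, -pi, pi)
  } else {
    # phase re-set to phi0 at sentence onset; deterministic per condition
    onset <- vapply(cond$RATE, function(r)
      config$event_times[[r]]$sentence_onset, 0, USE.NAMES = FALSE)
    psi <- .wrap_phase(config$preferred_phase - 2 * pi * f * onset)
  }
  seg_t <- vapply(cond$RATE, function(r)
    config$event_times[[r]]$segmentation_point, 0, USE.NAMES = FALSE)
  phase_seg <- .wrap_phase(2 * pi * f * seg_t + psi)
  amp_noise <- stats::rnorm(n, 0, config$amp_noise_sd)
  neg_amp <- config$neg_amplitude + stats::rnorm(n, 0, config$amp_noise_sd)
  amp <- config$baseline_amplitude +
    config$rate_effect * (cond$RATE == "FAST") +
    config$coupling_strength * cos(phase_seg - config$preferred_phase) +
    amp_noise
  tibble::tibble(participant = as.integer(participant),
                 trial = seq_len(n),
                 RATE = cond$RATE, BOUNDARY = cond$BOUNDARY,
                 psi = psi,
                 true_phase_at_segpoint = phase_seg,
                 amp_noise = amp_noise,
                 neg_amp = neg_amp,
                 true_evoked_amplitude = amp,
                 kappa = config$coupling_strength,
                 phi0 = config$preferred_phase)
}

.wrap_phase <- function(x) {
  out <- (x + pi) %% (2 * pi) - pi
  out[out <= -pi] <- pi
  out
}

# Hanning bump of full width `width`, peak 1 at tau = 0
.hann_bump <- function(tau, width) {
  ifelse(abs(tau) <= width / 2, 0.5 * (1 + cos(2 * pi * tau / width)), 0)
}

#' Generate a multi-participant phase-coupled EEG dataset
#'
#' For each participant, builds a continuous recording of concatenated
#' trials containing (a) an ongoing delta oscillation with per-trial random
#' phase and a broad spatial weight map, (b) a downstream positivity bump
#' whose single-trial amplitude follows the ground truth of
#' [draw_ground_truth()] with a centro-parietal map, (c) an uncoupled later
#' negativity bump, and (d) 1/f background plus white sensor noise — along
#' with the per-trial prosodic envelope proxy and an event table
#' (sentence onset, segmentation point, verb onset per trial).
#'
#' @param config [simulation_config()]
#' @return object of class `segphase_dataset`: `participants` (list of
#'   `recording` ([continuous_recording()]) and `envelopes`
#'   (trials x samples matrix)), `ground_truth` tibble, `layout`, `maps`
#'   (delta/p600/neg weight vectors), `env_times` (trial-local time axis of
#'   the envelope rows), and the `config`
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  layout <- make_layout(config$n_channels)
  center_of <- function(cen) {
    if (!isTRUE(config$snap_maps)) return(cen)
    d2 <- (layout$pos[, 1] - cen[1])^2 + (layout$pos[, 2] - cen[2])^2
    layout$pos[which.min(d2), ]
  }
  maps <- list(
    delta = gaussian_weight_map(layout, center_of(config$map_centers$delta),
                                config$map_widths$delta),
    p600 = gaussian_weight_map(layout, center_of(config$map_centers$p600),
                               config$map_widths$p600),
    neg = gaussian_weight_map(layout, center_of(config$map_centers$neg),
                              config$map_widths$neg))
  set.seed(config$seed)
  part_seeds <- sample.int(.Machine$integer.max - 1, config$n_participants)
  participants <- vector("list", config$n_participants)
  gt_all <- vector("list", config$n_participants)
  for (p in seq_len(config$n_participants)) {
    sim <- .generate_participant(config, layout, maps, p, part_seeds[p])
    participants[[p]] <- sim[c("recording", "envelopes")]
    gt_all[[p]] <- sim$ground_truth
  }
  rate <- config$sampling_rate
  ns <- round((config$span[2] - config$span[1]) * rate)
  structure(list(participants = participants,
                 ground_truth = do.call(rbind, gt_all),
                 layout = layout, maps = maps,
                 env_times = config$span[1] + (seq_len(ns) - 1) / rate,
                 config = config),
            class = "segphase_dataset")
}

.generate_participant <- function(config, layout, maps, participant, seed) {
  gt <- draw_ground_truth(config, participant, seed)
  rate <- config$sampling_rate
  t0 <- config$span[1]
  ns <- round((config$span[2] - t0) * rate)
  t <- t0 + (seq_len(ns) - 1) / rate
  n_tr <- nrow(gt)
  nch <- config$n_channels
  f <- config$delta_freq

  # sources as trial-blocked vectors (length n_tr * ns, trial-major)
  delta_src <- cos(outer(2 * pi * f * t, gt$psi, "+"))  # ns x n_tr
  p600_src <- matrix(0, ns, n_tr); neg_src <- matrix(0, ns, n_tr)
  for (i in seq_len(n_tr)) {
    ev <- config$event_times[[gt$RATE[i]]]
    p600_src[, i] <- gt$true_evoked_amplitude[i] *
      .hann_bump(t - (ev$verb_onset + config$p600_latency), config$p600_width)
    neg_src[, i] <- gt$neg_amp[i] *
      .hann_bump(t - (ev$verb_onset + config$neg_latency), config$neg_width)
  }
  total <- ns * n_tr
  data <- (maps$delta * config$delta_amplitude) %o% as.vector(delta_src) +
    maps$p600 %o% as.vector(p600_src) +
    maps$neg %o% as.vector(neg_src)
  # independent 1/f background per channel over the whole recording
  if (config$noise_sd > 0) {
    data <- data + config$noise_sd *
      t(.pink_matrix(total, nch, config$noise_exponent, rate))
  }
  if (config$sensor_noise_sd > 0) {
    data <- data + matrix(stats::rnorm(nch * total, 0,
                                       config$sensor_noise_sd), nch, total)
  }

  trial_starts <- (seq_len(n_tr) - 1) * ns / rate
  ev_names <- c("sentence_onset", "segmentation_point", "verb_onset")
  ev_mat <- vapply(gt$RATE, function(r)
    unlist(config$event_times[[r]][ev_names]), numeric(3))  # 3 x n_tr
  events <- tibble::tibble(
    label = rep(ev_names, n_tr),
    time = as.vector(ev_mat) + rep(trial_starts, each = 3) - t0,
    participant = as.integer(participant),
    trial = rep(gt$trial, each = 3),
    RATE = rep(gt$RATE, each = 3),
    BOUNDARY = rep(gt$BOUNDARY, each = 3))
  rec <- continuous_recording(data, rate, layout$channels, events)

  env <- matrix(0, n_tr, ns)
  ref_dur <- with(config$event_times$SLOW, sentence_end - sentence_onset)
  for (i in seq_len(n_tr)) {
    pause <- if (gt$BOUNDARY[i] == "PRESENT")
      config$boundary_pause_s[[gt$RATE[i]]] else 0
    env[i, ] <- make_envelope(config$event_times[[gt$RATE[i]]], pause, rate,
                              t0, config$span[2], ref_duration = ref_dur,
                              syllable_rate = config$syllable_rate,
                              floor = config$envelope_floor)
  }
  list(recording = rec, envelopes = env, ground_truth = gt)
}

#' @export
print.segphase_dataset <- function(x, ...) {
  cat(sprintf("segphase_dataset: %d participants, %d trials each, %d channels @ %g Hz\n",
              length(x$participants), nrow(x$participants[[1]]$envelopes),
              length(x$layout$channels), x$config$sampling_rate))
  invisible(x)
}
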