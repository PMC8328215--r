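#' Full-run configuration
#'
#' Validates and assembles the settings of every pipeline stage. Unknown
#' keys in any stage list are rejected, and cross-stage preconditions
#' (windows inside epochs, positive permutation counts) are checked here,
#' before any computation.
#'
#' @param sim [simulation_config()]
#' @param prep list: `erp_highpass` (Hz), `erp_highpass_order`,
#'   `lowpass` (Hz), `lowpass_order`, `analysis_rate` (Hz), `erp_epoch`
#'   (c(tmin, tmax) s around verb onset), `phase_epoch` (s around the
#'   segmentation point), `baseline` (c(t0, t1) s),
#'   `baseline_single_trial` (logical: baseline-correct the single-trial
#'   amplitudes the same way as the ERPs)
#' @param erp list: `window` (s), `alpha`, `n_perm`, `min_channels`
#' @param phase list: `window` (s, relative to the segmentation point),
#'   `n_perm`, `q`, `half_width` (s, amplitude extraction), optional
#'   `forced_peak` (list `channel`, `time`) used when the ERP stage finds
#'   no significant positive cluster
#' @param coherence list: `fmax` (Hz), `half_span` (s; the segment is
#'   `center +/- half_span`, a full delta cycle by default)
#' @param seed master seed; stage seeds are derived from it
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(sim = simulation_config(),
                            prep = list(), erp = list(), phase = list(),
                            coherence = list(), seed = 1) {
  prep <- .merge_opts(prep, list(
    erp_highpass = 1, erp_highpass_order = 6,
    lowpass = 4, lowpass_order = 10,
    analysis_rate = 100,
    erp_epoch = c(-0.5, 1.5), phase_epoch = c(-3, 3),
    baseline = c(0, 0.15), baseline_single_trial = TRUE), "prep")
  erp <- .merge_opts(erp, list(window = c(0.15, 1), alpha = 0.05,
                               n_perm = 1000, min_channels = 3), "erp")
  phase <- .merge_opts(phase, list(window = c(-0.5, 0), n_perm = 1000,
                                   q = 0.05, half_width = 0,
                                   forced_peak = NULL), "phase")
  coherence <- .merge_opts(coherence, list(fmax = 4, half_span = 1.5),
                           "coherence")
  stopifnot(inherits(sim, "simulation_config"))
  if (erp$n_perm < 1 || phase$n_perm < 1) stop("n_perm must be >= 1")
  if (prep$analysis_rate > sim$sampling_rate) {
    stop("analysis_rate may not exceed the simulated sampling rate")
  }
  if (erp$window[1] < prep$erp_epoch[1] || erp$window[2] > prep$erp_epoch[2]) {
    stop("erp window must lie within the verb epoch")
  }
  if (phase$window[1] < prep$phase_epoch[1] ||
      phase$window[2] > prep$phase_epoch[2]) {
    stop("phase window must lie within the segmentation-point epoch")
  }
  structure(list(sim = sim, prep = prep, erp = erp, phase = phase,
                 coherence = coherence, seed = seed),
            class = "pipeline_config")
}

.merge_opts <- function(user, defaults, what) {
  extra <- setdiff(names(user), names(defaults))
  if (length(extra)) stop("unknown ", what, " option(s): ",
                          paste(extra, collapse = ", "))
  defaults[names(user)] <- user
  defaults
}

#' Signal conditioning for one participant
#'
#' Branches the (average-referenced) continuous recording into the two
#' analysis paths: the ERP branch is high-pass filtered (removing the
#' ongoing delta component from single-trial amplitudes), resampled,
#' epoched around verb onset and baseline-corrected; the phase branch is
#' resampled, low-pass filtered within the delta band, epoched widely
#' around the segmentation point (filtering always precedes cropping so
#' edge artifacts stay outside the analysis window), and Hilbert-phased.
#'
#' @param recording [continuous_recording()]
#' @param prep the `prep` list of a [pipeline_config()]
#' @return list: `erp_epochs` ([eeg_epochs()]), `delta_epochs` (low-passed
#'   real-valued epochs around the segmentation point), `phase`
#'   (`phase_map`)
#' @export
prep_participant <- function(recording, prep) {
  rec <- rereference_average(recording)
  hp <- butterworth_zero_phase(rec, prep$erp_highpass,
                               prep$erp_highpass_order, "highpass")
  hp <- resample_to(hp, prep$analysis_rate)
  erp_ep <- epoch_data(hp, "verb_onset", prep$erp_epoch[1], prep$erp_epoch[2])
  erp_ep <- baseline_correct(erp_ep, prep$baseline[1], prep$baseline[2])

  ph <- resample_to(rec, prep$analysis_rate)
  ph <- butterworth_zero_phase(ph, prep$lowpass, prep$lowpass_order, "lowpass")
  delta_ep <- epoch_data(ph, "segmentation_point", prep$phase_epoch[1],
                         prep$phase_epoch[2])
  list(erp_epochs = erp_ep, delta_epochs = delta_ep,
       phase = hilbert_phase(delta_ep))
}

#' Run the full inference chain on a (simulated) dataset
#'
#' simulate -> prep -> ERP cluster test (FAST vs SLOW) -> positive-cluster
#' peak -> single-trial amplitude at the peak -> delta-phase x amplitude
#' correlation with surrogate null and FDR -> envelope-EEG coherence
#' control at the correlation peak electrode. Deterministic given the
#' master seed. When `out_dir` is given, stage results are cached there
#' (with a config-hash manifest) and completed stages are reused on re-run.
#'
#' @param config [pipeline_config()]
#' @param out_dir optional run directory for results, manifest and caches
#' @param dataset optional pre-generated [generate_dataset()] output (must
#'   match `config$sim`); when `NULL` the dataset is generated
#' @param verbose print stage progress
#' @return list of class `pipeline_result`: `status` (`"ok"` or
#'   `"no-positive-cluster"`), `erp` ([cluster_permutation_test()] result),
#'   `peak`, `negative_peak`, `phase` ([group_phase_amplitude_test()]
#'   result or `NULL`), `coherence` (per-participant band means and the
#'   Wilcoxon comparison, or `NULL`), `ground_truth`, `config`
#' @export
run_pipeline <- function(config, out_dir = NULL, dataset = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(...)
  cache <- .make_cache(out_dir, config)

  dataset <- cache("dataset", {
    say("stage simulate")
    if (is.null(dataset)) generate_dataset(config$sim) else dataset
  })
  prepped <- cache("prep", {
    say("stage prep")
    lapply(dataset$participants, function(p)
      prep_participant(p$recording, config$prep))
  })

  erp_res <- cache("erp", {
    say("stage erp")
    erp_eps <- lapply(prepped, `[[`, "erp_epochs")
    cropped <- lapply(erp_eps, crop_epochs, tmin = config$erp$window[1],
                      tmax = config$erp$window[2])
    cm <- condition_means(cropped, "RATE", "FAST", "SLOW")
    adj <- build_adjacency(dataset$layout)
    cluster_permutation_test(cm$a, cm$b, cm$times, adj,
                             alpha = config$erp$alpha,
                             n_perm = config$erp$n_perm,
                             min_channels = config$erp$min_channels,
                             seed = config$seed)
  })
  peak <- extract_peak(erp_res, "positive")
  neg_peak <- extract_peak(erp_res, "negative")
  if (!peak$found && !is.null(config$phase$forced_peak)) {
    fp <- config$phase$forced_peak
    peak <- list(found = TRUE, channel = fp$channel,
                 channel_index = match(fp$channel, dataset$layout$channels),
                 time = fp$time, sample = NA_integer_, t = NA_real_,
                 forced = TRUE)
  }
  if (!peak$found) {
    res <- structure(list(status = "no-positive-cluster", erp = erp_res,
                          peak = peak, negative_peak = neg_peak,
                          phase = NULL, coherence = NULL,
                          ground_truth = dataset$ground_truth,
                          config = config),
                     class = "pipeline_result")
    .write_results(out_dir, res)
    return(res)
  }

  phase_res <- cache("phase", {
    say("stage phase")
    amps <- lapply(prepped, function(p)
      extract_single_trial_amplitude(p$erp_epochs, peak$channel, peak$time,
                                     config$phase$half_width))
    group_phase_amplitude_test(lapply(prepped, `[[`, "phase"), amps,
                               window = config$phase$window,
                               n_perm = config$phase$n_perm,
                               q = config$phase$q,
                               seed = config$seed + 1)
  })

  coh_res <- cache("coherence", {
    say("stage coherence")
    center <- if (phase_res$peak$found) phase_res$peak$time else
      mean(config$phase$window)
    coh_channel <- if (phase_res$peak$found) phase_res$peak$channel else
      peak$channel
    .coherence_stage(dataset, prepped, coh_channel, center,
                     config$coherence, config$prep)
  })

  res <- structure(list(status = "ok", erp = erp_res, peak = peak,
                        negative_peak = neg_peak, phase = phase_res,
                        coherence = coh_res,
                        ground_truth = dataset$ground_truth,
                        config = config),
                   class = "pipeline_result")
  .write_results(out_dir, res)
  res
}

# per-participant, per-RATE band-averaged envelope-EEG coherence at the
# peak electrode, on a segment center +/- half_span around the phase peak
.coherence_stage <- function(dataset, prepped, channel, center, copts, prep) {
  np <- length(prepped)
  rate <- prep$analysis_rate
  out <- vector("list", np)
  for (p in seq_len(np)) {
    dep <- prepped[[p]]$delta_epochs
    ci <- match(channel, dep$channels)
    sel <- which(dep$times >= center - copts$half_span - 1e-9 &
                   dep$times < center + copts$half_span - 1e-9)
    env <- dataset$participants[[p]]$envelopes
    env_rs <- .resample_matrix(t(env), dataset$config$sampling_rate, rate)
    env_t <- dataset$env_times[1] + (seq_len(nrow(env_rs)) - 1) / rate
    vals <- c(FAST = NA_real_, SLOW = NA_real_)
    for (cond in c("FAST", "SLOW")) {
      tr <- which(dep$trials$RATE == cond)
      seg <- dataset$config$event_times[[cond]]$segmentation_point
      esel <- which(env_t >= seg + center - copts$half_span - 1e-9 &
                      env_t < seg + center + copts$half_span - 1e-9)
      nkeep <- min(length(sel), length(esel))
      eeg <- matrix(dep$data[tr, ci, sel[seq_len(nkeep)]], length(tr), nkeep)
      envm <- t(env_rs[esel[seq_len(nkeep)], tr, drop = FALSE])
      spec <- mscoherence_across_trials(eeg, envm, rate, copts$fmax)
      vals[cond] <- band_average(spec, copts$fmax)
    }
    out[[p]] <- vals
  }
  bands <- do.call(rbind, out)
  test <- wilcoxon_signed_rank(bands[, "FAST"], bands[, "SLOW"])
  list(band_means = tibble::tibble(participant = seq_len(np),
                                   FAST = bands[, "FAST"],
                                   SLOW = bands[, "SLOW"]),
       wilcoxon = test, channel = channel, center = center)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result: status =", x$status, "\n")
  if (x$peak$found) {
    cat(sprintf("  ERP positive-cluster peak: %s at %.3f s\n",
                x$peak$channel, x$peak$time))
  }
  if (!is.null(x$phase)) print(x$phase)
  if (!is.null(x$coherence)) {
    cat(sprintf("  coherence control: Wilcoxon z = %.3f, p = %.3f\n",
                x$coherence$wilcoxon$z, x$coherence$wilcoxon$p))
  }
  invisible(x)
}

# stage cache: evaluates `expr` or reloads the stage RDS when the manifest
# hash matches; no-op closure when out_dir is NULL
.make_cache <- function(out_dir, config) {
  if (is.null(out_dir)) return(function(name, expr) force(expr))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- .config_hash(config)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path)
  } else list()
  if (!identical(manifest$config_hash, hash)) {
    manifest <- list(config_hash = hash, seed = config$seed,
                     package_version = as.character(
                       utils::packageVersion("segphase")),
                     stages = list())
  }
  function(name, expr) {
    path <- file.path(out_dir, paste0("stage_", name, ".rds"))
    if (!is.null(manifest$stages[[name]]) && file.exists(path)) {
      return(readRDS(path))
    }
    val <- force(expr)
    saveRDS(val, path)
    manifest$stages[[name]] <<- TRUE
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
    val
  }
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(.jsonable(unclass(config)), auto_unbox = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

.jsonable <- function(x) {
  if (is.list(x)) return(lapply(x, .jsonable))
  if (is.function(x)) return(NULL)
  x
}

# summary JSON + TSV outputs for a completed run
.write_results <- function(out_dir, res) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  erp_sum <- list(
    status = res$status,
    clusters = lapply(res$erp$clusters, function(cl)
      list(sign = cl$sign, mass = cl$mass, n_cells = nrow(cl$members),
           p = cl$p, significant = cl$significant)),
    peak = res$peak[c("found", "channel", "time")],
    negative_peak = res$negative_peak[c("found", "channel", "time")])
  jsonlite::write_json(erp_sum, file.path(out_dir, "erp_result.json"),
                       auto_unbox = TRUE, digits = NA)
  tmap <- res$erp$tmap$t
  utils::write.table(
    data.frame(channel = rep(res$erp$channels, ncol(tmap)),
               time = rep(res$erp$times, each = nrow(tmap)),
               t = as.vector(tmap)),
    file.path(out_dir, "erp_tmap.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  if (!is.null(res$phase)) {
    ph <- res$phase
    jsonlite::write_json(
      list(peak = ph$peak[c("found", "channel", "time")],
           mean_z_at_peak = ph$mean_z_at_peak,
           mean_z_over_mask = ph$mean_z_over_mask,
           preferred_phase = ph$preferred_phase,
           mask_size = sum(ph$mask), q = ph$q, n_perm = ph$n_perm),
      file.path(out_dir, "phase_result.json"), auto_unbox = TRUE,
      digits = NA)
    utils::write.table(
      data.frame(channel = rep(ph$channels, ncol(ph$mean_z)),
                 time = rep(ph$times, each = nrow(ph$mean_z)),
                 mean_z = as.vector(ph$mean_z), p = as.vector(ph$p),
                 significant = as.vector(ph$mask)),
      file.path(out_dir, "phase_cells.tsv"), sep = "\t", row.names = FALSE,
      quote = FALSE)
  }
  if (!is.null(res$coherence)) {
    utils::write.table(res$coherence$band_means,
                       file.path(out_dir, "coherence.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    jsonlite::write_json(res$coherence$wilcoxon,
                         file.path(out_dir, "coherence_test.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  utils::write.table(res$ground_truth,
                     file.path(out_dir, "ground_truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Write / read a generated dataset as a directory container
#'
#' One directory per dataset: JSON metadata, TSV layout / event /
#' ground-truth tables, and one serialized data blob per participant.
#'
#' @param dataset [generate_dataset()] output
#' @param path directory to create
#' @return `path`, invisibly (`read_dataset` returns the dataset)
#' @export
write_dataset <- function(dataset, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(n_participants = length(dataset$participants),
         channels = dataset$layout$channels,
         rate = dataset$config$sampling_rate,
         config = .jsonable(unclass(dataset$config))),
    file.path(path, "dataset.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(
    data.frame(channel = dataset$layout$channels, dataset$layout$pos),
    file.path(path, "layout.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  utils::write.table(dataset$ground_truth,
                     file.path(path, "ground_truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  ev <- do.call(rbind, lapply(dataset$participants, function(p)
    p$recording$events))
  utils::write.table(ev, file.path(path, "events.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  for (p in seq_along(dataset$participants)) {
    saveRDS(dataset$participants[[p]],
            file.path(path, sprintf("participant_%02d.rds", p)))
  }
  saveRDS(dataset[c("layout", "maps", "env_times", "config")],
          file.path(path, "meta.rds"))
  invisible(path)
}

#' @rdname write_dataset
#' @param path dataset directory written by [write_dataset()]
#' @export
read_dataset <- function(path) {
  meta <- readRDS(file.path(path, "meta.rds"))
  files <- sort(list.files(path, "^participant_\\d+\\.rds$",
                           full.names = TRUE))
  participants <- lapply(files, readRDS)
  gt <- tibble::as_tibble(utils::read.delim(
    file.path(path, "ground_truth.tsv")))
  structure(c(list(participants = participants, ground_truth = gt), meta),
            class = "segphase_dataset")
}
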