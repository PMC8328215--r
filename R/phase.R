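#' Circular-linear correlation
#'
#' Correlation between an angle `theta` and a linear variable `x`:
#' `r = sqrt((r_cx^2 + r_sx^2 - 2 r_cx r_sx r_cs) / (1 - r_cs^2))` with
#' `r_cx = cor(cos theta, x)`, `r_sx = cor(sin theta, x)`,
#' `r_cs = cor(sin theta, cos theta)`. Equivalently (the defining
#' variational property, exercised in the tests), the maximum over `phi` of
#' `|cor(x, cos(theta - phi))|`. Lies in \[0, 1\]; invariant to rotating all
#' angles by a constant and to affine transforms of `x`.
#'
#' @param theta angles in radians
#' @param x linear variable, same length (>= 4)
#' @return r in \[0, 1\]; `NA_real_` for degenerate input (constant `x` or
#'   all-equal angles)
#' @export
circ_lin_corr <- function(theta, x) {
  stopifnot(length(theta) == length(x))
  if (length(x) < 4) stop("need at least 4 observations")
  if (stats::sd(x) == 0) return(NA_real_)
  ct <- cos(theta); st <- sin(theta)
  if (stats::sd(ct) == 0 && stats::sd(st) == 0) return(NA_real_)
  .r_from_cors(.safe_cor(ct, x), .safe_cor(st, x), .safe_cor(st, ct))
}

.safe_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

.r_from_cors <- function(rcx, rsx, rcs) {
  denom <- 1 - rcs^2
  if (denom <= .Machine$double.eps) return(NA_real_)
  r2 <- (rcx^2 + rsx^2 - 2 * rcx * rsx * rcs) / denom
  sqrt(pmin(pmax(r2, 0), 1))
}

#' Fisher z-transformation
#'
#' `z = atanh(r)`, variance-stabilizing for averaging correlation
#' coefficients across participants.
#'
#' @param r correlation in \[0, 1)
#' @return z; `Inf` (with a warning) at r = 1
#' @export
fisher_z <- function(r) {
  if (any(r < 0 | r > 1, na.rm = TRUE)) stop("r must lie in [0, 1]")
  if (any(r == 1, na.rm = TRUE)) warning("r = 1 maps to infinite z")
  atanh(r)
}

#' Preferred phase of a cosine-fit phase-amplitude relation
#'
#' The angle `phi0` maximizing `cor(x, cos(theta - phi0))`, in closed form
#' from the regression of `x` on `(cos theta, sin theta)`:
#' `phi0 = atan2(b_sin, b_cos)`, wrapped to (-pi, pi].
#'
#' @inheritParams circ_lin_corr
#' @return phi0 in radians; `NA_real_` for degenerate input
#' @export
estimate_preferred_phase <- function(theta, x) {
  if (length(x) < 4 || stats::sd(x) == 0) return(NA_real_)
  ct <- cos(theta); st <- sin(theta)
  fit <- try(stats::lm.fit(cbind(1, ct, st), x), silent = TRUE)
  if (inherits(fit, "try-error")) return(NA_real_)
  b <- fit$coefficients
  if (anyNA(b[2:3])) return(NA_real_)
  unname(atan2(b[3], b[2]))
}

#' Trial-shuffled surrogate null for phase-amplitude correlation
#'
#' Re-pairs the amplitude vector with the phases by random permutation of
#' the trial assignment and recomputes the circular-linear correlation (as
#' Fisher z) for every (channel, sample) cell. One shuffle per permutation
#' is applied identically across all cells, preserving the spatial/temporal
#' dependence of the data in the null. Fully vectorized over cells and
#' permutations.
#'
#' @param phase trials x cells matrix of phase angles (radians); a cell is
#'   one (channel, sample) pair
#' @param amp amplitude vector, one value per trial (>= 4 trials)
#' @param n_perm number of permutations (>= 1)
#' @param seed integer seed for the shuffle sequence
#' @param include_identity prepend the identity permutation, so row 1 of
#'   the result equals the observed z (convention check; default `FALSE`)
#' @return n_perm x cells matrix of null Fisher z values (plus the identity
#'   row first when requested); attribute `"observed"` carries the observed
#'   z per cell
#' @export
surrogate_null <- function(phase, amp, n_perm, seed = 1,
                           include_identity = FALSE) {
  phase <- as.matrix(phase)
  n <- nrow(phase)
  if (length(amp) != n) stop("amp must have one value per trial")
  if (n < 4) stop("need at least 4 trials")
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (stats::sd(amp) == 0) {
    warning("constant amplitude vector: correlation undefined, null degenerate")
    out <- matrix(NA_real_, n_perm + include_identity, ncol(phase))
    attr(out, "observed") <- rep(NA_real_, ncol(phase))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  set.seed(seed)
  perms <- replicate(n_perm, sample.int(n))
  if (include_identity) perms <- cbind(seq_len(n), perms)
  X <- matrix(amp[perms], n, ncol(perms))
  z <- .z_matrix(phase, X)
  attr(z, "observed") <- .z_matrix(phase, matrix(amp, n, 1))[1, ]
  z
}

# Fisher z of the circular-linear correlation for every column of X
# against every cell (column) of the phase matrix; returns perms x cells
.z_matrix <- function(phase, X) {
  n <- nrow(phase)
  C <- cos(phase); S <- sin(phase)
  Cc <- sweep(C, 2, colMeans(C)); Sc <- sweep(S, 2, colMeans(S))
  nC <- sqrt(colSums(Cc^2)); nS <- sqrt(colSums(Sc^2))
  rcs <- colSums(Sc * Cc) / (nS * nC)
  rcs[!is.finite(rcs)] <- 0
  Xc <- sweep(X, 2, colMeans(X))
  nX <- sqrt(colSums(Xc^2))
  Rcx <- crossprod(Cc, Xc) / outer(nC, nX)      # cells x perms
  Rsx <- crossprod(Sc, Xc) / outer(nS, nX)
  Rcx[!is.finite(Rcx)] <- 0
  Rsx[!is.finite(Rsx)] <- 0
  denom <- pmax(1 - rcs^2, .Machine$double.eps)
  r2 <- (Rcx^2 + Rsx^2 - 2 * Rcx * Rsx * rcs) / denom
  r <- sqrt(pmin(pmax(r2, 0), 1))
  z <- atanh(pmin(r, 1 - 1e-15))
  t(z)
}

#' Benjamini-Hochberg FDR step-up
#'
#' Sorts the p values ascending, finds the largest k with
#' `p_(k) <= k q / m`, and rejects every p at or below that cutoff.
#'
#' @param pvals p values in \[0, 1\]
#' @param q FDR level
#' @return list with `mask` (logical rejections, input order) and `cutoff`
#'   (the critical p; `-Inf` when nothing is rejected)
#' @export
fdr_bh <- function(pvals, q) {
  m <- length(pvals)
  if (m == 0) return(list(mask = logical(0), cutoff = -Inf))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p values must be in [0, 1]")
  ps <- sort(pvals)
  ok <- which(ps <= seq_len(m) * q / m)
  cutoff <- if (length(ok)) ps[max(ok)] else -Inf
  list(mask = pvals <= cutoff, cutoff = cutoff)
}

#' Group-level phase-amplitude correlation test with surrogate null and FDR
#'
#' For each participant, correlates the delta phase at every (channel,
#' sample) cell of the analysis window with the downstream single-trial
#' amplitude; Fisher-z coefficients are averaged across participants. The
#' null averages, per permutation, one independent trial-shuffled surrogate
#' z per participant. Cell-level `p = (1 + #(null >= observed)) /
#' (1 + n_perm)` (one-sided: r is nonnegative by construction), then
#' Benjamini-Hochberg FDR at level `q` across all cells in the window.
#'
#' @param phase_list list of `phase_map` objects (one per participant, from
#'   [hilbert_phase()]), consistent layouts
#' @param amp_list list of per-trial amplitude vectors (from
#'   [extract_single_trial_amplitude()]), matched trial order
#' @param window length-2 window (s) on the phase time axis (half-open)
#' @param n_perm surrogate permutations
#' @param q FDR level
#' @param seed master seed; per-participant shuffle seeds are derived from
#'   it by one `sample.int` draw
#' @return object of class `phase_corr`: `mean_z` (channels x samples),
#'   `p` (same shape), `mask` (FDR rejections), `cutoff`, `times`,
#'   `channels`, `peak` (channel/sample/time of max |mean z| within the
#'   mask, or `found = FALSE`), `mean_z_at_peak`, `mean_z_over_mask`,
#'   `participant_z_at_peak`, `preferred_phase` (circular mean across
#'   participants of the per-participant estimate at the peak cell),
#'   `preferred_phase_at_event` (same estimate at the peak channel but at
#'   the sample nearest t = 0, i.e. referred to the locking event),
#'   `n_participants`, `n_perm`, `q`, `seed`
#' @export
group_phase_amplitude_test <- function(phase_list, amp_list, window = c(-0.5, 0),
                                       n_perm = 10000, q = 0.05, seed = 1) {
  stopifnot(length(phase_list) == length(amp_list))
  keep <- vapply(amp_list, function(a) length(a) >= 4, TRUE)
  if (any(!keep)) {
    warning(sum(!keep), " participant(s) with < 4 trials dropped")
    phase_list <- phase_list[keep]; amp_list <- amp_list[keep]
  }
  np <- length(phase_list)
  if (np == 0) stop("no participant with >= 4 trials")
  times <- phase_list[[1]]$times
  sel <- which(times >= window[1] - 1e-9 & times < window[2] - 1e-9)
  if (!length(sel)) stop("window contains no samples")
  channels <- phase_list[[1]]$channels
  nch <- length(channels); nt <- length(sel)
  set.seed(seed)
  part_seeds <- sample.int(.Machine$integer.max - 1, np)

  obs <- matrix(0, np, nch * nt)
  null_sum <- matrix(0, n_perm, nch * nt)
  theta_peak <- vector("list", np)
  phase_flat <- vector("list", np)
  for (p in seq_len(np)) {
    ph <- phase_list[[p]]$phase[, , sel, drop = FALSE]
    dmp <- dim(ph)
    flat <- matrix(ph, dmp[1], nch * nt)
    z <- surrogate_null(flat, amp_list[[p]], n_perm, seed = part_seeds[p])
    obs[p, ] <- attr(z, "observed")
    null_sum <- null_sum + z
    phase_flat[[p]] <- flat
  }
  mean_z <- colMeans(obs)
  null_mean <- null_sum / np
  pvals <- (1 + colSums(null_mean >= matrix(mean_z, n_perm, nch * nt,
                                            byrow = TRUE))) / (1 + n_perm)
  fdr <- fdr_bh(pvals, q)
  mz <- matrix(mean_z, nch, nt)
  pm <- matrix(pvals, nch, nt)
  mask <- matrix(fdr$mask, nch, nt)

  peak <- list(found = FALSE, channel = NA_character_,
               channel_index = NA_integer_, sample = NA_integer_,
               time = NA_real_)
  mean_z_at_peak <- NA_real_; mean_z_over_mask <- NA_real_
  part_z_peak <- rep(NA_real_, np); phi0 <- NA_real_
  if (any(mask)) {
    amz <- abs(mz); amz[!mask] <- -Inf
    best <- arrayInd(which.max(amz), dim(amz))
    cell <- (best[2] - 1) * nch + best[1]
    peak <- list(found = TRUE, channel = channels[best[1]],
                 channel_index = best[1][[1]], sample = sel[best[2]],
                 time = times[sel[best[2]]])
    mean_z_at_peak <- mz[best]
    mean_z_over_mask <- mean(mz[mask])
    part_z_peak <- obs[, cell]
    phis <- vapply(seq_len(np), function(p)
      estimate_preferred_phase(phase_flat[[p]][, cell], amp_list[[p]]),
      0)
    phi0 <- atan2(mean(sin(phis), na.rm = TRUE),
                  mean(cos(phis), na.rm = TRUE))
    # preferred phase referred to the locking event (t = 0): at the peak
    # channel, the phase there (not at the earlier peak sample) is the
    # angle the coupling acts on, free of the oscillation's deterministic
    # advance between the peak sample and the event
    s0 <- which.min(abs(times))
    phis0 <- vapply(seq_len(np), function(p)
      estimate_preferred_phase(phase_list[[p]]$phase[, best[1], s0],
                               amp_list[[p]]), 0)
    w0 <- vapply(seq_len(np), function(p)
      circ_lin_corr(phase_list[[p]]$phase[, best[1], s0], amp_list[[p]]), 0)
    w0[!is.finite(w0)] <- 0
    phi0_event <- atan2(sum(w0 * sin(phis0), na.rm = TRUE),
                        sum(w0 * cos(phis0), na.rm = TRUE))
  } else phi0_event <- NA_real_
  structure(list(mean_z = mz, p = pm, mask = mask, cutoff = fdr$cutoff,
                 times = times[sel], channels = channels, peak = peak,
                 mean_z_at_peak = mean_z_at_peak,
                 mean_z_over_mask = mean_z_over_mask,
                 participant_z_at_peak = part_z_peak,
                 preferred_phase = phi0,
                 preferred_phase_at_event = phi0_event,
                 n_participants = np, n_perm = n_perm, q = q, seed = seed),
            class = "phase_corr")
}

#' @export
print.phase_corr <- function(x, ...) {
  cat(sprintf("phase_corr: %d participants, %d channels x %d samples, %d permutations\n",
              x$n_participants, nrow(x$mean_z), ncol(x$mean_z), x$n_perm))
  if (x$peak$found) {
    cat(sprintf("  FDR mask: %d cells (q = %g); peak %s at %.3f s, mean z = %.3f\n",
                sum(x$mask), x$q, x$peak$channel, x$peak$time,
                x$mean_z_at_peak))
    cat(sprintf("  preferred phase: %.3f rad at the peak cell, %.3f rad at the locking event\n",
                x$preferred_phase, x$preferred_phase_at_event))
  } else {
    cat(sprintf("  no FDR-significant cells at q = %g\n", x$q))
  }
  invisible(x)
}
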