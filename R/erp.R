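#' Paired-samples t map over channels and time
#'
#' Samplewise paired t statistic between two within-participant condition
#' averages: `t = mean(d) / (sd(d) / sqrt(n))` with `d = a - b` and the
#' n-1 sample SD. Zero-variance cells are flagged `NA` with a warning and
#' are excluded from cluster formation downstream.
#'
#' @param cond_a,cond_b participants x channels x time arrays of condition
#'   means (matched participants, identical shape)
#' @return object of class `t_stat_map`: `t` (channels x time matrix), `df`
#'   (`n - 1`), `n_degenerate` (zero-variance cell count)
#' @export
paired_t_map <- function(cond_a, cond_b) {
  stopifnot(identical(dim(cond_a), dim(cond_b)), length(dim(cond_a)) == 3)
  n <- dim(cond_a)[1]
  if (n < 2) stop("paired t map needs >= 2 participants")
  d <- cond_a - cond_b
  dm <- matrix(d, n, prod(dim(d)[2:3]))
  m <- colMeans(dm)
  v <- (colSums(dm^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0
  tt <- m / sqrt(v / n)
  degen <- v <= .Machine$double.eps * max(1, max(abs(dm))^2)
  if (any(degen)) {
    tt[degen] <- NA_real_
    warning(sum(degen), " zero-variance cell(s) flagged and excluded from ",
            "clustering")
  }
  structure(list(t = matrix(tt, dim(d)[2], dim(d)[3]), df = n - 1,
                 n_degenerate = sum(degen)),
            class = "t_stat_map")
}

#' Supra-threshold spatio-temporal clusters of a t map
#'
#' Groups samples with `t > threshold` (and, separately, `t < -threshold`)
#' into connected components, where `(c, s)` and `(c', s')` are connected
#' iff they share the channel and are adjacent in time (`|s - s'| = 1`), or
#' share the time sample and are neighbors on the sensor graph. Clusters
#' spanning fewer than `min_channels` distinct channels are discarded.
#'
#' @param tmat channels x time matrix of t values (`NA` cells are skipped)
#' @param threshold positive cluster-forming threshold
#' @param adjacency [build_adjacency()] result
#' @param min_channels minimum number of distinct channels per cluster
#' @return list of clusters, each a list with `members` (two-column matrix
#'   of channel/time indices), `sign` (+1/-1), `mass` (sum of member t
#'   values), sorted by decreasing `|mass|`
#' @export
find_clusters <- function(tmat, threshold, adjacency, min_channels = 1) {
  stopifnot(threshold > 0)
  out <- c(.clusters_one_sign(tmat, threshold, adjacency, min_channels, +1),
           .clusters_one_sign(tmat, threshold, adjacency, min_channels, -1))
  if (length(out)) out <- out[order(-vapply(out, function(cl) abs(cl$mass), 0))]
  out
}

# connected components over the masked grid via union-find
.clusters_one_sign <- function(tmat, threshold, adjacency, min_channels, sign) {
  mask <- if (sign > 0) !is.na(tmat) & tmat > threshold else
    !is.na(tmat) & tmat < -threshold
  idx <- which(mask)
  if (!length(idx)) return(list())
  nch <- nrow(tmat); nt <- ncol(tmat)
  id <- matrix(0L, nch, nt)
  id[idx] <- seq_along(idx)
  parent <- seq_along(idx)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  ch <- ((idx - 1) %% nch) + 1
  ts <- ((idx - 1) %/% nch) + 1
  nbs <- adjacency$neighbors
  for (m in seq_along(idx)) {
    c0 <- ch[m]; t0 <- ts[m]
    if (t0 > 1 && id[c0, t0 - 1] > 0) {          # temporal neighbor
      ra <- find(m); rb <- find(id[c0, t0 - 1])
      if (ra != rb) parent[ra] <- rb
    }
    for (cn in nbs[[c0]]) {                       # spatial neighbors
      if (cn < c0 && id[cn, t0] > 0) {
        ra <- find(m); rb <- find(id[cn, t0])
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  roots <- vapply(seq_along(idx), find, 0L)
  out <- list()
  for (r in unique(roots)) {
    sel <- roots == r
    if (length(unique(ch[sel])) < min_channels) next
    out[[length(out) + 1]] <- list(
      members = cbind(channel = ch[sel], sample = ts[sel]),
      sign = sign, mass = sum(tmat[idx[sel]]))
  }
  out
}

# max positive / negative cluster mass of one t map (0 when none survives)
.max_cluster_masses <- function(tmat, threshold, adjacency, min_channels) {
  cl <- find_clusters(tmat, threshold, adjacency, min_channels)
  pos <- 0; neg <- 0
  for (c0 in cl) {
    if (c0$sign > 0) pos <- max(pos, c0$mass) else neg <- min(neg, c0$mass)
  }
  c(pos = pos, neg = neg)
}

#' Spatio-temporal cluster-based permutation test for a paired ERP contrast
#'
#' The observed channels x time t map (paired, participants as the unit) is
#' thresholded at the two-tailed samplewise critical value
#' `qt(1 - 0.025, n - 1)` and clustered under the spatio-temporal adjacency
#' of [find_clusters()]. The null distribution of the maximum cluster mass
#' (per sign) is built by random sign flips of the participant difference
#' maps — the exchangeability the paired design affords. Each cluster's
#' Monte-Carlo p is `(1 + #(null >= observed)) / (1 + n_perm)` against its
#' own sign's max-null, doubled for two-sided control and capped at 1.
#' `exhaustive = TRUE` enumerates all `2^n` sign patterns and returns the
#' exact p (only for `n <= 16`).
#'
#' @param cond_a,cond_b participants x channels x time arrays of condition
#'   means, already restricted to the analysis window
#' @param times time axis (s) matching dim 3
#' @param adjacency [build_adjacency()] result
#' @param alpha cluster-level significance level (two-sided)
#' @param n_perm number of random sign-flip permutations
#' @param min_channels minimum distinct channels per cluster
#' @param seed integer seed for the permutation draw
#' @param exhaustive enumerate all sign patterns instead of sampling
#' @return object of class `cluster_test`: `tmap` ([paired_t_map()] result),
#'   `mean_diff` (channels x time grand-average difference), `null_max`
#'   (per-permutation max positive / min negative cluster masses),
#'   `clusters` (each with `members`, `sign`, `mass`, `p`, `significant`),
#'   `threshold`, `alpha`, `n_perm`, `times`, `channels`, `seed`
#' @export
cluster_permutation_test <- function(cond_a, cond_b, times, adjacency,
                                     alpha = 0.05, n_perm = 10000,
                                     min_channels = 3, seed = 1,
                                     exhaustive = FALSE) {
  n <- dim(cond_a)[1]
  if (!exhaustive && n < 5) stop("need >= 5 participants (or exhaustive mode)")
  if (exhaustive && n > 16) stop("exhaustive enumeration limited to n <= 16")
  if (!exhaustive && n_perm < 100) warning("n_perm < 100 gives a very coarse p")
  tm <- paired_t_map(cond_a, cond_b)
  thr <- stats::qt(1 - 0.025, tm$df)
  clusters <- find_clusters(tm$t, thr, adjacency, min_channels)

  d <- cond_a - cond_b
  nch <- dim(d)[2]; nt <- dim(d)[3]
  dflat <- matrix(d, n, nch * nt)
  ssq <- colSums(dflat^2)
  if (exhaustive) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    set.seed(seed)
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), ncol = n)
  }
  B <- nrow(signs)
  msums <- signs %*% dflat
  null_pos <- numeric(B); null_neg <- numeric(B)
  for (b in seq_len(B)) {
    m <- msums[b, ] / n
    v <- (ssq - n * m^2) / (n - 1)
    v[v < 0] <- 0
    tt <- m / sqrt(v / n)
    tt[!is.finite(tt)] <- NA_real_
    mm <- .max_cluster_masses(matrix(tt, nch, nt), thr, adjacency,
                              min_channels)
    null_pos[b] <- mm["pos"]; null_neg[b] <- mm["neg"]
  }
  for (i in seq_along(clusters)) {
    cl <- clusters[[i]]
    if (exhaustive) {
      p1 <- if (cl$sign > 0) mean(null_pos >= cl$mass) else
        mean(null_neg <= cl$mass)
    } else {
      p1 <- if (cl$sign > 0) (1 + sum(null_pos >= cl$mass)) / (1 + B) else
        (1 + sum(null_neg <= cl$mass)) / (1 + B)
    }
    clusters[[i]]$p <- min(1, 2 * p1)
    clusters[[i]]$significant <- clusters[[i]]$p <= alpha
  }
  structure(list(tmap = tm,
                 mean_diff = matrix(colMeans(dflat), nch, nt),
                 null_max = list(pos = null_pos, neg = null_neg),
                 clusters = clusters, threshold = thr,
                 alpha = alpha, n_perm = B, times = times,
                 channels = adjacency$channels, seed = seed,
                 exhaustive = exhaustive),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("cluster_test: %d cluster(s), threshold |t| > %.3f (df = %d), %s%d permutations\n",
              length(x$clusters), x$threshold, x$tmap$df,
              if (x$exhaustive) "exhaustive " else "", x$n_perm))
  for (cl in x$clusters) {
    cat(sprintf("  %s cluster: mass = %.1f, %d cells, p = %.4g%s\n",
                if (cl$sign > 0) "positive" else "negative", cl$mass,
                nrow(cl$members), cl$p, if (cl$significant) " *" else ""))
  }
  invisible(x)
}

#' Peak channel and latency of the strongest significant cluster
#'
#' Locates, within the largest-|mass| significant cluster of the requested
#' sign, the member cell where the ERP peaked — i.e. of maximal |mean
#' condition difference| (`by = "amplitude"`, the default: the electrode
#' and time point at which the ERP itself peaks, which is also a more
#' stable localizer than the t map, whose denominator is a noisy SD
#' estimate at small n). `by = "t"` selects the max-|t| member instead.
#' Ties break to the lowest channel index, then the earliest time. Returns
#' a "no-peak" outcome (not an error) when no cluster of that sign is
#' significant.
#'
#' @param result [cluster_permutation_test()] output
#' @param sign `"positive"` or `"negative"`
#' @param by peak criterion: `"amplitude"` (grand-average difference) or
#'   `"t"`
#' @return list with `found` (logical), `channel` (name), `channel_index`,
#'   `time` (s), `sample` (index into `result$times`), `t`, `amplitude`
#' @export
extract_peak <- function(result, sign = c("positive", "negative"),
                         by = c("amplitude", "t")) {
  sign <- match.arg(sign)
  by <- match.arg(by)
  sgn <- if (sign == "positive") 1 else -1
  cand <- Filter(function(cl) cl$sign == sgn && isTRUE(cl$significant),
                 result$clusters)
  if (!length(cand)) {
    return(list(found = FALSE, channel = NA_character_,
                channel_index = NA_integer_, time = NA_real_,
                sample = NA_integer_, t = NA_real_, amplitude = NA_real_))
  }
  cl <- cand[[which.max(vapply(cand, function(c0) abs(c0$mass), 0))]]
  score <- if (by == "amplitude") abs(result$mean_diff[cl$members]) else
    abs(result$tmap$t[cl$members])
  ord <- order(-score, cl$members[, "channel"], cl$members[, "sample"])
  best <- cl$members[ord[1], ]
  list(found = TRUE,
       channel = result$channels[best["channel"]],
       channel_index = unname(best["channel"]),
       time = result$times[best["sample"]],
       sample = unname(best["sample"]),
       t = result$tmap$t[best["channel"], best["sample"]],
       amplitude = result$mean_diff[best["channel"], best["sample"]])
}

#' Single-trial amplitude at a channel and latency
#'
#' Voltage at the sample nearest `time` (for `half_width = 0`, the default
#' "masked for the peak time point and electrode" convention) or the mean
#' over `time +/- half_width`.
#'
#' @param epochs [eeg_epochs()] (typically baseline-corrected verb-locked
#'   epochs)
#' @param channel channel name or index
#' @param time latency in seconds (epoch time axis)
#' @param half_width half-width of the averaging window, s (0 = single sample)
#' @return numeric vector, one amplitude per trial (uV)
#' @export
extract_single_trial_amplitude <- function(epochs, channel, time,
                                           half_width = 0) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (is.character(channel)) {
    ci <- match(channel, epochs$channels)
    if (is.na(ci)) stop("unknown channel '", channel, "'")
  } else ci <- as.integer(channel)
  if (ci < 1 || ci > length(epochs$channels)) stop("unknown channel index")
  if (time - half_width < epochs$times[1] - 1e-9 ||
      time + half_width > epochs$times[length(epochs$times)] + 1e-9) {
    stop("time +/- half_width outside the epoch")
  }
  if (half_width <= 0) {
    s <- which.min(abs(epochs$times - time))
    return(epochs$data[, ci, s])
  }
  sel <- which(epochs$times >= time - half_width - 1e-9 &
                 epochs$times <= time + half_width + 1e-9)
  rowMeans(matrix(epochs$data[, ci, sel], dim(epochs$data)[1], length(sel)))
}

#' Per-participant condition means for a paired contrast
#'
#' Averages epochs over trials within each level of a label column,
#' returning the participants x channels x time arrays
#' [cluster_permutation_test()] consumes.
#'
#' @param epoch_list list of [eeg_epochs()], one per participant
#' @param label trial column to split on (e.g. `"RATE"`)
#' @param level_a,level_b the two levels to contrast (a minus b downstream)
#' @return list `a`, `b` (participants x channels x time arrays), `times`,
#'   `channels`
#' @export
condition_means <- function(epoch_list, label, level_a, level_b) {
  n <- length(epoch_list)
  dm <- dim(epoch_list[[1]]$data)
  a <- array(0, c(n, dm[2], dm[3])); b <- a
  for (p in seq_len(n)) {
    ep <- epoch_list[[p]]
    la <- ep$trials[[label]] == level_a
    lb <- ep$trials[[label]] == level_b
    if (!any(la) || !any(lb)) stop("participant ", p, " lacks trials in one level")
    a[p, , ] <- colMeans(ep$data[la, , , drop = FALSE], dims = 1)
    b[p, , ] <- colMeans(ep$data[lb, , , drop = FALSE], dims = 1)
  }
  list(a = a, b = b, times = epoch_list[[1]]$times,
       channels = epoch_list[[1]]$channels)
}
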