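# Independent oracles used to check the implementation from a second route.

# Welch power spectral density: Hann-tapered 50%-overlap segment-averaged
# periodogram
welch_psd <- function(x, rate, n_seg = 8) {
  n <- length(x)
  seg_len <- floor(n / (n_seg / 2 + 0.5))
  seg_len <- max(8, seg_len - seg_len %% 2)
  step <- seg_len / 2
  taper <- 0.5 * (1 - cos(2 * pi * (seq_len(seg_len) - 1) / (seg_len - 1)))
  u <- sum(taper^2)
  starts <- seq(1, n - seg_len + 1, by = step)
  acc <- 0
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1)]
    seg <- (seg - mean(seg)) * taper
    acc <- acc + Mod(fft(seg))^2 / (u * rate)
  }
  psd <- acc / length(starts)
  freq <- (seq_len(seg_len) - 1) * rate / seg_len
  keep <- freq > 0 & freq <= rate / 2
  list(freq = freq[keep], psd = psd[keep])
}

# least-squares log-log PSD slope between fmin and fmax
psd_slope <- function(x, rate, fmin, fmax) {
  w <- welch_psd(x, rate)
  sel <- w$freq >= fmin & w$freq <= fmax
  stats::coef(stats::lm(log10(w$psd[sel]) ~ log10(w$freq[sel])))[[2]]
}

# grid-search definition of the circular-linear correlation:
# max over phi of |cor(x, cos(theta - phi))|
grid_circ_lin <- function(theta, x, n_grid = 10000) {
  phis <- seq(-pi, pi, length.out = n_grid)
  best <- 0
  for (phi in phis) {
    r <- abs(stats::cor(x, cos(theta - phi)))
    if (r > best) best <- r
  }
  best
}

# vectorized variant (for many repetitions)
grid_circ_lin_fast <- function(theta, x, n_grid = 10000) {
  phis <- seq(-pi, pi, length.out = n_grid)
  cmat <- cos(outer(theta, phis, "-"))
  max(abs(suppressWarnings(stats::cor(x, cmat))), na.rm = TRUE)
}

# brute-force connected components of a supra-threshold (channel, time)
# mask by exhaustive pairwise neighbor scan + BFS; independent of the
# union-find implementation under test
bfs_clusters <- function(tmat, threshold, adj_matrix, min_channels, sign) {
  mask <- if (sign > 0) !is.na(tmat) & tmat > threshold else
    !is.na(tmat) & tmat < -threshold
  cells <- which(mask, arr.ind = TRUE)
  n <- nrow(cells)
  if (n == 0) return(list())
  is_nb <- function(i, j) {
    (cells[i, 1] == cells[j, 1] && abs(cells[i, 2] - cells[j, 2]) == 1) ||
      (cells[i, 2] == cells[j, 2] && adj_matrix[cells[i, 1], cells[j, 1]])
  }
  unvisited <- rep(TRUE, n)
  out <- list()
  for (s in seq_len(n)) {
    if (!unvisited[s]) next
    comp <- integer(0)
    queue <- s
    unvisited[s] <- FALSE
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      comp <- c(comp, v)
      for (j in seq_len(n)) {
        if (unvisited[j] && is_nb(v, j)) {
          unvisited[j] <- FALSE
          queue <- c(queue, j)
        }
      }
    }
    if (length(unique(cells[comp, 1])) < min_channels) next
    out[[length(out) + 1]] <- list(
      members = cells[comp, , drop = FALSE],
      mass = sum(tmat[cells[comp, , drop = FALSE]]))
  }
  out
}

# canonical form of a cluster member set for comparison
cluster_key <- function(members) {
  paste(sort(paste(members[, 1], members[, 2], sep = ":")), collapse = ";")
}

# Rayleigh test p (uniformity of angles), standard approximation
rayleigh_p <- function(theta) {
  n <- length(theta)
  rbar <- Mod(mean(exp(1i * theta)))
  z <- n * rbar^2
  exp(-z) * (1 + (2 * z - z^2) / (4 * n))
}

# exhaustive-enumeration two-sided p for the Wilcoxon signed-rank W+
exhaustive_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  mu <- n * (n + 1) / 4
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

circ_diff <- function(a, b) Arg(exp(1i * (a - b)))

# small quick simulation config used across tests
quick_config <- function(...) {
  simulation_config(n_participants = 2, n_trials_per_condition = 4,
                    n_channels = 6, sampling_rate = 100, ...)
}

.wrap_test <- function(x) {
  out <- (x + pi) %% (2 * pi) - pi
  out[out <= -pi] <- pi
  out
}
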