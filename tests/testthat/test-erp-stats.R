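arr3 <- function(m, nch, nt) array(m, c(length(m) / (nch * nt), nch, nt))

test_that("paired t map matches hand computation and flags degeneracies", {
  # d = [1, 2, 3] at a single cell: t = 2 / (1 / sqrt(3)) = 3.4641
  a <- array(c(1, 2, 3), c(3, 1, 1))
  b <- array(0, c(3, 1, 1))
  tm <- paired_t_map(a, b)
  expect_equal(tm$t[1, 1], 2 / (1 / sqrt(3)), tolerance = 1e-6)
  expect_equal(tm$df, 2)

  expect_warning(tm0 <- paired_t_map(b, b), "zero-variance")
  expect_true(is.na(tm0$t[1, 1]))

  # constant offset identical across participants: zero variance everywhere
  set.seed(1)
  base <- array(rnorm(3 * 2 * 4), c(3, 2, 4))
  expect_warning(tmc <- paired_t_map(base + 2, base), "zero-variance")
  expect_equal(tmc$n_degenerate, 8)

  expect_error(paired_t_map(a[1, , , drop = FALSE], b[1, , , drop = FALSE]),
               ">= 2")
})

test_that("cluster finding respects thresholds and the channel minimum", {
  lay <- make_layout(5)
  adj <- build_adjacency(lay)
  tmat <- matrix(0.5, 5, 20)
  expect_length(find_clusters(tmat, 2, adj), 0)

  # one channel crossing threshold for 10 samples, min_channels = 3
  tmat2 <- matrix(0, 5, 20)
  tmat2[2, 5:14] <- 3
  expect_length(find_clusters(tmat2, 2, adj, min_channels = 3), 0)
  one <- find_clusters(tmat2, 2, adj, min_channels = 1)
  expect_length(one, 1)
  expect_equal(one[[1]]$mass, 30)
  expect_equal(one[[1]]$sign, 1)
})

test_that("clusters agree with the exhaustive BFS oracle on random maps", {
  lay <- make_layout(5)
  adj <- build_adjacency(lay)
  for (s in 1:10) {
    set.seed(s)
    tmat <- matrix(rnorm(5 * 20, sd = 2), 5, 20)
    for (mc in c(1, 3)) {
      mine <- find_clusters(tmat, 1.5, adj, min_channels = mc)
      oracle <- c(bfs_clusters(tmat, 1.5, adj$matrix, mc, +1),
                  bfs_clusters(tmat, 1.5, adj$matrix, mc, -1))
      expect_equal(length(mine), length(oracle))
      k_mine <- sort(vapply(mine, function(cl) cluster_key(cl$members), ""))
      k_oracle <- sort(vapply(oracle, function(cl) cluster_key(cl$members), ""))
      expect_identical(k_mine, k_oracle)
      m_mine <- sort(vapply(mine, `[[`, 0, "mass"))
      m_oracle <- sort(vapply(oracle, `[[`, 0, "mass"))
      expect_equal(m_mine, m_oracle, tolerance = 1e-12)
    }
  }
})

test_that("cluster masses are invariant under adjacency-preserving relabeling", {
  lay <- make_layout(6)
  adj <- build_adjacency(lay)
  set.seed(4)
  tmat <- matrix(rnorm(6 * 15, sd = 2), 6, 15)
  perm <- sample(6)
  adj_p <- adj
  adj_p$matrix <- adj$matrix[perm, perm]
  adj_p$neighbors <- apply(adj_p$matrix, 1, which, simplify = FALSE)
  a <- find_clusters(tmat, 1.5, adj, min_channels = 1)
  b <- find_clusters(tmat[perm, ], 1.5, adj_p, min_channels = 1)
  expect_equal(sort(vapply(a, `[[`, 0, "mass")),
               sort(vapply(b, `[[`, 0, "mass")), tolerance = 1e-12)
})

make_fixture <- function(seed = 1, n = 6, nch = 3, nt = 4, effect = 1.2) {
  set.seed(seed)
  a <- array(rnorm(n * nch * nt), c(n, nch, nt))
  b <- array(rnorm(n * nch * nt), c(n, nch, nt))
  a[, 1:2, 2:3] <- a[, 1:2, 2:3] + effect
  list(a = a, b = b, times = seq_len(nt) / 100,
       adj = build_adjacency(make_layout(nch)))
}

test_that("Monte-Carlo cluster p matches the exhaustive sign-flip p", {
  fx <- make_fixture(seed = 3, effect = 2)
  exh <- cluster_permutation_test(fx$a, fx$b, fx$times, fx$adj,
                                  min_channels = 1, exhaustive = TRUE)
  mc <- cluster_permutation_test(fx$a, fx$b, fx$times, fx$adj,
                                 n_perm = 10000, min_channels = 1, seed = 8)
  expect_gt(length(exh$clusters), 0)
  key <- function(cl) cluster_key(cl$members)
  exh_p <- setNames(vapply(exh$clusters, `[[`, 0, "p"),
                    vapply(exh$clusters, key, ""))
  for (cl in mc$clusters) {
    expect_lt(abs(cl$p - exh_p[[key(cl)]]), 0.02)
  }
})

test_that("p-values respect the plus-one floor and mass monotonicity", {
  fx <- make_fixture(seed = 5, n = 8, effect = 50)
  res <- cluster_permutation_test(fx$a, fx$b, fx$times, fx$adj,
                                  n_perm = 999, min_channels = 1, seed = 2)
  # every reported p follows the documented plus-one rule exactly
  for (cl in res$clusters) {
    b <- if (cl$sign > 0) sum(res$null_max$pos >= cl$mass) else
      sum(res$null_max$neg <= cl$mass)
    expect_equal(cl$p, min(1, 2 * (1 + b) / (1 + 999)))
  }
  biggest <- res$clusters[[1]]
  expect_lte(biggest$p, 0.01)  # huge effect: at the floor bar identity draws
  expect_true(all(vapply(res$clusters, `[[`, 0, "p") > 0))
  # within a sign, smaller |mass| never gets a smaller p (same max-null)
  for (sgn in c(1, -1)) {
    cls <- Filter(function(cl) cl$sign == sgn, res$clusters)
    if (length(cls) > 1) {
      expect_true(all(diff(vapply(cls, `[[`, 0, "p")) >= 0))
    }
  }
})

test_that("permutation test guards its preconditions", {
  fx <- make_fixture(n = 3)
  expect_error(cluster_permutation_test(fx$a, fx$b, fx$times, fx$adj,
                                        n_perm = 100, seed = 1),
               ">= 5 participants")
  big <- make_fixture(n = 17)
  expect_error(cluster_permutation_test(big$a, big$b, big$times, big$adj,
                                        exhaustive = TRUE),
               "n <= 16")
  fx8 <- make_fixture(n = 8)
  expect_warning(cluster_permutation_test(fx8$a, fx8$b, fx8$times, fx8$adj,
                                          n_perm = 50, seed = 1),
                 "coarse")
})

test_that("peak extraction follows the amplitude rule with documented tie-breaks", {
  fx <- make_fixture(seed = 9, n = 8, effect = 6)
  res <- cluster_permutation_test(fx$a, fx$b, fx$times, fx$adj,
                                  n_perm = 500, min_channels = 1, seed = 3)
  pk <- extract_peak(res, "positive")
  expect_true(pk$found)
  cl <- res$clusters[[which.max(vapply(res$clusters, function(c0)
    abs(c0$mass) * (c0$sign > 0), 0))]]
  amp_members <- abs(res$mean_diff[cl$members])
  expect_equal(abs(res$mean_diff[pk$channel_index, pk$sample]),
               max(amp_members))

  none <- extract_peak(res, "negative")
  if (!none$found) expect_true(is.na(none$channel))

  # tie-break: equal amplitudes -> lowest channel, then earliest sample
  res_t <- res
  res_t$mean_diff[] <- 0
  res_t$mean_diff[cbind(cl$members[, 1], cl$members[, 2])] <- 1
  pk_t <- extract_peak(res_t, "positive")
  ord <- order(cl$members[, "channel"], cl$members[, "sample"])
  expect_equal(pk_t$channel_index, cl$members[ord[1], "channel"][[1]])
  expect_equal(pk_t$sample, cl$members[ord[1], "sample"][[1]])
})

test_that("single-trial amplitude extraction is exact on known inputs", {
  rate <- 100
  times <- seq(-0.5, 1.5 - 1 / rate, by = 1 / rate)
  d <- array(0, c(2, 2, length(times)))
  d[1, 1, ] <- 7
  d[2, 1, ] <- sin(2 * pi * 1 * times)
  ep <- eeg_epochs(d, rate, times, c("a", "b"), tibble::tibble(trial = 1:2))
  expect_equal(extract_single_trial_amplitude(ep, "a", 0.3)[1], 7)
  expect_equal(extract_single_trial_amplitude(ep, 1, 0.3, half_width = 0.05)[1], 7)
  # windowed vs point estimate differ by less than slope x window on smooth data
  v0 <- extract_single_trial_amplitude(ep, "a", 0.25)[2]
  v1 <- extract_single_trial_amplitude(ep, "a", 0.25, half_width = 0.01)[2]
  expect_lt(abs(v1 - v0), 2 * pi * 1 * 0.02)
  expect_error(extract_single_trial_amplitude(ep, "zz", 0.3), "unknown channel")
  expect_error(extract_single_trial_amplitude(ep, "a", 2), "outside the epoch")
})

test_that("amplitude at the bump peak recovers the generator's ground truth", {
  cfg <- quick_config(noise_sd = 0, sensor_noise_sd = 0, delta_amplitude = 0,
                      neg_amplitude = 0, seed = 6)
  ds <- generate_dataset(cfg)
  prep <- pipeline_config(sim = cfg)$prep
  prep$erp_highpass <- 0.1  # keep the bump undistorted for the exact check
  rec <- ds$participants[[1]]$recording  # no re-reference: raw weights
  ep <- epoch_data(rec, "verb_onset", -0.5, 1.5)
  gt <- ds$ground_truth[ds$ground_truth$participant == 1, ]
  ch <- which.max(ds$maps$p600)
  amp <- extract_single_trial_amplitude(ep, names(ch), 0.456)
  expect_equal(amp, gt$true_evoked_amplitude * ds$maps$p600[[ch]],
               tolerance = 0.02)
})
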