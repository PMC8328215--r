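test_that("circular-linear correlation satisfies its defining variational property", {
  set.seed(1)
  for (rep in 1:20) {
    theta <- runif(50, -pi, pi)
    x <- rnorm(50) + if (rep %% 2) 2 * cos(theta - 0.7) else 0
    r <- circ_lin_corr(theta, x)
    expect_gte(r, 0); expect_lte(r, 1)
    expect_lt(abs(r - grid_circ_lin_fast(theta, x)), 1e-4)
  }
})

test_that("perfect cosine coupling gives r = 1 and independence gives r near 0", {
  set.seed(2)
  theta <- runif(200, -pi, pi)
  for (phi in c(-2, 0.3, 1.4)) {
    expect_equal(circ_lin_corr(theta, cos(theta - phi)), 1, tolerance = 1e-10)
  }
  theta_big <- runif(10000, -pi, pi)
  expect_lt(circ_lin_corr(theta_big, rnorm(10000)), 0.05)
})

test_that("r is invariant to phase rotation and affine amplitude transforms", {
  set.seed(3)
  theta <- runif(80, -pi, pi)
  x <- rnorm(80) + cos(theta)
  r0 <- circ_lin_corr(theta, x)
  for (rot in c(0.5, -2.2)) {
    expect_equal(circ_lin_corr(theta + rot, x), r0, tolerance = 1e-10)
  }
  expect_equal(circ_lin_corr(theta, 3.7 * x - 11), r0, tolerance = 1e-10)
  expect_equal(circ_lin_corr(theta, -2 * x), r0, tolerance = 1e-10)
})

test_that("degenerate circular-linear inputs are flagged, not mis-scored", {
  theta <- runif(20, -pi, pi)
  expect_true(is.na(circ_lin_corr(theta, rep(5, 20))))
  expect_true(is.na(circ_lin_corr(rep(1.2, 20), rnorm(20))))
  expect_error(circ_lin_corr(theta[1:3], rnorm(3)), "at least 4")
})

test_that("Fisher z matches atanh with guarded endpoints", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)
  set.seed(4)
  r <- sort(runif(20, 0, 0.99))
  expect_true(all(diff(fisher_z(r)) > 0))
  expect_error(fisher_z(-0.1), "\\[0, 1\\]")
  expect_error(fisher_z(1.2), "\\[0, 1\\]")
  expect_warning(zi <- fisher_z(1), "infinite")
  expect_equal(zi, Inf)
})

test_that("preferred-phase estimation is exact, matches the grid, and recovers under noise", {
  set.seed(5)
  theta <- runif(300, -pi, pi)
  expect_equal(estimate_preferred_phase(theta, cos(theta - 1)), 1,
               tolerance = 1e-8)

  # closed form equals grid search within grid resolution
  for (rep in 1:25) {
    th <- runif(60, -pi, pi)
    x <- rnorm(60) + 1.5 * cos(th - runif(1, -pi, pi))
    est <- estimate_preferred_phase(th, x)
    grid <- seq(-pi, pi, length.out = 10000)
    cors <- suppressWarnings(stats::cor(x, cos(outer(th, grid, "-"))))
    expect_lt(abs(circ_diff(est, grid[which.max(cors)])), 2 * pi / 10000 * 4)
  }

  # SNR 1 recovery: |error| < 0.2 rad in >= 95% of seeds
  hits <- 0
  for (s in 1:40) {
    set.seed(100 + s)
    th <- runif(500, -pi, pi)
    phi <- runif(1, -pi, pi)
    x <- cos(th - phi) + rnorm(500, sd = sqrt(1 / 2))
    if (abs(circ_diff(estimate_preferred_phase(th, x), phi)) < 0.2) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 38)
})

test_that("surrogate null honors the identity convention and seed determinism", {
  set.seed(6)
  theta <- matrix(runif(40 * 3, -pi, pi), 40, 3)
  amp <- rnorm(40) + 2 * cos(theta[, 1])
  z <- surrogate_null(theta, amp, n_perm = 50, seed = 9,
                      include_identity = TRUE)
  expect_equal(unname(z[1, ]), unname(attr(z, "observed")), tolerance = 1e-12)
  obs_direct <- vapply(1:3, function(j)
    fisher_z(circ_lin_corr(theta[, j], amp)), 0)
  expect_equal(unname(attr(z, "observed")), obs_direct, tolerance = 1e-10)

  z2 <- surrogate_null(theta, amp, n_perm = 50, seed = 9,
                       include_identity = TRUE)
  expect_identical(z, z2)

  expect_warning(zc <- surrogate_null(theta, rep(1, 40), n_perm = 10, seed = 1),
                 "constant amplitude")
  expect_true(all(is.na(zc)))
  expect_true(attr(zc, "degenerate"))
})

test_that("strong coupling puts the observed z far above the surrogate null", {
  wins <- 0
  for (s in 1:5) {
    set.seed(200 + s)
    theta <- matrix(runif(60, -pi, pi), 60, 1)
    amp <- 4 * cos(theta[, 1] - 0.5) + rnorm(60, sd = 1)
    z <- surrogate_null(theta, amp, n_perm = 1000, seed = s)
    if (attr(z, "observed")[1] > max(z[, 1])) wins <- wins + 1
  }
  expect_gte(wins, 5)
})

test_that("surrogate p at a fixed cell is uniform under the null", {
  ps <- numeric(150)
  for (s in seq_along(ps)) {
    set.seed(300 + s)
    theta <- matrix(runif(24, -pi, pi), 24, 1)
    amp <- rnorm(24)
    z <- surrogate_null(theta, amp, n_perm = 199, seed = s)
    ps[s] <- (1 + sum(z[, 1] >= attr(z, "observed")[1])) / (1 + 199)
  }
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("BH step-up matches the hand-worked example and p.adjust", {
  # the classic 15-test worked example: q = 0.05 rejects exactly the
  # smallest four p values, cutoff p_(4) = 0.0095
  p <- c(0.0001, 0.0004, 0.0019, 0.0095, 0.0201, 0.0278, 0.0298, 0.0344,
         0.0459, 0.3240, 0.4262, 0.5719, 0.6528, 0.7590, 1.0000)
  res <- fdr_bh(p, 0.05)
  expect_identical(which(res$mask), 1:4)
  expect_equal(res$cutoff, 0.0095)

  expect_false(any(fdr_bh(rep(1, 10), 0.05)$mask))
  expect_true(all(fdr_bh(rep(0, 10), 0.05)$mask))
  expect_length(fdr_bh(numeric(0), 0.05)$mask, 0)

  set.seed(7)
  for (rep in 1:20) {
    pv <- runif(50)^2
    mine <- fdr_bh(pv, 0.05)$mask
    ref <- stats::p.adjust(pv, "BH") <= 0.05
    expect_identical(mine, ref)
  }
})

test_that("group test aggregates Fisher z with a matched permutation null", {
  # strongly coupled two-participant data: observed mean z beats all nulls
  set.seed(8)
  rate <- 50
  times <- seq(-1, 1 - 1 / rate, by = 1 / rate)
  mk <- function(seed) {
    set.seed(seed)
    n <- 40
    phases <- runif(n, -pi, pi)
    ph <- array(rep(phases, 2 * length(times)), c(n, 2, length(times)))
    list(phase = structure(list(phase = ph, times = times, rate = rate,
                                channels = c("a", "b"),
                                trials = tibble::tibble(trial = 1:n)),
                           class = "phase_map"),
         amp = 5 * cos(phases - 0.3) + rnorm(n, sd = 0.5))
  }
  d1 <- mk(21); d2 <- mk(22)
  res <- group_phase_amplitude_test(list(d1$phase, d2$phase),
                                    list(d1$amp, d2$amp),
                                    window = c(-0.5, 0), n_perm = 400,
                                    q = 0.05, seed = 5)
  expect_true(res$peak$found)
  expect_equal(min(res$p), 1 / (1 + 400))
  expect_true(all(res$p[res$mask] <= res$cutoff))
  expect_equal(dim(res$mean_z), c(2, sum(times >= -0.5 & times < 0)))
  # phases constant over time here, so the preferred phase is recoverable
  expect_lt(abs(circ_diff(res$preferred_phase_at_event, 0.3)), 0.1)

  # participants with < 4 trials are dropped with a warning
  short <- mk(23)
  short$amp <- short$amp[1:3]
  short$phase$phase <- short$phase$phase[1:3, , , drop = FALSE]
  short$phase$trials <- short$phase$trials[1:3, ]
  expect_warning(
    group_phase_amplitude_test(list(d1$phase, short$phase),
                               list(d1$amp, short$amp),
                               window = c(-0.5, 0), n_perm = 50, seed = 1),
    "dropped")
})
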