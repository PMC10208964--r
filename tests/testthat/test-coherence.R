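# time-varying magnitude coherence and dyad contrasts

noise_epochs <- function(n_trials, rho = 0, seed = 1, fs = 500, ns = 1250) {
  # two channels sharing a common component with mixing weight rho
  dat <- array(0, c(n_trials, 2, ns))
  withr::with_seed(seed, for (i in seq_len(n_trials)) {
    s <- rnorm(ns)
    dat[i, 1, ] <- sqrt(rho) * s + sqrt(1 - rho) * rnorm(ns)
    dat[i, 2, ] <- sqrt(rho) * s + sqrt(1 - rho) * rnorm(ns)
  })
  lfp_epochs(dat, fs, -0.5, rep("neutral", n_trials))
}

test_that("self-coherence is exactly one and the measure is symmetric", {
  ep <- noise_epochs(10, seed = 1)
  ep$data[, 2, ] <- ep$data[, 1, ]
  m <- time_varying_coherence(ep, c(1, 2), time_step = 0.1, freq_step = 2,
                              freq_range = c(4, 45))
  expect_true(all(abs(m$values - 1) < 1e-10))
  # symmetry on distinct channels
  ep2 <- noise_epochs(30, rho = 0.3, seed = 2)
  m12 <- time_varying_coherence(ep2, c(1, 2), time_step = 0.1, freq_step = 2,
                                freq_range = c(4, 45))
  m21 <- time_varying_coherence(ep2, c(2, 1), time_step = 0.1, freq_step = 2,
                                freq_range = c(4, 45))
  expect_equal(m12$values, m21$values)
  expect_true(all(m12$values >= 0 & m12$values <= 1))
})

test_that("independent channels sit at the small-sample bias level", {
  ep <- noise_epochs(90, rho = 0, seed = 3)
  m <- time_varying_coherence(ep, c(1, 2), time_step = 0.05, freq_step = 1,
                              freq_range = c(4, 45))
  bias <- sqrt(pi / (4 * 90))
  expect_lt(abs(mean(m$values) - bias), 0.03)
  expect_lt(max(m$values), 0.35)
})

test_that("equal-variance additive noise gives 1/sqrt(2) coherence", {
  # Y = X + N with X, N independent white noise of equal variance:
  # |Sxy| / sqrt(Sxx Syy) = 1 / sqrt(2)
  ns <- 1250
  dat <- array(0, c(120, 2, ns))
  withr::with_seed(4, for (i in 1:120) {
    x <- rnorm(ns)
    dat[i, 1, ] <- x
    dat[i, 2, ] <- x + rnorm(ns)
  })
  ep <- lfp_epochs(dat, 500, -0.5, rep("neutral", 120))
  m <- time_varying_coherence(ep, c(1, 2), time_step = 0.05, freq_step = 1,
                              freq_range = c(4, 45))
  expect_equal(mean(m$values), sqrt(0.5), tolerance = 0.05 / sqrt(0.5))
})

test_that("coherence ignores per-channel amplitude scaling", {
  ep <- noise_epochs(30, rho = 0.5, seed = 5)
  m1 <- time_varying_coherence(ep, c(1, 2), time_step = 0.1, freq_step = 2,
                               freq_range = c(4, 45))
  ep$data[, 1, ] <- 7 * ep$data[, 1, ]
  ep$data[, 2, ] <- 0.1 * ep$data[, 2, ]
  m2 <- time_varying_coherence(ep, c(1, 2), time_step = 0.1, freq_step = 2,
                               freq_range = c(4, 45))
  expect_equal(m1$values, m2$values, tolerance = 1e-10)
})

test_that("null coherence bias shrinks with the trial count", {
  m50 <- time_varying_coherence(noise_epochs(50, seed = 6), c(1, 2),
                                time_step = 0.1, freq_step = 2,
                                freq_range = c(4, 45))
  m200 <- time_varying_coherence(noise_epochs(200, seed = 6), c(1, 2),
                                 time_step = 0.1, freq_step = 2,
                                 freq_range = c(4, 45))
  expect_lt(mean(m200$values), mean(m50$values))
})

test_that("single-trial coherence is rejected as degenerate", {
  ep <- noise_epochs(1, seed = 7)
  expect_error(time_varying_coherence(ep, c(1, 2)), "trials")
})

test_that("dyad contrast flags an injected coherence difference only", {
  mk_maps <- function(n, rho, seed0) lapply(seq_len(n), function(i) {
    ep <- noise_epochs(40, rho = rho, seed = seed0 + i, ns = 750)
    time_varying_coherence(ep, c(1, 2), time_step = 0.1, freq_step = 2,
                           freq_range = c(4, 45))
  })
  dy1 <- mk_maps(6, rho = 0.35, seed0 = 10)
  dy2 <- mk_maps(6, rho = 0.0, seed0 = 40)
  res <- dyad_contrast(dy1, dy2, n_perm = 200, min_size = 10, seed = 1)
  expect_gte(length(res$clusters), 1)
  expect_lt(res$clusters[[1]]$p_cluster, 0.05)
  expect_equal(res$clusters[[1]]$sign, 1)
  # identical sets: nothing survives
  res0 <- dyad_contrast(dy1, dy1, n_perm = 100, min_size = 10, seed = 2)
  expect_length(res0$clusters, 0)
  expect_error(dyad_contrast(dy1[1:3], dy2), "at least 5")
})
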