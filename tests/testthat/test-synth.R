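# synthetic-data generators: VAR, burst/ERSP datasets, Jansen-Rit, ratings

test_that("VAR simulator reproduces closed-form moments", {
  # white noise: lag-1 autocorrelation ~ 0
  cs0 <- coupling_spec(matrix(0, 2, 2))
  ep0 <- simulate_var(cs0, small_paradigm(40), seed = 1)
  x <- as.vector(t(ep0$data[, 1, ]))
  r1 <- cor(x[-length(x)], x[-1])
  expect_lt(abs(r1), 0.05)

  # AR(1) a = 0.5: variance 1/(1 - 0.25) = 4/3
  cs1 <- coupling_spec(matrix(c(0.5, 0.4, 0, 0.5), 2, 2))
  ep1 <- simulate_var(cs1, small_paradigm(60), seed = 2)
  expect_equal(var(as.vector(ep1$data[, 1, ])), 4 / 3, tolerance = 0.05)

  # lower-triangular coupling: regression oracle finds x -> y, not y -> x
  x1 <- as.vector(t(ep1$data[, 1, ])); y1 <- as.vector(t(ep1$data[, 2, ]))
  n <- length(x1)
  fit <- lm(y1[-1] ~ x1[-n] + y1[-n])
  expect_gt(coef(fit)["x1[-n]"], 0.3)
  fit_rev <- lm(x1[-1] ~ x1[-n] + y1[-n])
  expect_lt(abs(coef(fit_rev)["y1[-n]"]), 0.02)
})

test_that("VAR simulator enforces stationarity and determinism", {
  expect_error(coupling_spec(matrix(c(1.05, 0, 0, 0.5), 2, 2)),
               "spectral radius")
  cs <- coupling_spec(matrix(c(0.5, 0.2, 0, 0.5), 2, 2))
  a <- simulate_var(cs, small_paradigm(3), seed = 7)
  b <- simulate_var(cs, small_paradigm(3), seed = 7)
  c <- simulate_var(cs, small_paradigm(3), seed = 8)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, c$data))
})

test_that("epoch geometry matches the paradigm at 500 Hz", {
  ep <- simulate_ersp_dataset(small_paradigm(2), seed = 1)
  expect_equal(dim(ep$data)[3], 1250)   # 250 baseline + 1000 post
  expect_equal(sum(epoch_times(ep) < 0), 250)
  expect_equal(sum(epoch_times(ep) >= 0), 1000)
})

test_that("effect-free dataset has matching baseline and post spectra", {
  ep <- simulate_ersp_dataset(paradigm_spec(), effects = list(), seed = 3)
  t <- epoch_times(ep)
  bp_base <- apply(ep$data[, 1, t < 0], 1, oracle_band_power,
                   fs = 500, band = c(8, 30))
  # same-duration post-stimulus segment for a like-for-like comparison
  post <- which(t >= 0)[1:250]
  bp_post <- apply(ep$data[, 1, post], 1, oracle_band_power,
                   fs = 500, band = c(8, 30))
  expect_gt(ks.test(bp_base, bp_post)$p.value, 0.01)
})

test_that("injected burst multiplies band power by the requested gain", {
  pd <- paradigm_spec(n_trials_per_condition = 200)
  eff <- list(burst_effect("negative", c(13, 30), c(1, 2), power_gain = 3))
  ep <- simulate_ersp_dataset(pd, eff, seed = 11)
  t <- epoch_times(ep)
  neg <- which(ep$conditions == "negative")
  win <- which(t >= 1 & t < 2)
  base <- which(t < 0)
  r_post <- mean(vapply(neg, function(i)
    oracle_band_power(ep$data[i, 1, win], 500, c(13, 30)), numeric(1)))
  r_base <- mean(vapply(neg, function(i)
    oracle_band_power(ep$data[i, 1, base], 500, c(13, 30)), numeric(1)))
  expect_equal(r_post / r_base, 2.0, tolerance = 0.1)
  # untouched condition stays flat
  neu <- which(ep$conditions == "neutral")[1:100]
  r_neu <- mean(vapply(neu, function(i)
    oracle_band_power(ep$data[i, 1, win], 500, c(13, 30)), numeric(1))) /
    mean(vapply(neu, function(i)
      oracle_band_power(ep$data[i, 1, base], 500, c(13, 30)), numeric(1)))
  expect_equal(r_neu, 1.0, tolerance = 0.1)
})

test_that("negative gains attenuate band power inside the window", {
  pd <- paradigm_spec(n_trials_per_condition = 150)
  eff <- list(burst_effect("negative", c(13, 30), c(0.5, 2), power_gain = -3))
  ep <- simulate_ersp_dataset(pd, eff, seed = 12)
  t <- epoch_times(ep)
  neg <- which(ep$conditions == "negative")
  win <- which(t >= 0.7 & t < 1.8)   # plateau, away from the ramps
  base <- which(t < 0)
  r <- mean(vapply(neg, function(i)
    oracle_band_power(ep$data[i, 1, win], 500, c(13, 30)), numeric(1))) /
    mean(vapply(neg, function(i)
      oracle_band_power(ep$data[i, 1, base], 500, c(13, 30)), numeric(1)))
  expect_equal(r, 10^(-0.3), tolerance = 0.12)
})

test_that("overlapping same-condition effects warn", {
  pd <- small_paradigm(2)
  eff <- list(burst_effect("negative", c(10, 20), c(0.5, 1.5), 3),
              burst_effect("negative", c(15, 25), c(1, 2), 3))
  expect_warning(simulate_ersp_dataset(pd, eff, seed = 1), "overlapping")
})

test_that("Jansen-Rit dyad oscillates in the alpha band", {
  ep <- simulate_jansen_rit_dyad(paradigm = small_paradigm(10), seed = 5)
  x <- as.vector(t(ep$data[, 1, ]))
  w <- oracle_welch(x, 500, seg = 500)
  pk <- w$f[w$f >= 2][which.max(w$p[w$f >= 2])]
  expect_gte(pk, 7); expect_lte(pk, 13)
  # linearised model agrees: stable slightly below the bifurcation, with a
  # resonance in the same band
  rp <- list(nmm_params(), nmm_params())
  fr <- seq(2, 45, 0.25)
  V <- dyadflow:::jr_transfer(rp, 0, 0, fr, rho_scale = 0.8)
  peak_lin <- fr[which.max(abs(V[1, 1, ])^2 * (1 / fr + 0.05))]
  expect_gte(peak_lin, 7); expect_lte(peak_lin, 13)
  expect_lt(dyadflow:::jr_linear_stability(rp, 0, 0, rho_scale = 0.8), 0)
})

test_that("uncoupled Jansen-Rit regions are incoherent", {
  pd <- paradigm_spec(n_trials_per_condition = 30)
  ep <- simulate_jansen_rit_dyad(coupling = c(forward = 0, backward = 0),
                                 paradigm = pd, seed = 6)
  coh <- time_varying_coherence(ep, c(1, 2), time_step = 0.05, freq_step = 1,
                                freq_range = c(2, 45))
  expect_lt(max(coh$values), 0.35)
  expect_lt(mean(coh$values), 0.15)
})

test_that("forward-coupled Jansen-Rit dyad shows directed GC", {
  pd <- paradigm_spec(n_trials_per_condition = 30)
  ep <- simulate_jansen_rit_dyad(coupling = c(forward = 15, backward = 0),
                                 paradigm = pd, seed = 7)
  sel <- select_order_aic(ep, m_max = 12)
  gc <- spectral_gc(fit_var(ep, order = sel$order),
                    freqs = seq(1, 45, 0.5))
  expect_gt(mean(gc$gc_xy), 2 * mean(gc$gc_yx))
})

test_that("rating generator recovers designed correlations", {
  pd <- small_paradigm(10)
  eff <- list(burst_effect("negative", c(13, 30), c(0, 2), 2))
  ep <- simulate_ersp_dataset(pd, eff, seed = 9)
  # noiseless slope -1: exact linear map
  tab <- simulate_ratings(ep, rating_model(slope = -1, noise_sd = 0),
                          band = c(13, 30), seed = 1)
  expect_equal(cor(tab$band_power_db, tab$rating), -1)
  # zero slope: ratings independent of power across patients
  rs <- vapply(1:30, function(s) {
    t2 <- simulate_ratings(ep, rating_model(slope = 0, noise_sd = 5),
                           band = c(13, 30), seed = s)
    cor(t2$band_power_db, t2$rating)
  }, numeric(1))
  expect_lt(abs(mean(rs)), 2 / sqrt(30))
  # band outside synthesis rejected
  expect_error(simulate_ratings(ep, rating_model(-1, 0), band = c(200, 400)),
               "band")
})

test_that("association study cohort hits the designed correlation", {
  tab <- simulate_association_study(n_patients = 100, seed = 13)
  r <- cor(tab$band_power_db, tab$rating_rel)
  # Fisher 95% interval around the design value -0.6 at n = 200 rows
  z <- atanh(-0.6); n <- nrow(tab)
  ci <- tanh(z + c(-1, 1) * 1.96 / sqrt(n - 3))
  expect_gt(r, ci[1]); expect_lt(r, ci[2])
  # ground-truth gain is faithfully measured by the power summary
  expect_gt(cor(tab$true_gain_db, tab$band_power_db), 0.9)
})
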