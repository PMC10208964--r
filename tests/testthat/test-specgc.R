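# multi-trial VAR fitting, AIC, Geweke spectral GC, permutation bounds

test_that("VAR coefficients are recovered consistently at scale", {
  A1 <- matrix(c(0.4, 0.3, 0, 0.3), 2, 2)
  A2 <- matrix(c(-0.3, 0.2, 0, -0.2), 2, 2)
  ep <- simulate_var(coupling_spec(list(A1, A2)),
                     small_paradigm(30), seed = 11)
  fit <- fit_var(ep, order = 2)
  expect_lt(max(abs(fit$coeffs[[1]] - A1)), 0.05)
  expect_lt(max(abs(fit$coeffs[[2]] - A2)), 0.05)
  # white noise: coefficients near zero
  ep0 <- simulate_var(coupling_spec(matrix(0, 2, 2)),
                      small_paradigm(30), seed = 12)
  fit0 <- fit_var(ep0, order = 1)
  expect_lt(max(abs(fit0$coeffs[[1]])), 0.02)
  expect_error(fit_var(ep, order = 0), "order")
})

test_that("AIC order selection brackets the generating order", {
  A <- list(matrix(0, 2, 2), matrix(0, 2, 2),
            matrix(c(0.4, 0.35, 0, 0.4), 2, 2))
  hits <- vapply(1:6, function(s) {
    ep <- simulate_var(coupling_spec(A), small_paradigm(30), seed = 100 + s)
    select_order_aic(ep, m_max = 8)$order
  }, numeric(1))
  expect_true(all(hits >= 3))
  # white noise: AIC picks a small order in the majority of runs
  # (occasional overselection by one or two lags is expected of AIC)
  wn <- vapply(1:7, function(s) {
    ep0 <- simulate_var(coupling_spec(matrix(0, 2, 2)), small_paradigm(10),
                        seed = 400 + s)
    select_order_aic(ep0, m_max = 8)$order
  }, numeric(1))
  expect_lte(median(wn), 2)
  # default m_max admits the 7-12 range seen in LFP pairs
  expect_gte(eval(formals(select_order_aic)$m_max), 12)
})

test_that("triangular models have exactly zero reverse-direction GC", {
  for (a in c(0.3, 0.5, 0.7)) {
    m <- structure(list(order = 1,
                        coeffs = list(matrix(c(a, 0.4, 0, a), 2, 2)),
                        sigma = diag(2), fs = 500), class = "var_model")
    g <- spectral_gc(m, freqs = seq(0, 250, 0.5))
    expect_lte(max(g$gc_yx), 1e-10)
    expect_gt(max(g$gc_xy), 0.01)
    expect_true(all(g$gc_xy >= 0) && all(g$gc_yx >= 0))
  }
})

test_that("band-integrated spectral GC matches time-domain GC", {
  models <- list(
    list(matrix(c(0.5, 0.4, 0, 0.5), 2, 2)),
    list(matrix(c(0.3, 0.5, 0, -0.4), 2, 2)),
    list(matrix(c(0.2, 0.3, 0, 0.3), 2, 2),
         matrix(c(-0.4, 0.25, 0, 0.2), 2, 2)))
  for (k in seq_along(models)) {
    cs <- coupling_spec(models[[k]])
    ep <- simulate_var(cs, paradigm_spec(n_trials_per_condition = 40),
                       seed = 200 + k)
    freqs <- seq(0, 250, by = 0.25)
    g <- spectral_gc(structure(list(order = length(models[[k]]),
                                    coeffs = models[[k]], sigma = diag(2),
                                    fs = 500), class = "var_model"), freqs)
    band_int <- mean(g$gc_xy)     # (fs/2)^-1 * integral over 0..fs/2
    x <- as.vector(t(ep$data[, 1, ])); y <- as.vector(t(ep$data[, 2, ]))
    td <- oracle_time_gc(y, x, order_full = length(models[[k]]) + 1)
    expect_lt(abs(band_int - td), 0.05 * td + 0.002)
  }
})

test_that("GC curves are scale invariant", {
  cs <- coupling_spec(matrix(c(0.5, 0.4, 0, 0.5), 2, 2))
  ep <- simulate_var(cs, small_paradigm(20), seed = 14)
  g1 <- spectral_gc(fit_var(ep, order = 2))
  ep$data[, 1, ] <- 12 * ep$data[, 1, ]
  ep$data[, 2, ] <- 0.3 * ep$data[, 2, ]
  g2 <- spectral_gc(fit_var(ep, order = 2))
  expect_equal(g1$gc_xy, g2$gc_xy, tolerance = 1e-8)
  expect_equal(g1$gc_yx, g2$gc_yx, tolerance = 1e-8)
})

test_that("permutation bounds separate driving from null directions", {
  cs <- coupling_spec(matrix(c(0.5, 0.4, 0, 0.5), 2, 2))
  ep <- simulate_var(cs, small_paradigm(30), seed = 15)
  g <- permutation_ci(ep, order = 2, n_perm = 300, seed = 16)
  low <- g$freqs <= 50
  expect_gt(mean(g$gc_xy[low] > g$ci_xy[low]), 0.9)  # driving direction out
  expect_lt(mean(g$gc_yx > g$ci_yx), 0.05)           # null direction inside
  expect_equal(g$granularity, 1 / 300)
  # block-shuffle scheme agrees qualitatively
  gb <- permutation_ci(ep, order = 2, n_perm = 120, scheme = "blocks",
                       seed = 17)
  expect_gt(mean(gb$gc_xy[low] > gb$ci_xy[low]), 0.75)
  expect_lt(mean(gb$gc_yx > gb$ci_yx), 0.05)
})

test_that("direction recovery holds across seeds", {
  cs <- coupling_spec(matrix(c(0.4, 0.45, 0, 0.4), 2, 2))
  wins <- vapply(1:10, function(s) {
    ep <- simulate_var(cs, small_paradigm(15), seed = 300 + s)
    g <- spectral_gc(fit_var(ep, order = 2))
    mean(g$gc_xy) > mean(g$gc_yx)
  }, logical(1))
  expect_true(all(wins))
})

test_that("dyad averaging returns exact means and SEMs", {
  f <- seq(0, 50, 1)
  mk <- function(val) structure(list(freqs = f, gc_xy = rep(val, length(f)),
                                     gc_yx = rep(0, length(f)), order = 2),
                                class = "gc_spectrum")
  one <- average_dyad(list(mk(1)))
  expect_equal(one$mean_xy, rep(1, length(f)))
  expect_equal(one$sem_xy, rep(0, length(f)))
  two <- average_dyad(list(mk(1), mk(3)))
  expect_equal(two$mean_xy, rep(2, length(f)))
  expect_equal(two$sem_xy, rep(1, length(f)))
  four <- average_dyad(list(mk(2), mk(2), mk(2), mk(2)))
  expect_equal(max(four$sem_xy), 0)
  expect_error(average_dyad(list()), "empty")
})
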