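# DCM-CSD: features, model space, forward model, inversion, BMS

test_that("CSD features are Hermitian with sensible dependence structure", {
  pd <- paradigm_spec(n_trials_per_condition = 25)
  ep <- simulate_jansen_rit_dyad(paradigm = pd, seed = 31)
  feat <- csd_features(ep, band = c(2, 45), freq_step = 1)
  for (cn in names(feat$csd)) {
    S <- feat$csd[[cn]]
    expect_equal(S[2, 1, ], Conj(S[1, 2, ]))
    expect_true(all(Re(S[1, 1, ]) > 0) && all(Re(S[2, 2, ]) > 0))
  }
  # independent channels: small normalised off-diagonals (the null level
  # scales as 1/sqrt(trials), so use a deep trial stack)
  dat <- array(rnorm(100 * 2 * 1250), c(100, 2, 1250))
  epw <- lfp_epochs(dat, 500, -0.5, rep("neutral", 100))
  fw <- csd_features(epw, band = c(2, 45), freq_step = 1)
  S <- fw$csd$neutral
  coh <- Mod(S[1, 2, ]) / sqrt(Re(S[1, 1, ]) * Re(S[2, 2, ]))
  expect_lt(max(coh), 0.35)
  expect_lt(mean(coh), 0.2)
  # identical channels: rank-1 at every frequency
  dat <- dat[1:25, , , drop = FALSE]
  dat[, 2, ] <- dat[, 1, ]
  epi <- lfp_epochs(dat, 500, -0.5, rep("neutral", 25))
  fi <- csd_features(epi, band = c(2, 45), freq_step = 1)
  S <- fi$csd$neutral
  for (k in c(1, 20, 44)) {
    ev <- eigen(S[, , k], only.values = TRUE)$values
    expect_gt(Re(ev[1]) / max(Re(ev[2]), 1e-30), 100)
  }
  expect_error(csd_features(ep, band = c(2, 400)), "Nyquist")
})

test_that("the model space holds eight valid dyadic hypotheses", {
  sp <- define_model_space("amygdala-mPFC")
  expect_length(sp, 8)
  for (m in sp) {
    expect_true(!m$mod_forward || m$forward)
    expect_true(!m$mod_backward || m$backward)
    expect_true(m$forward || m$backward)
  }
  # model 2 encodes the top-down (backward-only, modulated) hypothesis
  m2 <- sp[[2]]
  expect_false(m2$forward); expect_true(m2$backward)
  expect_true(m2$mod_backward); expect_false(m2$mod_forward)
  expect_equal(sum(vapply(sp, function(m) m$forward && m$backward,
                          logical(1))), 4)
})

test_that("the forward model decouples, peaks in alpha, scales with gain", {
  sp <- define_model_space()
  freqs <- seq(2, 45, 1)
  th0 <- list(tau = 0, taui = 0, rho = 0, amp1 = 0, amp2 = 0, obs = 0)
  # no coupling: off-diagonal exactly zero (independent innovations)
  null_model <- sp[[6]]; null_model$forward <- FALSE
  pr0 <- predict_csd(th0, null_model, u = 0, freqs)
  expect_true(all(Mod(pr0$S[1, 2, ]) == 0))
  # diagonal spectra peak in the alpha band at defaults
  pk <- freqs[which.max(Re(pr0$S[1, 1, ]))]
  expect_gte(pk, 7); expect_lte(pk, 13)
  # increasing forward gain monotonically increases coupling spectra
  peaks <- vapply(c(-3, -1, 0, 0.5), function(lg) {
    p <- predict_csd(c(th0, af = lg), sp[[6]], u = 0, freqs)
    max(Mod(p$S[1, 2, ]))
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
})

test_that("modulation follows the exp(B u) sign convention", {
  sp <- define_model_space()
  freqs <- seq(2, 45, 1)
  th <- list(tau = 0, taui = 0, rho = 0, af = 0, bf = 0.5,
             amp1 = 0, amp2 = 0, obs = 0)
  hi <- predict_csd(th, sp[[1]], u = 1, freqs)
  lo <- predict_csd(th, sp[[1]], u = -1, freqs)
  expect_gt(max(Mod(hi$S[1, 2, ])), max(Mod(lo$S[1, 2, ])))
})

test_that("self-inversion recovers the generating parameters and beats null", {
  sp <- define_model_space()
  model <- sp[[2]]                      # B + mod B
  freqs <- seq(2, 45, 1)
  # data generated at the prior means with tiny noise
  th_true <- c(tau = 0, taui = 0, rho = 0, ab = 0, bb = 0,
               amp1 = 0, amp2 = 0, obs = 0)
  conds <- c(positive = 1, neutral = 0, negative = -1)
  csd <- withr::with_seed(41, lapply(conds, function(u) {
    S <- predict_csd(as.list(th_true), model, u, freqs)$S
    S * (1 + 0.01 * rnorm(1))           # tiny multiplicative noise
  }))
  feat <- structure(list(freqs = freqs, csd = csd,
                         n_trials = setNames(rep(30, 3), names(conds)),
                         fs = 500), class = "csd_feature")
  fit <- invert_dcm(feat, model)
  expect_lt(max(abs(fit$theta[names(th_true)] - th_true) /
                  fit$prior_sd[names(th_true)]), 1)
  # the generating model beats an explicit connection-free null by > 3 nats
  null_model <- structure(list(forward = FALSE, backward = FALSE,
                               mod_forward = FALSE, mod_backward = FALSE,
                               name = "null", dyad = NA), class = "dcm_model")
  fit_null <- invert_dcm(feat, null_model)
  expect_gt(fit$F, fit_null$F + 3)
  # free energy never decreases across accepted iterations
  expect_true(all(diff(fit$trace) > -1e-6))
})

test_that("pure-noise features shrink the posterior to the prior", {
  freqs <- seq(2, 45, 1)
  sp <- define_model_space()
  mk <- function(seed) withr::with_seed(seed, {
    S <- array(0 + 0i, c(2, 2, length(freqs)))
    S[1, 1, ] <- 1 + 0.05 * rnorm(length(freqs))
    S[2, 2, ] <- 1 + 0.05 * rnorm(length(freqs))
    z <- 0.02 * complex(real = rnorm(length(freqs)),
                        imaginary = rnorm(length(freqs)))
    S[1, 2, ] <- z; S[2, 1, ] <- Conj(z)
    S
  })
  feat <- structure(list(
    freqs = freqs,
    csd = list(positive = mk(1), neutral = mk(2), negative = mk(3)),
    n_trials = c(positive = 30, neutral = 30, negative = 30), fs = 500),
    class = "csd_feature")
  fit <- invert_dcm(feat, sp[[2]], max_iter = 48)
  maha <- sqrt(sum((fit$theta / fit$prior_sd)^2) / length(fit$theta))
  expect_lt(maha, 1)
})

test_that("permuting frequency bins degrades the fit accuracy", {
  sp <- define_model_space()
  model <- sp[[7]]
  freqs <- seq(2, 45, 1)
  th <- c(tau = 0, taui = 0, rho = 0.1, ab = 0.2, amp1 = 0, amp2 = 0,
          obs = 0)
  S <- predict_csd(as.list(th), model, 0, freqs)$S
  feat <- structure(list(freqs = freqs, csd = list(neutral = S),
                         n_trials = c(neutral = 30), fs = 500),
                    class = "csd_feature")
  fit <- invert_dcm(feat, model, u_map = c(neutral = 0))
  perm <- withr::with_seed(7, sample(length(freqs)))
  featp <- feat; featp$csd$neutral <- S[, , perm]
  fitp <- invert_dcm(featp, model, u_map = c(neutral = 0))
  expect_gt(fit$F, fitp$F)
})

test_that("random-effects BMS honours symmetry, dominance, conservation", {
  # identical evidence: exceedance 1/K each
  F0 <- matrix(0, 12, 4)
  b0 <- bms_rfx(F0, seed = 1)
  expect_equal(b0$exceedance, rep(0.25, 4), tolerance = 0.05)
  expect_equal(sum(b0$exceedance), 1, tolerance = 1e-3)
  # Dirichlet conservation: sum(alpha) = sum(alpha0) + n_subjects
  expect_equal(sum(b0$alpha), 4 + 12)
  # one model better by 10 nats for 10 subjects dominates
  F1 <- matrix(0, 10, 4); F1[, 1] <- 10
  b1 <- bms_rfx(F1, seed = 2)
  expect_gt(b1$exceedance[1], 0.99)
  Fbad <- F1; Fbad[3, 2] <- NaN
  expect_error(bms_rfx(Fbad), "subject 3")
})

test_that("model recovery rejects empty cohorts", {
  expect_error(model_recovery(2, n_subjects = 0), "n_subjects")
})
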