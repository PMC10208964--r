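#' Simulate valence ratings linearly coupled to band power
#'
#' For one synthetic patient, computes per-condition post-stimulus band power
#' from the epochs, expresses it in dB relative to the neutral condition, and
#' maps it to a 0-100 valence rating through a [rating_model()]:
#' `rating = intercept + slope * power_dB_rel_neutral + N(0, noise_sd)`,
#' clipped to the scale.  The neutral condition receives
#' `intercept + N(0, noise_sd)` (its relative power is zero by definition).
#'
#' @param epochs an [lfp_epochs()] object for one patient.
#' @param model a [rating_model()].
#' @param band length-2 numeric, analysis band in Hz.
#' @param seed integer seed.
#' @param channel channel used for the power summary (default 1).
#' @param neutral label of the reference condition.
#' @return data.frame with columns condition, band_power_db (dB relative to
#'   neutral) and rating.
#' @export
simulate_ratings <- function(epochs, model, band, seed = 1, channel = 1,
                             neutral = "neutral") {
  stopifnot(inherits(epochs, "lfp_epochs"), inherits(model, "rating_model"))
  if (band[2] >= epochs$fs / 2) stop("band outside the synthesised range")
  conds <- unique(epochs$conditions)
  stopifnot(neutral %in% conds)
  pow <- vapply(conds, function(cn)
    condition_band_power(epochs, cn, channel, band), numeric(1))
  db_rel <- 10 * log10(pow / pow[neutral])
  with_seed(seed, {
    noise <- rnorm(length(conds), 0, model$noise_sd)
    rating <- model$intercept + model$slope * db_rel + noise
    rating <- pmin(pmax(rating, model$range[1]), model$range[2])
    data.frame(condition = conds, band_power_db = unname(db_rel),
               rating = unname(rating), row.names = NULL)
  })
}

# mean post-stimulus band power over kept trials of one condition
condition_band_power <- function(ep, condition, channel, band) {
  x <- kept_condition_data(ep, condition, channel)
  t <- epoch_times(ep)
  x <- x[, t >= 0, drop = FALSE]
  n <- ncol(x)
  f <- (0:(n - 1)) * ep$fs / n
  sel <- f >= band[1] & f <= band[2]
  P <- abs(mvfft(t(x)))^2 / n^2
  mean(colSums(P[sel, , drop = FALSE]) * 2)
}

#' Simulate a multi-patient power/rating association study
#'
#' Generates a cohort of synthetic patients whose condition band power carries
#' a patient-specific gain (positive condition centred at `+gain_shift` dB,
#' negative at `-gain_shift` dB, both with between-patient SD `gain_sd`) and
#' whose ratings follow a [rating_model()].  With the defaults (slope -6
#' ratings/dB, rating noise SD 8 per condition, condition shift 1 dB,
#' patient SD 1 dB) the population correlation between relative band power
#' and relative rating is approximately -0.6: the pooled power spread is
#' about 1.4 dB (patient variation + condition shift + estimation noise),
#' and relative ratings carry sqrt(2) * 8 units of noise, giving
#' rho = 6*1.4 / sqrt((6*1.4)^2 + 128) ~ 0.6.
#'
#' To keep the cohort cheap to generate, each patient's epochs contain
#' `n_trials_per_condition` trials of the 1/f background with the band gain
#' injected over the full post-stimulus window.
#'
#' @param n_patients cohort size.
#' @param band analysis band in Hz.
#' @param model a [rating_model()].
#' @param gain_shift per-condition mean gain in dB (positive condition gets
#'   `+gain_shift`, negative `-gain_shift`).
#' @param gain_sd between-patient SD of the gain in dB.
#' @param paradigm a [paradigm_spec()]; default uses 10 trials/condition for
#'   speed.
#' @param seed master seed.
#' @return data.frame with one row per patient x non-neutral condition:
#'   patient, condition, band_power_db, rating_rel (rating relative to
#'   neutral), true_gain_db.
#' @export
simulate_association_study <- function(n_patients, band = c(13, 30),
                                       model = rating_model(slope = -6,
                                                            noise_sd = 8),
                                       gain_shift = 1, gain_sd = 1,
                                       paradigm = paradigm_spec(n_trials_per_condition = 10),
                                       seed = 1) {
  rows <- vector("list", n_patients)
  for (p in seq_len(n_patients)) {
    sp <- derive_seed(seed, p)
    gains <- with_seed(derive_seed(sp, 1), c(
      positive = gain_shift + rnorm(1, 0, gain_sd),
      negative = -gain_shift + rnorm(1, 0, gain_sd)))
    effects <- list(
      burst_effect("positive", band, c(0, paradigm$stim_duration), gains["positive"]),
      burst_effect("negative", band, c(0, paradigm$stim_duration), gains["negative"]))
    ep <- simulate_ersp_dataset(paradigm, effects, n_channels = 1,
                                seed = derive_seed(sp, 2))
    tab <- simulate_ratings(ep, model, band, seed = derive_seed(sp, 3))
    neu <- tab$rating[tab$condition == "neutral"]
    keep <- tab$condition != "neutral"
    rows[[p]] <- data.frame(patient = p, condition = tab$condition[keep],
                            band_power_db = tab$band_power_db[keep],
                            rating_rel = tab$rating[keep] - neu,
                            true_gain_db = unname(gains[tab$condition[keep]]))
  }
  do.call(rbind, rows)
}
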