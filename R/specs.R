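#' Experimental paradigm description
#'
#' Captures the acquisition and trial-structure parameters of the
#' affective-picture paradigm: three valence conditions (positive, neutral,
#' negative), 30 trials each, 2 s picture presentation with a jittered 1-1.5 s
#' inter-trial interval, a 500 ms pre-stimulus baseline, and 500 Hz sampling.
#'
#' @param n_trials_per_condition trials per valence condition (default 30,
#'   i.e. 90 trials in total).
#' @param stim_duration stimulus presentation time in seconds.
#' @param iti_range length-2 numeric, uniform jitter range of the inter-trial
#'   interval in seconds.
#' @param baseline pre-stimulus baseline duration in seconds.
#' @param fs sampling rate in Hz.
#' @param conditions ordered condition labels.
#' @return An object of class `paradigm_spec`.
#' @export
paradigm_spec <- function(n_trials_per_condition = 30,
                          stim_duration = 2.0,
                          iti_range = c(1.0, 1.5),
                          baseline = 0.5,
                          fs = 500,
                          conditions = c("positive", "neutral", "negative")) {
  stopifnot(n_trials_per_condition >= 1, length(iti_range) == 2,
            iti_range[1] <= iti_range[2], fs > 0, baseline > 0,
            stim_duration > 0, length(conditions) >= 1)
  structure(list(
    n_trials_per_condition = as.integer(n_trials_per_condition),
    stim_duration = stim_duration,
    iti_range = iti_range,
    baseline = baseline,
    fs = fs,
    conditions = conditions
  ), class = "paradigm_spec")
}

#' @export
print.paradigm_spec <- function(x, ...) {
  cat("Paradigm:", x$n_trials_per_condition, "trials x",
      length(x$conditions), "conditions (",
      paste(x$conditions, collapse = ", "), ")\n")
  cat(sprintf("  fs %g Hz | baseline %.3g s | stimulus %.3g s | ITI %.3g-%.3g s\n",
              x$fs, x$baseline, x$stim_duration, x$iti_range[1], x$iti_range[2]))
  invisible(x)
}

# samples per epoch implied by the paradigm
epoch_samples <- function(paradigm) {
  n_base <- round(paradigm$baseline * paradigm$fs)
  n_post <- round(paradigm$stim_duration * paradigm$fs)
  c(baseline = n_base, post = n_post)
}

#' Band-limited condition effect
#'
#' A burst of induced band-limited power attached to one condition, expressed
#' as a dB gain over the background power in the same band, confined to a
#' post-stimulus time window.  Mimics the early-theta (0-1 s) / late-beta
#' (1-2 s) cluster layout of task-induced intracranial responses.
#'
#' @param condition condition label the effect is attached to.
#' @param band length-2 numeric, frequency band in Hz.
#' @param window length-2 numeric, time window in seconds relative to stimulus
#'   onset.
#' @param power_gain gain in dB over background band power (multiplicative in
#'   power: `10^(power_gain/10)`).
#' @return An object of class `burst_effect`.
#' @export
burst_effect <- function(condition, band, window, power_gain) {
  stopifnot(length(band) == 2, band[1] > 0, band[1] < band[2],
            length(window) == 2, window[1] >= 0, window[1] < window[2],
            is.numeric(power_gain), length(power_gain) == 1)
  structure(list(condition = condition, band = band, window = window,
                 power_gain = power_gain), class = "burst_effect")
}

#' Ground-truth VAR coupling description
#'
#' A vector-autoregressive generator used as directed-coupling ground truth
#' for the coherence and spectral Granger causality analyses.  Coefficients
#' are given per lag; an optional per-condition multiplier scales the
#' off-diagonal (between-channel) coefficients, emulating valence-modulated
#' coupling gain.
#'
#' @param var_coeffs list of k x k coefficient matrices, one per lag, or a
#'   single matrix for a VAR(1).
#' @param noise_cov innovation covariance (symmetric positive definite);
#'   defaults to the identity.
#' @param modulation_gain named numeric, per-condition multiplier applied to
#'   off-diagonal coefficients (default: none).
#' @return An object of class `coupling_spec`.
#' @export
coupling_spec <- function(var_coeffs, noise_cov = NULL, modulation_gain = NULL) {
  if (is.matrix(var_coeffs)) var_coeffs <- list(var_coeffs)
  stopifnot(length(var_coeffs) >= 1)
  k <- nrow(var_coeffs[[1]])
  for (A in var_coeffs) stopifnot(is.matrix(A), nrow(A) == k, ncol(A) == k)
  if (is.null(noise_cov)) noise_cov <- diag(k)
  stopifnot(nrow(noise_cov) == k, ncol(noise_cov) == k,
            isTRUE(all.equal(noise_cov, t(noise_cov))))
  ev <- eigen(noise_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("noise_cov must be positive definite (min eigenvalue ",
         format(min(ev)), ")")
  spec <- structure(list(var_coeffs = var_coeffs, noise_cov = noise_cov,
                         modulation_gain = modulation_gain),
                    class = "coupling_spec")
  rho <- companion_spectral_radius(var_coeffs)
  if (rho >= 1)
    stop("VAR coefficients are non-stationary: companion spectral radius ",
         format(rho, digits = 4), " >= 1")
  if (!is.null(modulation_gain)) {
    for (g in modulation_gain) {
      rho_g <- companion_spectral_radius(modulate_coeffs(var_coeffs, g))
      if (rho_g >= 1)
        stop("modulated VAR is non-stationary (spectral radius ",
             format(rho_g, digits = 4), ")")
    }
  }
  spec
}

# spectral radius of the VAR companion matrix; < 1 iff stationary
companion_spectral_radius <- function(var_coeffs) {
  k <- nrow(var_coeffs[[1]])
  p <- length(var_coeffs)
  comp <- matrix(0, k * p, k * p)
  for (j in seq_len(p)) comp[1:k, (j - 1) * k + 1:k] <- var_coeffs[[j]]
  if (p > 1) comp[(k + 1):(k * p), 1:(k * (p - 1))] <- diag(k * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

# scale off-diagonal (coupling) coefficients by g, keep diagonals
modulate_coeffs <- function(var_coeffs, g) {
  lapply(var_coeffs, function(A) {
    B <- A * g
    diag(B) <- diag(A)
    B
  })
}

#' Linear power-to-rating model
#'
#' Maps condition band power (dB relative to neutral) to a valence rating on
#' the 0-100 sliding scale through a linear relation with Gaussian noise;
#' generated ratings are clipped to the scale.
#'
#' @param slope rating units per dB.
#' @param noise_sd rating-unit standard deviation of the additive noise.
#' @param intercept rating at zero relative power (default 50, scale midpoint).
#' @param range length-2 clipping range of the scale.
#' @return An object of class `rating_model`.
#' @export
rating_model <- function(slope, noise_sd, intercept = 50, range = c(0, 100)) {
  stopifnot(noise_sd >= 0, length(range) == 2, range[1] < range[2])
  structure(list(slope = slope, noise_sd = noise_sd, intercept = intercept,
                 range = range), class = "rating_model")
}

# --- seeding ------------------------------------------------------------
# One master seed; per-unit substreams derived by a counter so that any
# trial/permutation/subject can be regenerated in isolation.  Knuth
# multiplicative hash keeps derived seeds spread out and below 2^31.
derive_seed <- function(master, counter) {
  as.integer((as.numeric(master) * 2654435761 + as.numeric(counter) * 40503) %%
               2147483629)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
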