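#' Simulate epoched LFP data with known band-limited condition effects
#'
#' Generates trial-structured data whose background is 1/f-shaped noise with a
#' white floor, stationary across baseline and post-stimulus, plus
#' condition-specific band-limited power bursts confined to post-stimulus
#' windows.  A burst with `power_gain` g dB multiplies the background band
#' power inside its window by `10^(g/10)` in expectation: the injected
#' component is band-pass noise, statistically independent of the background
#' (induced, not phase-locked), with a 100 ms raised-cosine on/off ramp and a
#' variance compensated for the ramp so that the average power over the whole
#' window hits the target.
#'
#' @param paradigm a [paradigm_spec()].
#' @param effects list of [burst_effect()] objects (may be empty).
#' @param n_channels number of (independent) channels.
#' @param seed master seed; per trial x channel streams derived by counter.
#' @param chi exponent of the 1/f^chi background.
#' @param white_floor white-noise floor of the background power spectrum,
#'   relative to the 1/f component at 1 Hz.
#' @param sigma2 total background variance per channel.
#' @return An [lfp_epochs()] object.
#' @export
simulate_ersp_dataset <- function(paradigm = paradigm_spec(), effects = list(),
                                  n_channels = 1, seed = 1,
                                  chi = 1, white_floor = 0.01, sigma2 = 1) {
  stopifnot(inherits(paradigm, "paradigm_spec"))
  for (e in effects) {
    stopifnot(inherits(e, "burst_effect"))
    if (!e$condition %in% paradigm$conditions)
      stop("effect condition '", e$condition, "' not in paradigm conditions")
    if (e$window[2] > paradigm$stim_duration + 1e-9)
      stop("effect window exceeds stimulus duration")
    if (e$band[2] >= paradigm$fs / 2)
      stop("effect band exceeds Nyquist")
  }
  warn_overlapping_effects(effects)
  fs <- paradigm$fs
  es <- epoch_samples(paradigm)
  ns <- sum(es)
  conds <- rep(paradigm$conditions, each = paradigm$n_trials_per_condition)
  nt <- length(conds)
  shape <- background_shape(ns, fs, chi, white_floor, sigma2)
  out <- array(0, dim = c(nt, n_channels, ns))
  t_rel <- -paradigm$baseline + (seq_len(ns) - 1) / fs
  for (i in seq_len(nt)) {
    for (ch in seq_len(n_channels)) {
      sig <- with_seed(derive_seed(seed, (i - 1) * n_channels + ch), {
        bg <- colored_noise_with_spectrum(shape)
        x <- bg$x
        for (e in effects) {
          if (e$condition != conds[i]) next
          if (e$power_gain >= 0) {
            # induced power increase: independent band-limited burst
            bvar <- band_variance(shape, e$band)
            target <- (10^(e$power_gain / 10) - 1) * bvar
            x <- x + burst_component(e, target, t_rel, fs)
          } else {
            # power decrease (desynchronisation): attenuate the in-band
            # background component inside the window, ramp-blended
            alpha <- 10^(e$power_gain / 20)
            xb <- inband_component(bg$X, fs, e$band)
            env <- window_envelope(e$window, t_rel, fs)
            x <- x + (alpha - 1) * env * xb
          }
        }
        x
      })
      out[i, ch, ] <- sig
    }
  }
  lfp_epochs(out, fs, -paradigm$baseline, conds)
}

warn_overlapping_effects <- function(effects) {
  if (length(effects) < 2) return(invisible())
  for (i in seq_len(length(effects) - 1)) for (j in (i + 1):length(effects)) {
    a <- effects[[i]]; b <- effects[[j]]
    if (a$condition == b$condition &&
        a$band[1] < b$band[2] && b$band[1] < a$band[2] &&
        a$window[1] < b$window[2] && b$window[1] < a$window[2])
      warning("overlapping effects on condition '", a$condition,
              "': powers are summed", call. = FALSE)
  }
  invisible()
}

# per-bin amplitude^2 of the background spectrum, normalised to variance sigma2
background_shape <- function(n, fs, chi, white_floor, sigma2) {
  kmax <- floor(n / 2)
  f <- (1:kmax) * fs / n
  a2 <- 1 / f^chi + white_floor
  # real signal: each positive-frequency bin contributes 2*a2/n^2 to variance
  nyq <- (n %% 2 == 0)
  w <- rep(2, kmax); if (nyq) w[kmax] <- 1
  a2 <- a2 * sigma2 / sum(w * a2 / n^2)
  list(n = n, fs = fs, f = f, a2 = a2, w = w)
}

# realisation plus its spectrum (for exact in-band decomposition)
colored_noise_with_spectrum <- function(shape) {
  n <- shape$n; kmax <- length(shape$f)
  z <- complex(real = rnorm(kmax), imaginary = rnorm(kmax)) / sqrt(2)
  if (shape$w[kmax] == 1) z[kmax] <- complex(real = rnorm(1), imaginary = 0)
  X <- complex(length.out = n)
  X[2:(kmax + 1)] <- sqrt(shape$a2) * z
  X[n + 2 - (2:(kmax + 1))] <- Conj(X[2:(kmax + 1)])
  list(x = Re(fft(X, inverse = TRUE)) / n, X = X)
}

# in-band part of a signal given its full spectrum
inband_component <- function(X, fs, band) {
  n <- length(X)
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)  # fold to physical frequency
  mask <- f >= band[1] & f <= band[2]
  Re(fft(X * mask, inverse = TRUE)) / n
}

# raised-cosine-edged window envelope over the full epoch time axis
window_envelope <- function(window, t_rel, fs, ramp_s = 0.1) {
  idx <- which(t_rel >= window[1] & t_rel < window[2])
  env <- numeric(length(t_rel))
  env[idx] <- raised_cosine_envelope(length(idx), fs,
                                     min(ramp_s, (length(idx) / fs) / 2))
  env
}

# one realisation of the shaped background (zero-mean real signal)
colored_noise <- function(shape) {
  n <- shape$n; kmax <- length(shape$f)
  z <- complex(real = rnorm(kmax), imaginary = rnorm(kmax)) / sqrt(2)
  if (shape$w[kmax] == 1) z[kmax] <- complex(real = rnorm(1), imaginary = 0)
  X <- complex(length.out = n)
  X[2:(kmax + 1)] <- sqrt(shape$a2) * z
  X[n + 2 - (2:(kmax + 1))] <- Conj(X[2:(kmax + 1)])
  Re(fft(X, inverse = TRUE)) / n  # R's inverse FFT is unnormalised
}

# expected variance contributed by bins inside [f1, f2]
band_variance <- function(shape, band) {
  idx <- shape$f >= band[1] & shape$f <= band[2]
  sum(shape$w[idx] * shape$a2[idx] / shape$n^2)
}

# band-limited burst of expected power `target` over its window, ramped
burst_component <- function(effect, target, t_rel, fs, ramp_s = 0.1) {
  idx <- which(t_rel >= effect$window[1] & t_rel < effect$window[2])
  nw <- length(idx)
  if (nw < 8) stop("effect window too short for the sampling rate")
  x <- bandlimited_noise(nw, fs, effect$band)
  env <- raised_cosine_envelope(nw, fs, min(ramp_s, (nw / fs) / 2))
  # compensate the ramp so mean power over the window equals `target`
  x <- x * env * sqrt(target / mean(env^2))
  out <- numeric(length(t_rel))
  out[idx] <- x
  out
}

# unit-variance noise with a flat spectrum confined to [f1, f2]
bandlimited_noise <- function(n, fs, band) {
  kmax <- floor(n / 2)
  f <- (1:kmax) * fs / n
  sel <- f >= band[1] & f <= band[2]
  if (!any(sel)) stop("band too narrow for window length")
  w <- rep(2, kmax); if (n %% 2 == 0) w[kmax] <- 1
  z <- complex(real = rnorm(kmax), imaginary = rnorm(kmax)) / sqrt(2)
  if (n %% 2 == 0) z[kmax] <- complex(real = rnorm(1), imaginary = 0)
  X <- complex(length.out = n)
  X[2:(kmax + 1)] <- ifelse(sel, z, 0 + 0i)
  X[n + 2 - (2:(kmax + 1))] <- Conj(X[2:(kmax + 1)])
  x <- Re(fft(X, inverse = TRUE)) / n
  x / sqrt(sum(w[sel] / n^2))  # analytic unit variance
}

raised_cosine_envelope <- function(n, fs, ramp_s) {
  nr <- max(1, round(ramp_s * fs))
  env <- rep(1, n)
  up <- 0.5 * (1 - cos(pi * (seq_len(nr) - 0.5) / nr))
  env[seq_len(nr)] <- up
  env[n - seq_len(nr) + 1] <- up
  env
}

#' Inject a brief high-amplitude transient into one trial
#'
#' Adds a smooth (Hann-shaped) transient to a single trial and channel, used
#' to exercise the automated spike-trial rejection rule.
#'
#' @param ep an [lfp_epochs()] object.
#' @param trial,channel indices of the target trial and channel.
#' @param at_s onset of the transient in seconds relative to stimulus onset.
#' @param width_s transient duration in seconds.
#' @param amplitude peak amplitude in signal units.
#' @return The modified `lfp_epochs` object.
#' @export
inject_transient <- function(ep, trial, channel, at_s, width_s, amplitude) {
  stopifnot(inherits(ep, "lfp_epochs"))
  t <- epoch_times(ep)
  idx <- which(t >= at_s & t < at_s + width_s)
  if (length(idx) == 0) stop("transient window outside the epoch")
  pulse <- amplitude * sin(pi * seq_along(idx) / (length(idx) + 1))^2
  ep$data[trial, channel, idx] <- ep$data[trial, channel, idx] + pulse
  ep
}
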