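# shared fixtures and small independent oracles

`%||%` <- function(a, b) if (is.null(a)) b else a

small_paradigm <- function(n = 10, fs = 500)
  paradigm_spec(n_trials_per_condition = n, fs = fs)

# band power of a signal segment by plain periodogram (oracle, independent
# of the package's spectral code paths)
oracle_band_power <- function(x, fs, band) {
  n <- length(x)
  P <- Mod(fft(x))^2 / n^2
  f <- (0:(n - 1)) * fs / n
  sum(P[f >= band[1] & f <= band[2]]) * 2
}

# Welch auto-spectrum with 50% overlapping Hann segments (oracle)
oracle_welch <- function(x, fs, seg = 256) {
  starts <- seq(1, length(x) - seg + 1, by = seg %/% 2)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg) / (seg + 1))
  P <- 0
  for (s in starts) P <- P + Mod(fft(x[s:(s + seg - 1)] * w))^2
  P <- P / length(starts)
  f <- (0:(seg - 1)) * fs / seg
  list(f = f[seq_len(seg %/% 2)], p = P[seq_len(seg %/% 2)])
}

# time-domain Granger causality oracle: ln(reduced/full residual variance),
# reduced model fitted by high-order AR to the target channel alone
oracle_time_gc <- function(x_target, x_source, order_full, order_reduced = 30) {
  n <- length(x_target)
  emb <- function(v, m) {
    T <- length(v)
    vapply(seq_len(m), function(l) v[(m + 1 - l):(T - l)], numeric(T - m))
  }
  m <- max(order_full, order_reduced)
  y <- x_target[(m + 1):n]
  Xr <- emb(x_target, m)[, seq_len(order_reduced), drop = FALSE]
  Xf <- cbind(emb(x_target, m)[, seq_len(order_full), drop = FALSE],
              emb(x_source, m)[, seq_len(order_full), drop = FALSE])
  v_red <- mean(lm.fit(Xr, y)$residuals^2)
  v_full <- mean(lm.fit(Xf, y)$residuals^2)
  log(v_red / v_full)
}

# quick Gaussian-noise tf_map stack for cluster tests
noise_maps <- function(n_contacts, nf, nt, sd = 1, seed = 1, add = NULL) {
  freqs <- seq_len(nf); times <- seq_len(nt) / 100
  withr::with_seed(seed, lapply(seq_len(n_contacts), function(i) {
    v <- matrix(rnorm(nf * nt, 0, sd), nf, nt)
    if (!is.null(add)) v <- v + add
    tf_map(v, freqs, times, units = "dB", channel = i)
  }))
}

# paired condition maps: each contact has a shared background plus
# condition-specific noise, so the paired DIFFERENCE has SD `diff_sd`
paired_noise_maps <- function(n_contacts, nf, nt, diff_sd = 1, seed = 1,
                              add = NULL) {
  freqs <- seq_len(nf); times <- seq_len(nt) / 100
  a <- list(); b <- list()
  withr::with_seed(seed, for (i in seq_len(n_contacts)) {
    shared <- matrix(rnorm(nf * nt), nf, nt)
    va <- shared + matrix(rnorm(nf * nt, 0, diff_sd / sqrt(2)), nf, nt)
    vb <- shared + matrix(rnorm(nf * nt, 0, diff_sd / sqrt(2)), nf, nt)
    if (!is.null(add)) va <- va + add
    a[[i]] <- tf_map(va, freqs, times, units = "dB", channel = i)
    b[[i]] <- tf_map(vb, freqs, times, units = "dB", channel = i)
  })
  list(a = a, b = b)
}
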