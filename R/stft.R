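# Sliding-window tapered FFT shared by the ERSP, coherence and CSD code.
#
# Windows that would cross the epoch edges are dropped; the time axis
# reports window-centre times.  The frequency grid is refined by
# zero-padding to round(fs / freq_step) points.

stft_grid <- function(ns, fs, t0, window_s, time_step, freq_step, freq_range) {
  win_n <- round(window_s * fs)
  if (win_n > ns) stop("analysis window longer than the epoch")
  step_n <- max(1L, round(time_step * fs))
  starts <- seq(1L, ns - win_n + 1L, by = step_n)
  times <- t0 + (starts - 1 + win_n / 2) / fs
  nfft <- max(win_n, round(fs / freq_step))
  f <- (0:(nfft %/% 2)) * fs / nfft
  fsel <- which(f >= freq_range[1] & f <= freq_range[2])
  if (length(fsel) == 0) stop("no frequencies inside freq_range")
  list(win_n = win_n, starts = starts, times = times, nfft = nfft,
       freqs = f[fsel], fsel = fsel,
       taper = 0.5 - 0.5 * cos(2 * pi * seq_len(win_n) / (win_n + 1)))
}

# complex sliding-window spectra of one trial: nfreq x ntime
stft_trial <- function(x, g) {
  seg <- matrix(0, g$nfft, length(g$starts))
  for (j in seq_along(g$starts))
    seg[seq_len(g$win_n), j] <- x[g$starts[j]:(g$starts[j] + g$win_n - 1)] * g$taper
  sp <- mvfft(seg)
  sp[g$fsel, , drop = FALSE]
}

# trial-averaged power (and optionally cross-spectra) for a channel set
stft_average <- function(ep, channels, trials, g) {
  nf <- length(g$freqs); ntm <- length(g$times)
  pow <- lapply(channels, function(i) matrix(0, nf, ntm))
  names(pow) <- as.character(channels)
  cross <- if (length(channels) == 2) matrix(0 + 0i, nf, ntm) else NULL
  for (tr in trials) {
    sps <- lapply(channels, function(ch) stft_trial(ep$data[tr, ch, ], g))
    for (k in seq_along(channels))
      pow[[k]] <- pow[[k]] + abs(sps[[k]])^2
    if (!is.null(cross)) cross <- cross + sps[[1]] * Conj(sps[[2]])
  }
  n <- length(trials)
  list(pow = lapply(pow, function(m) m / n),
       cross = if (!is.null(cross)) cross / n, n = n)
}
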