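#' Event-related spectral perturbation maps
#'
#' FFT-based ERSP: per trial, tapered (Hann) sliding-window power spectra;
#' trial-averaged per condition; converted to dB relative to the mean
#' baseline power per frequency, `10*log10(P(f,t) / Pbase(f))`, where the
#' baseline statistic is the mean power over window centres at or before
#' stimulus onset (divisive baseline).  The frequency grid step is achieved
#' by zero-padding the FFT; windows crossing the epoch edges are dropped, so
#' the time axis covers the valid range only.
#'
#' @param ep an [lfp_epochs()].
#' @param channel channel index or label.
#' @param freq_range length-2 numeric, Hz.
#' @param window_s taper length in seconds (default 0.512, i.e. 256 samples
#'   at 500 Hz).
#' @param time_step output time resolution in seconds.
#' @param freq_step output frequency resolution in Hz.
#' @param conditions conditions to map (default: all present among kept
#'   trials).
#' @return Named list of [tf_map()] objects (units dB), one per condition.
#' @export
compute_ersp <- function(ep, channel = 1, freq_range = c(2, 140),
                         window_s = 0.512, time_step = 0.002,
                         freq_step = 0.2, conditions = NULL) {
  stopifnot(inherits(ep, "lfp_epochs"))
  ch <- resolve_channel(ep, channel)
  if (freq_range[2] >= ep$fs / 2) stop("freq_range exceeds Nyquist")
  ns <- dim(ep$data)[3]
  g <- stft_grid(ns, ep$fs, ep$t0, window_s, time_step, freq_step, freq_range)
  if (is.null(conditions))
    conditions <- intersect(unique(ep$conditions), ep$conditions[ep$kept])
  base_idx <- which(g$times <= 0)
  if (length(base_idx) == 0)
    stop("no baseline window centres; shorten window_s or extend baseline")
  out <- list()
  for (cn in conditions) {
    trials <- which(ep$kept & ep$conditions == cn)
    if (length(trials) == 0) stop("no kept trials for condition ", cn)
    av <- stft_average(ep, ch, trials, g)
    P <- av$pow[[1]]
    base <- rowMeans(P[, base_idx, drop = FALSE])
    vals <- 10 * log10(sweep(P, 1, base, `/`))
    out[[cn]] <- tf_map(vals, g$freqs, g$times, units = "dB",
                        channel = ep$channel_labels[ch], condition = cn)
  }
  out
}

#' Subtract the neutral-condition ERSP map
#'
#' Element-wise difference of two ERSP maps on identical axes; used to
#' express positive and negative conditions relative to neutral before
#' statistics.
#'
#' @param map_cond [tf_map()] for the condition of interest.
#' @param map_neutral [tf_map()] for the neutral condition.
#' @return A [tf_map()] labelled `"<condition>-<neutral>"`.
#' @export
subtract_neutral <- function(map_cond, map_neutral) {
  stopifnot(inherits(map_cond, "tf_map"), inherits(map_neutral, "tf_map"))
  if (!same_axes(map_cond, map_neutral))
    stop("time-frequency axes differ between the two maps")
  tf_map(map_cond$values - map_neutral$values, map_cond$freqs, map_cond$times,
         units = map_cond$units, channel = map_cond$channel,
         condition = paste0(map_cond$condition, "-", map_neutral$condition))
}

#' Mean value inside a cluster mask
#'
#' @param map a [tf_map()].
#' @param mask logical matrix of the same shape.
#' @return The arithmetic mean (dB) of the masked values.
#' @export
cluster_mean <- function(map, mask) {
  stopifnot(inherits(map, "tf_map"), is.logical(mask),
            all(dim(mask) == dim(map$values)))
  if (!any(mask)) stop("empty cluster mask")
  mean(map$values[mask])
}
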