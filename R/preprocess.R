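#' Zero-phase FIR band-pass with power-line notches
#'
#' Applies a windowed-sinc (Hamming) linear-phase FIR band-pass followed by
#' narrow FIR band-stop notches at the line frequency and its harmonics
#' (below the passband edge).  Filters are applied in a single pass with
#' exact group-delay compensation, so the net phase response is zero.
#'
#' @param rec an [lfp_recording()].
#' @param band length-2 numeric passband in Hz.
#' @param line line frequency in Hz (harmonics are notched too).
#' @param notch_width full width of each notch in Hz.
#' @param transition transition bandwidth at the low edge in Hz; sets the
#'   band-pass filter order (Hamming: about `3.3 * fs / transition` taps).
#'   Defaults to the low band edge itself.
#' @return The filtered [lfp_recording()].
#' @export
bandpass_and_notch <- function(rec, band = c(0.1, 195), line = 50,
                               notch_width = 2, transition = NULL) {
  stopifnot(inherits(rec, "lfp_recording"), length(band) == 2,
            band[1] > 0, band[1] < band[2])
  fs <- rec$fs
  if (band[2] >= fs / 2)
    stop("band upper edge ", band[2], " Hz infeasible for fs ", fs, " Hz")
  if (is.null(transition)) transition <- band[1]
  n_bp <- fir_order(fs, transition)
  h_bp <- signal::fir1(n_bp, band / (fs / 2), type = "pass")
  x <- fir_zerophase(rec$data, h_bp)
  harmonics <- line * seq_len(floor(min(band[2], fs / 2 - 1) / line))
  n_nt <- fir_order(fs, notch_width / 2)
  for (f0 in harmonics) {
    h_nt <- signal::fir1(n_nt, c(f0 - notch_width / 2, f0 + notch_width / 2) / (fs / 2),
                         type = "stop")
    x <- fir_zerophase(x, h_nt)
  }
  rec$data <- x
  rec
}

# odd FIR order from Hamming transition-width rule
fir_order <- function(fs, transition) {
  n <- ceiling(3.3 * fs / transition)
  if (n %% 2 == 1) n <- n + 1  # even order -> odd length -> integer delay
  n
}

# single-pass FIR with exact group-delay compensation (zero net phase);
# FFT convolution, edges zero-padded.
fir_zerophase <- function(x, h) {
  d <- (length(h) - 1) / 2
  stopifnot(d == round(d))
  one <- function(v) {
    y <- convolve(v, rev(h), type = "open")
    y[(d + 1):(d + length(v))]
  }
  if (is.matrix(x)) t(apply(x, 1, one)) else one(x)
}

#' Downsample a recording with anti-alias filtering
#'
#' Applies a Hamming-window FIR low-pass at 90% of the new Nyquist frequency
#' and decimates by the (integer) factor `fs / target_fs`.  Event onsets are
#' remapped to the nearest new sample using round-half-to-even.
#'
#' @param rec an [lfp_recording()].
#' @param target_fs new sampling rate in Hz; must divide `fs`.
#' @return The downsampled [lfp_recording()].
#' @export
downsample_recording <- function(rec, target_fs = 500) {
  stopifnot(inherits(rec, "lfp_recording"))
  fs <- rec$fs
  if (target_fs > fs) stop("target_fs exceeds the current sampling rate")
  if (target_fs == fs) return(rec)
  k <- fs / target_fs
  if (abs(k - round(k)) > 1e-9)
    stop("target_fs must divide fs (rational resampling not supported)")
  k <- round(k)
  cutoff <- 0.9 * (target_fs / 2)
  h <- signal::fir1(fir_order(fs, 0.1 * target_fs / 2), cutoff / (fs / 2))
  x <- fir_zerophase(rec$data, h)
  idx <- seq(1, ncol(x), by = k)
  rec$data <- x[, idx, drop = FALSE]
  rec$fs <- target_fs
  if (nrow(rec$events)) {
    # 0-based time remap, round half to even, back to 1-based
    rec$events$onset <- as.integer(round((rec$events$onset - 1) / k) + 1)
    rec$events$onset <- pmin(pmax(rec$events$onset, 1L), ncol(rec$data))
  }
  rec
}

#' Bipolar re-referencing along electrode shafts
#'
#' Re-references to adjacent-contact differences within each shaft.  The
#' output channel for contacts `cA`, `cB` (geometric neighbours) is
#' `cA - cB`, labelled `"cA-cB"`.  The region label is inherited only when
#' both contacts share a region; mixed-region pairs are dropped (with a
#' message reporting the count).
#'
#' @param rec an [lfp_recording()].
#' @param shaft_layout named list; each element is a character vector of
#'   contact labels in geometric order along one shaft (>= 2 contacts).
#' @return An [lfp_recording()] of bipolar channels.
#' @export
bipolar_rereference <- function(rec, shaft_layout) {
  stopifnot(inherits(rec, "lfp_recording"), is.list(shaft_layout))
  rows <- list(); labels <- character(); regions <- character()
  dropped <- 0L
  for (shaft in shaft_layout) {
    stopifnot(length(shaft) >= 2)
    idx <- match(shaft, rec$channel_labels)
    if (anyNA(idx))
      stop("unknown contact(s) in layout: ",
           paste(shaft[is.na(idx)], collapse = ", "))
    for (j in seq_len(length(idx) - 1)) {
      a <- idx[j]; b <- idx[j + 1]
      ra <- rec$region_labels[a]; rb <- rec$region_labels[b]
      if (!identical(ra, rb) && !(is.na(ra) && is.na(rb))) {
        dropped <- dropped + 1L
        next
      }
      rows[[length(rows) + 1]] <- rec$data[a, ] - rec$data[b, ]
      labels <- c(labels, paste0(shaft[j], "-", shaft[j + 1]))
      regions <- c(regions, ra)
    }
  }
  if (dropped > 0)
    message(dropped, " mixed-region bipolar pair(s) dropped")
  if (length(rows) == 0) stop("no bipolar channels left after region gating")
  lfp_recording(do.call(rbind, rows), rec$fs, labels, regions, rec$events)
}

#' Cut a recording into stimulus-locked epochs
#'
#' Extracts `pre_s` seconds of baseline and `post_s` seconds after each event
#' onset (the onset sample is the first post-stimulus sample).  Events whose
#' window would cross the record boundary are retained in the bookkeeping but
#' marked rejected with reason `"edge"`.
#'
#' @param rec an [lfp_recording()] with events.
#' @param pre_s baseline duration in seconds.
#' @param post_s post-stimulus duration in seconds.
#' @return An [lfp_epochs()] with `t0 = -pre_s`.
#' @export
epoch_recording <- function(rec, pre_s = 0.5, post_s = 2.0) {
  stopifnot(inherits(rec, "lfp_recording"), nrow(rec$events) > 0)
  fs <- rec$fs
  n_pre <- round(pre_s * fs); n_post <- round(post_s * fs)
  ns <- n_pre + n_post
  nt <- nrow(rec$events); nc <- nrow(rec$data)
  out <- array(0, dim = c(nt, nc, ns))
  kept <- rep(TRUE, nt); reasons <- rep("", nt)
  for (i in seq_len(nt)) {
    on <- rec$events$onset[i]
    lo <- on - n_pre; hi <- on + n_post - 1
    if (lo < 1 || hi > ncol(rec$data)) {
      kept[i] <- FALSE; reasons[i] <- "edge"
      next
    }
    out[i, , ] <- rec$data[, lo:hi]
  }
  lfp_epochs(out, fs, -pre_s, rec$events$condition,
             channel_labels = rec$channel_labels,
             region_labels = rec$region_labels,
             kept = kept, reasons = reasons)
}

#' Automated spike-trial rejection
#'
#' Reproducible surrogate for visual rejection of inter-ictal spikes, defined
#' as paroxysmal discharges shorter than 250 ms: a trial is rejected when any
#' channel contains a contiguous excursion of `|z| > z_thresh` whose duration
#' is at most `max_width_s`, with z computed per channel from the median and
#' MAD over all kept trials' samples.  Sub-threshold dips shorter than 10 ms
#' inside an excursion are bridged, so a single smooth transient counts as
#' one excursion when noise briefly interrupts it.
#'
#' @param ep an [lfp_epochs()].
#' @param z_thresh robust z threshold.
#' @param max_width_s maximal excursion width counted as a spike, seconds.
#' @param min_trials minimal kept-trial count required for robust statistics.
#' @return The [lfp_epochs()] with spike trials marked rejected
#'   (reason `"spike"`).
#' @export
reject_spike_trials <- function(ep, z_thresh = 6, max_width_s = 0.25,
                                min_trials = 20) {
  stopifnot(inherits(ep, "lfp_epochs"))
  if (sum(ep$kept) < min_trials)
    stop("need at least ", min_trials, " kept trials for robust statistics")
  d <- dim(ep$data)
  max_w <- round(max_width_s * ep$fs)
  kept_idx <- which(ep$kept)
  for (ch in seq_len(d[2])) {
    vals <- as.vector(ep$data[kept_idx, ch, ])
    ctr <- median(vals); sc <- mad(vals)
    if (sc == 0) next
    gap_w <- round(0.01 * ep$fs)   # bridge sub-threshold dips < 10 ms
    for (i in kept_idx) {
      z <- abs(ep$data[i, ch, ] - ctr) / sc
      above <- z > z_thresh
      if (!any(above)) next
      r <- rle(above)
      if (length(r$lengths) > 2) {
        inner <- 2:(length(r$lengths) - 1)
        bridge <- inner[!r$values[inner] & r$lengths[inner] <= gap_w]
        r$values[bridge] <- TRUE
        r <- rle(inverse.rle(r))
      }
      if (any(r$values & r$lengths <= max_w)) {
        ep$kept[i] <- FALSE
        ep$reasons[i] <- "spike"
      }
    }
  }
  if (!any(ep$kept))
    stop("all trials rejected as spikes; review z_thresh/max_width_s")
  ep
}
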