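#' Trial-structured epoched LFP data
#'
#' Container for epoched data: a trials x channels x samples array with the
#' sampling rate, the time of the first sample relative to stimulus onset,
#' per-trial condition labels and a kept/rejected bookkeeping mask.
#'
#' @param data numeric array, trials x channels x samples.
#' @param fs sampling rate, Hz.
#' @param t0 time of the first sample relative to stimulus onset, seconds
#'   (negative for a pre-stimulus baseline).
#' @param conditions character vector, one condition label per trial.
#' @param channel_labels optional channel names.
#' @param region_labels optional region-of-interest label per channel.
#' @param kept logical per trial; `reasons` holds a reason code for rejected
#'   trials ("" for kept ones).
#' @param reasons character per trial.
#' @return An object of class `lfp_epochs`.
#' @export
lfp_epochs <- function(data, fs, t0, conditions,
                       channel_labels = NULL, region_labels = NULL,
                       kept = NULL, reasons = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3, fs > 0)
  nt <- dim(data)[1]; nc <- dim(data)[2]
  stopifnot(length(conditions) == nt)
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(nc))
  if (is.null(region_labels)) region_labels <- rep(NA_character_, nc)
  if (is.null(kept)) kept <- rep(TRUE, nt)
  if (is.null(reasons)) reasons <- rep("", nt)
  stopifnot(length(channel_labels) == nc, length(region_labels) == nc,
            length(kept) == nt, length(reasons) == nt)
  structure(list(data = data, fs = fs, t0 = t0,
                 conditions = as.character(conditions),
                 channel_labels = channel_labels,
                 region_labels = region_labels,
                 kept = kept, reasons = reasons),
            class = "lfp_epochs")
}

#' @export
print.lfp_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("LFP epochs: %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat(sprintf("  t0 = %.3f s; kept %d / %d trials\n",
              x$t0, sum(x$kept), d[1]))
  tab <- table(x$conditions[x$kept])
  cat("  conditions:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Time axis of an epochs object
#' @param ep an `lfp_epochs` object.
#' @return numeric vector of sample times in seconds relative to onset.
#' @export
epoch_times <- function(ep) {
  ep$t0 + (seq_len(dim(ep$data)[3]) - 1) / ep$fs
}

# subset trials (keeps bookkeeping aligned)
subset_trials <- function(ep, idx) {
  lfp_epochs(ep$data[idx, , , drop = FALSE], ep$fs, ep$t0,
             ep$conditions[idx], ep$channel_labels, ep$region_labels,
             ep$kept[idx], ep$reasons[idx])
}

# data for kept trials of one condition: trials x samples for one channel
kept_condition_data <- function(ep, condition = NULL, channel = NULL) {
  idx <- ep$kept
  if (!is.null(condition)) idx <- idx & ep$conditions == condition
  if (is.null(channel)) ep$data[idx, , , drop = FALSE]
  else ep$data[idx, channel, , drop = TRUE]
}

resolve_channel <- function(ep, channel) {
  if (is.character(channel)) {
    i <- match(channel, ep$channel_labels)
    if (is.na(i)) stop("channel '", channel, "' not found")
    i
  } else {
    stopifnot(channel >= 1, channel <= dim(ep$data)[2])
    as.integer(channel)
  }
}
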