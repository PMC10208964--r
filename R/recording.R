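#' Continuous multichannel LFP recording
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param fs sampling rate, Hz.
#' @param channel_labels character, one per channel.
#' @param region_labels region of interest per channel (e.g. amygdala, OFC,
#'   mPFC, other); `NA` allowed.
#' @param events data.frame with columns `onset` (sample index, 1-based) and
#'   `condition`.
#' @return An object of class `lfp_recording`.
#' @export
lfp_recording <- function(data, fs, channel_labels = NULL,
                          region_labels = NULL, events = NULL) {
  stopifnot(is.matrix(data), fs > 0)
  nc <- nrow(data)
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(nc))
  if (is.null(region_labels)) region_labels <- rep(NA_character_, nc)
  stopifnot(length(channel_labels) == nc, length(region_labels) == nc)
  if (is.null(events))
    events <- data.frame(onset = integer(0), condition = character(0))
  stopifnot(all(c("onset", "condition") %in% names(events)))
  if (nrow(events) && (min(events$onset) < 1 || max(events$onset) > ncol(data)))
    stop("event onsets outside the record")
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 region_labels = region_labels, events = events),
            class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("LFP recording: %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              nrow(x$events)))
  invisible(x)
}

#' Read an events table (tab-separated)
#'
#' Expects columns `onset_s` (seconds) and `condition`; optional `trial_id`.
#'
#' @param path file path.
#' @param fs sampling rate used to convert onsets to sample indices.
#' @return data.frame with columns `onset` (1-based sample) and `condition`.
#' @export
read_events_tsv <- function(path, fs) {
  ev <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("onset_s", "condition") %in% names(ev)))
  data.frame(onset = round(ev$onset_s * fs) + 1L,
             condition = ev$condition,
             stringsAsFactors = FALSE)
}

#' Write an events table (tab-separated)
#' @param rec an [lfp_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(rec, path) {
  ev <- data.frame(onset_s = (rec$events$onset - 1) / rec$fs,
                   condition = rec$events$condition,
                   trial_id = seq_len(nrow(rec$events)))
  write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
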