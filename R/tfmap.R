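#' Time-frequency map
#'
#' Frequency x time matrix with explicit axes: ERSP values in dB, or
#' magnitude coherence in [0, 1].
#'
#' @param values numeric matrix, frequencies x times.
#' @param freqs frequency axis, Hz (strictly increasing).
#' @param times time axis, seconds relative to stimulus onset.
#' @param units `"dB"` or `"coherence"`.
#' @param channel channel/contact identifier.
#' @param condition condition label.
#' @return An object of class `tf_map`.
#' @export
tf_map <- function(values, freqs, times, units = "dB",
                   channel = NA, condition = NA) {
  stopifnot(is.matrix(values), nrow(values) == length(freqs),
            ncol(values) == length(times), all(diff(freqs) > 0),
            all(is.finite(values)))
  structure(list(values = values, freqs = freqs, times = times,
                 units = units, channel = channel, condition = condition),
            class = "tf_map")
}

#' @export
print.tf_map <- function(x, ...) {
  cat(sprintf("TF map [%s]: %d freqs (%.2f-%.2f Hz) x %d times (%.3f-%.3f s)\n",
              x$units, length(x$freqs), min(x$freqs), max(x$freqs),
              length(x$times), min(x$times), max(x$times)))
  if (!is.na(x$condition)) cat("  condition:", x$condition, "\n")
  cat(sprintf("  range %.3f .. %.3f\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.tf_map <- function(x, main = NULL, ...) {
  if (is.null(main))
    main <- paste0(x$units, if (!is.na(x$condition)) paste0(" - ", x$condition))
  image(x$times, x$freqs, t(x$values), col = hcl.colors(64, "RdBu", rev = TRUE),
        xlab = "time (s)", ylab = "frequency (Hz)", main = main, ...)
  abline(v = 0, lty = 2)
  invisible(x)
}

same_axes <- function(a, b, tol = 1e-9) {
  length(a$freqs) == length(b$freqs) && length(a$times) == length(b$times) &&
    max(abs(a$freqs - b$freqs)) < tol && max(abs(a$times - b$times)) < tol
}
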