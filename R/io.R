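# Minimal hand-written EDF (European Data Format) continuous-recording
# reader/writer for interoperability: 16-bit integer samples, standard
# 256-byte header + 256 bytes per signal, one data-record length for all
# signals.  Covers plain EDF only (no EDF+ annotations).

#' Write a recording to an EDF file
#'
#' @param rec an [lfp_recording()]; data are physically scaled to the
#'   per-channel min/max and quantised to 16 bits.
#' @param path output path.
#' @param record_s data-record duration in seconds (default 1).
#' @return `path`, invisibly.  Events are not stored (write them with
#'   [write_events_tsv()]).
#' @export
write_edf <- function(rec, path, record_s = 1) {
  stopifnot(inherits(rec, "lfp_recording"))
  ns_rec <- round(record_s * rec$fs)
  nc <- nrow(rec$data)
  n_rec <- floor(ncol(rec$data) / ns_rec)
  if (n_rec < 1) stop("recording shorter than one data record")
  pad <- function(x, w) formatC(substr(as.character(x), 1, w), width = -w)
  phys_min <- apply(rec$data, 1, min); phys_max <- apply(rec$data, 1, max)
  same <- phys_max - phys_min < 1e-12
  phys_max[same] <- phys_min[same] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad("0", 8), pad("synthetic", 80), pad("dyadflow export", 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(256 * (nc + 1), 8), pad("", 44), pad(n_rec, 8),
    pad(format(record_s), 8), pad(nc, 4)), con, eos = NULL)
  fields <- list(
    pad(rec$channel_labels, 16), rep(pad("", 80), nc), rep(pad("uV", 8), nc),
    pad(sprintf("%.6g", phys_min), 8), pad(sprintf("%.6g", phys_max), 8),
    rep(pad("-32768", 8), nc), rep(pad("32767", 8), nc),
    rep(pad("", 80), nc), rep(pad(ns_rec, 8), nc), rep(pad("", 32), nc))
  for (f in fields) writeChar(paste(f, collapse = ""), con, eos = NULL)
  scale <- (phys_max - phys_min) / 65535
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * ns_rec + 1):(r * ns_rec)
    for (ch in seq_len(nc)) {
      dig <- round((rec$data[ch, idx] - phys_min[ch]) / scale[ch]) - 32768
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' @param path EDF file path.
#' @param events optional events data.frame (`onset`, `condition`) to attach.
#' @return An [lfp_recording()] (region labels NA; attach separately).
#' @export
read_edf <- function(path, events = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  num <- function(s) as.numeric(trimws(s))
  n_rec <- num(substr(hdr, 237, 244))
  record_s <- num(substr(hdr, 245, 252))
  nc <- as.integer(num(substr(hdr, 253, 256)))
  sig <- readChar(con, 256 * nc, useBytes = TRUE)
  fld <- function(off, w) {
    vapply(seq_len(nc), function(i)
      trimws(substr(sig, off + (i - 1) * w + 1, off + i * w)), character(1))
  }
  labels <- fld(0, 16)
  phys_min <- as.numeric(fld(nc * (16 + 80 + 8), 8))
  phys_max <- as.numeric(fld(nc * (16 + 80 + 8 + 8), 8))
  dig_min <- as.numeric(fld(nc * (16 + 80 + 8 + 16), 8))
  dig_max <- as.numeric(fld(nc * (16 + 80 + 8 + 24), 8))
  ns_rec <- as.integer(fld(nc * (16 + 80 + 8 + 32 + 80), 8))
  stopifnot(length(unique(ns_rec)) == 1)
  ns <- ns_rec[1]
  fs <- ns / record_s
  data <- matrix(0, nc, n_rec * ns)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(nc)) {
      dig <- readBin(con, integer(), n = ns, size = 2, endian = "little",
                     signed = TRUE)
      phys <- phys_min[ch] + (dig - dig_min[ch]) *
        (phys_max[ch] - phys_min[ch]) / (dig_max[ch] - dig_min[ch])
      data[ch, ((r - 1) * ns + 1):(r * ns)] <- phys
    }
  }
  lfp_recording(data, fs, channel_labels = labels, events = events)
}

#' Save an analysis artifact with a JSON sidecar
#'
#' Serialises any package object to RDS and writes a small JSON sidecar with
#' the class, creation time and a content hash, so pipeline outputs are
#' self-describing and stale caches detectable.
#'
#' @param obj object to save.
#' @param path `.rds` output path.
#' @return The md5 content hash, invisibly.
#' @export
save_artifact <- function(obj, path) {
  saveRDS(obj, path)
  h <- unname(tools::md5sum(path))
  meta <- list(class = class(obj)[1], md5 = h,
               created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(h)
}

#' Load an analysis artifact
#' @param path `.rds` path written by [save_artifact()].
#' @return The deserialised object.
#' @export
load_artifact <- function(path) readRDS(path)
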