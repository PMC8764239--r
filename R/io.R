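# Recording I/O: delimited numeric text with a JSON sidecar (primary,
# text-only format) and a minimal EDF (European Data Format) writer/reader
# pair. The EDF support covers the subset this package writes: one data
# record per second, 16-bit samples, identical rate across signals.

#' Write a recording as delimited text plus JSON sidecar
#'
#' One row per channel, tab-separated. Metadata (rate, labels, subject,
#' group) goes to `<path>.json`.
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording_text <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  utils::write.table(rec$data, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(sampling_rate = rec$sampling_rate,
               channel_labels = rec$channel_labels,
               subject_id = rec$subject_id, group_label = rec$group_label,
               units = "uV")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

read_recording_text <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop_input("missing metadata sidecar ", sidecar,
               " (needs sampling_rate and channel_labels)")
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (f in c("sampling_rate", "channel_labels")) {
    if (is.null(meta[[f]])) stop_input("sidecar ", sidecar,
                                       " lacks field \"", f, "\"")
  }
  x <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(x) <- NULL
  if (nrow(x) != length(meta$channel_labels)) {
    stop_input(path, ": ", nrow(x), " rows but sidecar declares ",
               length(meta$channel_labels), " channels")
  }
  eeg_recording(x, meta$sampling_rate, meta$channel_labels,
                subject_id = meta$subject_id %||% NA_character_,
                group_label = meta$group_label %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a recording as EDF
#'
#' Minimal EDF writer: 16-bit samples, one data record per second, physical
#' range taken from the data. The recording is truncated to a whole number
#' of seconds (EDF stores fixed-length records).
#'
#' @param rec An [eeg_recording()] with an integer sampling rate.
#' @param path Output `.edf` path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate
  if (fs != round(fs)) stop_input("EDF writer needs an integer sampling rate")
  ns <- nrow(rec$data)
  n_rec <- floor(ncol(rec$data) / fs)
  if (n_rec < 1) stop_input("recording shorter than one 1-s EDF record")
  x <- rec$data[, seq_len(n_rec * fs), drop = FALSE]
  pmin_ <- apply(x, 1, min)
  pmax_ <- apply(x, 1, max)
  pmax_[pmax_ <= pmin_] <- pmin_[pmax_ <= pmin_] + 1
  # quantize the physical range to what the 8-char header field can hold,
  # widening outward so all samples stay in range
  quant <- function(z, up) {
    for (dg in 7:1) {
      zz <- if (up) ceiling(z * 10^(dg - 1 - floor(log10(abs(z) + 1e-30)))) /
                    10^(dg - 1 - floor(log10(abs(z) + 1e-30)))
            else floor(z * 10^(dg - 1 - floor(log10(abs(z) + 1e-30)))) /
                 10^(dg - 1 - floor(log10(abs(z) + 1e-30)))
      s <- formatC(zz, format = "g", digits = dg)
      if (nchar(s) <= 8) return(as.numeric(s))
    }
    0
  }
  pmin_ <- vapply(pmin_, quant, 0, up = FALSE)
  pmax_ <- vapply(pmax_, quant, 0, up = TRUE)
  dmin <- -32768; dmax <- 32767
  pad <- function(s, w) {
    s <- substr(as.character(s), 1, w)
    paste0(s, strrep(" ", w - nchar(s)))
  }
  num <- function(v, w) {
    vapply(v, function(z) {
      for (dg in 7:1) {         # widest representation that fits the field
        s <- formatC(signif(z, dg), format = "g", digits = dg)
        if (nchar(s) <= w) return(pad(s, w))
      }
      pad("0", w)
    }, "")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad("0", 8),
    pad(rec$subject_id %||% "X", 80),
    pad("tinnconn synthetic recording", 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(256 * (1 + ns), 8), pad("", 44),
    pad(n_rec, 8), pad("1", 8), pad(ns, 4)
  ), con, eos = NULL)
  writeChar(paste0(
    paste0(vapply(rec$channel_labels, pad, "", w = 16), collapse = ""),
    strrep(pad("", 80), ns),
    strrep(pad("uV", 8), ns),
    paste0(num(pmin_, 8), collapse = ""),
    paste0(num(pmax_, 8), collapse = ""),
    strrep(pad(dmin, 8), ns),
    strrep(pad(dmax, 8), ns),
    strrep(pad("", 80), ns),
    strrep(pad(fs, 8), ns),
    strrep(pad("", 32), ns)
  ), con, eos = NULL)
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      seg <- x[ch, ((r - 1) * fs + 1):(r * fs)]
      dig <- as.integer(round((seg - pmin_[ch]) / scale[ch]) + dmin)
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Reads the subset of EDF written by [write_edf()] (uniform rate, 16-bit).
#'
#' @param path `.edf` file.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  if (nchar(hdr) < 256 || substr(hdr, 1, 1) != "0") {
    stop_input(path, ": not an EDF file (bad version field)")
  }
  fld <- function(s, from, w) trimws(substr(s, from, from + w - 1))
  subject <- fld(hdr, 9, 80)
  n_rec <- as.integer(fld(hdr, 237, 8))
  dur <- as.numeric(fld(hdr, 245, 8))
  ns <- as.integer(fld(hdr, 253, 4))
  if (is.na(ns) || ns < 1) stop_input(path, ": bad signal count")
  shdr <- readChar(con, 256 * ns, useBytes = TRUE)
  if (nchar(shdr) < 256 * ns) stop_input(path, ": truncated signal header")
  take <- function(offset, w) {
    vapply(seq_len(ns), function(i) {
      trimws(substr(shdr, offset * ns + (i - 1) * w + 1,
                    offset * ns + i * w))
    }, "")
  }
  labels <- take(0, 16)
  pmin_ <- as.numeric(substring_block(shdr, ns, 16 + 80 + 8, 8))
  pmax_ <- as.numeric(substring_block(shdr, ns, 16 + 80 + 8 + 8, 8))
  dmin <- as.numeric(substring_block(shdr, ns, 16 + 80 + 8 + 16, 8))
  dmax <- as.numeric(substring_block(shdr, ns, 16 + 80 + 8 + 24, 8))
  nsamp <- as.integer(substring_block(shdr, ns, 16 + 80 + 8 + 32 + 80, 8))
  if (length(unique(nsamp)) != 1L) {
    stop_input(path, ": mixed per-signal rates unsupported")
  }
  fs <- nsamp[1] / dur
  x <- matrix(0, ns, n_rec * nsamp[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = nsamp[1], size = 2, signed = TRUE,
                     endian = "little")
      if (length(dig) < nsamp[1]) stop_input(path, ": truncated data record")
      phys <- pmin_[ch] + (dig - dmin[ch]) *
        (pmax_[ch] - pmin_[ch]) / (dmax[ch] - dmin[ch])
      x[ch, ((r - 1) * nsamp[1] + 1):(r * nsamp[1])] <- phys
    }
  }
  eeg_recording(x, fs, labels, subject_id = subject)
}

# field blocks inside the EDF signal header: each field is repeated ns
# times with width w, starting after `before` bytes per signal
substring_block <- function(shdr, ns, before, w) {
  start <- before * ns
  vapply(seq_len(ns), function(i) {
    trimws(substr(shdr, start + (i - 1) * w + 1, start + i * w))
  }, "")
}

#' Read a recording, auto-detecting the format
#'
#' `.edf` files go through [read_edf()]; anything else is treated as
#' delimited text with a `.json` sidecar.
#'
#' @param path Input file.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  if (grepl("\\.edf$", path, ignore.case = TRUE)) read_edf(path)
  else read_recording_text(path)
}

#' Write dataset ground truth as JSON
#'
#' @param ground_truth Data.frame from [make_labeled_dataset()].
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  jsonlite::write_json(ground_truth, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
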