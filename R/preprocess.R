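# Zero-phase frequency-domain filtering.
#
# All filters share one mechanism: take the FFT of each channel, multiply by
# a real, non-negative frequency response H(|f|) and invert. A real symmetric
# response has exactly zero phase, unity in-band gain and is idempotent in
# the passband, which makes the response contracts directly testable.
# Transitions are raised-cosine to avoid ringing from brick-wall edges.

# raised cosine going 0 -> 1 over [a, b]
.rcos_up <- function(f, a, b) {
  y <- (f - a) / (b - a)
  y <- pmin(pmax(y, 0), 1)
  0.5 - 0.5 * cos(pi * y)
}

.apply_fft_filter <- function(data, sampling_rate, response_fn) {
  n <- ncol(data)
  freqs <- seq(0, n - 1) / n * sampling_rate
  freqs <- pmin(freqs, sampling_rate - freqs)  # fold to [0, fs/2]
  h <- response_fn(freqs)
  out <- t(apply(data, 1L, function(x) Re(fft(fft(x) * h, inverse = TRUE) / n)))
  dimnames(out) <- dimnames(data)
  out
}

#' Zero-phase band-pass filter
#'
#' Frequency-domain band-pass with raised-cosine transitions spanning a third
#' of an octave outside each edge, so attenuation one octave outside the
#' passband is complete while in-band gain is exactly one. DC is always
#' removed.
#'
#' @param rec An [eeg_recording()] (or epoch).
#' @param low_hz,high_hz Passband edges in Hz; `0 < low < high < rate/2`.
#' @return A filtered recording of the same class.
#' @export
bandpass_filter <- function(rec, low_hz = 0.5, high_hz = 90) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$sampling_rate / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stop_input("band edges must satisfy 0 < low < high < Nyquist (",
               nyq, " Hz); got [", low_hz, ", ", high_hz, "]")
  }
  lo_stop <- low_hz / 2^(1 / 3)   # third-octave transitions
  hi_stop <- high_hz * 2^(1 / 3)
  resp <- function(f) {
    .rcos_up(f, lo_stop, low_hz) * (1 - .rcos_up(f, high_hz, min(hi_stop, nyq)))
  }
  rec$data <- .apply_fft_filter(rec$data, rec$sampling_rate, resp)
  rec
}

#' Zero-phase notch (band-stop) filter
#'
#' Removes mains interference at `line_hz` with a stop band of
#' `line_hz +/- width_hz` and a 1 Hz raised-cosine transition on each side;
#' frequencies outside the transition are passed with exactly unit gain.
#'
#' @param rec An [eeg_recording()].
#' @param line_hz Line frequency, default 50 Hz.
#' @param width_hz Stop-band half width, default 2 Hz.
#' @return The filtered recording.
#' @export
notch_filter <- function(rec, line_hz = 50, width_hz = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$sampling_rate / 2
  if (line_hz >= nyq) stop_input("line frequency ", line_hz,
                                 " Hz is not below Nyquist (", nyq, " Hz)")
  trans <- 1
  resp <- function(f) {
    d <- abs(f - line_hz)
    1 - (1 - .rcos_up(d, width_hz, width_hz + trans))
  }
  rec$data <- .apply_fft_filter(rec$data, rec$sampling_rate, resp)
  rec
}

#' Baseline correction and re-referencing
#'
#' Subtracts each channel's mean (baseline correction), then re-references.
#' `"average"` subtracts the instantaneous mean across channels so the
#' channel-mean at every sample is zero. `"REST"` (reference electrode
#' standardization) needs a head model and is left as a named extension
#' point; requesting it raises a configuration error.
#'
#' @param rec An [eeg_recording()] with at least two channels.
#' @param method `"average"` (default) or `"REST"`.
#' @return The re-referenced recording.
#' @export
rereference <- function(rec, method = c("average", "REST")) {
  stopifnot(inherits(rec, "eeg_recording"))
  method <- match.arg(method)
  if (nrow(rec$data) < 2L) stop_input("re-referencing needs >= 2 channels")
  if (method == "REST") {
    stop_config("REST re-referencing requires a leadfield/head model; ",
                "none is bundled. Use method = \"average\".")
  }
  x <- rec$data - rowMeans(rec$data)          # baseline correction
  rec$data <- sweep(x, 2L, colMeans(x), "-")  # common average reference
  rec
}

#' Select the auditory-cortex channel subset
#'
#' Restrict a recording to the requested channels, in the requested order.
#' Defaults to the 12-channel auditory montage of [auditory_channels()].
#'
#' @param rec An [eeg_recording()].
#' @param names Channel labels to keep, in output order.
#' @return Recording containing exactly `names`.
#' @export
select_auditory_channels <- function(rec, names = auditory_channels()) {
  stopifnot(inherits(rec, "eeg_recording"))
  missing <- setdiff(names, rec$channel_labels)
  if (length(missing)) {
    stop_input("channel(s) not present in recording: ",
               paste(missing, collapse = ", "))
  }
  rec$data <- rec$data[match(names, rec$channel_labels), , drop = FALSE]
  rec$channel_labels <- names
  rec
}

#' Segment a recording into fixed-length epochs
#'
#' Cuts non-overlapping `epoch_s`-second epochs from the start of the
#' recording; a trailing remainder shorter than one epoch is discarded.
#' Group labels propagate to every epoch.
#'
#' @param rec An [eeg_recording()].
#' @param epoch_s Epoch length in seconds, default 10.
#' @return List of [eeg_epoch()] objects.
#' @export
segment_epochs <- function(rec, epoch_s = 10) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (epoch_s <= 0) stop_input("`epoch_s` must be positive")
  len <- round(epoch_s * rec$sampling_rate)
  n_ep <- floor(ncol(rec$data) / len)
  if (n_ep < 1L) {
    stop_input("recording (", rec_duration(rec), " s) shorter than one ",
               epoch_s, " s epoch")
  }
  lapply(seq_len(n_ep), function(i) {
    idx <- ((i - 1L) * len + 1L):(i * len)
    eeg_epoch(rec$data[, idx, drop = FALSE], rec$sampling_rate,
              rec$channel_labels, label = rec$group_label,
              epoch_id = i, subject_id = rec$subject_id)
  })
}

#' Amplitude-threshold epoch rejection
#'
#' Default stand-in for artifact rejection: an epoch is dropped when any
#' sample exceeds `threshold_uv` in magnitude. Pass `threshold_uv = Inf`
#' to disable.
#'
#' @param epochs List of [eeg_epoch()].
#' @param threshold_uv Rejection threshold in microvolts, default 100.
#' @return The surviving epochs.
#' @export
reject_epochs <- function(epochs, threshold_uv = 100) {
  keep <- vapply(epochs, function(e) max(abs(e$data)) <= threshold_uv,
                 logical(1))
  epochs[keep]
}

#' Bad-lead interpolation hook
#'
#' Placeholder for interpolation of bad leads. The criterion and method are
#' acquisition-specific, so the default is the identity; supply `fn` to plug
#' in a real implementation.
#'
#' @param rec An [eeg_recording()].
#' @param fn Optional function `rec -> rec`.
#' @return The (possibly repaired) recording.
#' @export
interpolate_channels <- function(rec, fn = NULL) {
  if (is.null(fn)) rec else fn(rec)
}

#' Run the full preprocessing chain
#'
#' Fixed stage order: interpolation hook, notch, band-pass, baseline
#' correction + re-reference, channel selection, segmentation, amplitude
#' rejection. Matching the acquisition narrative this mirrors, the order is
#' not configurable; individual stages can be disabled through `config`.
#'
#' @param rec Raw [eeg_recording()].
#' @param config List of preprocessing parameters; see [default_config()]
#'   element `preprocess`. Missing entries fall back to the defaults.
#' @return List of clean [eeg_epoch()] objects.
#' @export
preprocess_recording <- function(rec, config = list()) {
  cfg <- modifyList(default_config()$preprocess, config)
  rec <- interpolate_channels(rec)
  if (!is.null(cfg$notch_hz) && !is.na(cfg$notch_hz)) {
    rec <- notch_filter(rec, cfg$notch_hz, cfg$notch_width_hz)
  }
  rec <- bandpass_filter(rec, cfg$band_low_hz, cfg$band_high_hz)
  rec <- rereference(rec, cfg$reference)
  if (!is.null(cfg$channels) && !identical(cfg$channels, rec$channel_labels)) {
    rec <- select_auditory_channels(rec, cfg$channels)
  }
  epochs <- segment_epochs(rec, cfg$epoch_s)
  reject_epochs(epochs, cfg$reject_uv)
}
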