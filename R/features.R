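# Time-frequency comparison features and the per-epoch feature assembler.

#' Band-rhythm statistics
#'
#' For every channel and frequency band, the mean and standard deviation of
#' the band-filtered signal. Layout is channel-major, band-minor, with
#' (mean, sd) innermost: `ch1.delta.mean, ch1.delta.sd, ch1.theta.mean, ...`;
#' length `channels x bands x 2` (144 for the 12-channel montage).
#'
#' @param epoch An [eeg_epoch()].
#' @param bands Band table as from [eeg_bands()].
#' @return Named numeric vector with attribute `layout`.
#' @export
rhythm_stats <- function(epoch, bands = eeg_bands()) {
  stopifnot(inherits(epoch, "eeg_recording"))
  n <- nrow(epoch$data)
  out <- numeric(0)
  nm <- character(0)
  filtered <- lapply(seq_len(nrow(bands)), function(b) {
    band_filter_data(epoch, c(bands$low_hz[b], bands$high_hz[b]))
  })
  for (ch in seq_len(n)) {
    for (b in seq_len(nrow(bands))) {
      x <- filtered[[b]][ch, ]
      out <- c(out, mean(x), stats::sd(x))
      nm <- c(nm, paste0(epoch$channel_labels[ch], ".", bands$name[b],
                         c(".mean", ".sd")))
    }
  }
  names(out) <- nm
  attr(out, "layout") <- "rhythm_ch_band_meansd_v1"
  out
}

#' Welch band-power features
#'
#' Per-channel power spectral density by Welch's averaged modified
#' periodogram (Hann window, 50% overlap), integrated over the six bands.
#' Length `channels x 6` (72 for the 12-channel montage). The one-sided
#' PSD is normalized so that its integral over all frequencies equals the
#' signal variance (Parseval).
#'
#' @param epoch An [eeg_epoch()].
#' @param window_s Welch segment length in seconds (default 1). Must give a
#'   segment of at least 8 samples no longer than half the epoch.
#' @param bands Band table as from [eeg_bands()].
#' @return Named numeric vector of band powers with attribute `layout`.
#' @export
psd_features <- function(epoch, window_s = 1, bands = eeg_bands()) {
  stopifnot(inherits(epoch, "eeg_recording"))
  fs <- epoch$sampling_rate
  nper <- round(window_s * fs)
  if (nper < 8 || nper * 2 > ncol(epoch$data)) {
    stop_input("Welch window of ", window_s,
               " s is incompatible with an epoch of ",
               ncol(epoch$data) / fs, " s")
  }
  out <- numeric(0)
  nm <- character(0)
  for (ch in seq_len(nrow(epoch$data))) {
    w <- welch_psd(epoch$data[ch, ], fs, nper)
    for (b in seq_len(nrow(bands))) {
      sel <- w$freq >= bands$low_hz[b] & w$freq <= bands$high_hz[b]
      df <- w$freq[2] - w$freq[1]
      out <- c(out, sum(w$psd[sel]) * df)
      nm <- c(nm, paste0(epoch$channel_labels[ch], ".", bands$name[b], ".power"))
    }
  }
  names(out) <- nm
  attr(out, "layout") <- "psd_ch_bandpower_v1"
  out
}

#' Welch power spectral density of one signal
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz.
#' @param nper Samples per segment.
#' @return List with `freq` (Hz) and `psd` (power per Hz, one-sided).
#' @export
welch_psd <- function(x, fs, nper) {
  step <- floor(nper / 2)
  starts <- seq(1, length(x) - nper + 1, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, nper - 1) / nper)  # Hann
  u <- sum(win^2)
  acc <- numeric(floor(nper / 2) + 1)
  for (s in starts) {
    seg <- x[s:(s + nper - 1)]
    seg <- (seg - mean(seg)) * win
    sp <- Mod(fft(seg))^2 / (u * fs)
    half <- sp[seq_len(length(acc))]
    # fold negative frequencies into the one-sided density
    half[2:(length(half) - if (nper %% 2 == 0) 1 else 0)] <-
      2 * half[2:(length(half) - if (nper %% 2 == 0) 1 else 0)]
    acc <- acc + half
  }
  list(freq = seq(0, length(acc) - 1) * fs / nper, psd = acc / length(starts))
}

#' Assemble per-epoch feature vectors
#'
#' Maps a feature extractor over a list of epochs and returns the
#' classifier-ready design: a numeric matrix (epochs x features) plus the
#' label vector. Connectivity measures are flattened with
#' [flatten_connectivity()]; `"rhythm"` and `"psd"` use the time-frequency
#' extractors.
#'
#' @param epochs List of [eeg_epoch()].
#' @param feature One of `"plv"`, `"pli"`, `"pcc"`, `"te"`, `"rhythm"`,
#'   `"psd"`, or a vector of them (feature blocks are concatenated, e.g.
#'   `c("plv", "pcc")`).
#' @param band Band for the phase measures, default `"broadband"`.
#' @param te_bins,te_lag TE parameters.
#' @param te_layout `"directed"` (length `n(n-1)`) or `"symmetric"`
#'   (directions averaged, length `n(n-1)/2`).
#' @return List with `x` (matrix), `labels` (character), `feature_name`,
#'   and `layout`.
#' @export
extract_features <- function(epochs, feature = "pcc", band = "broadband",
                             te_bins = 4, te_lag = 1,
                             te_layout = c("directed", "symmetric")) {
  te_layout <- match.arg(te_layout)
  if (!length(epochs)) stop_input("no epochs supplied")
  known <- c("plv", "pli", "pcc", "te", "rhythm", "psd")
  bad <- setdiff(feature, known)
  if (length(bad)) stop_input("unknown feature(s): ", paste(bad, collapse = ", "))
  one <- function(ep) {
    blocks <- lapply(feature, function(f) {
      if (f %in% c("plv", "pli", "pcc", "te")) {
        m <- connectivity_matrix(ep, f, band = band, bins = te_bins, lag = te_lag)
        if (f == "te" && te_layout == "symmetric") {
          sym <- (unclass(m) + t(unclass(m))) / 2
          flatten_connectivity(sym, directed = FALSE)
        } else {
          flatten_connectivity(m)
        }
      } else if (f == "rhythm") {
        rhythm_stats(ep)
      } else {
        psd_features(ep)
      }
    })
    do.call(c, blocks)
  }
  first <- one(epochs[[1]])
  x <- matrix(NA_real_, length(epochs), length(first),
              dimnames = list(NULL, names(first)))
  x[1, ] <- first
  if (length(epochs) > 1) {
    for (i in 2:length(epochs)) x[i, ] <- one(epochs[[i]])
  }
  list(x = x,
       labels = vapply(epochs, function(e) as.character(e$label), character(1)),
       feature_name = paste(feature, collapse = "+"),
       layout = attr(first, "layout"))
}
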