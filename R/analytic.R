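#' Analytic signal via the discrete Hilbert transform
#'
#' Returns the complex analytic representation of a real signal (FFT method:
#' zero negative frequencies, double positive ones). For a matrix, channels
#' are rows and the transform is applied per row.
#'
#' @param x Numeric vector or channels x samples matrix.
#' @return Complex vector/matrix of the same shape.
#' @export
analytic_signal <- function(x) {
  one <- function(v) {
    n <- length(v)
    h <- numeric(n)
    if (n %% 2 == 0) {
      h[c(1, n / 2 + 1)] <- 1
      h[2:(n / 2)] <- 2
    } else {
      h[1] <- 1
      h[2:((n + 1) / 2)] <- 2
    }
    fft(fft(v) * h, inverse = TRUE) / n
  }
  if (is.matrix(x)) t(apply(x, 1L, one)) else one(x)
}

#' Instantaneous phase of a band-limited signal
#'
#' Band-filters the epoch (unless `band = "broadband"`, which uses the data
#' as is, assumed already band-passed by preprocessing), then takes the
#' angle of the analytic signal. Phases lie in (-pi, pi].
#'
#' @param epoch An [eeg_epoch()] or [eeg_recording()].
#' @param band `"broadband"`, a band name from [eeg_bands()], or a
#'   `c(low, high)` numeric pair in Hz.
#' @return Channels x samples matrix of phases in radians.
#' @export
analytic_phase <- function(epoch, band = "broadband") {
  stopifnot(inherits(epoch, "eeg_recording"))
  x <- band_filter_data(epoch, band)
  ph <- Arg(analytic_signal(x))
  # Arg returns [-pi, pi]; map the closed lower edge onto +pi
  ph[ph <= -pi] <- pi
  ph
}

#' Band-limited analytic signal
#'
#' Complex time-frequency representation of each channel in a given band:
#' the analytic signal of the band-filtered epoch. This is the input the
#' phase lag index is defined on.
#'
#' @inheritParams analytic_phase
#' @return Complex channels x samples matrix.
#' @export
band_analytic_signal <- function(epoch, band = "broadband") {
  stopifnot(inherits(epoch, "eeg_recording"))
  analytic_signal(band_filter_data(epoch, band))
}

# resolve a band spec and return the (filtered) data matrix
band_filter_data <- function(epoch, band) {
  if (identical(band, "broadband")) return(epoch$data)
  if (is.character(band) && length(band) == 1L) {
    bands <- eeg_bands()
    row <- bands[bands$name == band, ]
    if (nrow(row) == 0L) {
      stop_input("unknown band \"", band, "\"; known: ",
                 paste(bands$name, collapse = ", "), " or \"broadband\"")
    }
    band <- c(row$low_hz, row$high_hz)
  }
  if (!is.numeric(band) || length(band) != 2L) {
    stop_input("`band` must be \"broadband\", a band name, or c(low, high)")
  }
  bandpass_filter(epoch, band[1], band[2])$data
}
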