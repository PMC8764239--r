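#' Multichannel EEG recording
#'
#' Construct the raw container every pipeline stage consumes: a channels x
#' samples numeric matrix in microvolts together with its sampling rate and
#' 10-20 channel labels.
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_labels Character vector of unique channel names, one per row.
#' @param subject_id Optional subject identifier.
#' @param group_label Optional group label (e.g. `"healthy"`, `"left"`).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sampling_rate, channel_labels,
                          subject_id = NA_character_,
                          group_label = NA_character_) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop_input("`data` must be a numeric channels x samples matrix")
  }
  if (ncol(data) < 1L) stop_input("recording has no samples")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) {
    stop_input("`sampling_rate` must be a single positive number")
  }
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data)) {
    stop_input("got ", length(channel_labels), " labels for ",
               nrow(data), " channels")
  }
  if (anyDuplicated(channel_labels)) {
    stop_input("channel labels must be unique")
  }
  rownames(data) <- channel_labels
  structure(
    list(data = data, sampling_rate = as.numeric(sampling_rate),
         channel_labels = channel_labels,
         subject_id = subject_id, group_label = group_label),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              ncol(x$data) / x$sampling_rate))
  cat("  channels:", paste(x$channel_labels, collapse = " "), "\n")
  if (!is.na(x$group_label)) cat("  group:", x$group_label, "\n")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

rec_duration <- function(rec) ncol(rec$data) / rec$sampling_rate

#' Fixed-duration EEG epoch
#'
#' One segment of a recording: the unit of feature extraction. Same layout
#' as [eeg_recording()] plus its duration and the class label it inherits.
#'
#' @param data Channels x samples numeric matrix, microvolts.
#' @param sampling_rate Hz.
#' @param channel_labels Channel names.
#' @param label Group label carried to the classifiers.
#' @param epoch_id Identifier within the parent recording.
#' @param subject_id Parent subject.
#' @return An object of class `eeg_epoch`.
#' @export
eeg_epoch <- function(data, sampling_rate, channel_labels,
                      label = NA_character_, epoch_id = NA_integer_,
                      subject_id = NA_character_) {
  rec <- eeg_recording(data, sampling_rate, channel_labels,
                       subject_id = subject_id, group_label = label)
  out <- unclass(rec)
  out$label <- label
  out$epoch_id <- epoch_id
  out$duration <- ncol(data) / sampling_rate
  structure(out, class = c("eeg_epoch", "eeg_recording"))
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch> %d channels, %g s @ %g Hz, label=%s, id=%s\n",
              nrow(x$data), x$duration, x$sampling_rate,
              x$label, x$epoch_id))
  invisible(x)
}
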