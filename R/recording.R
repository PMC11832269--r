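#' Construct a multichannel EEG recording
#'
#' Container for one subject's continuous signal: a channels-by-samples
#' numeric matrix in microvolts, the sampling rate, ordered channel names,
#' and the reference state (`"raw"` before mastoid re-referencing,
#' `"mastoid-average"` after).
#'
#' @param data Numeric matrix, channels x samples, microvolts.
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector, one name per row of `data`.
#' @param subject_id Subject identifier.
#' @param reference `"raw"` or `"mastoid-average"`.
#' @return Object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_names, subject_id = "unknown",
                          reference = c("raw", "mastoid-average")) {
  reference <- match.arg(reference)
  if (!is.matrix(data) || !is.numeric(data)) stopf("'data' must be a numeric matrix")
  if (nrow(data) != length(channel_names)) {
    stopf("row count of 'data' (%d) must equal length of 'channel_names' (%d)",
          nrow(data), length(channel_names))
  }
  if (!(is.numeric(fs) && length(fs) == 1 && fs > 0)) stopf("'fs' must be > 0")
  if (any(!is.finite(data))) stopf("'data' contains non-finite samples")
  rownames(data) <- channel_names
  structure(
    list(data = data, fs = fs, channel_names = as.character(channel_names),
         subject_id = as.character(subject_id), reference = reference),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s: %d channels x %d samples @ %g Hz (%s reference)\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$fs, x$reference))
  invisible(x)
}
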