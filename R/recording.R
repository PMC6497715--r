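#' Multichannel EEG recording container
#'
#' A light S3 container for a channels-by-samples EEG matrix with its
#' sampling rate, channel labels, referencing state, per-sample artifact
#' mask and bad-channel set.
#'
#' @param data Numeric matrix, channels x samples.
#' @param fs Sampling rate in Hz (> 0).
#' @param labels Character vector of channel names, one per row of `data`.
#' @param reference `"earlobe"` or `"average"`.
#' @param artifact_mask Logical vector, one entry per sample; `TRUE` marks a
#'   usable sample. Defaults to all usable.
#' @param bad_channels Character vector, subset of `labels`.
#' @param unit_state `"volts"` (microvolt scale) or `"zscored"`.
#' @return An object of class `eeg_recording`.
#' @export
new_recording <- function(data, fs, labels,
                          reference = c("earlobe", "average"),
                          artifact_mask = NULL,
                          bad_channels = character(),
                          unit_state = c("volts", "zscored")) {
  reference <- match.arg(reference)
  unit_state <- match.arg(unit_state)
  if (!is.matrix(data)) stopf("data must be a channels x samples matrix")
  if (nrow(data) != length(labels))
    stopf("data has %d rows but %d labels", nrow(data), length(labels))
  if (anyDuplicated(labels)) stopf("duplicate channel labels")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stopf("fs must be > 0")
  if (is.null(artifact_mask)) artifact_mask <- rep(TRUE, ncol(data))
  if (length(artifact_mask) != ncol(data))
    stopf("artifact_mask length %d != sample count %d",
          length(artifact_mask), ncol(data))
  if (!all(bad_channels %in% labels))
    stopf("bad_channels not in labels: %s",
          paste(setdiff(bad_channels, labels), collapse = ", "))
  rownames(data) <- labels
  structure(list(data = data, fs = fs, labels = labels,
                 reference = reference,
                 artifact_mask = as.logical(artifact_mask),
                 bad_channels = bad_channels, unit_state = unit_state),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d ch x %d samples @ %g Hz (%.1f min, %.1f usable), %s-ref, %s%s\n",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs / 60,
    usable_minutes(x), x$reference, x$unit_state,
    if (length(x$bad_channels)) paste0(", bad: ",
                                       paste(x$bad_channels, collapse = ","))
    else ""))
  invisible(x)
}

#' Usable minutes of a recording
#'
#' @param rec An `eeg_recording`.
#' @return Minutes of artifact-free signal.
#' @export
usable_minutes <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  sum(rec$artifact_mask) / rec$fs / 60
}

# Internal: single-channel reference trace with its mask.
new_ref_signal <- function(x, fs, usable = NULL) {
  if (is.null(usable)) usable <- rep(TRUE, length(x))
  structure(list(x = as.numeric(x), fs = fs, usable = usable),
            class = "ref_signal")
}
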