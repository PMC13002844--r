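#' Multichannel EEG recording
#'
#' Container for a continuous recording: a channels x samples matrix of
#' potentials in microvolts, the sampling rate, the montage and a reference
#' descriptor (either a channel name or `"average"`).
#'
#' @param data numeric matrix, channels x samples, microvolts
#' @param fs sampling rate in Hz
#' @param montage an `ms_montage` matching the rows of `data`
#' @param reference reference descriptor, default `"average"`
#' @return object of class `ms_recording`
#' @export
eeg_recording <- function(data, fs, montage, reference = "average") {
  data <- as.matrix(data)
  if (!is.numeric(fs) || fs <= 0) stop("sampling rate must be positive")
  if (!all(is.finite(data))) stop("recording contains non-finite samples")
  if (!is.null(montage)) {
    stopifnot(inherits(montage, "ms_montage"))
    if (nrow(data) != nrow(montage))
      stop("data rows and montage channel count differ")
    rownames(data) <- montage$name
  }
  structure(list(data = data, fs = as.numeric(fs), montage = montage,
                 reference = reference),
            class = "ms_recording")
}

#' @export
print.ms_recording <- function(x, ...) {
  cat(sprintf("<ms_recording> %d ch x %d samples @ %g Hz (%.1f s), ref = %s\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              x$reference))
  invisible(x)
}

#' Drop channels from a recording
#'
#' Removes the named channels (e.g. electrooculogram channels recorded on
#' the cap but excluded from topographic analysis) from data and montage.
#' Names absent from the montage are ignored.
#'
#' @param rec an `ms_recording`
#' @param names channel names to remove
#' @return the reduced `ms_recording`
#' @export
drop_channels <- function(rec, names) {
  stopifnot(inherits(rec, "ms_recording"))
  keep <- !(rec$montage$name %in% names)
  if (sum(keep) < 2L) stop("dropping these channels leaves fewer than 2")
  eeg_recording(rec$data[keep, , drop = FALSE], rec$fs,
                ms_montage(rec$montage$name[keep], rec$montage$x[keep],
                           rec$montage$y[keep]),
                rec$reference)
}

#' Re-reference a recording to a named channel
#'
#' Subtracts the potential of the chosen channel from every channel. Used in
#' tests of reference invariance: once data are average-referenced any prior
#' single-channel reference is irrelevant.
#'
#' @param rec an `ms_recording`
#' @param channel channel name to use as reference
#' @return the re-referenced `ms_recording`
#' @export
rereference_to_channel <- function(rec, channel) {
  stopifnot(inherits(rec, "ms_recording"))
  i <- match(channel, rec$montage$name)
  if (is.na(i)) stop("unknown reference channel: ", channel)
  eeg_recording(sweep(rec$data, 2L, rec$data[i, ], "-"), rec$fs,
                rec$montage, reference = channel)
}
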