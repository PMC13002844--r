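#' Zero-phase band-pass filter
#'
#' Filters every channel of a continuous recording with a zero-phase
#' (forward-backward) Butterworth filter, realized as a high-pass /
#' low-pass cascade of the given order per section. The cascade form keeps
#' the recursion numerically well-behaved for narrow relative bands such as
#' 1-40 Hz at a 1000 Hz rate.
#'
#' @param rec an `ms_recording`
#' @param low,high band edges in Hz, `0 < low < high < fs/2`
#' @param order Butterworth order per section (default 4)
#' @return the filtered `ms_recording`
#' @export
bandpass_filter <- function(rec, low, high, order = 4L) {
  stopifnot(inherits(rec, "ms_recording"))
  fs <- rec$fs
  if (!(low > 0 && high > low && high < fs / 2))
    stop("band edges must satisfy 0 < low < high < fs/2")
  hp <- signal::butter(order, low / (fs / 2), type = "high")
  lp <- signal::butter(order, high / (fs / 2), type = "low")
  out <- t(apply(rec$data, 1L, function(ch) {
    signal::filtfilt(lp, signal::filtfilt(hp, ch))
  }))
  eeg_recording(out, fs, rec$montage, rec$reference)
}

#' Segment a recording into fixed-length epochs with amplitude rejection
#'
#' Cuts the recording into consecutive, non-overlapping epochs of
#' `epoch_s` seconds (a trailing partial epoch is dropped) and flags any
#' epoch containing a sample with `|v| > reject_uv` on any channel as
#' rejected (strict inequality: a sample exactly at the threshold is kept).
#'
#' @param rec an `ms_recording`
#' @param epoch_s epoch length in seconds (default 2)
#' @param reject_uv rejection threshold in microvolts (default 100)
#' @return object of class `ms_epochs`: channels x samples x epochs array
#'   plus per-epoch `kept` flags and `reason` strings
#' @export
segment_epochs <- function(rec, epoch_s = 2, reject_uv = 100) {
  stopifnot(inherits(rec, "ms_recording"))
  spe <- round(epoch_s * rec$fs)
  n_ep <- ncol(rec$data) %/% spe
  if (n_ep < 1L) stop("recording shorter than one epoch")
  K <- nrow(rec$data)
  dat <- array(rec$data[, seq_len(n_ep * spe)], dim = c(K, spe, n_ep))
  kept <- logical(n_ep)
  reason <- character(n_ep)
  for (e in seq_len(n_ep)) {
    bad <- any(abs(dat[, , e]) > reject_uv)
    kept[e] <- !bad
    reason[e] <- if (bad) "amplitude" else ""
  }
  if (!any(kept)) warning("all epochs rejected")
  structure(list(data = dat, fs = rec$fs, montage = rec$montage,
                 epoch_s = epoch_s, kept = kept, reason = reason,
                 reference = rec$reference),
            class = "ms_epochs")
}

#' @export
print.ms_epochs <- function(x, ...) {
  cat(sprintf("<ms_epochs> %d x %d x %d (%d kept of %d epochs), ref = %s\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              sum(x$kept), length(x$kept), x$reference))
  invisible(x)
}

#' Re-reference epochs (or a recording) to the common average
#'
#' Subtracts, at every sample, the instantaneous mean across channels, so
#' the channel mean of every output sample is zero. Idempotent, and the
#' result is independent of whatever single-channel reference the input was
#' recorded against.
#'
#' @param x an `ms_epochs` or `ms_recording`
#' @return the same class of object, average-referenced
#' @export
average_reference <- function(x) {
  if (inherits(x, "ms_recording")) {
    out <- x
    out$data <- sweep(x$data, 2L, colMeans(x$data), "-")
    out$reference <- "average"
    return(out)
  }
  stopifnot(inherits(x, "ms_epochs"))
  d <- x$data
  dm <- dim(d)
  m <- matrix(d, dm[1], dm[2] * dm[3])
  m <- sweep(m, 2L, colMeans(m), "-")
  x$data <- array(m, dm)
  x$reference <- "average"
  x
}

#' Epoch QC report
#'
#' @param ep an `ms_epochs`
#' @return data.frame with `epoch`, `kept`, `reason`
#' @export
epoch_qc <- function(ep) {
  stopifnot(inherits(ep, "ms_epochs"))
  data.frame(epoch = seq_along(ep$kept), kept = ep$kept, reason = ep$reason,
             stringsAsFactors = FALSE)
}

# internal: kept epochs as one channels x frames matrix plus the epoch id
# of every frame (in original epoch numbering)
flatten_kept_epochs <- function(ep) {
  keep <- which(ep$kept)
  if (length(keep) == 0L) stop("no kept epochs")
  dm <- dim(ep$data)
  mats <- lapply(keep, function(e) ep$data[, , e, drop = FALSE])
  m <- matrix(unlist(mats, use.names = FALSE), dm[1],
              dm[2] * length(keep))
  list(data = m, epoch = rep(keep, each = dm[2]), fs = ep$fs)
}

#' Standard preprocessing chain
#'
#' Applies the full signal-conditioning chain to a continuous recording:
#' broad-band filtering (default 1-40 Hz), the narrower microstate band
#' (default 2-20 Hz), segmentation into 2-s epochs with the +/-100 uV
#' amplitude rule (applied before re-referencing), then common average
#' referencing.
#'
#' @param rec an `ms_recording`
#' @param broad_band,ms_band numeric length-2 band edges in Hz; either may
#'   be `NULL` to skip that stage
#' @param epoch_s epoch length in seconds
#' @param reject_uv amplitude rejection threshold in microvolts
#' @param drop optional channel names to drop first (e.g. EOG channels)
#' @return an average-referenced `ms_epochs`
#' @export
preprocess_recording <- function(rec, broad_band = c(1, 40), ms_band = c(2, 20),
                                 epoch_s = 2, reject_uv = 100, drop = NULL) {
  if (!is.null(drop)) rec <- drop_channels(rec, drop)
  if (!is.null(broad_band)) rec <- bandpass_filter(rec, broad_band[1], broad_band[2])
  if (!is.null(ms_band)) rec <- bandpass_filter(rec, ms_band[1], ms_band[2])
  ep <- segment_epochs(rec, epoch_s = epoch_s, reject_uv = reject_uv)
  average_reference(ep)
}
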