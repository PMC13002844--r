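#' Per-frame microstate label sequence
#'
#' Holds one label per analyzed frame (integer index into `classes`, `NA`
#' for unlabeled), the epoch each frame belongs to (segments never span
#' epochs), the frame rate, and optionally the polarity-invariant
#' correlation of every frame with every template (used by the short-segment
#' rejection to decide which flank absorbs a dissolved frame).
#'
#' @param labels integer vector (values in `1..k` or `NA`)
#' @param fs frame rate in Hz
#' @param epoch integer epoch id per frame (non-decreasing)
#' @param classes character class names, default `c("A","B","C","D")`
#' @param corr optional k x n matrix of absolute template correlations
#' @return object of class `ms_labels`
#' @export
label_sequence <- function(labels, fs, epoch = rep(1L, length(labels)),
                           classes = c("A", "B", "C", "D"), corr = NULL) {
  labels <- as.integer(labels)
  if (length(epoch) != length(labels)) stop("one epoch id per frame required")
  if (is.unsorted(epoch)) stop("epoch ids must be non-decreasing")
  if (any(!is.na(labels) & (labels < 1L | labels > length(classes))))
    stop("labels outside the class set")
  if (!is.null(corr) && (nrow(corr) != length(classes) ||
                         ncol(corr) != length(labels)))
    stop("corr must be k x n_frames")
  structure(list(labels = labels, fs = fs, epoch = as.integer(epoch),
                 classes = classes, corr = corr),
            class = "ms_labels")
}

#' @export
print.ms_labels <- function(x, ...) {
  cat(sprintf("<ms_labels> %d frames @ %g Hz, %d epochs, classes %s (%.1f%% labeled)\n",
              length(x$labels), x$fs, length(unique(x$epoch)),
              paste(x$classes, collapse = ""),
              100 * mean(!is.na(x$labels))))
  invisible(x)
}

#' Backfit templates to epoched data
#'
#' Labels every frame of the kept epochs with the template of highest
#' polarity-invariant spatial correlation. Zero-variance frames are labeled
#' by their nearest labeled neighbor within the same epoch (earlier frame
#' on ties).
#'
#' @param templates an `ms_templates` (e.g. canonical-labeled group maps)
#' @param ep an average-referenced `ms_epochs`
#' @return an `ms_labels` carrying the frame-template correlation matrix
#' @export
backfit <- function(templates, ep) {
  stopifnot(inherits(templates, "ms_templates"), inherits(ep, "ms_epochs"))
  fl <- flatten_kept_epochs(ep)
  V <- sweep(fl$data, 2L, colMeans(fl$data), "-")
  nrm <- sqrt(colSums(V^2))
  A <- abs(crossprod(templates$maps, V))          # k x n, |t . vc|
  ok <- nrm > .EPS
  A[, ok] <- sweep(A[, ok, drop = FALSE], 2L, nrm[ok], "/")
  A[, !ok] <- 0
  lab <- max.col(t(A), ties.method = "first")
  lab[!ok] <- NA_integer_
  lab <- fill_nearest_neighbor(lab, fl$epoch)
  label_sequence(lab, ep$fs, fl$epoch, templates$labels, corr = A)
}

# fill NA labels from the nearest labeled frame within the same epoch
# (earlier frame wins ties); frames in fully-unlabeled epochs stay NA.
fill_nearest_neighbor <- function(lab, epoch) {
  nas <- which(is.na(lab))
  if (length(nas) == 0L) return(lab)
  labeled <- which(!is.na(lab))
  for (i in nas) {
    cand <- labeled[epoch[labeled] == epoch[i]]
    if (length(cand) == 0L) next
    d <- abs(cand - i)
    lab[i] <- lab[cand[which.min(d)]]   # which.min: first = earlier frame
  }
  lab
}

#' Reject short microstate segments
#'
#' Temporal smoothing: iteratively dissolves every interior segment of
#' duration `<= min_tf` frames, reassigning each of its frames to the
#' flanking segment whose template correlates higher with that frame
#' (left flank on ties), until no interior segment of `min_tf` frames or
#' shorter remains. Segments touching an epoch edge are truncated rather
#' than short and are exempt. The shortest qualifying segment (earliest on
#' ties) is dissolved first.
#'
#' When the sequence carries no correlation matrix, dissolved frames are
#' split at the segment midpoint (first half to the left flank).
#'
#' @param ls an `ms_labels`
#' @param min_tf rejection threshold in frames; segments with length
#'   `<= min_tf` are dissolved (default 20, i.e. 20 ms at 1000 Hz)
#' @return the smoothed `ms_labels`
#' @export
reject_short_segments <- function(ls, min_tf = 20L) {
  stopifnot(inherits(ls, "ms_labels"))
  lab <- ls$labels
  if (sum(!is.na(lab)) <= min_tf) {
    warning("labeled sequence no longer than min_tf; returned unchanged")
    return(ls)
  }
  for (e in unique(ls$epoch)) {
    idx <- which(ls$epoch == e)
    lab[idx] <- smooth_epoch(lab[idx], idx, ls$corr, min_tf)
  }
  out <- ls
  out$labels <- lab
  out
}

smooth_epoch <- function(l, global_idx, corr, min_tf) {
  n <- length(l)
  maxit <- 10L * nrow(label_runs(l)) + 100L
  for (it in seq_len(maxit)) {
    runs <- label_runs(l)
    nr <- nrow(runs)
    if (nr < 3L) break
    val <- runs$value
    leftv <- c(NA, val[-nr])
    rightv <- c(val[-1], NA)
    qual <- which(seq_len(nr) > 1L & seq_len(nr) < nr & !is.na(val) &
                    runs$length <= min_tf & !is.na(leftv) & !is.na(rightv))
    if (length(qual) == 0L) break
    j <- qual[which.min(runs$length[qual])]
    f <- (runs$start[j] + 1L):runs$end[j]        # 1-based frame indices
    L <- runs$value[j - 1L]
    R <- runs$value[j + 1L]
    if (L == R || is.null(corr)) {
      if (L == R) {
        l[f] <- L
      } else {
        half <- f[seq_len(ceiling(length(f) / 2))]
        l[f] <- R
        l[half] <- L
      }
    } else {
      gf <- global_idx[f]
      take_left <- corr[L, gf] >= corr[R, gf]
      l[f] <- ifelse(take_left, L, R)
    }
  }
  l
}

#' Temporal microstate parameters
#'
#' Computes, per class, the mean segment duration (ms), the occurrence
#' (segment appearances per second of analyzed time) and the time coverage
#' (percent of labeled frames), with segments delimited within epochs and
#' pooled across epochs. Segments touching an epoch edge are flagged
#' truncated; they always count toward occurrence and coverage and, by
#' default, toward mean duration as well.
#'
#' @param ls an `ms_labels` (after smoothing)
#' @param include_truncated include epoch-edge segments in the mean
#'   duration (default `TRUE`)
#' @return data.frame with one row per class: `class`, `n_segments`,
#'   `mean_duration_ms`, `occurrence_per_s`, `coverage_pct`; analyzed
#'   seconds in attribute `"analyzed_s"`
#' @export
temporal_parameters <- function(ls, include_truncated = TRUE) {
  stopifnot(inherits(ls, "ms_labels"))
  segs <- epoch_segments(ls)
  k <- length(ls$classes)
  labeled <- sum(!is.na(ls$labels))
  analyzed_s <- labeled / ls$fs
  out <- data.frame(class = ls$classes, n_segments = 0L,
                    mean_duration_ms = NA_real_, occurrence_per_s = 0,
                    coverage_pct = 0, stringsAsFactors = FALSE)
  for (c in seq_len(k)) {
    m <- segs$value == c
    md <- if (include_truncated) m else m & !segs$truncated
    out$n_segments[c] <- sum(m)
    if (any(md)) out$mean_duration_ms[c] <- mean(segs$length[md]) / ls$fs * 1000
    out$occurrence_per_s[c] <- sum(m) / analyzed_s
    out$coverage_pct[c] <- sum(segs$length[m]) / labeled * 100
  }
  attr(out, "analyzed_s") <- analyzed_s
  out
}

# all labeled segments of a label sequence, epoch-wise, with truncation flag
epoch_segments <- function(ls) {
  res <- NULL
  for (e in unique(ls$epoch)) {
    idx <- which(ls$epoch == e)
    runs <- label_runs(ls$labels[idx])
    runs$epoch <- e
    runs$truncated <- runs$start == 0L | runs$end == length(idx)
    res <- rbind(res, runs[!is.na(runs$value), , drop = FALSE])
  }
  res %||% data.frame(value = integer(), start = integer(), end = integer(),
                      length = integer(), epoch = integer(),
                      truncated = logical())
}

#' Microstate transition matrix
#'
#' Counts label changes at segment boundaries within epochs (junctions
#' across epochs, and junctions interrupted by unlabeled frames, are
#' excluded) and returns conditional probabilities `p(i -> j) =
#' N(i -> j) / sum_j' N(i -> j')` alongside the raw counts and the jointly
#' normalized matrix.
#'
#' @param ls an `ms_labels` (after smoothing)
#' @return object of class `ms_transitions`: list with `counts`, `prob`
#'   (row-conditional, zero diagonal), `joint`, `n_transitions` and
#'   logical `empty`
#' @export
transition_matrix <- function(ls) {
  stopifnot(inherits(ls, "ms_labels"))
  k <- length(ls$classes)
  counts <- matrix(0L, k, k, dimnames = list(ls$classes, ls$classes))
  for (e in unique(ls$epoch)) {
    idx <- which(ls$epoch == e)
    runs <- label_runs(ls$labels[idx])
    v <- runs$value
    for (i in seq_len(max(0L, nrow(runs) - 1L))) {
      if (!is.na(v[i]) && !is.na(v[i + 1L]))
        counts[v[i], v[i + 1L]] <- counts[v[i], v[i + 1L]] + 1L
    }
  }
  tot <- sum(counts)
  rs <- rowSums(counts)
  prob <- counts / ifelse(rs > 0, rs, 1)
  joint <- if (tot > 0) counts / tot else counts * 0
  structure(list(counts = counts, prob = prob, joint = joint,
                 n_transitions = tot, empty = tot == 0L),
            class = "ms_transitions")
}

#' @export
print.ms_transitions <- function(x, ...) {
  cat(sprintf("<ms_transitions> %d transitions\n", x$n_transitions))
  print(round(x$prob, 3))
  invisible(x)
}
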