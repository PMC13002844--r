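#' Write a recording as a BrainVision triplet
#'
#' Writes `<basename>.vhdr` (text header), `<basename>.vmrk` (marker file)
#' and `<basename>.eeg` (32-bit IEEE float, multiplexed, little-endian,
#' microvolts).
#'
#' @param rec an `ms_recording`
#' @param basename output path without extension
#' @return invisibly, the path of the `.vhdr` file
#' @export
write_brainvision <- function(rec, basename) {
  stopifnot(inherits(rec, "ms_recording"))
  dir.create(dirname(basename), showWarnings = FALSE, recursive = TRUE)
  stem <- basename(basename)
  K <- nrow(rec$data)
  hdr <- c(
    "BrainVision Data Exchange Header File Version 1.0",
    "", "[Common Infos]",
    paste0("DataFile=", stem, ".eeg"),
    paste0("MarkerFile=", stem, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", K),
    sprintf("SamplingInterval=%.6f", 1e6 / rec$fs),
    "", "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "", "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(K), rec$montage$name)
  )
  writeLines(hdr, paste0(basename, ".vhdr"), useBytes = FALSE)
  writeLines(c(
    "BrainVision Data Exchange Marker File, Version 1.0",
    "", "[Common Infos]",
    paste0("DataFile=", stem, ".eeg"),
    "", "[Marker Infos]",
    "Mk1=New Segment,,1,1,0"
  ), paste0(basename, ".vmrk"))
  con <- file(paste0(basename, ".eeg"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec$data), con, size = 4L, endian = "little")
  invisible(paste0(basename, ".vhdr"))
}

# minimal INI section parser for BrainVision headers
parse_vhdr <- function(lines) {
  section <- ""
  out <- list()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("\\[|\\]", "", ln)
      out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE) && section != "") {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      out[[section]][[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
    }
  }
  out
}

#' Read a BrainVision recording
#'
#' Supports binary multiplexed IEEE float (32-bit) and 16-bit signed
#' integer data with per-channel resolution scaling. Channel positions are
#' filled from the built-in 64-channel layout when the names match, else
#' set on a circle (positions are only needed for template synthesis).
#'
#' @param vhdr path to the `.vhdr` header file
#' @return an `ms_recording`
#' @export
read_brainvision <- function(vhdr) {
  ini <- parse_vhdr(readLines(vhdr, encoding = "UTF-8", warn = FALSE))
  ci <- ini[["Common Infos"]]
  bi <- ini[["Binary Infos"]]
  if (!identical(ci$DataOrientation, "MULTIPLEXED"))
    stop("only MULTIPLEXED BrainVision data supported")
  K <- as.integer(ci$NumberOfChannels)
  fs <- 1e6 / as.numeric(ci$SamplingInterval)
  chan <- ini[["Channel Infos"]]
  specs <- lapply(chan[sprintf("Ch%d", seq_len(K))], function(s)
    strsplit(s, ",", fixed = TRUE)[[1]])
  nms <- vapply(specs, `[`, "", 1L)
  res <- vapply(specs, function(s)
    if (length(s) >= 3 && nzchar(s[3])) as.numeric(s[3]) else 1, 0)
  eeg_path <- file.path(dirname(vhdr), ci$DataFile)
  fmt <- bi$BinaryFormat %||% "IEEE_FLOAT_32"
  sz <- file.info(eeg_path)$size
  con <- file(eeg_path, "rb")
  on.exit(close(con))
  raw <- if (fmt == "IEEE_FLOAT_32") {
    readBin(con, "numeric", n = sz / 4, size = 4L, endian = "little")
  } else if (fmt == "INT_16") {
    readBin(con, "integer", n = sz / 2, size = 2L, signed = TRUE,
            endian = "little")
  } else stop("unsupported BinaryFormat: ", fmt)
  n <- length(raw) %/% K
  data <- matrix(raw[seq_len(n * K)], K, n) * res
  std <- montage_64_1020()
  m <- match(nms, std$name)
  montage <- if (!anyNA(m)) {
    ms_montage(nms, std$x[m], std$y[m])
  } else {
    th <- seq(0, 2 * pi, length.out = K + 1L)[seq_len(K)]
    ms_montage(nms, 0.9 * cos(th), 0.9 * sin(th))
  }
  eeg_recording(data, fs, montage, reference = "as-recorded")
}

#' Write cohort ground truth
#'
#' Exports, per subject, the planted frame labels as a run-length TSV
#' (`class`, `start_frame`, `end_frame`; half-open, 0-based) and a JSON
#' file with the planted and realized per-class statistics.
#'
#' @param cohort an `ms_cohort` from [simulate_cohort()]
#' @param dir output directory
#' @return invisibly, the directory
#' @export
write_ground_truth <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ms_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  classes <- cohort$ground_truth[[1]]$templates$labels
  for (gt in cohort$ground_truth) {
    runs <- label_runs(gt$labels)
    utils::write.table(
      data.frame(class = classes[runs$value], start_frame = runs$start,
                 end_frame = runs$end),
      file.path(dir, paste0(gt$subject, "_labels.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    meta <- list(subject = gt$subject, arm = gt$arm,
                 planted_duration_ms = as.list(gt$planted_duration_ms),
                 realized = list(
                   duration_ms = gt$realized$duration_ms,
                   occurrence_per_s = gt$realized$occurrence_per_s,
                   coverage_pct = gt$realized$coverage_pct,
                   transition_prob = gt$realized$transition_prob))
    jsonlite::write_json(meta, file.path(dir, paste0(gt$subject, "_truth.json")),
                         digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  }
  utils::write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
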