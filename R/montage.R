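#' Electrode montage
#'
#' A montage holds electrode names together with 2-D head-disc coordinates
#' (x: left negative / right positive; y: posterior negative / anterior
#' positive; the scalp projected onto the unit disc). Coordinates are only
#' used to synthesize dipolar template topographies and to check map
#' orientations; no volume conduction modeling is attempted.
#'
#' @param names character vector of unique channel names
#' @param x,y numeric coordinates on the unit disc
#' @return an object of class `ms_montage`: a data.frame with columns
#'   `name`, `x`, `y`
#' @export
ms_montage <- function(names, x, y) {
  names <- as.character(names)
  if (anyDuplicated(names)) stop("montage channel names must be unique")
  if (length(names) < 2L) stop("a montage needs at least 2 channels")
  if (length(x) != length(names) || length(y) != length(names))
    stop("names, x and y must have equal length")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("montage positions must be finite")
  out <- data.frame(name = names, x = as.numeric(x), y = as.numeric(y),
                    stringsAsFactors = FALSE)
  class(out) <- c("ms_montage", "data.frame")
  out
}

#' Schematic 64-channel 10-20 montage
#'
#' Builds a 64-channel layout with international 10-20/10-10 channel names
#' arranged on a schematic grid projected into the unit head disc. The layout
#' preserves the left/right and anterior/posterior structure of a standard
#' 64-channel cap, which is all the generator and the orientation checks
#' rely on.
#'
#' @return an `ms_montage` with 64 channels
#' @export
montage_64_1020 <- function() {
  rows <- list(
    list(y = 0.85, nm = c("Fp1", "Fpz", "Fp2"), x = c(-0.28, 0, 0.28)),
    list(y = 0.68, nm = c("AF7", "AF3", "AFz", "AF4", "AF8"),
         x = c(-0.52, -0.26, 0, 0.26, 0.52)),
    list(y = 0.48, nm = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"),
         x = seq(-0.68, 0.68, length.out = 9)),
    list(y = 0.24, nm = c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4",
                          "FC6", "FT8"),
         x = seq(-0.80, 0.80, length.out = 9)),
    list(y = 0.00, nm = c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8"),
         x = seq(-0.88, 0.88, length.out = 9)),
    list(y = -0.24, nm = c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4",
                           "CP6", "TP8"),
         x = seq(-0.80, 0.80, length.out = 9)),
    list(y = -0.48, nm = c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8"),
         x = seq(-0.68, 0.68, length.out = 9)),
    list(y = -0.68, nm = c("PO7", "PO3", "POz", "PO4", "PO8"),
         x = c(-0.52, -0.26, 0, 0.26, 0.52)),
    list(y = -0.85, nm = c("O1", "Oz", "O2"), x = c(-0.28, 0, 0.28))
  )
  nm <- unlist(lapply(rows, `[[`, "nm"))
  x <- unlist(lapply(rows, `[[`, "x"))
  y <- unlist(lapply(rows, function(r) rep(r$y, length(r$nm))))
  # mastoid-adjacent and inion sites complete the 64-channel cap
  nm <- c(nm, "TP9", "TP10", "Iz")
  x <- c(x, -0.95, 0.95, 0)
  y <- c(y, -0.22, -0.22, -0.95)
  ms_montage(nm, x, y)
}

#' @export
print.ms_montage <- function(x, ...) {
  cat(sprintf("<ms_montage> %d channels (%s ... %s)\n",
              nrow(x), x$name[1], x$name[nrow(x)]))
  invisible(x)
}
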