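#' Template set
#'
#' A template set bundles k unit-norm, average-referenced scalp maps with
#' their class labels and, after clustering, the global explained variance
#' (GEV) they achieve on the maps they were fitted to.
#'
#' @param maps numeric matrix, channels x k
#' @param labels character labels, one per map (e.g. `c("A","B","C","D")`)
#' @param montage the `ms_montage` the maps live on
#' @param gev global explained variance in `[0, 1]`, or `NA` if not fitted
#' @return object of class `ms_templates`
#' @export
ms_templates <- function(maps, labels, montage, gev = NA_real_) {
  maps <- as.matrix(maps)
  if (ncol(maps) != length(labels)) stop("one label per template map required")
  if (anyDuplicated(labels)) stop("template labels must be unique")
  if (!is.null(montage) && nrow(maps) != nrow(montage))
    stop("template maps and montage disagree on channel count")
  # enforce the invariants: zero channel mean, unit norm
  maps <- sweep(maps, 2L, colMeans(maps), "-")
  nrm <- sqrt(colSums(maps^2))
  if (any(nrm < .EPS)) stop("degenerate (flat) template map")
  maps <- sweep(maps, 2L, nrm, "/")
  colnames(maps) <- labels
  structure(list(maps = maps, labels = as.character(labels),
                 montage = montage, gev = gev),
            class = "ms_templates")
}

#' @export
print.ms_templates <- function(x, ...) {
  cat(sprintf("<ms_templates> %d maps (%s) on %d channels; GEV = %s\n",
              ncol(x$maps), paste(x$labels, collapse = ","),
              nrow(x$maps),
              ifelse(is.na(x$gev), "NA", sprintf("%.3f", x$gev))))
  invisible(x)
}

# Dipole-like source geometry for the four canonical classes, in head-disc
# coordinates. Each class is a pair of opposite-signed Gaussian sources:
#  A: right-frontal positive vs left-posterior negative (diagonal axis)
#  B: left-frontal positive vs right-posterior negative (mirror diagonal)
#  C: midline anterior-posterior axis
#  D: fronto-central focal maximum against a far-occipital counterpole
canonical_source_geometry <- function() {
  list(
    A = list(pos = c(0.60, 0.55), neg = c(-0.60, -0.55), sigma = c(0.35, 0.35)),
    B = list(pos = c(-0.60, 0.55), neg = c(0.60, -0.55), sigma = c(0.35, 0.35)),
    C = list(pos = c(0.00, 0.65), neg = c(0.00, -0.60), sigma = c(0.45, 0.45)),
    D = list(pos = c(0.00, 0.15), neg = c(0.00, -0.95), sigma = c(0.28, 0.30))
  )
}

#' Canonical microstate template maps
#'
#' Synthesizes the four canonical resting-state map classes A-D as smooth
#' dipolar fields: two opposite-signed Gaussian sources per class placed at
#' the scalp sites that give microstate A a right-frontal to left-posterior
#' orientation, B the mirrored left-frontal to right-posterior orientation,
#' C an anterior-posterior midline pattern and D a fronto-central maximum.
#' Maps are average-referenced and unit-normed. With `jitter > 0` a random
#' per-channel perturbation (standard deviation `jitter` relative to unit
#' norm) is added before renormalization, to emulate between-subject
#' topographic variability.
#'
#' @param montage an `ms_montage` with at least 4 channels
#' @param seed integer seed (only consulted when `jitter > 0`)
#' @param jitter topographic jitter standard deviation, default 0
#' @return an `ms_templates` with labels A-D
#' @export
make_canonical_templates <- function(montage, seed = 1L, jitter = 0) {
  stopifnot(inherits(montage, "ms_montage"))
  if (nrow(montage) < 4L) stop("montage must have at least 4 channels")
  geom <- canonical_source_geometry()
  base <- sapply(geom, function(g) {
    dp <- (montage$x - g$pos[1])^2 + (montage$y - g$pos[2])^2
    dn <- (montage$x - g$neg[1])^2 + (montage$y - g$neg[2])^2
    exp(-dp / (2 * g$sigma[1]^2)) - exp(-dn / (2 * g$sigma[2]^2))
  })
  if (jitter > 0) {
    noise <- with_preserved_seed(seed,
      matrix(stats::rnorm(length(base), sd = jitter), nrow(base), ncol(base)))
    # maps are renormalized in the constructor, so jitter is relative to
    # the unit-norm map
    base <- sweep(base, 2L, sqrt(colSums(base^2)), "/") + noise
  }
  ms_templates(base, names(geom), montage)
}
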