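#' Global field power
#'
#' GFP at one instant is the population standard deviation of the
#' potentials across all electrodes of the average-referenced map:
#' `sqrt(mean((v - mean(v))^2))`.
#'
#' @param ep an `ms_epochs` (average-referenced) or a channels x frames
#'   matrix
#' @return for epochs: object of class `ms_gfp` (list with `gfp`, `epoch`,
#'   `fs`); for a matrix: numeric vector of per-frame GFP
#' @export
gfp <- function(ep) {
  if (is.matrix(ep)) return(gfp_frames(ep))
  stopifnot(inherits(ep, "ms_epochs"))
  fl <- flatten_kept_epochs(ep)
  structure(list(gfp = gfp_frames(fl$data), epoch = fl$epoch, fs = ep$fs),
            class = "ms_gfp")
}

gfp_frames <- function(m) {
  mu <- colMeans(m)
  sqrt(colMeans(m^2) - mu^2)
}

#' GFP peak frames
#'
#' Strict local maxima of the GFP series, searched within each epoch so no
#' peak straddles an epoch boundary.
#'
#' @param g an `ms_gfp` (from [gfp()]) or a numeric vector (treated as a
#'   single epoch)
#' @return integer frame indices of the peaks (into the flattened kept
#'   frames); possibly empty
#' @export
gfp_peaks <- function(g) {
  if (is.numeric(g)) g <- list(gfp = g, epoch = rep(1L, length(g)))
  v <- g$gfp
  n <- length(v)
  if (n == 0L) stop("empty GFP series")
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1)
  is_peak <- v[i] > v[i - 1] & v[i] > v[i + 1] &
    g$epoch[i] == g$epoch[i - 1] & g$epoch[i] == g$epoch[i + 1]
  i[is_peak]
}

#' Spatial correlation of two scalp maps
#'
#' Pearson correlation across channels of two maps (centering across
#' channels is inherent to the correlation, i.e. maps are compared in
#' average reference). With `polarity_invariant = TRUE` (the default, as
#' used throughout microstate analysis) the absolute value is returned.
#'
#' @param u,v numeric vectors of per-channel potentials on the same montage
#' @param polarity_invariant ignore map polarity (default `TRUE`)
#' @return correlation in `[-1, 1]` (or `[0, 1]`); `NA` with a warning if
#'   either map has zero variance
#' @export
spatial_correlation <- function(u, v, polarity_invariant = TRUE) {
  if (length(u) != length(v)) stop("maps must share the montage")
  if (stats::sd(u) < .EPS || stats::sd(v) < .EPS) {
    warning("zero-variance map: spatial correlation undefined")
    return(NA_real_)
  }
  r <- stats::cor(u, v)
  if (polarity_invariant) abs(r) else r
}

#' Extract GFP-peak maps from epochs
#'
#' Returns the average-referenced scalp maps at the GFP peaks of the kept
#' epochs, together with their GFP values (used as weights in clustering).
#'
#' @param ep an average-referenced `ms_epochs`
#' @return list with `maps` (channels x n, unit-norm), `gfp` (numeric n),
#'   `epoch` and `frame` indices
#' @export
extract_peak_maps <- function(ep) {
  stopifnot(inherits(ep, "ms_epochs"))
  g <- gfp(ep)
  pk <- gfp_peaks(g)
  fl <- flatten_kept_epochs(ep)
  maps <- fl$data[, pk, drop = FALSE]
  maps <- sweep(maps, 2L, colMeans(maps), "-")
  nrm <- sqrt(colSums(maps^2))
  ok <- nrm > .EPS
  maps <- sweep(maps[, ok, drop = FALSE], 2L, nrm[ok], "/")
  list(maps = maps, gfp = g$gfp[pk][ok], epoch = fl$epoch[pk][ok],
       frame = pk[ok])
}

# ---- T-AAHC internals -------------------------------------------------------

# first principal axis of a set of unit-norm zero-mean maps (columns of M),
# sign-aligned with the majority of members; polarity-blind because it is
# the leading eigenvector of the sum of outer products.
principal_map <- function(M) {
  if (ncol(M) == 1L) return(M[, 1L])
  ev <- eigen(tcrossprod(M), symmetric = TRUE)
  v <- ev$vectors[, 1L]
  s <- crossprod(v, M)            # signed correlations with members
  if (sum(sign(s)) < 0) v <- -v
  v / sqrt(sum(v^2))
}

# assign each orphan map (columns of U) to the centroid (columns of C) of
# highest polarity-invariant correlation; ties broken by lowest cluster
# index. U and C columns must be unit-norm and zero-mean.
reassign_orphans <- function(U, C) {
  A <- abs(crossprod(C, U))       # clusters x orphans
  apply(A, 2L, which.max)         # which.max takes the first (lowest) index
}

# GEV contribution of one cluster: sum over members of (gfp * |corr|)^2
cluster_contribution <- function(centroid, M, w) {
  sum((w * as.numeric(abs(crossprod(centroid, M))))^2)
}

#' Topographic atomize-and-agglomerate hierarchical clustering
#'
#' Clusters GFP-peak maps under polarity-invariant spatial correlation.
#' Starting from singleton clusters, the cluster contributing least to the
#' global explained variance is repeatedly dissolved ("atomized") and each
#' of its maps reassigned to the cluster whose centroid correlates highest
#' (in absolute value) with it; centroids are the first principal axis of
#' the member maps. The procedure stops at `k_target` clusters.
#'
#' GEV is `sum((gfp_i * corr_i)^2) / sum(gfp_i^2)` over the clustered maps,
#' where `corr_i` is the polarity-invariant correlation of map i with its
#' cluster centroid.
#'
#' @param maps channels x n matrix of average-referenced maps (normalized
#'   internally), or the list returned by [extract_peak_maps()]
#' @param k_target number of clusters to keep
#' @param weights per-map GFP weights; default taken from `maps$gfp` or 1
#' @param montage optional `ms_montage` carried into the result
#' @return list with `templates` (an `ms_templates`, labels `T1..Tk` until
#'   canonical labels are assigned), `assignment` (cluster index per map)
#'   and `gev`
#' @export
taahc <- function(maps, k_target = 4L, weights = NULL, montage = NULL) {
  if (is.list(maps) && !is.null(maps$maps)) {
    weights <- weights %||% maps$gfp
    maps <- maps$maps
  }
  U <- as.matrix(maps)
  n <- ncol(U)
  if (k_target < 1L || k_target > n)
    stop("k_target must be between 1 and the number of maps")
  U <- sweep(U, 2L, colMeans(U), "-")
  nrm <- sqrt(colSums(U^2))
  if (any(nrm < .EPS)) stop("zero-variance map cannot be clustered")
  U <- sweep(U, 2L, nrm, "/")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n) stop("one weight per map required")

  members <- as.list(seq_len(n))           # cluster -> map indices
  centroids <- U                           # one column per live cluster
  contrib <- w^2                           # singleton: corr = 1
  while (length(members) > k_target) {
    worst <- which.min(contrib)            # ties: lowest index
    orphans <- members[[worst]]
    members[[worst]] <- NULL
    centroids <- centroids[, -worst, drop = FALSE]
    contrib <- contrib[-worst]
    tgt <- reassign_orphans(U[, orphans, drop = FALSE], centroids)
    for (cl in unique(tgt)) {
      members[[cl]] <- c(members[[cl]], orphans[tgt == cl])
      M <- U[, members[[cl]], drop = FALSE]
      centroids[, cl] <- principal_map(M)
      contrib[cl] <- cluster_contribution(centroids[, cl], M, w[members[[cl]]])
    }
  }
  assignment <- integer(n)
  for (cl in seq_along(members)) assignment[members[[cl]]] <- cl
  gev <- sum(contrib) / sum(w^2)
  tmpl <- ms_templates(centroids, sprintf("T%d", seq_len(ncol(centroids))),
                       montage, gev = gev)
  list(templates = tmpl, assignment = assignment, gev = gev)
}

#' Group-level templates from subject template sets
#'
#' Pools the template maps of all subjects (unit weight each) and
#' re-clusters them with [taahc()] to `k_target` group maps. Subject order
#' does not affect the result beyond cluster numbering.
#'
#' @param subject_sets list of `ms_templates`, one per subject
#' @param k_target number of group templates (default 4)
#' @return as [taahc()]
#' @export
group_templates <- function(subject_sets, k_target = 4L) {
  if (length(subject_sets) == 0L) stop("no subject template sets supplied")
  stopifnot(all(vapply(subject_sets, inherits, TRUE, "ms_templates")))
  pooled <- do.call(cbind, lapply(subject_sets, `[[`, "maps"))
  taahc(pooled, k_target, weights = rep(1, ncol(pooled)),
        montage = subject_sets[[1L]]$montage)
}

# best one-to-one matching of columns of similarity matrix S (candidates x
# references): returns the permutation p with p[j] = candidate assigned to
# reference j, maximizing sum of S. Exhaustive depth-first search.
best_assignment <- function(S) {
  k <- nrow(S)
  best <- list(score = -Inf, perm = integer(k))
  rec <- function(j, used, score, perm) {
    if (j > k) {
      if (score > best$score) best <<- list(score = score, perm = perm)
      return(invisible())
    }
    for (i in seq_len(k)) {
      if (!used[i]) {
        used[i] <- TRUE
        perm[j] <- i
        rec(j + 1L, used, score + S[i, j], perm)
        used[i] <- FALSE
      }
    }
  }
  rec(1L, logical(k), 0, integer(k))
  best$perm
}

#' Assign canonical class labels A-D to a template set
#'
#' Finds the one-to-one matching between the candidate maps and a reference
#' set (by default the built-in canonical orientation templates) that
#' maximizes the summed polarity-invariant correlation, and returns the
#' candidate set reordered as A, B, C, D with each map sign-aligned to its
#' reference.
#'
#' @param t an `ms_templates` with as many maps as the reference
#' @param reference an `ms_templates` on the same montage; default
#'   `make_canonical_templates(t$montage)`
#' @return an `ms_templates` ordered/labeled like the reference, with an
#'   attribute `"matching"` giving, for each reference class, the index of
#'   the candidate map assigned to it
#' @export
assign_canonical_labels <- function(t, reference = NULL) {
  stopifnot(inherits(t, "ms_templates"))
  if (is.null(reference)) reference <- make_canonical_templates(t$montage)
  stopifnot(inherits(reference, "ms_templates"))
  if (ncol(t$maps) != ncol(reference$maps))
    stop("candidate and reference sets must have the same number of maps")
  if (nrow(t$maps) != nrow(reference$maps))
    stop("candidate and reference sets must share the montage")
  S <- abs(crossprod(t$maps, reference$maps))   # candidates x references
  perm <- best_assignment(S)
  maps <- t$maps[, perm, drop = FALSE]
  # orient each map like its reference (cosmetic; analysis is sign-blind)
  sgn <- sign(colSums(maps * reference$maps))
  sgn[sgn == 0] <- 1
  maps <- sweep(maps, 2L, sgn, "*")
  out <- ms_templates(maps, reference$labels, t$montage, gev = t$gev)
  attr(out, "matching") <- perm
  out
}
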