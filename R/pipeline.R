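#' Full microstate analysis of a set of recordings
#'
#' Runs the complete analysis chain on a list of recordings: per-subject
#' preprocessing (broad band, microstate band, 2-s epochs with amplitude
#' rejection, average reference), GFP-peak map extraction, subject-level
#' T-AAHC, group-level template derivation, canonical A-D labeling against
#' a reference set, backfitting, short-segment rejection, and extraction of
#' the temporal parameters and transition matrices.
#'
#' Group templates are derived from all subjects pooled by default, so the
#' same template set is backfitted to everyone and parameters are
#' comparable across arms; `template_scope = "per_arm"` instead clusters
#' and backfits each arm with its own template set.
#'
#' @param recordings list of `ms_recording`
#' @param subjects optional data.frame with columns `subject` and `arm`
#'   aligned with `recordings`
#' @param k number of microstate classes (default 4)
#' @param reference_templates `ms_templates` used for canonical labeling;
#'   default: the built-in canonical orientation maps
#' @param template_scope `"pooled"` (default) or `"per_arm"`
#' @param min_tf short-segment rejection threshold in frames (default 20)
#' @param broad_band,ms_band,epoch_s,reject_uv,drop passed to
#'   [preprocess_recording()]
#' @return list of class `ms_analysis` with `params` (long data.frame:
#'   subject, arm, class, n_segments, mean_duration_ms, occurrence_per_s,
#'   coverage_pct), `transitions` (long data.frame: subject, arm, from, to,
#'   count, prob), `templates` (group `ms_templates`, or per-arm list),
#'   `subject_gev` and `labels` (per-subject `ms_labels`)
#' @export
run_microstate_pipeline <- function(recordings, subjects = NULL, k = 4L,
                                    reference_templates = NULL,
                                    template_scope = c("pooled", "per_arm"),
                                    min_tf = 20L,
                                    broad_band = c(1, 40), ms_band = c(2, 20),
                                    epoch_s = 2, reject_uv = 100, drop = NULL) {
  template_scope <- match.arg(template_scope)
  nsub <- length(recordings)
  if (is.null(subjects))
    subjects <- data.frame(subject = sprintf("sub-%02d", seq_len(nsub)),
                           arm = rep("all", nsub), stringsAsFactors = FALSE)
  stopifnot(nrow(subjects) == nsub)

  epochs <- vector("list", nsub)
  subj_sets <- vector("list", nsub)
  subj_gev <- numeric(nsub)
  for (i in seq_len(nsub)) {
    rec <- recordings[[i]]
    if (is.character(rec)) rec <- read_brainvision(rec)
    ep <- preprocess_recording(rec, broad_band = broad_band, ms_band = ms_band,
                               epoch_s = epoch_s, reject_uv = reject_uv,
                               drop = drop)
    fit <- taahc(extract_peak_maps(ep), k, montage = ep$montage)
    epochs[[i]] <- ep
    subj_sets[[i]] <- fit$templates
    subj_gev[i] <- fit$gev
  }
  if (is.null(reference_templates))
    reference_templates <- make_canonical_templates(epochs[[1L]]$montage)

  group_for <- function(idx) {
    g <- group_templates(subj_sets[idx], k)
    assign_canonical_labels(g$templates, reference_templates)
  }
  if (template_scope == "pooled") {
    tmpl <- group_for(seq_len(nsub))
    tmpl_of <- function(i) tmpl
  } else {
    tmpl <- lapply(split(seq_len(nsub), subjects$arm), group_for)
    tmpl_of <- function(i) tmpl[[subjects$arm[i]]]
  }

  params <- NULL
  transitions <- NULL
  labels <- vector("list", nsub)
  for (i in seq_len(nsub)) {
    ls <- reject_short_segments(backfit(tmpl_of(i), epochs[[i]]),
                                min_tf = min_tf)
    labels[[i]] <- ls
    tp <- temporal_parameters(ls)
    tp <- cbind(subject = subjects$subject[i], arm = subjects$arm[i], tp,
                stringsAsFactors = FALSE)
    params <- rbind(params, tp)
    tm <- transition_matrix(ls)
    cls <- ls$classes
    tr <- expand.grid(from = cls, to = cls, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
    tr <- tr[tr$from != tr$to, ]
    tr$count <- tm$counts[cbind(match(tr$from, cls), match(tr$to, cls))]
    tr$prob <- tm$prob[cbind(match(tr$from, cls), match(tr$to, cls))]
    tr <- cbind(subject = subjects$subject[i], arm = subjects$arm[i], tr,
                stringsAsFactors = FALSE)
    transitions <- rbind(transitions, tr)
  }
  rownames(params) <- rownames(transitions) <- NULL
  structure(list(params = params, transitions = transitions,
                 templates = tmpl, subject_gev = subj_gev, labels = labels,
                 subjects = subjects),
            class = "ms_analysis")
}

#' @export
print.ms_analysis <- function(x, ...) {
  cat(sprintf("<ms_analysis> %d subjects, mean subject GEV %.3f\n",
              nrow(x$subjects), mean(x$subject_gev)))
  invisible(x)
}

#' Ground-truth recovery errors of a cohort analysis
#'
#' Compares the cohort-mean recovered temporal parameters and transition
#' probabilities with the cohort-mean realized ground truth of a simulated
#' cohort: relative errors for duration, occurrence and coverage per class,
#' and for every off-diagonal transition probability.
#'
#' @param cohort an `ms_cohort` from [simulate_cohort()]
#' @param analysis an `ms_analysis` from [run_microstate_pipeline()] run on
#'   the cohort's recordings
#' @return list with `parameters` (data.frame: class, measure, recovered,
#'   planted, rel_error) and `transitions` (data.frame: from, to,
#'   recovered, planted, rel_error)
#' @export
recovery_errors <- function(cohort, analysis) {
  stopifnot(inherits(cohort, "ms_cohort"), inherits(analysis, "ms_analysis"))
  k <- length(cohort$ground_truth[[1]]$realized$duration_ms)
  classes <- analysis$params$class[seq_len(k)]
  tru <- function(field) rowMeans(vapply(cohort$ground_truth,
    function(g) g$realized[[field]], numeric(k)))
  cols <- c(duration = "mean_duration_ms", occurrence = "occurrence_per_s",
            coverage = "coverage_pct")
  fields <- c(duration = "duration_ms", occurrence = "occurrence_per_s",
              coverage = "coverage_pct")
  params <- NULL
  for (m in names(cols)) {
    rec <- sapply(split(analysis$params[[cols[m]]], analysis$params$class),
                  mean)[classes]
    pl <- tru(fields[m])
    params <- rbind(params, data.frame(class = classes, measure = m,
                                       recovered = unname(rec), planted = pl,
                                       rel_error = unname(rec) / pl - 1))
  }
  n <- length(cohort$ground_truth)
  tru_tp <- Reduce(`+`, lapply(cohort$ground_truth,
                               function(g) g$realized$transition_prob)) / n
  tr <- analysis$transitions
  rec_tp <- matrix(0, k, k)
  agg <- stats::aggregate(prob ~ from + to, data = tr, FUN = mean)
  rec_tp[cbind(match(agg$from, classes), match(agg$to, classes))] <- agg$prob
  off <- which(row(tru_tp) != col(tru_tp), arr.ind = TRUE)
  trans <- data.frame(from = classes[off[, 1]], to = classes[off[, 2]],
                      recovered = rec_tp[off], planted = tru_tp[off],
                      rel_error = rec_tp[off] / tru_tp[off] - 1)
  list(parameters = params, transitions = trans)
}
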