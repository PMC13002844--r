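#' Microstate dynamics specification
#'
#' Parameters of the semi-Markov generative model: per-class mean segment
#' durations with a gamma duration law (given shape), a conditional
#' between-class transition matrix with zero diagonal, the oscillatory
#' carrier frequency, and the signal-to-noise ratio (RMS of the state signal
#' over RMS of the additive sensor noise).
#'
#' @param mean_duration_ms named numeric vector of per-class mean segment
#'   durations in milliseconds (defaults place class C at the long end of
#'   the 60-120 ms quasi-stability band)
#' @param shape gamma shape parameter of the duration law (default 4)
#' @param transition k x k conditional transition matrix, zero diagonal,
#'   rows summing to 1; default: uniform over the other classes
#' @param carrier_hz carrier frequency in Hz (default 10, the eyes-closed
#'   alpha rhythm)
#' @param snr signal-to-noise RMS ratio, `> 0`, may be `Inf`
#' @param amplitude_uv scalp amplitude scale in microvolts applied to the
#'   unit-norm templates
#' @return object of class `ms_dynamics`
#' @export
dynamics_spec <- function(mean_duration_ms = c(A = 60, B = 60, C = 80, D = 60),
                          shape = 4, transition = NULL, carrier_hz = 10,
                          snr = 10, amplitude_uv = 40) {
  k <- length(mean_duration_ms)
  if (k < 2L) stop("at least two classes required")
  if (is.null(names(mean_duration_ms))) names(mean_duration_ms) <- LETTERS[1:k]
  if (any(mean_duration_ms <= 0)) stop("mean durations must be positive")
  if (is.null(transition)) {
    transition <- matrix(1 / (k - 1), k, k)
    diag(transition) <- 0
  }
  transition <- as.matrix(transition)
  if (!all(dim(transition) == k)) stop("transition matrix must be k x k")
  if (any(diag(transition) != 0)) stop("transition matrix diagonal must be 0")
  if (any(transition < 0)) stop("transition probabilities must be >= 0")
  rs <- rowSums(transition)
  if (any(rs < .EPS)) stop("degenerate transition row (all zero)")
  if (any(abs(rs - 1) > 1e-8)) stop("transition rows must sum to 1")
  if (!(snr > 0)) stop("snr must be positive")
  if (shape <= 0) stop("gamma shape must be positive")
  dimnames(transition) <- list(names(mean_duration_ms), names(mean_duration_ms))
  structure(list(mean_duration_ms = mean_duration_ms, shape = shape,
                 transition = transition, carrier_hz = carrier_hz,
                 snr = snr, amplitude_uv = amplitude_uv,
                 classes = names(mean_duration_ms)),
            class = "ms_dynamics")
}

# summarize a realized label vector: per-class mean duration / occurrence /
# coverage and the between-run transition matrix. Generator-side twin used
# for ground truth; the analysis path has its own extraction in the metrics
# functions.
realized_dynamics <- function(labels, fs, k) {
  runs <- label_runs(labels)
  total_s <- length(labels) / fs
  dur <- occ <- cov <- numeric(k)
  for (c in seq_len(k)) {
    m <- runs$value == c & !is.na(runs$value)
    dur[c] <- if (any(m)) mean(runs$length[m]) / fs * 1000 else NA_real_
    occ[c] <- sum(m) / total_s
    cov[c] <- sum(runs$length[m]) / length(labels) * 100
  }
  counts <- matrix(0L, k, k)
  v <- runs$value[!is.na(runs$value)]
  if (length(v) > 1L) {
    for (i in seq_len(length(v) - 1L))
      counts[v[i], v[i + 1L]] <- counts[v[i], v[i + 1L]] + 1L
  }
  prob <- counts / pmax(rowSums(counts), 1L)
  list(duration_ms = dur, occurrence_per_s = occ, coverage_pct = cov,
       transition_counts = counts, transition_prob = prob)
}

#' Simulate a semi-Markov microstate label sequence
#'
#' Draws segment durations from a gamma law with the per-class means and
#' common shape of `dyn` (truncated below at 10 ms and rounded to whole
#' frames, minimum 1), and successor classes from the conditional transition
#' matrix. The initial class is uniform. The realized per-class statistics
#' (the recoverable ground truth) are returned alongside the frame labels.
#'
#' @param dyn an `ms_dynamics`
#' @param length_s sequence length in seconds
#' @param fs frame rate in Hz
#' @param seed integer seed
#' @return a list of class `ms_state_sequence` with elements `labels`
#'   (integer frames), `fs`, `dyn`, `segments` (run-length data.frame) and
#'   `realized` (per-class duration/occurrence/coverage and the transition
#'   matrix actually realized)
#' @export
simulate_state_sequence <- function(dyn, length_s, fs, seed = 1L) {
  stopifnot(inherits(dyn, "ms_dynamics"))
  n <- round(length_s * fs)
  k <- length(dyn$classes)
  mean_frames <- dyn$mean_duration_ms * fs / 1000
  if (n < 10 * max(mean_frames))
    stop("sequence must be at least 10 planted mean durations long")
  labels <- with_preserved_seed(seed, {
    states <- integer(0)
    lens <- integer(0)
    got <- 0L
    s <- sample.int(k, 1L)
    while (got < n) {
      m <- max(16L, ceiling((n - got) / min(mean_frames)) + 8L)
      chunk <- integer(m)
      for (i in seq_len(m)) {
        chunk[i] <- s
        s <- sample.int(k, 1L, prob = dyn$transition[s, ])
      }
      dms <- pmax(10, stats::rgamma(m, shape = dyn$shape,
                                    scale = dyn$mean_duration_ms[chunk] / dyn$shape))
      dfr <- pmax(1L, as.integer(round(dms * fs / 1000)))
      states <- c(states, chunk)
      lens <- c(lens, dfr)
      got <- got + sum(dfr)
    }
    rep(states, lens)[seq_len(n)]
  })
  structure(list(labels = labels, fs = fs, dyn = dyn,
                 segments = label_runs(labels),
                 realized = realized_dynamics(labels, fs, k)),
            class = "ms_state_sequence")
}

#' Synthesize a multichannel recording from a label sequence
#'
#' Each frame is the template of its planted class, scaled by a sinusoidal
#' alpha-band carrier (amplitude constant within a segment, drawn uniformly
#' in 0.7-1.3 across segments) and the microvolt amplitude scale, plus
#' spatially white Gaussian sensor noise scaled so the state-signal RMS over
#' noise RMS equals the requested SNR. Polarity reversals of the carrier are
#' intended: all downstream analysis is polarity-invariant.
#'
#' @param templates an `ms_templates` with one map per class of `seq`
#' @param seq an `ms_state_sequence`
#' @param seed integer seed for amplitudes and noise
#' @return an `ms_recording` (average reference)
#' @export
synthesize_recording <- function(templates, seq, seed = 1L) {
  stopifnot(inherits(templates, "ms_templates"),
            inherits(seq, "ms_state_sequence"))
  dyn <- seq$dyn
  if (ncol(templates$maps) < length(dyn$classes))
    stop("templates and dynamics disagree on class count")
  if (!(dyn$snr > 0)) stop("snr must be positive")
  n <- length(seq$labels)
  K <- nrow(templates$maps)
  with_preserved_seed(seed, {
    seg_amp <- stats::runif(nrow(seq$segments), 0.7, 1.3)
    amp <- rep(seg_amp, seq$segments$length)
    carrier <- sin(2 * pi * dyn$carrier_hz * (seq_len(n) - 1L) / seq$fs)
    gain <- carrier * amp * dyn$amplitude_uv
    S <- templates$maps[, seq$labels, drop = FALSE] *
      matrix(gain, K, n, byrow = TRUE)
    if (is.finite(dyn$snr)) {
      sdn <- sqrt(mean(S^2)) / dyn$snr
      S <- S + matrix(stats::rnorm(K * n, sd = sdn), K, n)
    }
    eeg_recording(S, seq$fs, templates$montage, reference = "average")
  })
}

#' Cohort specification
#'
#' Describes a two-arm study: arm sizes, per-arm dynamics, recording length
#' and rate, between-subject variability of the planted mean durations, and
#' the clinical-score generative model (which clinical score is planted to
#' correlate, with which subject-level dynamics parameter, and how
#' strongly).
#'
#' @param n_per_arm named integer vector, e.g. `c(patient = 30, control = 40)`
#' @param dynamics named list of `ms_dynamics`, one per arm
#' @param length_s recording length per subject in seconds
#' @param fs sampling rate in Hz
#' @param subject_cv between-subject log-normal coefficient of variation of
#'   the per-class mean durations (default 0.08)
#' @param template_jitter per-subject topographic jitter passed to
#'   [make_canonical_templates()] (default 0)
#' @param clinical list with `score` (currently `"anxiety_somatization"`),
#'   `parameter` (`"duration_A"` ... `"duration_D"`), and planted Pearson
#'   correlation `r` with `|r| < 1` (applies within the patient arm)
#' @return object of class `ms_cohort_spec`
#' @export
cohort_spec <- function(n_per_arm = c(patient = 30, control = 40),
                        dynamics = list(
                          patient = dynamics_spec(c(A = 60, B = 55, C = 68, D = 62)),
                          control = dynamics_spec(c(A = 60, B = 65, C = 58, D = 62))),
                        length_s = 180, fs = 1000,
                        subject_cv = 0.08, template_jitter = 0,
                        clinical = list(score = "anxiety_somatization",
                                        parameter = "duration_C", r = -0.4)) {
  if (any(n_per_arm < 1L)) stop("each arm needs at least one subject")
  if (length(n_per_arm) != 2L || is.null(names(n_per_arm)))
    stop("n_per_arm must be a named vector of two arms")
  if (!setequal(names(dynamics), names(n_per_arm)))
    stop("dynamics must be named like n_per_arm")
  if (fs <= 0 || length_s <= 0) stop("length_s and fs must be positive")
  if (!is.null(clinical$r) && abs(clinical$r) >= 1)
    stop("planted correlation must satisfy |r| < 1")
  structure(list(n_per_arm = n_per_arm, dynamics = dynamics,
                 length_s = length_s, fs = fs, subject_cv = subject_cv,
                 template_jitter = template_jitter, clinical = clinical),
            class = "ms_cohort_spec")
}

#' Plant a correlated score against a subject-level parameter
#'
#' Bivariate-normal construction: given the subject parameter vector `x`,
#' draws `y` with target mean and SD whose expected Pearson correlation with
#' `x` equals `rho`.
#'
#' @param x numeric subject-level parameter
#' @param mean,sd target moments of the score
#' @param rho planted correlation, `|rho| < 1`
#' @param seed optional seed; if `NULL` the current RNG stream is used
#' @return numeric vector of scores (continuous; callers round/clip to the
#'   instrument range)
#' @export
plant_correlated_scores <- function(x, mean, sd, rho, seed = NULL) {
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  if (sd < 0) stop("sd must be >= 0")
  if (sd == 0 && rho != 0)
    stop("a zero score SD is incompatible with a nonzero planted correlation")
  if (stats::sd(x) < .EPS && rho != 0)
    stop("cannot plant a correlation against a constant parameter")
  draw <- function() {
    z <- if (stats::sd(x) < .EPS) rep(0, length(x)) else
      (x - base::mean(x)) / stats::sd(x)
    mean + sd * (rho * z + sqrt(1 - rho^2) * stats::rnorm(length(x)))
  }
  if (is.null(seed)) draw() else with_preserved_seed(seed, draw())
}

# distribute an integer score total across items respecting per-item maxima
distribute_items <- function(total, item_max) {
  v <- integer(length(item_max))
  total <- min(total, sum(item_max))
  while (total > 0L) {
    open <- which(v < item_max)
    i <- if (length(open) == 1L) open else sample(open, 1L)
    v[i] <- v[i] + 1L
    total <- total - 1L
  }
  v
}

# Table of per-arm demographic generative settings used for synthetic
# clinical tables; moments mirror the study-size defaults.
demographic_defaults <- function() {
  list(patient = list(age = c(26.4, 7.36), education = c(14.3, 3.53),
                      p_male = 8 / 30),
       control = list(age = c(24.1, 5.99), education = c(15.85, 2.55),
                      p_male = 16 / 40))
}

# HAMD-24 seven-factor target moments (patients only): mean, sd
hamd_factor_moments <- function() {
  list(anxiety_somatization = c(5.50, 2.61), weight = c(0.63, 0.85),
       cognitive_impairment = c(5.00, 2.64), diurnal_variation = c(0.73, 0.64),
       retardation = c(2.37, 1.71), sleep_disorder = c(2.93, 1.62),
       sense_of_despair = c(5.90, 2.28))
}

# internal: clinical table for a simulated cohort; planted correlation is
# applied within the patient arm against `param` (subject-level planted
# dynamics parameter).
simulate_clinical_table <- function(subjects, param, spec) {
  demo <- demographic_defaults()
  fm <- hamd24_default_factors()
  imax <- hamd24_item_max()
  n <- nrow(subjects)
  age <- education <- hama <- madrs <- rep(NA_real_, n)
  sex <- rep(NA_character_, n)
  items <- matrix(NA_integer_, n, 24,
                  dimnames = list(NULL, sprintf("hamd%02d", 1:24)))
  for (arm in unique(subjects$arm)) {
    idx <- which(subjects$arm == arm)
    d <- demo[[arm]]
    age[idx] <- round(pmin(60, pmax(16, stats::rnorm(length(idx), d$age[1], d$age[2]))))
    education[idx] <- round(pmin(22, pmax(6, stats::rnorm(length(idx), d$education[1], d$education[2]))))
    sex[idx] <- ifelse(stats::runif(length(idx)) < d$p_male, "male", "female")
  }
  pat <- which(subjects$arm == "patient")
  if (length(pat) > 0L) {
    fmom <- hamd_factor_moments()
    cl <- spec$clinical
    for (fname in names(fm)) {
      mom <- fmom[[fname]]
      mx <- sum(imax[fm[[fname]]])
      plantable <- !is.null(cl$r) && identical(cl$score, fname) &&
        length(pat) >= 4L && stats::sd(param[pat]) > .EPS
      sc <- if (plantable) {
        plant_correlated_scores(param[pat], mom[1], mom[2], cl$r)
      } else {
        stats::rnorm(length(pat), mom[1], mom[2])
      }
      sc <- pmin(mx, pmax(0, round(sc)))
      for (j in seq_along(pat))
        items[pat[j], fm[[fname]]] <- distribute_items(sc[j], imax[fm[[fname]]])
    }
    hama[pat] <- pmin(56, pmax(0, round(stats::rnorm(length(pat), 18.47, 7.67))))
    madrs[pat] <- pmin(60, pmax(0, round(stats::rnorm(length(pat), 22.10, 8.67))))
    if (length(pat) > 1L) madrs[sample(pat, 1L)] <- NA_real_
  }
  out <- data.frame(subject = subjects$subject, arm = subjects$arm,
                    age = age, sex = sex, education = education,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(items))
  out$hamd_total <- rowSums(items)
  out$hama <- hama
  out$madrs <- madrs
  out
}

#' Simulate a two-arm cohort with ground truth
#'
#' Generates per-subject recordings from the per-arm dynamics (subject-level
#' mean durations jittered log-normally with coefficient of variation
#' `subject_cv`), a clinical table whose planted score correlates with the
#' named subject-level dynamics parameter within the patient arm, and a
#' ground-truth bundle (planted and realized per-class statistics, frame
#' labels, templates). All randomness derives deterministically from `seed`.
#'
#' With the study-scale defaults (70 subjects of 3 minutes at 1000 Hz) the
#' recordings do not fit comfortably in memory; pass `out_dir` to stream
#' each recording to BrainVision files instead of keeping it.
#'
#' @param spec an `ms_cohort_spec`
#' @param seed master integer seed
#' @param out_dir optional directory: recordings are written as BrainVision
#'   triplets (`sub-XX.vhdr/.vmrk/.eeg`) and not kept in memory
#' @return list of class `ms_cohort` with `subjects` (data.frame),
#'   `recordings` (list of `ms_recording`, or file paths when `out_dir` is
#'   used), `clinical` (data.frame) and `ground_truth` (per-subject list)
#' @export
simulate_cohort <- function(spec, seed = 1L, out_dir = NULL) {
  stopifnot(inherits(spec, "ms_cohort_spec"))
  montage <- montage_64_1020()
  arms <- rep(names(spec$n_per_arm), spec$n_per_arm)
  nsub <- length(arms)
  subjects <- data.frame(subject = sprintf("sub-%02d", seq_len(nsub)),
                         arm = arms, stringsAsFactors = FALSE)
  recordings <- vector("list", nsub)
  ground_truth <- vector("list", nsub)
  param <- numeric(nsub)
  pclass <- match(sub("^duration_", "", spec$clinical$parameter %||% "duration_C"),
                  c("A", "B", "C", "D"))
  for (i in seq_len(nsub)) {
    base_dyn <- spec$dynamics[[arms[i]]]
    sdur <- with_preserved_seed(derive_seed(seed, 3L * i), {
      base_dyn$mean_duration_ms *
        exp(stats::rnorm(length(base_dyn$mean_duration_ms), 0, spec$subject_cv))
    })
    dyn <- dynamics_spec(sdur, shape = base_dyn$shape,
                         transition = base_dyn$transition,
                         carrier_hz = base_dyn$carrier_hz, snr = base_dyn$snr,
                         amplitude_uv = base_dyn$amplitude_uv)
    tmpl <- make_canonical_templates(montage, seed = derive_seed(seed, 3L * i + 1L),
                                     jitter = spec$template_jitter)
    sq <- simulate_state_sequence(dyn, spec$length_s, spec$fs,
                                  seed = derive_seed(seed, 3L * i + 2L))
    rec <- synthesize_recording(tmpl, sq, seed = derive_seed(seed, 3L * i + 2L) + 1L)
    param[i] <- sdur[pclass]
    ground_truth[[i]] <- list(subject = subjects$subject[i], arm = arms[i],
                              planted_duration_ms = sdur,
                              labels = sq$labels, templates = tmpl,
                              realized = sq$realized)
    if (is.null(out_dir)) {
      recordings[[i]] <- rec
    } else {
      recordings[[i]] <- write_brainvision(rec,
        file.path(out_dir, subjects$subject[i]))
    }
  }
  clinical <- with_preserved_seed(derive_seed(seed, 900001L),
    simulate_clinical_table(subjects, param, spec))
  structure(list(subjects = subjects, recordings = recordings,
                 clinical = clinical, ground_truth = ground_truth,
                 spec = spec, montage = montage),
            class = "ms_cohort")
}
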