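#' Group statistics for a microstate study
#'
#' Reproduces the study-level statistics on the extracted tables:
#' demographics (pooled t tests for age and education, Yates-corrected
#' chi-squared for sex), ANCOVA of every temporal parameter and transition
#' probability on group with education as covariate, Benjamini-Hochberg FDR
#' within each family (duration, occurrence, coverage: 4 tests each; the 12
#' transitions: one family), and Pearson correlations (with Fisher-z CIs)
#' between the clinical scores and the FDR-surviving parameters within the
#' patient arm.
#'
#' @param params long parameter table from [run_microstate_pipeline()]
#'   (columns subject, arm, class, mean_duration_ms, occurrence_per_s,
#'   coverage_pct)
#' @param transitions long transition table (subject, arm, from, to, prob)
#' @param clinical clinical table (subject, arm, age, sex, education,
#'   hamd01..hamd24, hama, madrs)
#' @param patient_arm,control_arm arm labels (defaults "patient",
#'   "control")
#' @param alpha significance threshold on FDR-adjusted p for selecting
#'   parameters to correlate (default 0.05)
#' @param factor_map HAMD-24 factor structure, default
#'   [hamd24_default_factors()]
#' @return list of class `ms_report` with data.frames `demographics`,
#'   `ancova` and `correlations`, plus `dropped` (subjects missing from
#'   either table)
#' @export
run_group_analysis <- function(params, transitions, clinical,
                               patient_arm = "patient",
                               control_arm = "control",
                               alpha = 0.05,
                               factor_map = hamd24_default_factors()) {
  ids <- Reduce(intersect, list(unique(params$subject),
                                unique(transitions$subject),
                                clinical$subject))
  dropped <- setdiff(unique(c(params$subject, transitions$subject,
                              clinical$subject)), ids)
  if (length(dropped) > 0L)
    message("dropping subjects without matched rows: ",
            paste(dropped, collapse = ", "))
  params <- params[params$subject %in% ids, ]
  transitions <- transitions[transitions$subject %in% ids, ]
  clinical <- clinical[clinical$subject %in% ids, ]
  clinical <- clinical[match(ids, clinical$subject), ]

  # --- demographics ----------------------------------------------------------
  pat <- clinical[clinical$arm == patient_arm, ]
  ctl <- clinical[clinical$arm == control_arm, ]
  demo <- NULL
  for (v in c("age", "education")) {
    tt <- summary_ttest(mean(pat[[v]]), stats::sd(pat[[v]]), nrow(pat),
                        mean(ctl[[v]]), stats::sd(ctl[[v]]), nrow(ctl))
    demo <- rbind(demo, data.frame(variable = v, statistic = tt$t,
                                   df = tt$df, p = tt$p, effect = tt$d,
                                   test = "t", stringsAsFactors = FALSE))
  }
  sex_tab <- rbind(table(factor(pat$sex, c("male", "female"))),
                   table(factor(ctl$sex, c("male", "female"))))
  cs <- chi2_2x2(sex_tab, yates = TRUE)
  demo <- rbind(demo, data.frame(variable = "sex", statistic = cs$chi2,
                                 df = cs$df, p = cs$p, effect = NA_real_,
                                 test = "chi2", stringsAsFactors = FALSE))

  # --- ANCOVA families -------------------------------------------------------
  edu <- stats::setNames(clinical$education, clinical$subject)
  arm <- stats::setNames(clinical$arm, clinical$subject)
  run_one <- function(sub, y, family, parameter) {
    g <- factor(arm[sub], levels = c(control_arm, patient_arm))
    a <- ancova_group(y, g, edu[sub])
    data.frame(family = family, parameter = parameter, F = a$F,
               df1 = a$df1, df2 = a$df2, p = a$p, eta_p2 = a$eta_p2,
               adj_mean_patient = a$adjusted_means[[patient_arm]],
               adj_mean_control = a$adjusted_means[[control_arm]],
               stringsAsFactors = FALSE)
  }
  anc <- NULL
  fam_cols <- c(duration = "mean_duration_ms", occurrence = "occurrence_per_s",
                coverage = "coverage_pct")
  for (fam in names(fam_cols)) {
    for (cl in sort(unique(params$class))) {
      d <- params[params$class == cl, ]
      anc <- rbind(anc, run_one(d$subject, d[[fam_cols[fam]]], fam,
                                paste0(fam, "_", cl)))
    }
  }
  for (ft in unique(paste(transitions$from, transitions$to))) {
    d <- transitions[paste(transitions$from, transitions$to) == ft, ]
    anc <- rbind(anc, run_one(d$subject, d$prob, "transition",
                              paste0("p_", d$from[1], "_to_", d$to[1])))
  }
  anc$p_fdr <- NA_real_
  for (fam in unique(anc$family)) {
    i <- anc$family == fam
    anc$p_fdr[i] <- bh_fdr(anc$p[i])
  }

  # --- correlations within the patient arm -----------------------------------
  items <- as.matrix(pat[, sprintf("hamd%02d", 1:24)])
  fsc <- hamd24_factor_scores(items, factor_map)
  scores <- data.frame(fsc, hamd_total = pat$hamd_total, hama = pat$hama,
                       madrs = pat$madrs)
  sig <- anc$parameter[anc$p_fdr < alpha]
  value_of <- function(parameter) {
    if (grepl("^p_", parameter)) {
      pp <- strsplit(parameter, "_")[[1]]
      d <- transitions[transitions$from == pp[2] & transitions$to == pp[4] &
                         transitions$arm == patient_arm, ]
      stats::setNames(d$prob, d$subject)
    } else {
      pp <- strsplit(parameter, "_")[[1]]
      d <- params[params$class == pp[2] & params$arm == patient_arm, ]
      stats::setNames(d[[fam_cols[pp[1]]]], d$subject)
    }
  }
  cors <- NULL
  for (par in sig) {
    v <- value_of(par)[pat$subject]
    for (sc in names(scores)) {
      ok <- stats::complete.cases(v, scores[[sc]])
      if (sum(ok) < 4L || stats::sd(scores[[sc]][ok]) < .EPS) next
      ci <- pearson_ci(v[ok], scores[[sc]][ok])
      cors <- rbind(cors, data.frame(parameter = par, score = sc, r = ci$r,
                                     n = ci$n, ci_low = ci$ci[1],
                                     ci_high = ci$ci[2], p = ci$p,
                                     stringsAsFactors = FALSE))
    }
  }
  structure(list(demographics = demo, ancova = anc, correlations = cors,
                 dropped = dropped),
            class = "ms_report")
}

#' @export
print.ms_report <- function(x, ...) {
  cat("<ms_report>\n-- demographics --\n")
  print(x$demographics, digits = 4)
  cat("-- group ANCOVA (FDR-significant rows) --\n")
  sig <- x$ancova[x$ancova$p_fdr < 0.05, ]
  print(if (nrow(sig) > 0) sig else x$ancova[0, ], digits = 4)
  if (!is.null(x$correlations)) {
    cat("-- patient-arm correlations --\n")
    print(x$correlations, digits = 4)
  }
  invisible(x)
}

#' Write a group-analysis report to disk
#'
#' Writes the demographics, ANCOVA and correlation tables as TSV plus a
#' combined JSON file.
#'
#' @param report an `ms_report`
#' @param dir output directory (created if missing)
#' @return invisibly, the paths written
#' @export
write_analysis_report <- function(report, dir) {
  stopifnot(inherits(report, "ms_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in c("demographics", "ancova", "correlations")) {
    tab <- report[[nm]]
    if (is.null(tab)) next
    p <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  pj <- file.path(dir, "report.json")
  jsonlite::write_json(report[c("demographics", "ancova", "correlations")],
                       pj, dataframe = "rows", na = "null", digits = NA,
                       auto_unbox = TRUE)
  invisible(c(paths, pj))
}

#' Type-I error calibration of the group ANCOVA at a planted null
#'
#' Simulates replicate null cohorts (both arms share the same dynamics),
#' extracts the mean duration of one class per subject from the planted
#' label sequences, draws an education covariate from the built-in
#' demographic model, runs the group ANCOVA, and reports the fraction of
#' replicates rejecting at `alpha`. Sequences are simulated at the label
#' level (no EEG synthesis), which isolates the parameter-extraction and
#' inference chain whose calibration is at stake.
#'
#' @param n_replicates number of replicate cohorts (default 200)
#' @param n_per_arm named sizes, default `c(patient = 30, control = 40)`
#' @param dyn shared `ms_dynamics` for both arms
#' @param length_s,fs sequence length and rate per subject
#' @param class_index which class's mean duration to test (default 3, C)
#' @param alpha nominal level (default 0.05)
#' @param seed master seed
#' @return list with `rejection_rate`, `p` (per-replicate p-values), and
#'   `n_replicates`
#' @export
calibrate_type1 <- function(n_replicates = 200,
                            n_per_arm = c(patient = 30, control = 40),
                            dyn = dynamics_spec(c(A = 60, B = 65, C = 62, D = 68)),
                            length_s = 60, fs = 1000, class_index = 3,
                            alpha = 0.05, seed = 1) {
  demo <- demographic_defaults()
  arms <- rep(names(n_per_arm), n_per_arm)
  nsub <- length(arms)
  pvals <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    dur <- numeric(nsub)
    for (s in seq_len(nsub)) {
      sq <- simulate_state_sequence(dyn, length_s, fs,
                                    seed = derive_seed(seed, r * 1000L + s))
      tp <- temporal_parameters(label_sequence(sq$labels, fs,
                                               classes = dyn$classes))
      dur[s] <- tp$mean_duration_ms[class_index]
    }
    edu <- with_preserved_seed(derive_seed(seed, 500000L + r), {
      vapply(arms, function(a)
        stats::rnorm(1, demo[[a]]$education[1], demo[[a]]$education[2]), 0)
    })
    pvals[r] <- ancova_group(dur, arms, edu)$p
  }
  list(rejection_rate = mean(pvals < alpha), p = pvals,
       n_replicates = n_replicates)
}
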