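test_that("HAMD-24 factor scoring sums items and validates the map", {
  expect_equal(unname(hamd24_factor_scores(rep(0, 24))), rep(0, 7))
  items <- rep(1, 24)
  fs <- hamd24_factor_scores(items)
  expect_equal(unname(fs), vapply(hamd24_default_factors(), length, 0L),
               ignore_attr = TRUE)
  # missing item flags the factor
  items[10] <- NA
  expect_true(is.na(hamd24_factor_scores(items)[["anxiety_somatization"]]))
  expect_false(anyNA(hamd24_factor_scores(items)[-1]))
  # an item assigned to two factors is rejected
  bad <- hamd24_default_factors()
  bad$weight <- c(16, 10)
  expect_error(hamd24_factor_scores(rep(0, 24), bad), "two factors")
  # matrix input gives one row per subject
  m <- rbind(rep(0, 24), rep(1, 24))
  expect_equal(hamd24_factor_scores(m)$weight, c(0, 1))
})

test_that("synthetic cohorts reproduce the planted anxiety/somatization moments", {
  dyn <- dynamics_spec(snr = 20)
  spec <- cohort_spec(n_per_arm = c(patient = 150, control = 2),
                      dynamics = list(patient = dyn, control = dyn),
                      length_s = 2, fs = 100,
                      clinical = list(score = "anxiety_somatization",
                                      parameter = "duration_C", r = -0.4))
  coh <- simulate_cohort(spec, seed = 23)
  pat <- coh$clinical[coh$clinical$arm == "patient", ]
  sc <- hamd24_factor_scores(as.matrix(pat[, sprintf("hamd%02d", 1:24)]))
  # Monte-Carlo tolerance ~ 3 SE
  expect_lt(abs(mean(sc$anxiety_somatization) - 5.50), 3 * 2.61 / sqrt(150))
  expect_lt(abs(sd(sc$anxiety_somatization) - 2.61), 0.8)
  # planted negative correlation with the subject-level class-C duration
  dur_c <- vapply(coh$ground_truth, function(g) g$planted_duration_ms[3], 0)
  r <- cor(dur_c[coh$subjects$arm == "patient"], sc$anxiety_somatization)
  expect_lt(r, -0.15)
})

test_that("summary t test reproduces pooled t, d and the raw-data equivalence", {
  # reference t values come from unrounded raw data; the printed
  # two-decimal moments determine t only to within ~0.005
  a <- summary_ttest(26.40, 7.36, 30, 24.10, 5.99, 40)
  expect_equal(a$t, 1.442, tolerance = 0.005)
  expect_equal(round(a$d, 2), 0.35)
  expect_equal(a$df, 68)
  b <- summary_ttest(14.30, 3.53, 30, 15.85, 2.55, 40)
  expect_equal(b$t, -2.133, tolerance = 0.005)
  expect_equal(round(b$d, 2), 0.52)
  z <- summary_ttest(5, 1, 10, 5, 1, 10)
  expect_equal(z$t, 0)
  expect_equal(z$d, 0)

  # consistency: computed moments of raw data give the same result as
  # t.test(var.equal = TRUE) on the raw data
  set.seed(2)
  x <- rnorm(14, 3, 2); y <- rnorm(19, 2, 2)
  s <- summary_ttest(mean(x), sd(x), 14, mean(y), sd(y), 19)
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(s$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(s$p, tt$p.value, tolerance = 1e-12)
  expect_error(summary_ttest(1, 1, 1, 2, 1, 10), "n >= 2")
})

test_that("2x2 chi-squared matches the Yates-corrected value and the brute-force oracle", {
  y <- chi2_2x2(rbind(c(8, 22), c(16, 24)), yates = TRUE)
  expect_equal(round(y$chi2, 3), 0.826)
  expect_equal(y$df, 1L)
  # perfectly proportional table: statistic 0 with the clipped correction
  expect_equal(chi2_2x2(rbind(c(10, 20), c(20, 40)))$chi2, 0)
  # without Yates: direct sum((O-E)^2/E)
  set.seed(6)
  for (rep in 1:10) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    raw <- chi2_2x2(tab, yates = FALSE)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(raw$chi2, sum((tab - E)^2 / E), tolerance = 1e-12)
    expect_equal(chi2_2x2(tab, yates = TRUE)$chi2,
                 unname(chisq.test(tab, correct = TRUE)$statistic),
                 tolerance = 1e-12)
  }
  expect_error(chi2_2x2(rbind(c(0, 0), c(1, 2))), "marginal")
})

test_that("ANCOVA matches the two-model RSS oracle and its eta-squared identity", {
  set.seed(10)
  n1 <- 30; n2 <- 40
  g <- rep(c("patient", "control"), c(n1, n2))
  edu <- rnorm(n1 + n2, 15, 3)
  y <- 60 + 0.5 * edu + ifelse(g == "patient", 4, 0) + rnorm(n1 + n2, sd = 6)
  a <- ancova_group(y, g, edu)
  expect_equal(a$df1, 1L)
  expect_equal(a$df2, 67L)      # n - 3 with one covariate

  # independent oracle: explicit full-vs-reduced residual sums of squares
  X_full <- cbind(1, edu, g == "patient")
  X_red <- cbind(1, edu)
  rss <- function(X) sum(qr.resid(qr(X), y)^2)
  F_oracle <- ((rss(X_red) - rss(X_full)) / 1) / (rss(X_full) / (n1 + n2 - 3))
  expect_equal(a$F, F_oracle, tolerance = 1e-10)
  expect_equal(a$eta_p2, a$F / (a$F + a$df2), tolerance = 1e-12)
  expect_equal(a$eta_p2,
               (rss(X_red) - rss(X_full)) / rss(X_red), tolerance = 1e-10)

  # adjusted means evaluated at the grand covariate mean
  fit <- lm(y ~ edu + g2, data = data.frame(y = y, edu = edu,
                                            g2 = factor(g, c("control", "patient"))))
  pred <- predict(fit, newdata = data.frame(edu = mean(edu),
                                            g2 = factor(c("control", "patient"))))
  expect_equal(unname(a$adjusted_means), unname(pred), tolerance = 1e-10)

  # null case: no group effect, orthogonal covariate -> median F near zero
  set.seed(11)
  Fs <- replicate(100, {
    yy <- rnorm(70)
    ancova_group(yy, g, edu)$F
  })
  expect_lt(median(Fs), qf(0.6, 1, 67))
  expect_gt(mean(Fs < qf(0.95, 1, 67)), 0.85)

  expect_warning(a0 <- ancova_group(y, g, rep(3, 70)), "constant covariate")
  expect_equal(a0$df2, 68L)
})

test_that("BH adjustment matches the textbook step-up oracle", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  set.seed(14)
  for (rep in 1:10) {
    p <- runif(12)
    got <- bh_fdr(p)
    # step-up: sort descending, cumulative min of p * m / rank, cap at 1
    o <- order(p, decreasing = TRUE)
    adj <- pmin(1, cummin(p[o] * length(p) / rank(p)[o]))
    oracle <- adj[order(o)]
    expect_equal(got, oracle, tolerance = 1e-12)
    expect_true(all(got >= p - 1e-15))
    expect_identical(order(got[order(p)]), seq_along(p))  # order preserved
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("Fisher-z correlation intervals reproduce reported CIs", {
  ci1 <- pearson_ci_summary(-0.403, 30)
  expect_equal(ci1$ci, c(-0.666, -0.050), tolerance = 1e-3)
  expect_lt(ci1$p, 0.05)
  ci2 <- pearson_ci_summary(-0.423, 30)
  expect_equal(ci2$ci, c(-0.680, -0.074), tolerance = 1e-3)
  ci3 <- pearson_ci_summary(0.380, 30)
  expect_equal(ci3$ci, c(0.023, 0.651), tolerance = 1e-3)

  set.seed(20)
  x <- rnorm(28); y <- 0.5 * x + rnorm(28)
  full <- pearson_ci(x, y)
  expect_equal(full$r, cor(x, y), tolerance = 1e-12)
  expect_equal(full$p, cor.test(x, y)$p.value, tolerance = 1e-10)
  expect_true(full$ci[1] < full$r && full$r < full$ci[2])

  # degenerate perfect correlation handled
  lin <- pearson_ci(1:10, 2 * (1:10) + 3)
  expect_equal(lin$r, 1)
  expect_equal(lin$p, 0)
  expect_error(pearson_ci(1:10, rep(2, 10)), "zero variance")
  expect_error(pearson_ci_summary(0.5, 3), "n >= 4")
})

test_that("the full group analysis produces the expected families and report shape", {
  dyn <- dynamics_spec(snr = 20)
  spec <- cohort_spec(n_per_arm = c(patient = 8, control = 8),
                      dynamics = list(patient = dyn, control = dyn),
                      length_s = 4, fs = 250)
  coh <- simulate_cohort(spec, seed = 29)
  # parameter/transition tables built directly from the planted sequences
  params <- NULL; transitions <- NULL
  for (i in seq_along(coh$ground_truth)) {
    gt <- coh$ground_truth[[i]]
    ls <- label_sequence(gt$labels, spec$fs)
    tp <- temporal_parameters(ls)
    params <- rbind(params, cbind(subject = gt$subject, arm = gt$arm, tp))
    tm <- transition_matrix(ls)
    tr <- expand.grid(from = ls$classes, to = ls$classes,
                      stringsAsFactors = FALSE)
    tr <- tr[tr$from != tr$to, ]
    tr$prob <- tm$prob[cbind(match(tr$from, ls$classes),
                             match(tr$to, ls$classes))]
    transitions <- rbind(transitions,
                         cbind(subject = gt$subject, arm = gt$arm, tr))
  }
  rep <- run_group_analysis(params, transitions, coh$clinical)
  expect_equal(nrow(rep$ancova), 12 + 12)   # 4 classes x 3 parameters + 12 transitions
  expect_equal(nrow(rep$demographics), 3)
  expect_setequal(unique(rep$ancova$family),
                  c("duration", "occurrence", "coverage", "transition"))
  expect_true(all(rep$ancova$p_fdr >= rep$ancova$p - 1e-12))
  expect_true(all(rep$ancova$df2 == 13))    # 16 subjects - 3
  # report writing round-trips through TSV
  out <- file.path(tempdir(), "ms-report-test")
  write_analysis_report(rep, out)
  back <- read.delim(file.path(out, "ancova.tsv"))
  expect_equal(nrow(back), 24)
  expect_true(file.exists(file.path(out, "report.json")))
})
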