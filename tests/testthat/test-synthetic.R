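test_that("canonical templates have the expected orientations and are well separated", {
  t <- make_canonical_templates(std_montage)
  expect_identical(t$labels, c("A", "B", "C", "D"))
  # unit norm, average reference
  expect_equal(colSums(t$maps^2), c(A = 1, B = 1, C = 1, D = 1))
  expect_lt(max(abs(colMeans(t$maps))), 1e-12)

  # orientation checks are sign-free: accept the extremal pair either way round
  quadrant <- function(map) {
    hi <- which.max(map); lo <- which.min(map)
    rbind(c(std_montage$x[hi], std_montage$y[hi]),
          c(std_montage$x[lo], std_montage$y[lo]))
  }
  qa <- quadrant(t$maps[, "A"])
  expect_true((qa[1, 1] > 0 && qa[1, 2] > 0 && qa[2, 1] < 0 && qa[2, 2] < 0) ||
              (qa[1, 1] < 0 && qa[1, 2] < 0 && qa[2, 1] > 0 && qa[2, 2] > 0))
  qb <- quadrant(t$maps[, "B"])
  expect_true((qb[1, 1] < 0 && qb[1, 2] > 0 && qb[2, 1] > 0 && qb[2, 2] < 0) ||
              (qb[1, 1] > 0 && qb[1, 2] < 0 && qb[2, 1] < 0 && qb[2, 2] > 0))
  qc <- quadrant(t$maps[, "C"])           # anterior-posterior midline axis
  expect_true(abs(qc[1, 1]) < 0.3 && abs(qc[2, 1]) < 0.3 &&
                qc[1, 2] * qc[2, 2] < 0)
  qd <- quadrant(t$maps[, "D"])           # fronto-central extremum
  expect_true(any(abs(qd[, 1]) < 0.3 & qd[, 2] > 0 & qd[, 2] < 0.5))

  # pairwise polarity-invariant correlations below 0.7 (oracle: channel-wise
  # Pearson)
  for (i in 1:3) for (j in (i + 1):4)
    expect_lt(spatial_correlation(t$maps[, i], t$maps[, j]), 0.7)

  # deterministic, also under jitter
  expect_identical(t$maps, make_canonical_templates(std_montage)$maps)
  j1 <- make_canonical_templates(std_montage, seed = 5, jitter = 0.1)
  j2 <- make_canonical_templates(std_montage, seed = 5, jitter = 0.1)
  expect_identical(j1$maps, j2$maps)
  expect_false(identical(j1$maps, t$maps))

  expect_error(make_canonical_templates(ms_montage(c("a", "b", "c"),
                                                   c(0, 1, -1), c(1, 0, 0))),
               "at least 4")
})

test_that("forced deterministic dynamics are realized exactly", {
  dyn <- dynamics_spec(c(A = 80, B = 80), shape = 1e8,
                       transition = matrix(c(0, 1, 1, 0), 2))
  sq <- simulate_state_sequence(dyn, 10, 1000, seed = 3)
  inner <- sq$segments$length[-nrow(sq$segments)]
  expect_true(all(inner == 80L))
  expect_equal(sq$realized$transition_prob[1, 2], 1)
  expect_equal(sq$realized$transition_prob[2, 1], 1)
  expect_true(all(abs(sq$labels[1:160] - rep(sq$labels[c(1, 81)], each = 80)) == 0))
})

test_that("semi-Markov sequences reproduce planted durations and the run-length identity", {
  dyn <- dynamics_spec(c(A = 60, B = 60, C = 80, D = 60))
  sq <- simulate_state_sequence(dyn, 300, 1000, seed = 21)
  expect_gt(sum(sq$segments$value == 3), 1000)  # enough class-C segments
  expect_lt(abs(sq$realized$duration_ms[3] / 80 - 1), 0.05)

  # coverage = occurrence x mean duration, from an independent run-length
  # oracle over the raw labels
  r <- rle(sq$labels)
  total_s <- length(sq$labels) / 1000
  for (c in 1:4) {
    occ <- sum(r$values == c) / total_s
    dur_s <- mean(r$lengths[r$values == c]) / 1000
    cov <- sum(r$lengths[r$values == c]) / length(sq$labels)
    expect_equal(occ * dur_s, cov, tolerance = 1e-12)
    expect_equal(sq$realized$coverage_pct[c], 100 * cov, tolerance = 1e-12)
  }
  expect_equal(sum(sq$realized$coverage_pct), 100, tolerance = 1e-9)

  # realized transition matrix: zero diagonal, populated rows sum to 1
  expect_true(all(diag(sq$realized$transition_prob) == 0))
  expect_equal(unname(rowSums(sq$realized$transition_prob)), rep(1, 4),
               tolerance = 1e-12)

  # determinism and error branches
  expect_identical(sq$labels,
                   simulate_state_sequence(dyn, 300, 1000, seed = 21)$labels)
  expect_error(dynamics_spec(c(A = 60, B = 60),
                             transition = matrix(c(0, 0, 1, 0), 2)),
               "row")
  expect_error(simulate_state_sequence(dyn, 0.5, 1000), "10 planted")
})

test_that("synthesized recordings are faithful in the noiseless limit and deterministic", {
  s <- quick_subject(seed = 5, length_s = 5, snr = Inf)
  rec <- s$rec
  carrier <- sin(2 * pi * 10 * (seq_len(ncol(rec$data)) - 1) / 1000)
  strong <- which(abs(carrier) > 0.2)
  for (i in strong[c(1, 50, 500, 2000)]) {
    r <- spatial_correlation(rec$data[, i], canon$maps[, s$seq$labels[i]])
    expect_gt(r, 1 - 1e-9)
  }
  expect_identical(rec$data,
                   synthesize_recording(canon, s$seq, seed = 6)$data)
  dyn_bad <- s$dyn
  dyn_bad$snr <- 0
  sq_bad <- s$seq
  sq_bad$dyn <- dyn_bad
  expect_error(synthesize_recording(canon, sq_bad), "snr")
})

test_that("noiseless backfit against the true templates recovers planted labels", {
  s <- quick_subject(seed = 9, length_s = 6, snr = Inf)
  ep <- average_reference(segment_epochs(s$rec, epoch_s = 2, reject_uv = 1e6))
  ls <- backfit(canon, ep)
  n <- length(ls$labels)
  agree <- mean(ls$labels == s$seq$labels[seq_len(n)], na.rm = TRUE)
  expect_gte(agree, 0.99)
})

test_that("cohort simulation produces consistent bookkeeping and ground truth", {
  dyn <- dynamics_spec(c(A = 60, B = 60, C = 80, D = 60), snr = 20)
  spec <- cohort_spec(n_per_arm = c(patient = 2, control = 3),
                      dynamics = list(patient = dyn, control = dyn),
                      length_s = 4, fs = 250)
  coh <- simulate_cohort(spec, seed = 17)
  expect_length(coh$recordings, 5)
  expect_equal(nrow(coh$clinical), 5)
  expect_identical(coh$clinical$subject, coh$subjects$subject)
  for (gt in coh$ground_truth) {
    expect_equal(sum(gt$realized$coverage_pct), 100, tolerance = 1e-9)
    expect_length(gt$labels, 4 * 250)
  }
  # patients carry item scores within instrument bounds; controls do not
  items <- as.matrix(coh$clinical[coh$clinical$arm == "patient",
                                  sprintf("hamd%02d", 1:24)])
  expect_true(all(items >= 0 & items <= rep(hamd24_item_max(),
                                            each = nrow(items))))
  expect_true(all(is.na(coh$clinical[coh$clinical$arm == "control", "hamd01"])))
  # deterministic in the master seed
  coh2 <- simulate_cohort(spec, seed = 17)
  expect_identical(coh$recordings[[1]]$data, coh2$recordings[[1]]$data)
  expect_identical(coh$clinical, coh2$clinical)
})

test_that("planted clinical correlations are recovered across replicates", {
  hits <- 0
  ci_ref <- tanh(atanh(0.4) + c(-1, 1) * qnorm(0.975) / sqrt(200 - 3))
  set.seed(1)
  for (r in 1:100) {
    x <- rnorm(200, 70, 8)
    y <- plant_correlated_scores(x, mean = 5.5, sd = 2.6, rho = 0.4)
    rr <- cor(x, y)
    if (rr > ci_ref[1] && rr < ci_ref[2]) hits <- hits + 1
  }
  expect_gte(hits, 90)
  expect_error(plant_correlated_scores(rnorm(10), 5, 0, 0.4), "incompatible")
  expect_error(plant_correlated_scores(rep(1, 10), 5, 2, 0.4), "constant")
})
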