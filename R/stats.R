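#' Default HAMD-24 seven-factor structure
#'
#' The conventional decomposition of the 24-item Hamilton Depression Rating
#' Scale into seven symptom factors. The anxiety/somatization factor
#' comprises psychic anxiety, somatic anxiety, gastrointestinal symptoms,
#' general somatic symptoms, hypochondriasis and insight. The mapping is
#' configurable wherever it is consumed.
#'
#' @return named list mapping factor name to 1-based item indices
#' @export
hamd24_default_factors <- function() {
  list(anxiety_somatization = c(10, 11, 12, 13, 15, 17),
       weight = 16,
       cognitive_impairment = c(2, 3, 9, 19, 20, 21),
       diurnal_variation = 18,
       retardation = c(1, 7, 8, 14),
       sleep_disorder = c(4, 5, 6),
       sense_of_despair = c(22, 23, 24))
}

#' Per-item maxima of the HAMD-24
#'
#' @return integer vector of length 24 (items scored 0-4 or 0-2)
#' @export
hamd24_item_max <- function() {
  mx <- rep(4L, 24)
  mx[c(4, 5, 6, 12, 13, 14, 16, 17, 18, 21)] <- 2L
  mx
}

validate_factor_map <- function(fm) {
  items <- unlist(fm)
  if (any(items < 1 | items > 24)) stop("factor items must lie in 1..24")
  if (anyDuplicated(items)) stop("an item is assigned to two factors")
  if (length(fm) != 7L) stop("seven factors expected")
  invisible(fm)
}

#' HAMD-24 factor scores
#'
#' Sums the item scores within each factor of the map. Factors containing
#' a missing item are returned as `NA`.
#'
#' @param items numeric vector (or one-row matrix/data.frame) of the 24
#'   item scores, or a matrix/data.frame with 24 columns (one row per
#'   subject)
#' @param factor_map named list of item indices; default
#'   [hamd24_default_factors()]
#' @return named numeric vector of factor sums, or a data.frame when
#'   `items` has multiple rows
#' @export
hamd24_factor_scores <- function(items, factor_map = hamd24_default_factors()) {
  validate_factor_map(factor_map)
  m <- as.matrix(items)
  if (ncol(m) == 1L && nrow(m) == 24L) m <- t(m)
  if (ncol(m) != 24L) stop("24 HAMD item scores required")
  out <- sapply(factor_map, function(ix) rowSums(m[, ix, drop = FALSE]))
  if (nrow(m) == 1L) {
    v <- as.numeric(out)
    names(v) <- names(factor_map)
    v
  } else {
    as.data.frame(out)
  }
}

#' Two-sample Student t test from summary statistics
#'
#' Pooled-variance two-sample t test computed from group means, standard
#' deviations and sizes, with Cohen's d on the pooled SD. Matches
#' `t.test(var.equal = TRUE)` on the raw data.
#'
#' @param m1,sd1,n1 mean, SD and size of group 1
#' @param m2,sd2,n2 mean, SD and size of group 2
#' @return list with `t`, `df`, `p` (two-tailed) and `d`
#' @export
summary_ttest <- function(m1, sd1, n1, m2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be >= 0")
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  if (sp2 < .EPS) {
    t <- if (abs(m1 - m2) < .EPS) 0 else sign(m1 - m2) * Inf
  } else {
    t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
       d = if (sp2 < .EPS) 0 else abs(m1 - m2) / sqrt(sp2))
}

#' Chi-squared test for a 2x2 table
#'
#' Pearson chi-squared statistic with optional Yates continuity correction
#' (the correction term is clipped at zero), df = 1.
#'
#' @param tab 2x2 matrix of nonnegative integer counts
#' @param yates apply the continuity correction (default `TRUE`)
#' @return list with `chi2`, `df`, `p`
#' @export
chi2_2x2 <- function(tab, yates = TRUE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2L)) stop("a 2x2 table is required")
  if (any(tab < 0)) stop("counts must be nonnegative")
  n <- sum(tab)
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) stop("zero marginal: test undefined")
  E <- outer(rs, cs) / n
  dev <- abs(tab - E)
  if (yates) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / E)
  list(chi2 = chi2, df = 1L, p = stats::pchisq(chi2, 1L, lower.tail = FALSE))
}

#' One-way ANCOVA with a single covariate
#'
#' Fits `y ~ covariate + group` and tests the group effect adjusted for the
#' covariate: `F = (SS_group / 1) / (SS_resid / (n - 3))`, with partial
#' eta squared `SS_group / (SS_group + SS_resid)` and covariate-adjusted
#' group means (predictions at the grand covariate mean). If the covariate
#' is constant the model degrades to a one-way ANOVA with a warning.
#'
#' @param y numeric response (one value per subject)
#' @param group two-level factor or character vector
#' @param covariate numeric covariate (e.g. education years)
#' @return list with `F`, `df1`, `df2`, `p`, `eta_p2`, `adjusted_means`
#'   (named by group level), and the fitted `lm` in `fit`
#' @export
ancova_group <- function(y, group, covariate) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L) stop("exactly two groups required")
  if (any(table(group) < 3L)) stop("at least 3 subjects per group required")
  ok <- stats::complete.cases(y, group, covariate)
  y <- y[ok]; group <- droplevels(group[ok]); covariate <- covariate[ok]
  use_cov <- stats::sd(covariate) > .EPS
  if (!use_cov) warning("constant covariate: reducing to one-way ANOVA")
  fit <- if (use_cov) stats::lm(y ~ covariate + group)
         else stats::lm(y ~ group)
  a <- stats::anova(fit)                    # sequential; group is last
  grow <- "group"
  ss_g <- a[grow, "Sum Sq"]
  ss_r <- a["Residuals", "Sum Sq"]
  Fv <- a[grow, "F value"]
  df1 <- a[grow, "Df"]
  df2 <- a["Residuals", "Df"]
  cm <- mean(covariate)
  nd <- data.frame(covariate = cm, group = levels(group))
  adj <- stats::predict(fit, newdata = nd)
  names(adj) <- levels(group)
  list(F = Fv, df1 = df1, df2 = df2, p = a[grow, "Pr(>F)"],
       eta_p2 = ss_g / (ss_g + ss_r), adjusted_means = adj, fit = fit)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1 (delegates to
#' `p.adjust(method = "BH")`).
#'
#' @param p numeric vector of p-values in `[0, 1]`
#' @return adjusted p-values in input order
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Sample correlation with a 95 percent confidence interval obtained by the
#' Fisher z transform, `tanh(atanh(r) +/- z_{0.975} / sqrt(n - 3))`, and a
#' two-tailed p-value from `t = r sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2`
#' degrees of freedom. [pearson_ci_summary()] computes the same interval
#' from a reported `(r, n)` pair.
#'
#' @param x,y numeric vectors (pairwise-complete observations are used)
#' @param conf confidence level, default 0.95
#' @return list with `r`, `n`, `ci` (length 2), `p`
#' @export
pearson_ci <- function(x, y, conf = 0.95) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("n >= 4 required")
  if (stats::sd(x) < .EPS || stats::sd(y) < .EPS)
    stop("zero variance: correlation undefined")
  r <- stats::cor(x, y)
  c(pearson_ci_summary(r, n, conf), list())
}

#' @rdname pearson_ci
#' @param r sample correlation
#' @param n sample size
#' @export
pearson_ci_summary <- function(r, n, conf = 0.95) {
  if (n < 4L) stop("n >= 4 required")
  zc <- stats::qnorm(1 - (1 - conf) / 2)
  if (abs(r) >= 1) {
    ci <- c(r, r)                       # degenerate perfect correlation
    p <- 0
  } else {
    z <- atanh(r)
    ci <- tanh(z + c(-1, 1) * zc / sqrt(n - 3))
    t <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p <- 2 * stats::pt(-abs(t), n - 2)
  }
  list(r = r, n = n, ci = ci, p = p)
}
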