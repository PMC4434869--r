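#' Pooled median of per-CTC keratin values
#'
#' Median over the pooled multiset of all patients' CTC keratin values
#' (standard mid-point convention for even counts). This single cohort-wide
#' value is the split point for the per-CTC high/low calls.
#'
#' @param ctcs Data frame with columns \code{patient_id} and
#'   \code{keratin}, one row per CTC (or a bare numeric vector).
#' @return The pooled median (scalar).
#' @export
pooled_median <- function(ctcs) {
  vals <- if (is.numeric(ctcs)) ctcs else ctcs$keratin
  if (length(vals) == 0L) stop("no CTC keratin values: cannot compute pooled median")
  median(vals)
}

#' Label patients as high-keratin (HK) or low-keratin (LK)
#'
#' Each CTC is "high" iff its keratin value is \emph{strictly above} the
#' pooled median (values equal to the median are not high). A patient is HK
#' iff strictly more than 50\% of their CTCs are high, and LK otherwise —
#' in particular, a patient with exactly half high CTCs is LK, which makes
#' the rule a partition.
#'
#' @param patients Data frame with a \code{patient_id} column.
#' @param ctcs Data frame with \code{patient_id} and \code{keratin}.
#' @param median_keratin The pooled median from \code{\link{pooled_median}}
#'   (computed from \code{ctcs} when missing).
#' @return \code{patients} with added columns \code{n_ctcs_observed},
#'   \code{fraction_high} and \code{keratin_group} ("HK"/"LK").
#' @export
label_patients <- function(patients, ctcs, median_keratin = pooled_median(ctcs)) {
  stopifnot("patient_id" %in% names(patients),
            all(c("patient_id", "keratin") %in% names(ctcs)))
  if (!all(patients$patient_id %in% ctcs$patient_id)) {
    stop("every patient must have at least one CTC keratin value")
  }
  high <- ctcs$keratin > median_keratin
  frac <- tapply(high, ctcs$patient_id, mean)
  n_obs <- tapply(high, ctcs$patient_id, length)
  patients$n_ctcs_observed <- as.integer(n_obs[patients$patient_id])
  patients$fraction_high <- as.numeric(frac[patients$patient_id])
  patients$keratin_group <- ifelse(patients$fraction_high > 0.5, "HK", "LK")
  patients
}

#' Compare per-CTC keratin levels between two patient groups
#'
#' Pools the per-CTC keratin values of all patients, splits them by a
#' binary patient-level covariate (e.g. triple-negative vs other) and
#' compares the two groups with a two-sample t-test. An F-test of equal
#' variances is reported alongside; the t-test pools variances when the
#' F-test does not reject at 0.05, mirroring the classical
#' check-then-pool workflow.
#'
#' @param patients Data frame with \code{patient_id} and the covariate.
#' @param ctcs Data frame with \code{patient_id} and \code{keratin}.
#' @param covariate Name of a logical/binary column of \code{patients};
#'   patients with NA are excluded listwise (counted in the result).
#' @return A list with per-group \code{n}, \code{mean}, \code{sd}, the
#'   \code{mean_difference} (group TRUE minus group FALSE),
#'   \code{t_statistic}, \code{p_value}, \code{variance_test_p} and
#'   \code{n_excluded}.
#' @export
compare_keratin_by_group <- function(patients, ctcs, covariate = "triple_negative") {
  stopifnot(covariate %in% names(patients))
  cov <- patients[[covariate]]
  if (is.character(cov)) cov <- cov == "positive"
  keep <- !is.na(cov)
  n_excluded <- sum(!keep)
  pts <- patients$patient_id[keep]; cov <- cov[keep]
  grp <- cov[match(ctcs$patient_id, pts)]
  x <- ctcs$keratin[which(grp)]          # covariate-positive group
  y <- ctcs$keratin[which(!grp)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least 2 CTC keratin values")
  }
  if (sd(x) == 0 && sd(y) == 0) {
    # degenerate: both groups constant; t-test is undefined, report the limit
    same <- isTRUE(all.equal(mean(x), mean(y)))
    tt <- list(statistic = c(t = if (same) 0 else sign(mean(x) - mean(y)) * Inf),
               p.value = if (same) 1 else 0)
    vt <- list(p.value = NA_real_)
  } else {
    vt <- var.test(x, y)
    pool <- is.na(vt$p.value) || vt$p.value >= 0.05
    tt <- t.test(x, y, var.equal = pool)
  }
  list(
    groups = setNames(data.frame(
      group = c(TRUE, FALSE), n = c(length(x), length(y)),
      mean = c(mean(x), mean(y)), sd = c(sd(x), sd(y))
    ), c(covariate, "n", "mean", "sd")),
    mean_difference = mean(x) - mean(y),
    t_statistic = unname(tt$statistic),
    p_value = tt$p.value,
    variance_test_p = vt$p.value,
    n_excluded = n_excluded
  )
}

#' Association of the HK/LK group with a binary covariate
#'
#' Builds the 2x2 contingency table of keratin group against a binary
#' patient covariate and tests association with Pearson's chi-squared
#' statistic (no continuity correction). Also reports the percentage of LK
#' patients within the covariate-positive stratum (e.g. "72.7\% of triple
#' negative patients were LK").
#'
#' @param patients Data frame with \code{keratin_group} (from
#'   \code{\link{label_patients}}) and the covariate column.
#' @param covariate Name of a logical/binary column; \code{"positive"}/
#'   \code{"negative"} strings are coerced. NA excluded listwise.
#' @return A list with \code{table} (2x2), \code{chi_squared},
#'   \code{p_value}, \code{lk_percent_in_positive} and \code{n_excluded}.
#' @export
associate_group_with_covariate <- function(patients, covariate = "triple_negative") {
  stopifnot(all(c("keratin_group", covariate) %in% names(patients)))
  cov <- patients[[covariate]]
  if (is.character(cov)) cov <- ifelse(cov == "unknown", NA, cov == "positive")
  keep <- !is.na(cov) & !is.na(patients$keratin_group)
  cov <- factor(cov[keep], levels = c(FALSE, TRUE))
  grp <- factor(patients$keratin_group[keep], levels = c("HK", "LK"))
  tab <- table(keratin_group = grp, covariate = cov)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate 2x2 table: a margin is zero; association undefined")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(
    table = tab,
    chi_squared = unname(ct$statistic),
    p_value = ct$p.value,
    lk_percent_in_positive = 100 * tab["LK", "TRUE"] / sum(tab[, "TRUE"]),
    n_excluded = sum(!keep)
  )
}

#' One-year overall survival by keratin group
#'
#' Kaplan-Meier estimates of overall survival per HK/LK group, the survival
#' probability at 12 months per group, and the log-rank test comparing the
#' groups.
#'
#' @param patients Data frame with \code{os_months}, \code{os_event} and
#'   \code{keratin_group}; both groups must be non-empty.
#' @param at_months Time point of the reported survival probability
#'   (default 12 months).
#' @return A list with \code{survival_at} (named vector, one probability
#'   per group), \code{at_months}, \code{logrank_p} and the
#'   \code{survfit} object in \code{fit}.
#' @export
one_year_os <- function(patients, at_months = 12) {
  stopifnot(all(c("os_months", "os_event", "keratin_group") %in% names(patients)))
  if (any(patients$os_months < 0)) stop("os_months must be >= 0")
  groups <- unique(patients$keratin_group)
  if (any(table(factor(patients$keratin_group, levels = c("HK", "LK"))) == 0)) {
    stop("both HK and LK groups must contain patients")
  }
  fit <- survival::survfit(
    survival::Surv(os_months, os_event) ~ keratin_group, data = patients)
  sm <- summary(fit, times = at_months, extend = TRUE)
  surv <- setNames(sm$surv, sub("^keratin_group=", "", as.character(sm$strata)))
  # the log-rank test is undefined without events or between-group
  # information (e.g. no deaths, or all deaths tied at one time)
  p <- tryCatch({
    sd_test <- survival::survdiff(
      survival::Surv(os_months, os_event) ~ keratin_group, data = patients)
    pv <- pchisq(sd_test$chisq, df = length(sd_test$n) - 1, lower.tail = FALSE)
    if (is.nan(pv)) NA_real_ else pv
  }, error = function(e) NA_real_)
  list(survival_at = surv, at_months = at_months, logrank_p = p, fit = fit)
}

#' Kruskal-Wallis test with Dunn's post test
#'
#' Omnibus nonparametric comparison of three or more cell populations
#' (cell lines, CTCs) followed by Dunn's pairwise rank-sum z tests with
#' multiplicity-adjusted p-values (Bonferroni by default). Dunn's z uses
#' the pooled mean ranks with the standard tie correction
#' \eqn{z_{ij} = (\bar R_i - \bar R_j) / \sqrt{(N(N+1)/12 - T)(1/n_i + 1/n_j)}},
#' \eqn{T = \sum (t^3 - t) / (12 (N - 1))} over tie groups of size t.
#'
#' @param groups Named list of >= 3 numeric vectors, each with >= 2 values.
#' @param p_adjust_method Adjustment passed to \code{\link[stats]{p.adjust}}
#'   (default \code{"bonferroni"}).
#' @return A list with \code{kruskal_h}, \code{kruskal_p} and \code{dunn},
#'   a data frame of pairwise comparisons (\code{group1}, \code{group2},
#'   \code{z}, \code{p_value}, \code{p_adjusted}).
#' @export
compare_cell_populations <- function(groups, p_adjust_method = "bonferroni") {
  if (length(groups) < 3L) {
    stop("need at least 3 groups (use compare_keratin_by_group / t-test for 2)")
  }
  if (any(vapply(groups, length, 1L) < 2L)) stop("each group needs >= 2 values")
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  kw <- kruskal.test(groups)

  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), vapply(groups, length, 1L))
  r <- rank(x)
  n_tot <- length(x)
  mean_rank <- tapply(r, g, mean)
  n_i <- tapply(r, g, length)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (n_tot - 1))
  pairs <- utils::combn(names(groups), 2)
  dunn <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt((n_tot * (n_tot + 1) / 12 - tie_corr) * (1 / n_i[[a]] + 1 / n_i[[b]]))
    z <- (mean_rank[[a]] - mean_rank[[b]]) / se
    data.frame(group1 = a, group2 = b, z = z,
               p_value = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE)
  }))
  dunn$p_adjusted <- p.adjust(dunn$p_value, method = p_adjust_method)
  list(kruskal_h = unname(kw$statistic), kruskal_p = kw$p.value, dunn = dunn)
}
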