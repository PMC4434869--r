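#' Configuration for the synthetic patient cohort generator
#'
#' Describes a metastatic breast cancer cohort in which every patient has at
#' least 2 CTCs detected (the inclusion rule), per-CTC keratin levels differ
#' by triple-negative (TN) status, and overall survival differs between the
#' high-keratin (HK) and low-keratin (LK) strata defined by the pooled
#' median split.
#'
#' @param n_patients Number of patients (>= 2).
#' @param ctcs_per_patient_range Length-2 integer, inclusive range of CTC
#'   counts per patient; minimum must be >= 2.
#' @param keratin_mean_tn,keratin_mean_other Mean per-CTC keratin CTCF for
#'   TN and non-TN patients (defaults 122.4 and 175.0).
#' @param keratin_sd SD of per-CTC keratin; either a single value for both
#'   groups or length-2 \code{c(tn, other)} (default \code{c(99.98, 128.0)}).
#' @param tn_fraction Probability a patient is triple negative.
#' @param one_year_surv_hk,one_year_surv_lk Target 1-year overall survival
#'   in the HK and LK strata (defaults 0.733 and 0.462).
#' @param max_followup Administrative censoring horizon in months.
#' @param seed Integer seed.
#'
#' @return An object of class \code{cohort_gen_config}.
#' @export
cohort_gen_config <- function(n_patients = 61L,
                              ctcs_per_patient_range = c(2L, 40L),
                              keratin_mean_tn = 122.4,
                              keratin_mean_other = 175.0,
                              keratin_sd = c(99.98, 128.0),
                              tn_fraction = 11 / 61,
                              one_year_surv_hk = 0.733,
                              one_year_surv_lk = 0.462,
                              max_followup = 36,
                              seed = NULL) {
  if (n_patients < 2) stop("n_patients must be >= 2")
  stopifnot(length(ctcs_per_patient_range) == 2L)
  if (ctcs_per_patient_range[1] < 2) {
    stop("ctcs_per_patient_range minimum must be >= 2 (patients need at least 2 CTCs)")
  }
  stopifnot(ctcs_per_patient_range[1] <= ctcs_per_patient_range[2])
  for (p in c(tn_fraction, one_year_surv_hk, one_year_surv_lk)) {
    if (p < 0 || p > 1) stop("proportions must lie in [0, 1]")
  }
  stopifnot(keratin_mean_tn > 0, keratin_mean_other > 0, all(keratin_sd >= 0),
            length(keratin_sd) %in% c(1L, 2L), max_followup > 0)
  if (length(keratin_sd) == 1L) keratin_sd <- rep(keratin_sd, 2L)
  structure(list(
    n_patients = as.integer(n_patients),
    ctcs_per_patient_range = as.integer(ctcs_per_patient_range),
    keratin_mean_tn = keratin_mean_tn,
    keratin_mean_other = keratin_mean_other,
    keratin_sd = as.numeric(keratin_sd),
    tn_fraction = tn_fraction,
    one_year_surv_hk = one_year_surv_hk,
    one_year_surv_lk = one_year_surv_lk,
    max_followup = max_followup,
    seed = seed
  ), class = "cohort_gen_config")
}

#' Generate a synthetic patient cohort with CTC keratin levels and survival
#'
#' Per patient: receptor status (ER/PR/HER2; triple negative with
#' probability \code{tn_fraction}), a CTC count uniform in
#' \code{ctcs_per_patient_range}, per-CTC keratin CTCF values drawn from a
#' moment-matched lognormal for the patient's TN group, and overall
#' survival. Survival is exponential with a stratum-specific rate solved
#' from the target 1-year survival, \code{rate = -log(S1) / 12}; the
#' stratum (HK/LK) is determined from the generated keratin values
#' themselves by the pooled-median strict-majority rule (see
#' \code{\link{label_patients}}), so re-deriving the labels downstream
#' reproduces the planted survival difference. Censoring is uniform on
#' (0, \code{max_followup}).
#'
#' @param config A \code{\link{cohort_gen_config}}.
#' @return A list with \code{patients} (data frame: \code{patient_id},
#'   \code{er_status}, \code{pr_status}, \code{her2_status},
#'   \code{triple_negative}, \code{n_ctcs}, \code{os_months},
#'   \code{os_event}, \code{true_group}) and \code{ctcs} (data frame:
#'   \code{patient_id}, \code{keratin}).
#' @examples
#' coh <- generate_cohort(cohort_gen_config(n_patients = 10, seed = 1))
#' head(coh$patients)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_gen_config"))
  with_seed(config$seed, {
    n <- config$n_patients
    tn <- rbinom(n, 1, config$tn_fraction) == 1
    # TN = ER-, PR-, HER2-; non-TN patients get at least one positive receptor
    er <- pr <- her2 <- rep("negative", n)
    for (i in which(!tn)) {
      repeat {
        s <- sample(c("positive", "negative"), 3, replace = TRUE,
                    prob = c(0.6, 0.4))
        if (any(s == "positive")) break
      }
      er[i] <- s[1]; pr[i] <- s[2]; her2[i] <- s[3]
    }
    n_ctcs <- sample(seq(config$ctcs_per_patient_range[1],
                         config$ctcs_per_patient_range[2]), n, replace = TRUE)
    mean_i <- ifelse(tn, config$keratin_mean_tn, config$keratin_mean_other)
    sd_i <- ifelse(tn, config$keratin_sd[1], config$keratin_sd[2])
    ctcs <- do.call(rbind, lapply(seq_len(n), function(i) {
      p <- lnorm_params(mean_i[i], sd_i[i])
      data.frame(patient_id = sprintf("P%03d", i),
                 keratin = exp(p[["mu"]] + p[["sigma"]] * rnorm(n_ctcs[i])),
                 stringsAsFactors = FALSE)
    }))

    patients <- data.frame(
      patient_id = sprintf("P%03d", seq_len(n)),
      er_status = er, pr_status = pr, her2_status = her2,
      triple_negative = tn,
      n_ctcs = n_ctcs,
      stringsAsFactors = FALSE
    )

    # survival stratum from the generated keratin values themselves
    med <- pooled_median(ctcs)
    lab <- label_patients(patients, ctcs, med)
    hk <- lab$keratin_group == "HK"
    s1 <- ifelse(hk, config$one_year_surv_hk, config$one_year_surv_lk)
    rate <- -log(pmin(pmax(s1, 1e-12), 1 - 1e-12)) / 12
    t_death <- rexp(n, rate = rate)
    t_cens <- runif(n, 0, config$max_followup)
    patients$os_months <- pmin(t_death, t_cens)
    patients$os_event <- t_death <= t_cens
    patients$true_group <- ifelse(hk, "HK", "LK")
    list(patients = patients, ctcs = ctcs)
  })
}
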