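make_patients <- function(values_list, ids = sprintf("P%02d", seq_along(values_list))) {
  patients <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  ctcs <- data.frame(
    patient_id = rep(ids, vapply(values_list, length, 1L)),
    keratin = unlist(values_list), stringsAsFactors = FALSE)
  list(patients = patients, ctcs = ctcs)
}

test_that("pooled median follows the standard mid-point convention", {
  expect_equal(pooled_median(c(1, 2, 3)), 2)
  expect_equal(pooled_median(c(1, 2, 3, 4)), 2.5)
  coh <- generate_cohort(cohort_gen_config(n_patients = 30, seed = 5))
  expect_equal(pooled_median(coh$ctcs),
               sort(coh$ctcs$keratin)[c(0, 1) + floor((nrow(coh$ctcs) + 1) / 2)] |>
                 mean())
  expect_error(pooled_median(numeric(0)), "pooled median")
})

test_that("HK/LK labelling uses the strict-majority strictly-above rule", {
  d <- make_patients(list(c(10, 10, 30), c(30, 30, 10), c(30, 30, 10, 10)))
  lab <- label_patients(d$patients, d$ctcs, median_keratin = 20)
  expect_equal(lab$fraction_high, c(1 / 3, 2 / 3, 0.5))
  # exactly half high is LK, not HK
  expect_equal(lab$keratin_group, c("LK", "HK", "LK"))
})

test_that("values exactly at the median are never high", {
  d <- make_patients(list(c(5, 5), c(5, 5, 5)))
  lab <- label_patients(d$patients, d$ctcs)  # pooled median = 5
  expect_equal(lab$fraction_high, c(0, 0))
  expect_equal(lab$keratin_group, c("LK", "LK"))
})

test_that("labels are invariant to patient and CTC permutation and form a partition", {
  coh <- generate_cohort(cohort_gen_config(n_patients = 40, seed = 17))
  lab1 <- label_patients(coh$patients, coh$ctcs)
  set.seed(1)
  perm_p <- coh$patients[sample(nrow(coh$patients)), ]
  perm_c <- coh$ctcs[sample(nrow(coh$ctcs)), ]
  lab2 <- label_patients(perm_p, perm_c)
  m <- match(lab1$patient_id, lab2$patient_id)
  expect_equal(lab1$keratin_group, lab2$keratin_group[m])
  expect_equal(sum(lab1$keratin_group == "HK") + sum(lab1$keratin_group == "LK"),
               nrow(coh$patients))
})

test_that("keratin group comparison handles degenerate and separated groups", {
  d <- make_patients(list(c(5, 5, 5, 5), c(5, 5, 5, 5)))
  d$patients$triple_negative <- c(TRUE, FALSE)
  cmp <- compare_keratin_by_group(d$patients, d$ctcs)
  expect_equal(cmp$mean_difference, 0)
  expect_equal(cmp$t_statistic, 0)   # identical groups: t = 0, p = 1
  expect_equal(cmp$p_value, 1)

  d2 <- make_patients(list(c(0, 0, 0, 0), c(1, 1, 1, 1)))
  d2$patients$triple_negative <- c(TRUE, FALSE)
  d2$ctcs$keratin <- d2$ctcs$keratin + rep(c(0, 1e-6, -1e-6, 0), 2)  # break 0 var
  cmp2 <- compare_keratin_by_group(d2$patients, d2$ctcs)
  expect_equal(cmp2$mean_difference, -1, tolerance = 1e-5)
  expect_lt(cmp2$p_value, 0.01)

  d3 <- make_patients(list(c(1, 2)))
  d3$patients$triple_negative <- TRUE
  expect_error(compare_keratin_by_group(d3$patients, d3$ctcs), "at least 2")
})

test_that("group-covariate association: independence, perfect association, stratum percent", {
  p <- data.frame(patient_id = sprintf("P%02d", 1:20),
                  keratin_group = rep(c("HK", "LK"), each = 10),
                  triple_negative = rep(c(TRUE, FALSE), 10))
  a <- associate_group_with_covariate(p)
  expect_equal(a$chi_squared, 0)
  expect_equal(a$p_value, 1)

  p2 <- data.frame(patient_id = sprintf("P%02d", 1:20),
                   keratin_group = rep(c("HK", "LK"), each = 10),
                   triple_negative = rep(c(FALSE, TRUE), each = 10))
  a2 <- associate_group_with_covariate(p2)
  expect_equal(a2$lk_percent_in_positive, 100)
  expect_lt(a2$p_value, 0.01)

  # 8 of 11 covariate-positive patients LK -> 72.7%
  p3 <- data.frame(patient_id = sprintf("P%02d", 1:30),
                   keratin_group = c(rep("LK", 8), rep("HK", 3), rep("HK", 12),
                                     rep("LK", 7)),
                   triple_negative = c(rep(TRUE, 11), rep(FALSE, 19)))
  a3 <- associate_group_with_covariate(p3)
  expect_equal(a3$lk_percent_in_positive, 100 * 8 / 11, tolerance = 1e-12)

  p4 <- data.frame(patient_id = "P1", keratin_group = "HK", triple_negative = TRUE)
  expect_error(associate_group_with_covariate(p4), "degenerate")
})

test_that("unknown receptor status is excluded listwise and counted", {
  p <- data.frame(patient_id = sprintf("P%02d", 1:6),
                  keratin_group = c("HK", "LK", "HK", "LK", "HK", "LK"),
                  er_status = c("positive", "negative", "unknown",
                                "positive", "negative", "positive"))
  a <- associate_group_with_covariate(p, "er_status")
  expect_equal(a$n_excluded, 1)
  expect_equal(sum(a$table), 5)
})

test_that("Kaplan-Meier survival at 12 months matches the no-censoring limits", {
  p <- data.frame(patient_id = sprintf("P%02d", 1:10),
                  keratin_group = rep(c("HK", "LK"), 5),
                  os_months = rep(20, 10), os_event = FALSE)
  os <- one_year_os(p)
  expect_equal(unname(os$survival_at), c(1, 1))

  p$os_months <- 6; p$os_event <- TRUE
  os2 <- one_year_os(p)
  expect_equal(unname(os2$survival_at), c(0, 0))

  # no censoring: KM at 12 equals the empirical survival fraction
  set.seed(2)
  p3 <- data.frame(patient_id = sprintf("P%03d", 1:60),
                   keratin_group = rep(c("HK", "LK"), 30),
                   os_months = rexp(60, 1 / 15), os_event = TRUE)
  os3 <- one_year_os(p3)
  for (g in c("HK", "LK")) {
    emp <- mean(p3$os_months[p3$keratin_group == g] > 12)
    expect_equal(os3$survival_at[[g]], emp)
  }
  expect_error(one_year_os(p3[p3$keratin_group == "HK", ]), "group")
})

test_that("planted survival difference is recovered within 3 SE at n = 400", {
  coh <- generate_cohort(cohort_gen_config(n_patients = 400, seed = 8))
  lab <- label_patients(coh$patients, coh$ctcs)
  os <- one_year_os(lab)
  for (g in c("HK", "LK")) {
    target <- if (g == "HK") 0.733 else 0.462
    n_g <- sum(lab$keratin_group == g)
    se <- sqrt(target * (1 - target) / n_g) * 1.3  # censoring inflates the SE
    expect_lt(abs(os$survival_at[[g]] - target), 3 * se,
              label = sprintf("%s S(12)=%.3f vs %.3f", g, os$survival_at[[g]], target))
  }
  expect_lt(os$logrank_p, 0.01)
})

test_that("Kruskal-Wallis and Dunn statistics match an independent oracle", {
  groups <- list(a = c(1, 5, 8, 12), b = c(3, 7, 9, 14), c = c(20, 25, 30, 35))
  res <- compare_cell_populations(groups)
  expect_equal(res$kruskal_h, 7.53846153846154, tolerance = 1e-10)
  expect_equal(res$kruskal_p, 0.0230698024654865, tolerance = 1e-10)
  z <- setNames(res$dunn$z, paste(res$dunn$group1, res$dunn$group2))
  expect_equal(z[["a b"]], -0.3922322702763681, tolerance = 1e-10)
  expect_equal(z[["a c"]], -2.5495097567963927, tolerance = 1e-10)
  expect_equal(z[["b c"]], -2.1572774865200244, tolerance = 1e-10)
  expect_equal(res$dunn$p_adjusted, pmin(res$dunn$p_value * 3, 1))
})

test_that("Kruskal-Wallis handles null and separated groups", {
  same <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(1, 2, 3, 4))
  res <- compare_cell_populations(same)
  expect_lt(res$kruskal_h, 1e-10)
  expect_equal(res$kruskal_p, 1)

  apart <- list(a = 1:10, b = 101:110, c = 201:210)
  res2 <- compare_cell_populations(apart)
  expect_true(all(res2$dunn$p_adjusted < 0.05))
  expect_lt(res2$kruskal_p, 0.01)

  expect_error(compare_cell_populations(list(a = 1:3, b = 1:3)), "3 groups")
})
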