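#' Pipeline configuration
#'
#' Bundles the stage configurations of the end-to-end demo pipeline:
#' simulate (beads, cytospin images, cohort), quantify, calibrate-check,
#' EMT classification and cohort analysis. All randomness flows from the
#' single \code{seed}; stage seeds are derived from it deterministically.
#'
#' @param seed Master integer seed.
#' @param out_dir Output directory (created if absent).
#' @param n_images Number of cytospin fields to simulate and quantify.
#' @param layout \code{\link{cytospin_layout}} template (its seed is
#'   overridden per image).
#' @param bead_config \code{\link{bead_gen_config}} (seed overridden).
#' @param cohort_config \code{\link{cohort_gen_config}} (seed overridden).
#' @param quant \code{\link{quant_config}}.
#' @param ctc_profile,epithelial_ref,mesenchymal_ref Cell-line profiles for
#'   the planted CTCs and the EMT cut-off references.
#' @param r2_min Linearity threshold for the calibration stage.
#' @param verbose Print stage progress to stderr.
#' @return An object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(seed = 1L,
                            out_dir = tempfile("ctcemt_run_"),
                            n_images = 2L,
                            layout = cytospin_layout(),
                            bead_config = bead_gen_config(),
                            cohort_config = cohort_gen_config(),
                            quant = quant_config(),
                            ctc_profile = cell_line_profiles()$MCF7_EGF,
                            epithelial_ref = cell_line_profiles()$MCF7,
                            mesenchymal_ref = cell_line_profiles()$Hs578T,
                            r2_min = 0.99,
                            verbose = FALSE) {
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 n_images = as.integer(n_images), layout = layout,
                 bead_config = bead_config, cohort_config = cohort_config,
                 quant = quant, ctc_profile = ctc_profile,
                 epithelial_ref = epithelial_ref,
                 mesenchymal_ref = mesenchymal_ref,
                 r2_min = r2_min, verbose = verbose),
            class = "pipeline_config")
}

#' Run the end-to-end demo pipeline
#'
#' Chains simulate -> quantify -> calibrate-check -> EMT classify -> cohort
#' analyze on synthetic inputs, writing every stage's table to
#' \code{out_dir} with provenance metadata (seed, config hash). A stage
#' error aborts with the stage name; outputs written so far are retained
#' alongside a \code{FAILED} marker file.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return A run report: list with per-stage record counts, the linear
#'   voltage, the EMT class summary and the cohort results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (config$verbose) message(sprintf(...))
  stage <- "init"
  report <- list(seed = config$seed, out_dir = config$out_dir, stages = list())
  on.exit({
    writeLines(stage, file.path(config$out_dir, "FAILED"))
  })

  # hash only the scientific configuration, not run-local paths/verbosity
  meta <- list(seed = config$seed,
               config = unclass(config)[setdiff(names(config),
                                                c("out_dir", "verbose"))])

  stage <- "simulate_beads"
  say("[%s]", stage)
  bc <- config$bead_config; bc$seed <- config$seed + 101L
  beads <- generate_beads(bc)
  write_table_csv(beads, file.path(config$out_dir, "beads.csv"), meta)
  report$stages$simulate_beads <- list(n = nrow(beads))

  stage <- "calibrate"
  fits <- fit_linearity(beads)
  linear_v <- linear_range(fits, config$r2_min)
  write_table_csv(fits, file.path(config$out_dir, "calibration_fits.csv"), meta)
  report$stages$calibrate <- list(n = nrow(fits), linear_voltage = linear_v)

  stage <- "simulate_quantify"
  say("[%s]", stage)
  records <- list()
  for (i in seq_len(config$n_images)) {
    lay <- config$layout; lay$seed <- config$seed + 200L + i
    sim <- generate_cytospin_image(lay, ctc_profile = config$ctc_profile)
    tiff_path <- file.path(config$out_dir, sprintf("cytospin_%02d.tiff", i))
    write_cytospin_tiff(sim$image, tiff_path, bit_depth = lay$bit_depth, meta = meta)
    write_table_csv(sim$truth,
                    file.path(config$out_dir, sprintf("cytospin_%02d_truth.csv", i)),
                    meta)
    records[[i]] <- quantify_image(sim$image, config$quant,
                                   sample_id = sprintf("img%02d", i))
  }
  all_cells <- do.call(rbind, records)
  write_table_csv(all_cells, file.path(config$out_dir, "cell_records.csv"), meta)
  ctcs_img <- all_cells[all_cells$is_ctc, , drop = FALSE]
  report$stages$quantify <- list(n_cells = nrow(all_cells), n_ctcs = nrow(ctcs_img))

  stage <- "calibrate_check"
  if (nrow(ctcs_img) > 0 && !is.na(linear_v)) {
    # cells and beads are measured on the same camera-count scale
    vals <- ctcs_img$mean_intensity_keratin
    chk <- check_in_range(vals, beads, linear_v)
    report$stages$calibrate_check <- chk[c("fraction_in_range", "n_in", "n_total")]
  }

  stage <- "emt_classify"
  say("[%s]", stage)
  if (nrow(ctcs_img) > 0) {
    epi <- generate_cellline_cells(config$epithelial_ref, 100, seed = config$seed + 301L)
    mes <- generate_cellline_cells(config$mesenchymal_ref, 100, seed = config$seed + 302L)
    cuts <- derive_cutoffs(epi$ratio_vim_k, mes$ratio_vim_k)
    floor_k <- default_denom_floor(epi$mean_intensity_keratin)
    ratios <- compute_ratio(ctcs_img, denom_floor = floor_k)
    cls <- classify_emt(ratios$ratio, cuts)
    ratios$emt_class <- as.character(cls$emt_class)
    write_table_csv(ratios, file.path(config$out_dir, "emt_ratios.csv"), meta)
    emt_summary <- summarize_classes(cls$emt_class, ctcs_img$sample_id)
    write_table_csv(emt_summary, file.path(config$out_dir, "emt_summary.csv"), meta)
    report$stages$emt <- list(n = nrow(ratios), summary = emt_summary,
                              cutoffs = unlist(cuts))
  } else {
    warning("no CTCs identified; EMT summary empty")
    report$stages$emt <- list(n = 0L, summary = summarize_classes(character(0)))
  }

  stage <- "cohort"
  say("[%s]", stage)
  if (nrow(ctcs_img) == 0) {
    warning("cohort stage skipped: no CTCs identified upstream")
    report$stages$cohort <- list(skipped = TRUE)
    on.exit()
    return(report)
  }
  cc <- config$cohort_config; cc$seed <- config$seed + 401L
  coh <- generate_cohort(cc)
  write_table_csv(coh$patients, file.path(config$out_dir, "patients.csv"), meta)
  write_table_csv(coh$ctcs, file.path(config$out_dir, "ctc_keratin.csv"), meta)
  med <- pooled_median(coh$ctcs)
  lab <- label_patients(coh$patients, coh$ctcs, med)
  cmp <- compare_keratin_by_group(lab, coh$ctcs, "triple_negative")
  assoc <- associate_group_with_covariate(lab, "triple_negative")
  os <- one_year_os(lab)
  write_table_csv(lab, file.path(config$out_dir, "patients_labeled.csv"), meta)
  report$stages$cohort <- list(
    n_patients = nrow(lab), pooled_median = med,
    n_hk = sum(lab$keratin_group == "HK"), n_lk = sum(lab$keratin_group == "LK"),
    tn_vs_other = cmp[c("mean_difference", "t_statistic", "p_value", "variance_test_p")],
    association = assoc[c("chi_squared", "p_value", "lk_percent_in_positive")],
    one_year_os = os$survival_at, logrank_p = os$logrank_p
  )

  on.exit()  # completed: clear the FAILED marker handler
  report
}
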