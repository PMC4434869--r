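paper_cuts <- emt_cutoffs(0.49, 5.47, 38.88)

test_that("the vim/K ratio is the quotient of background-corrected mean intensities", {
  rec <- data.frame(cell_id = c("a", "b", "c", "d"),
                    mean_intensity_keratin = c(87.34, 50, 0.5, -2),
                    mean_intensity_vimentin = c(15.68, 0, 10, 10))
  rr <- compute_ratio(rec, denom_floor = 1)
  expect_equal(rr$ratio[1], 15.68 / 87.34, tolerance = 1e-12)
  expect_equal(rr$ratio[2], 0)                  # no vimentin expression
  expect_true(is.na(rr$ratio[3]))               # keratin below floor: undefined
  expect_false(rr$ratio_defined[3])
  expect_true(is.na(rr$ratio[4]))               # negative keratin clamps to 0
  # negative numerator clamps to 0, not to a negative ratio
  rec$mean_intensity_vimentin[1] <- -4
  expect_equal(compute_ratio(rec)$ratio[1], 0)
})

test_that("unknown marker names are rejected", {
  rec <- data.frame(cell_id = "a", mean_intensity_keratin = 1,
                    mean_intensity_vimentin = 1)
  expect_error(compute_ratio(rec, numerator = "epcam"), "epcam")
})

test_that("the ratio operation is generic over marker pairs", {
  rec <- data.frame(cell_id = "a",
                    mean_intensity_keratin = 20,
                    mean_intensity_fibronectin = 60)
  rr <- compute_ratio(rec, numerator = "fibronectin", denominator = "keratin")
  expect_equal(rr$ratio, 3)
  expect_equal(rr$numerator_marker, "fibronectin")
})

test_that("cut-offs are the extremes of the reference ratio distributions", {
  cuts <- derive_cutoffs(c(0.12, 0.25, 0.49), c(5.47, 13.1, 38.88))
  expect_equal(cuts$epithelial_upper, 0.49)
  expect_equal(cuts$mesenchymal_lower, 5.47)
  expect_equal(cuts$mesenchymal_upper, 38.88)

  single <- derive_cutoffs(0.1, 10.0)
  expect_equal(unlist(single), c(epithelial_upper = 0.1,
                                 mesenchymal_lower = 10, mesenchymal_upper = 10))

  expect_error(derive_cutoffs(c(0.5, 2.0), c(1.0, 9)), "overlap")
  expect_error(derive_cutoffs(numeric(0), 1), "non-empty")
})

test_that("cut-off derivation is scale-equivariant", {
  epi <- c(0.12, 0.3, 0.49); mes <- c(5.47, 20, 38.88)
  base <- derive_cutoffs(epi, mes)
  for (c_mult in c(0.5, 3, 10)) {
    scaled <- derive_cutoffs(epi * c_mult, mes * c_mult)
    expect_equal(unlist(scaled), unlist(base) * c_mult)
  }
})

test_that("reference cell-line means classify to their expected EMT state", {
  cls <- classify_emt(c(0.19, 1.57, 13.14), paper_cuts)
  expect_equal(as.character(cls$emt_class),
               c("epithelial", "intermediate", "mesenchymal"))
})

test_that("boundary and above-reference handling is deterministic", {
  cls <- classify_emt(c(0.49, 5.47, 38.88, 50, 0), paper_cuts)
  expect_equal(as.character(cls$emt_class),
               c("epithelial", "mesenchymal", "mesenchymal", "mesenchymal",
                 "epithelial"))
  expect_equal(cls$above_reference, c(FALSE, FALSE, FALSE, TRUE, FALSE))
})

test_that("classification is a monotone partition of defined ratios", {
  set.seed(31)
  ratios <- sort(c(runif(200, 0, 45), 0.49, 5.47, 38.88))
  cls <- classify_emt(ratios, paper_cuts)
  expect_false(any(is.na(cls$emt_class)))
  # each cell gets exactly one of the ordered labels; order is monotone
  expect_true(all(diff(as.integer(cls$emt_class)) >= 0))
})

test_that("class proportions are exact tallies summing to one", {
  labels <- rep(c("epithelial", "intermediate", "mesenchymal"), c(5, 4, 1))
  s <- summarize_classes(labels)
  expect_equal(s$proportion, c(0.5, 0.4, 0.1))
  expect_equal(sum(s$n), 10)

  one <- summarize_classes(rep("epithelial", 7))
  expect_equal(one$proportion, c(1, 0, 0))

  empty <- summarize_classes(character(0))
  expect_equal(nrow(empty), 0)

  # synthetic CTC mixture: proportions equal a brute-force tally
  ctcs <- generate_cellline_cells(ref_profiles$CTC, 300, seed = 9)
  cls <- classify_emt(ctcs$ratio_vim_k, paper_cuts)
  s2 <- summarize_classes(cls$emt_class)
  manual <- as.vector(table(as.character(cls$emt_class))[
    c("epithelial", "intermediate", "mesenchymal")]) / 300
  manual[is.na(manual)] <- 0
  expect_equal(s2$proportion, manual)
  expect_equal(sum(s2$proportion), 1)
})

test_that("per-sample summaries tally within each sample", {
  labels <- c("epithelial", "epithelial", "mesenchymal", "intermediate")
  samples <- c("s1", "s1", "s2", "s2")
  s <- summarize_classes(labels, samples)
  s1 <- s[s$sample_id == "s1", ]
  expect_equal(s1$n[s1$emt_class == "epithelial"], 2)
  expect_equal(sum(s[s$sample_id == "pooled", "n"]), 4)
})

test_that("the default denominator floor is 1% of the epithelial reference median", {
  expect_equal(default_denom_floor(c(80, 90, 100)), 0.9)
})
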