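test_that("segmentation recovers well-separated planted cells with accurate centroids", {
  lay <- small_layout(seed = 11, n_ctcs = 3L, n_pbmcs = 5L)
  sim <- generate_cytospin_image(lay)
  regions <- segment_cells(sim$image)
  expect_length(regions, 8)
  cents <- t(vapply(regions, `[[`, c(row = 0, col = 0), "centroid"))
  for (i in seq_len(nrow(sim$truth))) {
    d <- sqrt((cents[, "row"] + 1 - sim$truth$row[i])^2 +
              (cents[, "col"] + 1 - sim$truth$col[i])^2)
    expect_lt(min(d), 2)
  }
  # regions are disjoint
  all_px <- do.call(rbind, lapply(regions, `[[`, "pixels"))
  expect_equal(nrow(all_px), nrow(unique(all_px)))
})

test_that("two nuclei closer than the dilation margin stay two disjoint regions", {
  img <- array(0, dim = c(64, 64, 4),
               dimnames = list(NULL, NULL, c("dapi", "keratin", "vimentin", "cd45")))
  # two hard discs 14 px apart, dilation margin 6 -> dilated masks overlap
  for (ctr in list(c(25, 32), c(39, 32))) {
    d <- sqrt(outer((1:64 - ctr[1])^2, (1:64 - ctr[2])^2, "+"))
    img[, , "dapi"] <- img[, , "dapi"] + 5000 * (d <= 5)
  }
  regions <- segment_cells(img, quant_config(min_cell_area = 20))
  expect_length(regions, 2)
  all_px <- do.call(rbind, lapply(regions, `[[`, "pixels"))
  expect_equal(nrow(all_px), nrow(unique(all_px)))
  # nearest-nucleus rule: split roughly along the midline between centers
  expect_lt(abs(regions[[1]]$area - regions[[2]]$area) / regions[[1]]$area, 0.2)
})

test_that("a blank image yields zero regions", {
  img <- array(100, dim = c(64, 64, 4),
               dimnames = list(NULL, NULL, c("dapi", "keratin", "vimentin", "cd45")))
  expect_length(segment_cells(img), 0)
})

test_that("an image without a nuclear channel is rejected", {
  img <- array(0, dim = c(32, 32, 2), dimnames = list(NULL, NULL, c("a", "b")))
  expect_error(segment_cells(img), "dapi")
})

test_that("background estimation: constant field, excluded bright region, and oracle", {
  img0 <- array(100, dim = c(64, 64, 4),
                dimnames = list(NULL, NULL, c("dapi", "keratin", "vimentin", "cd45")))
  none <- segment_cells(img0)
  expect_equal(estimate_background(img0[, , "keratin"], none), 100)

  # a bright planted cell must not bias the median estimator
  lay <- small_layout(seed = 2, background_level = 100, noise_sd = 0)
  sim <- generate_cytospin_image(lay)
  regions <- segment_cells(sim$image)
  expect_equal(estimate_background(sim$image[, , "keratin"], regions), 100)

  # noisy image: equals the brute-force median over the complement pixel set
  lay2 <- small_layout(seed = 2, noise_sd = 10)
  sim2 <- generate_cytospin_image(lay2)
  reg2 <- segment_cells(sim2$image)
  chan <- sim2$image[, , "vimentin"]
  lab <- attr(reg2, "label")
  expect_equal(estimate_background(chan, reg2), median(chan[lab == 0]))
})

test_that("CTCF follows the integrated-density-minus-background formula", {
  chan <- matrix(10, 20, 20)
  reg <- list(region_id = 1L,
              pixels = as.matrix(expand.grid(0:9, 0:9)), area = 100L)
  res <- compute_ctcf(reg, chan, background = 2)
  expect_equal(res$ctcf, 800)
  expect_equal(res$mean_intensity, 8)
  # background 0: CTCF equals the raw integrated density
  expect_equal(compute_ctcf(reg, chan, 0)$ctcf, 1000)
  # dimmer than background: negative CTCF preserved
  expect_equal(compute_ctcf(reg, chan, 15)$ctcf, -500)
})

test_that("compute_ctcf matches a naive per-pixel loop on random regions", {
  set.seed(4)
  for (rep in 1:5) {
    chan <- matrix(runif(64 * 64, 0, 5000), 64, 64)
    px <- unique(cbind(sample(0:63, 200, TRUE), sample(0:63, 200, TRUE)))
    reg <- list(region_id = 1L, pixels = px, area = nrow(px))
    bg <- runif(1, 0, 100)
    expect_equal(compute_ctcf(reg, chan, bg)$ctcf, naive_ctcf(reg, chan, bg),
                 tolerance = 1e-12)
  }
})

test_that("CTCF is additive over a partition of a region", {
  set.seed(5)
  chan <- matrix(runif(32 * 32, 0, 100), 32, 32)
  px <- as.matrix(expand.grid(5:14, 5:14))
  reg <- list(region_id = 1L, pixels = px, area = nrow(px))
  split_at <- 50
  a <- list(region_id = 2L, pixels = px[1:split_at, , drop = FALSE], area = split_at)
  b <- list(region_id = 3L, pixels = px[-(1:split_at), , drop = FALSE],
            area = nrow(px) - split_at)
  bg <- 7.5
  expect_equal(compute_ctcf(reg, chan, bg)$ctcf,
               compute_ctcf(a, chan, bg)$ctcf + compute_ctcf(b, chan, bg)$ctcf)
})

test_that("mean_intensity times area equals ctcf exactly for every record", {
  sim <- generate_cytospin_image(small_layout(seed = 8))
  rec <- quantify_image(sim$image, quant_config(), "s1")
  for (ch in c("dapi", "keratin", "vimentin", "cd45")) {
    expect_equal(rec[[paste0("mean_intensity_", ch)]] * rec$area,
                 rec[[paste0("ctcf_", ch)]])
  }
})

test_that("identified CTCs match planted ground truth identity", {
  sim <- generate_cytospin_image(small_layout(seed = 11))
  rec <- quantify_image(sim$image, quant_config(), "s1")
  ctc <- identify_ctcs(rec)
  expect_equal(nrow(ctc), 3)
  truth_idx <- match_truth(ctc, sim$truth)
  expect_true(all(sim$truth$type[truth_idx] == "CTC"))
  # input order preserved
  expect_identical(ctc$cell_id, rec$cell_id[rec$is_ctc])
})

test_that("all CD45-bright samples yield no CTCs and zero-DAPI cells are excluded", {
  rec <- data.frame(
    cell_id = paste0("c", 1:6), sample_id = "s",
    area = 100,
    mean_intensity_dapi = c(0, 2000, 2000, 2000, 2000, 2000),
    mean_intensity_cd45 = c(5, 1500, 1600, 1400, 1550, 1450)
  )
  out <- identify_ctcs(rec, quant_config(), dapi_background = 200,
                       cd45_background = 10)
  # cell 1 has no DAPI (excluded regardless of CD45); the rest are CD45-bright
  expect_equal(nrow(out), 0)
})

test_that("noise-free recovery: measured CTCF equals planted signal within 0.1%", {
  lay <- small_layout(seed = 9, noise_sd = 0)
  sim <- generate_cytospin_image(lay)
  rec <- quantify_image(sim$image, quant_config(), "s1")
  idx <- match_truth(rec, sim$truth)
  for (ch in c("keratin", "vimentin", "cd45")) {
    truth_tot <- sim$truth[[paste0("total_", ch)]][idx]
    meas <- rec[[paste0("ctcf_", ch)]]
    nz <- truth_tot > 0
    expect_true(all(abs(meas[nz] - truth_tot[nz]) / truth_tot[nz] < 0.001),
                label = paste("channel", ch))
  }
})

test_that("keratin expression separates identified CTCs from PBMCs on fixtures", {
  recs <- lapply(1:4, function(s) {
    sim <- generate_cytospin_image(small_layout(seed = 20 + s))
    quantify_image(sim$image, quant_config(), paste0("s", s))
  })
  rec <- do.call(rbind, recs)
  p <- t.test(rec$mean_intensity_keratin[rec$is_ctc],
              rec$mean_intensity_keratin[!rec$is_ctc])$p.value
  expect_lt(p, 1e-6)
})
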