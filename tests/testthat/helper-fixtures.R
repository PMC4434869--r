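# shared fixtures: profiles and a compact cytospin layout used across tests
ref_profiles <- cell_line_profiles()

small_layout <- function(seed, n_ctcs = 3L, n_pbmcs = 10L, ...) {
  cytospin_layout(image_shape = c(256L, 256L), n_ctcs = n_ctcs,
                  n_pbmcs = n_pbmcs, seed = seed, ...)
}

# brute-force CTCF: naive per-pixel loop, independent of compute_ctcf
naive_ctcf <- function(region, channel, background) {
  total <- 0
  for (i in seq_len(nrow(region$pixels))) {
    total <- total + channel[region$pixels[i, 1] + 1L, region$pixels[i, 2] + 1L]
  }
  total - region$area * background
}

# match quantified records to planted truth by nearest centroid
match_truth <- function(records, truth) {
  vapply(seq_len(nrow(records)), function(i) {
    d <- sqrt((truth$row - (records$row[i] + 1))^2 +
              (truth$col - (records$col[i] + 1))^2)
    which.min(d)
  }, 1L)
}
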