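#' Layout of a synthetic cytospin image
#'
#' Geometry and imaging parameters for a simulated 4-channel cytospin field
#' containing CTCs (DAPI+/CD45-) mixed with PBMCs (CD45+). Cells are
#' rendered as discs with smooth (sigmoid) edges on a constant background;
#' the per-cell total signal in each channel is spread over the disc so that
#' channel pixel sums are exactly conserved when background and noise are
#' off.
#'
#' @param image_shape Length-2 integer, (rows, cols) in pixels.
#' @param n_ctcs,n_pbmcs Numbers of tumor cells and leukocytes to plant.
#' @param cell_radius_range Length-2 numeric, (min, max) cell radius in px.
#' @param channel_names Names of the four channels, in page order.
#' @param background_level Constant background intensity added to every
#'   channel (camera offset + autofluorescence), in counts.
#' @param noise_sd SD of additive Gaussian read noise (counts); 0 disables.
#' @param bit_depth Bits per pixel of the simulated camera (default 16);
#'   intensities are clamped to [0, 2^bit_depth - 1] when written to TIFF.
#' @param intensity_scale Counts per CTCF/area unit: converts profile mean
#'   intensities into camera counts.
#' @param nucleus_fraction Nucleus radius as a fraction of the cell radius.
#' @param dapi_mean_intensity Mean DAPI counts over the nucleus disc.
#' @param cd45_mean_intensity Mean CD45 counts over a PBMC disc.
#' @param pbmc_vimentin_mean Mean vimentin counts over a PBMC disc (PBMCs
#'   are vimentin-positive, keratin-negative).
#' @param edge_softness Width (px) of the sigmoid edge falloff.
#' @param seed Integer seed.
#'
#' @return An object of class \code{cytospin_layout}.
#' @export
cytospin_layout <- function(image_shape = c(256L, 256L),
                            n_ctcs = 3L, n_pbmcs = 10L,
                            cell_radius_range = c(7, 10),
                            channel_names = c("dapi", "keratin", "vimentin", "cd45"),
                            background_level = 200,
                            noise_sd = 10,
                            bit_depth = 16L,
                            intensity_scale = 30,
                            nucleus_fraction = 0.7,
                            dapi_mean_intensity = 8000,
                            cd45_mean_intensity = 3000,
                            pbmc_vimentin_mean = 1500,
                            edge_softness = 0.5,
                            seed = NULL) {
  stopifnot(length(image_shape) == 2L, all(image_shape >= 32L))
  stopifnot(n_ctcs >= 0, n_pbmcs >= 0)
  stopifnot(length(cell_radius_range) == 2L,
            cell_radius_range[1] > 0,
            cell_radius_range[1] <= cell_radius_range[2])
  stopifnot(length(channel_names) == 4L, !anyDuplicated(channel_names))
  stopifnot(background_level >= 0, noise_sd >= 0, bit_depth >= 8L)
  structure(list(
    image_shape = as.integer(image_shape),
    n_ctcs = as.integer(n_ctcs), n_pbmcs = as.integer(n_pbmcs),
    cell_radius_range = as.numeric(cell_radius_range),
    channel_names = channel_names,
    background_level = background_level,
    noise_sd = noise_sd,
    bit_depth = as.integer(bit_depth),
    intensity_scale = intensity_scale,
    nucleus_fraction = nucleus_fraction,
    dapi_mean_intensity = dapi_mean_intensity,
    cd45_mean_intensity = cd45_mean_intensity,
    pbmc_vimentin_mean = pbmc_vimentin_mean,
    edge_softness = edge_softness,
    seed = seed
  ), class = "cytospin_layout")
}

# soft-edged disc weights on the full image grid; returns a list with pixel
# indices and normalized weights (sum 1) so planted totals are conserved
soft_disc <- function(shape, center, radius, softness) {
  rr <- seq_len(shape[1]); cc <- seq_len(shape[2])
  # restrict to a bounding box for speed
  ext <- ceiling(radius + 4 * softness + 1)
  r_idx <- rr[rr >= center[1] - ext & rr <= center[1] + ext]
  c_idx <- cc[cc >= center[2] - ext & cc <= center[2] + ext]
  d <- sqrt(outer((r_idx - center[1])^2, (c_idx - center[2])^2, "+"))
  w <- 1 / (1 + exp((d - radius) / max(softness, 1e-6)))
  w[w < 1e-4] <- 0
  keep <- which(w > 0, arr.ind = TRUE)
  idx <- cbind(r_idx[keep[, 1]], c_idx[keep[, 2]])
  wts <- w[keep]
  list(idx = idx, w = wts / sum(wts))
}

#' Generate a synthetic multi-channel cytospin image with ground truth
#'
#' Plants \code{n_ctcs} tumor cells and \code{n_pbmcs} leukocytes at
#' non-overlapping positions. Every cell gets a bright DAPI nucleus. CTC
#' discs carry keratin and vimentin signal drawn from \code{ctc_profile}
#' (mean intensity times disc area, scaled by \code{intensity_scale}) and no
#' CD45; PBMC discs carry CD45 and vimentin signal and no keratin. The
#' constant background and Gaussian read noise configured in the layout are
#' added to all channels.
#'
#' @param layout A \code{\link{cytospin_layout}}.
#' @param ctc_profile \code{\link{cell_line_profile}} for the planted tumor
#'   cells (default MCF-7).
#' @param pbmc_profile Optional profile for PBMC vimentin; if \code{NULL}
#'   the layout's \code{pbmc_vimentin_mean} is used with 20\% CV.
#'
#' @return A list with \code{image} (numeric array rows x cols x 4, channel
#'   names in \code{dimnames}) and \code{truth}, a data frame per planted
#'   cell: \code{cell}, \code{type} ("CTC"/"PBMC"), \code{row}, \code{col},
#'   \code{radius}, \code{is_cd45_positive}, and \code{total_<channel>}
#'   columns with the planted (background-free) per-channel totals.
#' @examples
#' sim <- generate_cytospin_image(cytospin_layout(n_ctcs = 2, n_pbmcs = 4, seed = 11))
#' dim(sim$image)
#' table(sim$truth$type)
#' @export
generate_cytospin_image <- function(layout,
                                    ctc_profile = cell_line_profiles()$MCF7,
                                    pbmc_profile = NULL) {
  stopifnot(inherits(layout, "cytospin_layout"))
  n_cells <- layout$n_ctcs + layout$n_pbmcs
  shape <- layout$image_shape
  rmax <- layout$cell_radius_range[2]
  # region extent seen by downstream segmentation: nucleus + dilation margin
  min_sep <- 2 * max(rmax + 2 * layout$edge_softness,
                     layout$nucleus_fraction * rmax + 6) + 4
  margin <- rmax + 4 * layout$edge_softness + 2

  with_seed(layout$seed, {
    # --- placement: rejection sampling with bounded attempts
    centers <- matrix(numeric(0), ncol = 2)
    attempts <- 0
    while (nrow(centers) < n_cells) {
      if (attempts > 200 * max(n_cells, 1)) {
        stop("could not place all cells without overlap; reduce cell count or radius")
      }
      cand <- c(runif(1, margin, shape[1] - margin),
                runif(1, margin, shape[2] - margin))
      ok <- nrow(centers) == 0 ||
        all(sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2) > min_sep)
      if (ok) centers <- rbind(centers, cand)
      attempts <- attempts + 1
    }
    radii <- runif(n_cells, layout$cell_radius_range[1], layout$cell_radius_range[2])
    types <- c(rep("CTC", layout$n_ctcs), rep("PBMC", layout$n_pbmcs))

    # --- per-cell marker mean intensities (counts over the cell disc)
    sc <- layout$intensity_scale
    if (layout$n_ctcs > 0) {
      ctc_cells <- generate_cellline_cells(ctc_profile, layout$n_ctcs)
      ker_ctc <- ctc_cells$mean_intensity_keratin * sc
      vim_ctc <- ctc_cells$mean_intensity_vimentin * sc
    } else {
      ker_ctc <- vim_ctc <- numeric(0)
    }
    if (layout$n_pbmcs > 0) {
      vim_pbmc <- if (!is.null(pbmc_profile)) {
        generate_cellline_cells(pbmc_profile, layout$n_pbmcs)$mean_intensity_vimentin * sc
      } else {
        pmax(rnorm(layout$n_pbmcs, layout$pbmc_vimentin_mean,
                   0.2 * layout$pbmc_vimentin_mean), 0)
      }
      cd45_pbmc <- pmax(rnorm(layout$n_pbmcs, layout$cd45_mean_intensity,
                              0.2 * layout$cd45_mean_intensity), 0)
    } else {
      vim_pbmc <- cd45_pbmc <- numeric(0)
    }

    img <- array(0, dim = c(shape[1], shape[2], 4L),
                 dimnames = list(NULL, NULL, layout$channel_names))
    chan <- function(nm) match(nm, layout$channel_names)
    totals <- matrix(0, nrow = n_cells, ncol = 4,
                     dimnames = list(NULL, layout$channel_names))

    for (i in seq_len(n_cells)) {
      cell_disc <- soft_disc(shape, centers[i, ], radii[i], layout$edge_softness)
      nuc_disc <- soft_disc(shape, centers[i, ],
                            layout$nucleus_fraction * radii[i], layout$edge_softness)
      area <- pi * radii[i]^2
      nuc_area <- pi * (layout$nucleus_fraction * radii[i])^2
      add <- function(ch, disc, total) {
        if (total <= 0) return(invisible())
        sl <- img[, , ch]
        sl[disc$idx] <- sl[disc$idx] + total * disc$w
        img[, , ch] <<- sl
        totals[i, ch] <<- totals[i, ch] + total
      }
      add(chan("dapi"), nuc_disc, layout$dapi_mean_intensity * nuc_area)
      if (types[i] == "CTC") {
        j <- i
        add(chan("keratin"), cell_disc, ker_ctc[j] * area)
        add(chan("vimentin"), cell_disc, vim_ctc[j] * area)
      } else {
        j <- i - layout$n_ctcs
        add(chan("vimentin"), cell_disc, vim_pbmc[j] * area)
        add(chan("cd45"), cell_disc, cd45_pbmc[j] * area)
      }
    }

    img <- img + layout$background_level
    if (layout$noise_sd > 0) {
      img <- img + array(rnorm(length(img), sd = layout$noise_sd), dim = dim(img))
    }
    img[img < 0] <- 0
    maxval <- 2^layout$bit_depth - 1
    img[img > maxval] <- maxval

    truth <- data.frame(
      cell = seq_len(n_cells),
      type = types,
      row = centers[, 1], col = centers[, 2],
      radius = radii,
      is_cd45_positive = types == "PBMC",
      stringsAsFactors = FALSE
    )
    for (nm in layout$channel_names) truth[[paste0("total_", nm)]] <- totals[, nm]
    list(image = img, truth = truth)
  })
}
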