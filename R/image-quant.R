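#' Quantification configuration
#'
#' Parameters controlling segmentation, background estimation and CTC
#' identification.
#'
#' @param nuclear_threshold_method Thresholding rule for the nuclear (DAPI)
#'   channel; currently \code{"otsu"}.
#' @param min_cell_area,max_cell_area Area bounds (pixels) for retained
#'   regions; objects outside are discarded.
#' @param dilation_margin Radius (pixels) by which each nucleus is dilated
#'   to capture cytoplasmic signal.
#' @param background_estimator \code{"median"} (median over all non-region
#'   pixels, the default) or \code{"boxes"} (mean over background boxes
#'   sampled away from regions).
#' @param n_background_boxes,background_box_size Number and side length of
#'   boxes for the \code{"boxes"} estimator.
#' @param cd45_negativity_quantile A cell is CD45-negative when its mean
#'   CD45 intensity is below this quantile of the CD45-bright population
#'   found by 2-class clustering (default 0.05, the 5th percentile).
#' @param dapi_positivity_factor A cell is DAPI-positive when its mean DAPI
#'   intensity exceeds this multiple of the DAPI background.
#' @return An object of class \code{quant_config}.
#' @export
quant_config <- function(nuclear_threshold_method = "otsu",
                         min_cell_area = 50,
                         max_cell_area = 5000,
                         dilation_margin = 6,
                         background_estimator = c("median", "boxes"),
                         n_background_boxes = 8L,
                         background_box_size = 9L,
                         cd45_negativity_quantile = 0.05,
                         dapi_positivity_factor = 2) {
  stopifnot(min_cell_area > 0, min_cell_area < max_cell_area)
  stopifnot(cd45_negativity_quantile > 0, cd45_negativity_quantile < 1)
  stopifnot(dapi_positivity_factor > 0, dilation_margin >= 0)
  structure(list(
    nuclear_threshold_method = match.arg(nuclear_threshold_method, "otsu"),
    min_cell_area = min_cell_area, max_cell_area = max_cell_area,
    dilation_margin = dilation_margin,
    background_estimator = match.arg(background_estimator),
    n_background_boxes = as.integer(n_background_boxes),
    background_box_size = as.integer(background_box_size),
    cd45_negativity_quantile = cd45_negativity_quantile,
    dapi_positivity_factor = dapi_positivity_factor
  ), class = "quant_config")
}

# coerce a rows x cols x channels array (dimnames on dim 3) and fetch a channel
get_channel <- function(image, name) {
  stopifnot(length(dim(image)) == 3L)
  nms <- dimnames(image)[[3]]
  if (is.null(nms) || !(name %in% nms)) {
    stop(sprintf("image has no '%s' channel (channels: %s)", name,
                 paste(nms %||% "<unnamed>", collapse = ", ")))
  }
  image[, , name]
}

#' Segment cells from the nuclear channel
#'
#' Thresholds the DAPI channel (Otsu), labels connected components, dilates
#' each nucleus by \code{dilation_margin} pixels to capture cytoplasmic
#' signal, resolves contested pixels by nearest-nucleus assignment
#' (geodesic propagation of the nucleus labels through the dilated mask),
#' and discards regions outside the configured area bounds.
#'
#' @param image Numeric array (rows x cols x channels) with a channel named
#'   \code{"dapi"} in \code{dimnames}.
#' @param config A \code{\link{quant_config}}.
#' @return An object of class \code{cell_regions}: a list of regions, each
#'   with \code{region_id}, \code{pixels} (n x 2 integer matrix of
#'   0-based (row, col) coordinates), \code{area} and \code{centroid};
#'   carries the label matrix as attribute \code{"label"}. A blank image
#'   yields an empty list.
#' @export
segment_cells <- function(image, config = quant_config()) {
  dapi <- get_channel(image, "dapi")
  shape <- dim(dapi)
  empty <- structure(list(), class = "cell_regions",
                     label = matrix(0L, shape[1], shape[2]), shape = shape)
  if (diff(range(dapi)) == 0) return(empty)

  x <- (dapi - min(dapi)) / diff(range(dapi))
  thr <- EBImage::otsu(EBImage::Image(x), range = c(0, 1))
  mask <- x > thr
  nuclei <- EBImage::bwlabel(mask)
  if (max(nuclei) == 0) return(empty)

  if (config$dilation_margin > 0) {
    brush <- EBImage::makeBrush(2L * ceiling(config$dilation_margin) + 1L, shape = "disc")
    dil <- EBImage::dilate(mask, brush)
  } else {
    dil <- mask
  }
  # nearest-nucleus assignment of dilated pixels (distance-dominated propagation)
  lab <- EBImage::imageData(EBImage::propagate(EBImage::Image(x), seeds = nuclei,
                                               mask = dil, lambda = 1e8))
  lab <- matrix(as.integer(lab), shape[1], shape[2])

  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= config$min_cell_area & areas <= config$max_cell_area)
  lab[!(lab %in% keep)] <- 0L
  if (length(keep) == 0L) return(empty)

  # relabel sequentially
  new_ids <- integer(max(keep)); new_ids[keep] <- seq_along(keep)
  lab[lab > 0] <- new_ids[lab[lab > 0]]

  regions <- lapply(seq_along(keep), function(i) {
    px <- which(lab == i, arr.ind = TRUE)
    list(region_id = i,
         pixels = unname(px) - 1L,  # 0-based (row, col)
         area = nrow(px),
         centroid = c(row = mean(px[, 1]) - 1, col = mean(px[, 2]) - 1))
  })
  structure(regions, class = "cell_regions", label = lab, shape = shape)
}

#' Estimate the background intensity of a channel
#'
#' Default estimator: median intensity over all pixels not belonging to any
#' segmented region. Alternative (\code{"boxes"}): mean over
#' \code{n_background_boxes} square boxes placed on a scan grid at
#' positions that do not intersect any region, emulating the manual
#' background-box practice of interactive image analysis.
#'
#' @param channel Numeric matrix, one image channel.
#' @param regions A \code{cell_regions} object (may be empty).
#' @param config A \code{\link{quant_config}}.
#' @return Background intensity (scalar).
#' @export
estimate_background <- function(channel, regions, config = quant_config()) {
  lab <- attr(regions, "label")
  if (is.null(lab)) {
    lab <- matrix(0L, nrow(channel), ncol(channel))
    for (r in regions) lab[r$pixels + 1L] <- r$region_id
  }
  stopifnot(all(dim(lab) == dim(channel)))
  free <- lab == 0L
  if (!any(free)) stop("regions cover the whole image; no background pixels left")
  if (config$background_estimator == "median") {
    return(median(channel[free]))
  }
  # "boxes": deterministic scan for region-free boxes
  b <- config$background_box_size
  vals <- numeric(0); found <- 0L
  step <- max(b, 4L)
  for (r0 in seq(1L, nrow(channel) - b + 1L, by = step)) {
    for (c0 in seq(1L, ncol(channel) - b + 1L, by = step)) {
      rows <- r0:(r0 + b - 1L); cols <- c0:(c0 + b - 1L)
      if (all(lab[rows, cols] == 0L)) {
        vals <- c(vals, mean(channel[rows, cols]))
        found <- found + 1L
        if (found >= config$n_background_boxes) return(mean(vals))
      }
    }
  }
  if (found == 0L) stop("no region-free background boxes found")
  mean(vals)
}

#' Corrected Total Cell Fluorescence of a region
#'
#' CTCF = integrated density over the region's pixels minus
#' area x mean background. Negative values (a cell dimmer than the local
#' background) are preserved, not clipped: they are data.
#'
#' @param region One region from \code{\link{segment_cells}} (list with
#'   \code{pixels} as 0-based (row, col) matrix and \code{area}).
#' @param channel Numeric matrix, the image channel to measure.
#' @param background Mean background intensity (>= 0).
#' @return Named list with \code{ctcf} and \code{mean_intensity}
#'   (= ctcf / area).
#' @examples
#' chan <- matrix(10, 20, 20)
#' reg <- list(region_id = 1L,
#'             pixels = as.matrix(expand.grid(0:9, 0:9)),
#'             area = 100L)
#' compute_ctcf(reg, chan, background = 2)  # ctcf 800, mean 8
#' @export
compute_ctcf <- function(region, channel, background) {
  stopifnot(region$area > 0, background >= 0)
  idx <- region$pixels + 1L
  total <- sum(channel[idx])
  ctcf <- total - region$area * background
  list(ctcf = ctcf, mean_intensity = ctcf / region$area)
}

#' Quantify all cells in a multi-channel image
#'
#' Runs segmentation, per-channel background estimation and CTCF
#' measurement, and sets the DAPI-positivity / CD45-negativity / CTC flags
#' (see \code{\link{identify_ctcs}} for the rules). Returns every segmented
#' cell; filter on \code{is_ctc} or call \code{identify_ctcs} to keep CTCs
#' only.
#'
#' @param image Numeric array (rows x cols x channels), channel names in
#'   \code{dimnames}; must include \code{dapi} and \code{cd45} for
#'   identity flags (missing markers yield NA columns and NA flags).
#' @param config A \code{\link{quant_config}}.
#' @param sample_id Sample label recorded in each record.
#' @return A \code{cell_record} data frame: \code{sample_id},
#'   \code{cell_id}, \code{area}, \code{ctcf_<marker>},
#'   \code{mean_intensity_<marker>}, \code{is_dapi_positive},
#'   \code{is_cd45_negative}, \code{is_ctc}; per-channel backgrounds in
#'   \code{attr(, "backgrounds")}.
#' @export
quantify_image <- function(image, config = quant_config(), sample_id = "sample") {
  regions <- segment_cells(image, config)
  channels <- dimnames(image)[[3]]
  backgrounds <- setNames(numeric(length(channels)), channels)
  rec <- data.frame(sample_id = character(0), cell_id = character(0),
                    area = integer(0), stringsAsFactors = FALSE)
  if (length(regions) > 0) {
    rec <- data.frame(
      sample_id = sample_id,
      cell_id = sprintf("%s_c%03d", sample_id, vapply(regions, `[[`, 1L, "region_id")),
      area = vapply(regions, `[[`, 1L, "area"),
      row = vapply(regions, function(r) r$centroid[["row"]], 1.0),
      col = vapply(regions, function(r) r$centroid[["col"]], 1.0),
      stringsAsFactors = FALSE
    )
  }
  for (ch in channels) {
    chan <- image[, , ch]
    bg <- estimate_background(chan, regions, config)
    backgrounds[[ch]] <- bg
    if (length(regions) > 0) {
      m <- t(vapply(regions, function(r) unlist(compute_ctcf(r, chan, bg)),
                    c(ctcf = 0, mean_intensity = 0)))
      rec[[paste0("ctcf_", ch)]] <- m[, "ctcf"]
      rec[[paste0("mean_intensity_", ch)]] <- m[, "mean_intensity"]
    } else {
      rec[[paste0("ctcf_", ch)]] <- numeric(0)
      rec[[paste0("mean_intensity_", ch)]] <- numeric(0)
    }
  }
  attr(rec, "backgrounds") <- backgrounds
  rec <- flag_ctcs(rec, config)
  class(rec) <- c("cell_record", "data.frame")
  rec
}

# set is_dapi_positive / is_cd45_negative / is_ctc flags on a record table
flag_ctcs <- function(records, config = quant_config(),
                      dapi_background = NULL, cd45_background = NULL) {
  bgs <- attr(records, "backgrounds")
  dapi_background <- dapi_background %||% bgs[["dapi"]]
  if (nrow(records) == 0L) {
    records$is_dapi_positive <- logical(0)
    records$is_cd45_negative <- logical(0)
    records$is_ctc <- logical(0)
    return(records)
  }
  if (is.null(dapi_background)) stop("dapi background required to flag DAPI positivity")
  records$is_dapi_positive <-
    records$mean_intensity_dapi > config$dapi_positivity_factor * max(dapi_background, 1e-9)

  cd45 <- records$mean_intensity_cd45
  thr <- cd45_threshold(cd45, config,
                        cd45_background %||% bgs[["cd45"]] %||% 0)
  records$is_cd45_negative <- cd45 < thr
  records$is_ctc <- records$is_dapi_positive & records$is_cd45_negative
  records
}

# CD45 negativity threshold: 2-class split (k-means) on CD45 mean intensity;
# threshold = configured quantile of the bright class. Falls back to an
# absolute threshold (3 x background) when clustering is impossible or the
# sample has no clear bright class.
cd45_threshold <- function(cd45, config, cd45_background) {
  fallback <- 3 * max(cd45_background, 1e-9)
  if (length(cd45) < 2L || diff(range(cd45)) == 0) {
    warning("fewer than 2 distinct CD45 values; falling back to absolute CD45 threshold")
    return(fallback)
  }
  # cluster on the square-root scale (variance-stabilizing for fluorescence):
  # compresses the size-driven spread of the CD45-bright class so small
  # leukocytes do not fall into the dim cluster
  s <- sqrt(pmax(cd45, 0))
  km <- kmeans(s, centers = range(s))
  bright <- cd45[km$cluster == which.max(km$centers)]
  dim_cl <- cd45[km$cluster == which.min(km$centers)]
  # guard: if the two classes are not separated, the "bright" class is noise
  if (min(bright) <= max(dim_cl) || length(bright) == 0L) {
    warning("CD45 intensities do not separate into two classes; falling back to absolute threshold")
    return(fallback)
  }
  # guard: the dim class must sit at background level, otherwise the sample
  # has no CD45-negative population and clustering merely split the bright one
  if (length(dim_cl) == 0L || min(dim_cl) > fallback) {
    warning("no CD45-negative population near background; falling back to absolute threshold")
    return(fallback)
  }
  # cap at the bright-cluster minimum: a cell in the CD45-positive class is
  # never CD45-negative, whatever the percentile guard says
  min(unname(quantile(bright, config$cd45_negativity_quantile)), min(bright))
}

#' Identify CTCs among quantified cells
#'
#' A CTC is a DAPI-positive, CD45-negative object. DAPI positivity: mean
#' DAPI intensity above \code{dapi_positivity_factor} times the DAPI
#' background. CD45 negativity: mean CD45 intensity below the configured
#' quantile (default 5th percentile) of the CD45-bright population found by
#' 2-class clustering of CD45 intensity; when clustering is impossible
#' (fewer than 2 cells, or no separation) an absolute threshold of 3 x the
#' CD45 background is used and a warning is raised. Keratin level is a
#' measurement, never a gate: vimentin-only CTCs are retained.
#'
#' @param records A \code{cell_record} data frame from
#'   \code{\link{quantify_image}} (or with the same columns plus a
#'   \code{backgrounds} attribute / explicit background arguments).
#' @param config A \code{\link{quant_config}}.
#' @param dapi_background,cd45_background Channel backgrounds; default
#'   taken from \code{attr(records, "backgrounds")}.
#' @return The subset of \code{records} that are CTCs, input order
#'   preserved, with the three identity flags set.
#' @export
identify_ctcs <- function(records, config = quant_config(),
                          dapi_background = NULL, cd45_background = NULL) {
  stopifnot(all(c("mean_intensity_dapi", "mean_intensity_cd45") %in% names(records)))
  records <- flag_ctcs(records, config, dapi_background, cd45_background)
  records[records$is_ctc, , drop = FALSE]
}
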