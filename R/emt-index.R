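#' EMT classification cut-offs
#'
#' Holds the epithelial upper bound and the mesenchymal band of the vim/K
#' EMT index. Cells at or below \code{epithelial_upper} are epithelial;
#' cells at or above \code{mesenchymal_lower} are mesenchymal; the open
#' interval between the two is the intermediate (EMT-undergoing) band.
#'
#' @param epithelial_upper,mesenchymal_lower,mesenchymal_upper Ratio bounds,
#'   \code{0 <= epithelial_upper < mesenchymal_lower <= mesenchymal_upper}.
#' @return An object of class \code{emt_cutoffs}.
#' @export
emt_cutoffs <- function(epithelial_upper, mesenchymal_lower, mesenchymal_upper) {
  if (!(0 <= epithelial_upper && epithelial_upper < mesenchymal_lower &&
        mesenchymal_lower <= mesenchymal_upper)) {
    stop("cutoffs must satisfy 0 <= epithelial_upper < mesenchymal_lower <= mesenchymal_upper")
  }
  structure(list(epithelial_upper = epithelial_upper,
                 mesenchymal_lower = mesenchymal_lower,
                 mesenchymal_upper = mesenchymal_upper),
            class = "emt_cutoffs")
}

#' @export
print.emt_cutoffs <- function(x, ...) {
  cat(sprintf("<emt_cutoffs> epithelial <= %.4g < intermediate < %.4g <= mesenchymal (ref max %.4g)\n",
              x$epithelial_upper, x$mesenchymal_lower, x$mesenchymal_upper))
  invisible(x)
}

#' Per-cell marker ratio (EMT index)
#'
#' Computes the ratio of two background-corrected mean intensities
#' (CTCF/area), by default vimentin over keratin — the EMT index. Negative
#' mean intensities (cells dimmer than background) are clamped to 0 before
#' division. When the denominator falls below \code{denom_floor} the ratio
#' is undefined (\code{NA}) and the cell is excluded from classification
#' but counted in QC.
#'
#' The operation is generic over marker pairs, so vimentin/EpCAM or
#' fibronectin/keratin indices use the same code path.
#'
#' @param records A data frame with \code{mean_intensity_<marker>} columns
#'   (e.g. from \code{\link{quantify_image}} or
#'   \code{\link{generate_cellline_cells}}).
#' @param numerator,denominator Marker names (default \code{"vimentin"},
#'   \code{"keratin"}).
#' @param denom_floor Mean-intensity floor below which the ratio is
#'   undefined (default 0: only exactly non-positive denominators are
#'   undefined).
#' @return A \code{ratio_record} data frame: \code{cell_id},
#'   \code{numerator_marker}, \code{denominator_marker}, \code{ratio}
#'   (NA when undefined), \code{ratio_defined}.
#' @examples
#' cells <- data.frame(cell_id = "a",
#'                     mean_intensity_keratin = 87.34,
#'                     mean_intensity_vimentin = 15.68)
#' compute_ratio(cells)$ratio  # 0.1795...
#' @export
compute_ratio <- function(records, numerator = "vimentin",
                          denominator = "keratin", denom_floor = 0) {
  num_col <- paste0("mean_intensity_", numerator)
  den_col <- paste0("mean_intensity_", denominator)
  for (col in c(num_col, den_col)) {
    if (!col %in% names(records)) {
      stop(sprintf("unknown marker: no column '%s' in records", col))
    }
  }
  num <- pmax(records[[num_col]], 0)
  den <- pmax(records[[den_col]], 0)
  defined <- den > max(denom_floor, 0)
  ratio <- ifelse(defined, num / den, NA_real_)
  out <- data.frame(
    cell_id = records$cell_id %||% sprintf("cell_%04d", seq_len(nrow(records))),
    numerator_marker = numerator,
    denominator_marker = denominator,
    ratio = ratio,
    ratio_defined = defined,
    stringsAsFactors = FALSE
  )
  class(out) <- c("ratio_record", "data.frame")
  out
}

#' Default denominator floor from an epithelial reference
#'
#' 1\% of the median keratin (denominator-marker) mean intensity of the
#' epithelial reference population: below this level the denominator is
#' considered unmeasured and the ratio undefined.
#'
#' @param epithelial_ref_denominator Numeric vector of denominator-marker
#'   mean intensities in the epithelial reference cells.
#' @return The floor (scalar).
#' @export
default_denom_floor <- function(epithelial_ref_denominator) {
  0.01 * median(epithelial_ref_denominator)
}

#' Derive EMT cut-offs from reference ratio distributions
#'
#' The epithelial upper bound is the maximum ratio observed in the
#' epithelial reference population; the mesenchymal band is the
#' min-to-max range of the mesenchymal reference population. With MCF-7 as
#' the epithelial and Hs578T as the mesenchymal reference this yields the
#' bounds 0.49 and [5.47, 38.88].
#'
#' @param epithelial_ref_ratios,mesenchymal_ref_ratios Non-empty numeric
#'   vectors of reference vim/K ratios. The populations must not overlap
#'   (\code{max(epithelial) < min(mesenchymal)}), otherwise the scheme is
#'   undefined and an error is raised.
#' @return An \code{\link{emt_cutoffs}} object.
#' @examples
#' derive_cutoffs(c(0.12, 0.3, 0.49), c(5.47, 12, 38.88))
#' @export
derive_cutoffs <- function(epithelial_ref_ratios, mesenchymal_ref_ratios) {
  if (length(epithelial_ref_ratios) == 0L || length(mesenchymal_ref_ratios) == 0L) {
    stop("both reference ratio sets must be non-empty")
  }
  e_max <- max(epithelial_ref_ratios)
  m_min <- min(mesenchymal_ref_ratios)
  m_max <- max(mesenchymal_ref_ratios)
  if (e_max >= m_min) {
    stop(sprintf("reference distributions overlap (epithelial max %.4g >= mesenchymal min %.4g); cut-off scheme undefined",
                 e_max, m_min))
  }
  emt_cutoffs(e_max, m_min, m_max)
}

#' Classify cells along the EMT gradient
#'
#' Assigns each defined ratio exactly one label: \code{"epithelial"} when
#' \code{ratio <= epithelial_upper} (the boundary belongs to the epithelial
#' class), \code{"mesenchymal"} when \code{ratio >= mesenchymal_lower}
#' (ratios above the mesenchymal reference maximum are still mesenchymal
#' but flagged \code{above_reference}), and \code{"intermediate"}
#' otherwise. \code{NA} ratios give \code{NA} labels.
#'
#' @param ratio Numeric vector of vim/K ratios (>= 0 where defined).
#' @param cutoffs An \code{\link{emt_cutoffs}} object.
#' @return A data frame with \code{ratio}, \code{emt_class} (factor with
#'   levels epithelial < intermediate < mesenchymal) and
#'   \code{above_reference}.
#' @examples
#' cuts <- emt_cutoffs(0.49, 5.47, 38.88)
#' classify_emt(c(0.19, 1.57, 13.14), cuts)$emt_class
#' @export
classify_emt <- function(ratio, cutoffs) {
  stopifnot(inherits(cutoffs, "emt_cutoffs"))
  if (any(ratio < 0, na.rm = TRUE)) stop("ratios must be >= 0")
  cls <- ifelse(is.na(ratio), NA_character_,
         ifelse(ratio <= cutoffs$epithelial_upper, "epithelial",
         ifelse(ratio >= cutoffs$mesenchymal_lower, "mesenchymal",
                "intermediate")))
  data.frame(
    ratio = ratio,
    emt_class = factor(cls, levels = c("epithelial", "intermediate", "mesenchymal"),
                       ordered = TRUE),
    above_reference = !is.na(ratio) & ratio > cutoffs$mesenchymal_upper
  )
}

#' Summarize EMT class proportions
#'
#' Counts and proportions per EMT class, pooled and (when a
#' \code{sample_id} is supplied) per sample. Proportions are over cells
#' with a defined ratio and sum to 1.
#'
#' @param emt_class Factor/character vector of class labels (NA = undefined
#'   ratio, excluded from proportions but counted in \code{n_undefined}).
#' @param sample_id Optional vector of sample labels, same length.
#' @return A data frame with \code{sample_id} (\code{"pooled"} for the
#'   overall row), \code{emt_class}, \code{n} and \code{proportion}; the
#'   number of undefined-ratio cells is in \code{attr(, "n_undefined")}.
#' @export
summarize_classes <- function(emt_class, sample_id = NULL) {
  lev <- c("epithelial", "intermediate", "mesenchymal")
  emt_class <- factor(as.character(emt_class), levels = lev)
  if (length(emt_class) == 0L) {
    out <- data.frame(sample_id = character(0), emt_class = character(0),
                      n = integer(0), proportion = numeric(0))
    attr(out, "n_undefined") <- 0L
    return(out)
  }
  tally <- function(x, label) {
    tab <- table(x[!is.na(x)])
    data.frame(sample_id = label, emt_class = lev, n = as.integer(tab[lev]),
               proportion = if (sum(tab) > 0) as.numeric(tab[lev] / sum(tab)) else NA_real_,
               stringsAsFactors = FALSE)
  }
  out <- tally(emt_class, "pooled")
  if (!is.null(sample_id)) {
    per <- lapply(split(emt_class, sample_id), identity)
    out <- rbind(out, do.call(rbind, Map(tally, per, names(per))))
    rownames(out) <- NULL
  }
  attr(out, "n_undefined") <- sum(is.na(emt_class))
  out
}
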