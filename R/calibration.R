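#' Fit per-voltage nominal-vs-measured linear regressions
#'
#' For each PMT voltage in the bead series, fits an unweighted ordinary
#' least squares regression of measured fluorescence on nominal level
#' (replicates enter as individual points) and reports slope, intercept and
#' R-squared. A degenerate fit with zero measured variance reports
#' \code{r_squared = 0}.
#'
#' @param series A bead series: data frame with columns
#'   \code{pmt_voltage}, \code{nominal_level}, \code{measured} (as produced
#'   by \code{\link{generate_beads}} or read from CSV).
#' @return A \code{calibration_fit} data frame sorted by voltage with
#'   columns \code{pmt_voltage}, \code{slope}, \code{intercept},
#'   \code{r_squared}, \code{n_points}.
#' @examples
#' beads <- generate_beads(bead_gen_config(seed = 1))
#' fit_linearity(beads)
#' @export
fit_linearity <- function(series) {
  req <- c("pmt_voltage", "nominal_level", "measured")
  if (!all(req %in% names(series))) {
    stop("bead series must have columns: ", paste(req, collapse = ", "))
  }
  if (any(series$measured < 0)) stop("measured intensities must be >= 0")
  volts <- sort(unique(series$pmt_voltage))
  fits <- lapply(volts, function(v) {
    sub <- series[series$pmt_voltage == v, ]
    if (length(unique(sub$nominal_level)) < 2L) {
      stop(sprintf("voltage %g has fewer than 2 distinct nominal levels; cannot fit", v))
    }
    fit <- lm(measured ~ nominal_level, data = sub)
    ss_tot <- sum((sub$measured - mean(sub$measured))^2)
    r2 <- if (ss_tot <= 0) 0 else 1 - sum(residuals(fit)^2) / ss_tot
    data.frame(pmt_voltage = v,
               slope = unname(coef(fit)[2]),
               intercept = unname(coef(fit)[1]),
               r_squared = min(max(r2, 0), 1),
               n_points = nrow(sub))
  })
  out <- do.call(rbind, fits)
  class(out) <- c("calibration_fit", "data.frame")
  out
}

#' Highest PMT voltage with linear detector response
#'
#' Returns the largest voltage \code{V} such that \emph{every} fitted
#' voltage up to and including \code{V} has \code{r_squared >= r2_min}.
#' Detector gain response degrades with voltage, so linearity is required
#' cumulatively from the bottom of the range up.
#'
#' @param fits A \code{calibration_fit} data frame from
#'   \code{\link{fit_linearity}}.
#' @param r2_min R-squared threshold defining "practically linear"
#'   (default 0.99).
#' @return The voltage (numeric), or \code{NA_real_} if even the lowest
#'   voltage fails the threshold.
#' @examples
#' fits <- data.frame(pmt_voltage = c(450, 500, 550, 600),
#'                    r_squared = c(0.999, 0.998, 0.995, 0.90))
#' linear_range(fits)  # 550
#' @export
linear_range <- function(fits, r2_min = 0.99) {
  if (nrow(fits) == 0L) stop("fits must be non-empty")
  fits <- fits[order(fits$pmt_voltage), ]
  ok <- fits$r_squared >= r2_min
  if (!ok[1]) return(NA_real_)
  last <- which(!ok)[1]
  if (is.na(last)) fits$pmt_voltage[nrow(fits)] else fits$pmt_voltage[last - 1]
}

#' Check that cell intensities lie within the bead standard curve
#'
#' Reports which of a set of per-cell mean intensities fall inside the
#' dynamic range spanned by the bead measurements at a given voltage, i.e.
#' inside \code{[min(measured), max(measured)]} for that voltage. Values in
#' range can be interpolated on the standard curve; values outside cannot.
#'
#' @param values Numeric vector of per-cell mean intensities.
#' @param series Bead series data frame (see \code{\link{fit_linearity}}).
#' @param voltage Voltage at which the cells were imaged; must be present
#'   in the series.
#' @return A list with \code{fraction_in_range}, \code{n_in},
#'   \code{n_total}, \code{range} (the bead min/max) and
#'   \code{out_of_range_values}.
#' @export
check_in_range <- function(values, series, voltage) {
  sub <- series[series$pmt_voltage == voltage, ]
  if (nrow(sub) == 0L) stop(sprintf("voltage %g not present in bead series", voltage))
  lo <- min(sub$measured); hi <- max(sub$measured)
  inside <- values >= lo & values <= hi
  list(
    fraction_in_range = if (length(values)) mean(inside) else NA_real_,
    n_in = sum(inside),
    n_total = length(values),
    range = c(lo, hi),
    out_of_range_values = values[!inside]
  )
}
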