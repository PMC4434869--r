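#' Configuration for the synthetic bead calibration series
#'
#' Describes a fluorescent-bead calibration experiment: beads of graded
#' nominal intensity imaged at several photomultiplier (PMT) voltages. Below
#' \code{saturation_voltage} the detector response is proportional to the
#' nominal level; above it the response soft-clips toward a ceiling, so the
#' brightest beads compress and the nominal-vs-measured regression degrades.
#'
#' @param pmt_voltages Numeric vector of PMT voltages (volts), all > 0.
#' @param nominal_levels Strictly decreasing nominal intensities in (0, 1]
#'   (default the 100/33/10/3 percent bead set).
#' @param saturation_voltage Voltage above which the response flattens.
#' @param gain_per_volt Exponential gain coefficient of the detector
#'   (dimensionless per volt); default 0.02 doubles the signal every ~35 V.
#' @param noise_cv Coefficient of variation of multiplicative measurement
#'   noise; >= 0.
#' @param replicates_per_level Replicate beads measured per (voltage, level).
#' @param base_intensity Measured intensity (CTCF units) of a 100% bead at
#'   the lowest voltage.
#' @param seed Integer seed; \code{NULL} leaves the RNG state alone.
#'
#' @return An object of class \code{bead_gen_config}.
#' @export
bead_gen_config <- function(pmt_voltages = c(450, 500, 550, 600),
                            nominal_levels = c(1.0, 0.33, 0.10, 0.03),
                            saturation_voltage = 560,
                            gain_per_volt = 0.02,
                            noise_cv = 0.02,
                            replicates_per_level = 3L,
                            base_intensity = 1000,
                            seed = NULL) {
  if (length(pmt_voltages) < 1L || any(pmt_voltages <= 0)) {
    stop("pmt_voltages must be a non-empty vector of positive voltages")
  }
  if (length(nominal_levels) < 1L) stop("nominal_levels must be non-empty")
  if (any(nominal_levels <= 0) || any(nominal_levels > 1)) {
    stop("nominal_levels must lie in (0, 1]")
  }
  if (is.unsorted(rev(nominal_levels), strictly = TRUE)) {
    stop("nominal_levels must be strictly decreasing")
  }
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (replicates_per_level < 1L) stop("replicates_per_level must be >= 1")
  structure(list(
    pmt_voltages = as.numeric(pmt_voltages),
    nominal_levels = as.numeric(nominal_levels),
    saturation_voltage = saturation_voltage,
    gain_per_volt = gain_per_volt,
    noise_cv = noise_cv,
    replicates_per_level = as.integer(replicates_per_level),
    base_intensity = base_intensity,
    seed = seed
  ), class = "bead_gen_config")
}

#' Generate a synthetic bead calibration series
#'
#' Simulates corrected total fluorescence of calibration beads per (PMT
#' voltage, nominal level, replicate). The noise-free expected response is
#' \code{base_intensity * level * exp(gain_per_volt * (V - min(V)))}; at
#' voltages above \code{saturation_voltage} the expectation is passed
#' through the soft-clip \code{C * (1 - exp(-x / C))} with ceiling \code{C}
#' set 10\% above the full-scale response at the saturation voltage, so
#' proportionality (and hence regression R-squared) degrades at the top end.
#' Multiplicative Gaussian noise with the configured CV is applied and
#' results are floored at 0.
#'
#' @param config A \code{\link{bead_gen_config}}.
#' @return A \code{bead_series}: data frame with columns
#'   \code{pmt_voltage}, \code{nominal_level}, \code{replicate},
#'   \code{measured}.
#' @examples
#' beads <- generate_beads(bead_gen_config(seed = 1))
#' head(beads)
#' @seealso \code{\link{fit_linearity}}, \code{\link{linear_range}}
#' @export
generate_beads <- function(config) {
  stopifnot(inherits(config, "bead_gen_config"))
  grid <- expand.grid(
    replicate = seq_len(config$replicates_per_level),
    nominal_level = config$nominal_levels,
    pmt_voltage = config$pmt_voltages,
    KEEP.OUT.ATTRS = FALSE
  )[, c("pmt_voltage", "nominal_level", "replicate")]
  v0 <- min(config$pmt_voltages)
  expected <- config$base_intensity * grid$nominal_level *
    exp(config$gain_per_volt * (grid$pmt_voltage - v0))
  ceiling_c <- 1.1 * config$base_intensity *
    exp(config$gain_per_volt * (config$saturation_voltage - v0))
  sat <- grid$pmt_voltage > config$saturation_voltage
  expected[sat] <- ceiling_c * (1 - exp(-expected[sat] / ceiling_c))
  measured <- with_seed(config$seed, {
    expected * (1 + rnorm(length(expected), sd = config$noise_cv))
  })
  grid$measured <- pmax(measured, 0)
  class(grid) <- c("bead_series", "data.frame")
  grid
}
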