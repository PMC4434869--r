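#' Reference cell-line marker profile
#'
#' A \code{cell_line_profile} holds the distributional parameters of keratin
#' and vimentin expression (background-corrected mean intensity, CTCF/area
#' units) for one reference cell population, together with the admissible
#' range of the per-cell vimentin/keratin (vim/K) ratio and the within-line
#' correlation between the two markers on the log scale.
#'
#' Marker levels are modelled as moment-matched lognormal marginals joined
#' by a Gaussian copula. When \code{marker_correlation} is \code{NULL} and a
#' target \code{ratio_mean} is supplied, the correlation is solved
#' analytically so that the implied mean of the vim/K ratio equals
#' \code{ratio_mean} (see \code{\link{calibrate_marker_correlation}});
#' otherwise it defaults to \code{-0.3}.
#'
#' @param name Label for the cell line.
#' @param keratin_mean,keratin_sd Mean and SD of keratin mean intensity
#'   (CTCF/area). Mean must be > 0 when the marker is expressed.
#' @param vimentin_mean,vimentin_sd Mean and SD of vimentin mean intensity
#'   (CTCF/area). A mean of 0 with SD 0 encodes a vimentin-null population.
#' @param ratio_range Length-2 numeric, the (min, max) of the per-cell vim/K
#'   ratio; cells outside this band are rejected by the generator.
#' @param marker_correlation Gaussian-copula correlation between log-keratin
#'   and log-vimentin, in [-1, 1], or \code{NULL} to calibrate/default.
#' @param ratio_mean Optional target mean of the vim/K ratio used to
#'   calibrate the correlation when \code{marker_correlation} is \code{NULL}.
#'
#' @return An object of class \code{cell_line_profile}.
#' @seealso \code{\link{cell_line_profiles}}, \code{\link{generate_cellline_cells}}
#' @export
cell_line_profile <- function(name, keratin_mean, keratin_sd,
                              vimentin_mean, vimentin_sd,
                              ratio_range, marker_correlation = NULL,
                              ratio_mean = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  stopifnot(keratin_sd >= 0, vimentin_sd >= 0)
  stopifnot(length(ratio_range) == 2L, ratio_range[1] <= ratio_range[2])
  if (keratin_mean <= 0) stop("keratin_mean must be > 0 (keratin is the ratio denominator)")
  if (vimentin_mean < 0) stop("vimentin_mean must be >= 0")
  if (is.null(marker_correlation)) {
    marker_correlation <- if (!is.null(ratio_mean) && vimentin_mean > 0) {
      calibrate_marker_correlation(keratin_mean, keratin_sd,
                                   vimentin_mean, vimentin_sd, ratio_mean)
    } else -0.3
  }
  stopifnot(marker_correlation >= -1, marker_correlation <= 1)
  structure(list(
    name = name,
    keratin_mean = keratin_mean, keratin_sd = keratin_sd,
    vimentin_mean = vimentin_mean, vimentin_sd = vimentin_sd,
    ratio_range = as.numeric(ratio_range),
    marker_correlation = as.numeric(marker_correlation),
    ratio_mean = ratio_mean
  ), class = "cell_line_profile")
}

#' @export
print.cell_line_profile <- function(x, ...) {
  cat(sprintf("<cell_line_profile> %s\n", x$name))
  cat(sprintf("  keratin  %.2f +/- %.2f  (CTCF/area)\n", x$keratin_mean, x$keratin_sd))
  cat(sprintf("  vimentin %.2f +/- %.2f  (CTCF/area)\n", x$vimentin_mean, x$vimentin_sd))
  cat(sprintf("  vim/K range [%.2f, %.2f], log-scale correlation %.2f\n",
              x$ratio_range[1], x$ratio_range[2], x$marker_correlation))
  invisible(x)
}

# lognormal parameters matched by moments to (mean, sd); sd = 0 gives a
# degenerate point mass (sigma = 0)
lnorm_params <- function(m, s) {
  stopifnot(m > 0, s >= 0)
  s2 <- log(1 + (s / m)^2)
  c(mu = log(m) - s2 / 2, sigma = sqrt(s2))
}

#' Calibrate the within-line marker correlation from a target ratio mean
#'
#' Under moment-matched lognormal marginals with a Gaussian copula, the mean
#' of the vimentin/keratin ratio has the closed form
#' \deqn{E[V/K] = (m_V/m_K)\, \exp(\sigma_K^2 - \rho\,\sigma_V\sigma_K),}
#' where \eqn{\sigma} are the log-scale SDs. Published per-line summaries
#' report the marginal means/SDs and the ratio mean but not the joint
#' distribution; solving this identity for \eqn{\rho} pins down the one free
#' copula parameter from the reported ratio mean.
#'
#' @param keratin_mean,keratin_sd,vimentin_mean,vimentin_sd Marginal moments
#'   (CTCF/area units).
#' @param ratio_mean Target mean of the vim/K ratio.
#' @return The copula correlation, clamped to [-0.99, 0.99].
#' @export
calibrate_marker_correlation <- function(keratin_mean, keratin_sd,
                                         vimentin_mean, vimentin_sd,
                                         ratio_mean) {
  sk <- lnorm_params(keratin_mean, keratin_sd)[["sigma"]]
  sv <- lnorm_params(vimentin_mean, vimentin_sd)[["sigma"]]
  if (sk == 0 || sv == 0) return(0)
  rho <- (sk^2 - log(ratio_mean / (vimentin_mean / keratin_mean))) / (sv * sk)
  max(min(rho, 0.99), -0.99)
}

#' Built-in reference cell-line profiles
#'
#' Keratin and vimentin expression statistics (CTCF/area) of the breast
#' cancer cell lines used as EMT references, measured by quantitative
#' immunofluorescence of cytospin preparations (about 100 cells per line):
#' the luminal/epithelial lines MCF-7 and T47D, the invasive/mesenchymal
#' lines MDA.MB231 and Hs578T, MCF-7 after EGF-induced EMT, and the pooled
#' patient CTC population. MCF-7 (lowest vim/K ratios) and Hs578T (highest)
#' are the canonical references for the epithelial and mesenchymal cut-offs.
#'
#' For each line the marker correlation is calibrated from the reported
#' ratio mean (see \code{\link{calibrate_marker_correlation}}).
#'
#' @return Named list of \code{\link{cell_line_profile}} objects with
#'   elements \code{MCF7}, \code{T47D}, \code{MDA_MB231}, \code{Hs578T},
#'   \code{MCF7_EGF} and \code{CTC}.
#' @examples
#' p <- cell_line_profiles()
#' p$MCF7$ratio_range   # vim/K range of the epithelial reference
#' @export
cell_line_profiles <- function() {
  list(
    MCF7 = cell_line_profile("MCF7", 87.34, 18.99, 15.68, 2.58,
                             c(0.12, 0.49), ratio_mean = 0.19),
    T47D = cell_line_profile("T47D", 35.43, 10.62, 6.73, 2.16,
                             c(0.17, 0.43), ratio_mean = 0.19),
    MDA_MB231 = cell_line_profile("MDA_MB231", 11.47, 4.87, 43.38, 12.06,
                                  c(1.19, 10.88), ratio_mean = 4.44),
    Hs578T = cell_line_profile("Hs578T", 4.02, 1.00, 53.64, 24.81,
                               c(5.47, 38.88), ratio_mean = 13.14),
    MCF7_EGF = cell_line_profile("MCF7_EGF", 18.37, 7.56, 23.63, 9.10,
                                 c(0.45, 5.05), ratio_mean = 1.57),
    CTC = cell_line_profile("CTC", 30.06, 25.00, 26.42, 25.45,
                            c(0.00, 22.46), ratio_mean = 1.62)
  )
}
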