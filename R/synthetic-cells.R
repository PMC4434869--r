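# Moments of exp(mu + s*(c*z + sqrt(1-c^2)*w)) where z ~ N(0,1) truncated to
# [a, b] and w ~ N(0,1) independent; used to pre-compensate the effect of the
# ratio-range rejection filter on each marker's marginal moments.
trunc_lnorm_moments <- function(mu, s, cc, a, b) {
  den <- pnorm(b) - pnorm(a)
  m1 <- exp(mu + s^2 / 2) * (pnorm(b - s * cc) - pnorm(a - s * cc)) / den
  m2 <- exp(2 * mu + 2 * s^2) * (pnorm(b - 2 * s * cc) - pnorm(a - 2 * s * cc)) / den
  c(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}

# Fixed-point adjustment of the lognormal (mu, sigma) of both markers so that
# the post-rejection (ratio in [lo, hi]) sample reproduces the profile's
# marginal means and SDs. The rejection acts on the standard score of the
# log-ratio, so the marginal effect is a univariate truncation with loading
# c = corr(log-marker, log-ratio); all moments are closed-form.
compensate_for_rejection <- function(profile, max_iter = 40) {
  pk <- lnorm_params(profile$keratin_mean, profile$keratin_sd)
  pv <- lnorm_params(profile$vimentin_mean, profile$vimentin_sd)
  muk <- pk[["mu"]]; sk <- pk[["sigma"]]
  muv <- pv[["mu"]]; sv <- pv[["sigma"]]
  rho <- profile$marker_correlation
  lo <- profile$ratio_range[1]; hi <- profile$ratio_range[2]
  vk_target <- log(1 + (profile$keratin_sd / profile$keratin_mean)^2)
  vv_target <- log(1 + (profile$vimentin_sd / profile$vimentin_mean)^2)
  for (i in seq_len(max_iter)) {
    sr <- sqrt(max(sk^2 + sv^2 - 2 * rho * sk * sv, 1e-12))
    mur <- muv - muk
    a <- (log(lo) - mur) / sr   # log(0) -> -Inf is fine (no lower truncation)
    b <- (log(hi) - mur) / sr
    if (pnorm(b) - pnorm(a) < 1e-10) {
      stop(sprintf("profile '%s': ratio_range [%g, %g] is incompatible with the marker marginals",
                   profile$name, lo, hi))
    }
    ck <- (rho * sv - sk) / sr
    cv <- (sv - rho * sk) / sr
    tk <- trunc_lnorm_moments(muk, sk, ck, a, b)
    tv <- trunc_lnorm_moments(muv, sv, cv, a, b)
    muk <- muk + log(profile$keratin_mean / tk[["mean"]])
    muv <- muv + log(profile$vimentin_mean / tv[["mean"]])
    sk <- sqrt(max(sk^2 + vk_target - log(1 + (tk[["sd"]] / tk[["mean"]])^2), 1e-10))
    sv <- sqrt(max(sv^2 + vv_target - log(1 + (tv[["sd"]] / tv[["mean"]])^2), 1e-10))
  }
  list(muk = muk, sk = sk, muv = muv, sv = sv)
}

#' Generate per-cell marker measurements for a reference cell line
#'
#' Draws \code{n} cells with correlated (keratin, vimentin) mean-intensity
#' pairs (CTCF/area units) from a lognormal model with Gaussian copula,
#' moment-matched to the profile's marginal means/SDs, and rejection-filters
#' each cell so that its vimentin/keratin ratio falls inside
#' \code{profile$ratio_range}. The lognormal parameters are pre-compensated
#' for the rejection step so that the \emph{delivered} sample matches the
#' profile moments, not just the pre-rejection distribution.
#'
#' A vimentin-null profile (\code{vimentin_mean = 0, vimentin_sd = 0})
#' yields vimentin identically 0 and vim/K ratios of exactly 0.
#'
#' @param profile A \code{\link{cell_line_profile}}.
#' @param n Number of cells (>= 1).
#' @param seed Integer seed for reproducibility; \code{NULL} uses the
#'   current RNG state.
#' @param max_attempts_per_cell Rejection-sampling budget per delivered
#'   cell; exceeding it raises an error naming the profile rather than
#'   silently truncating.
#'
#' @return Data frame with one row per cell: \code{cell_id},
#'   \code{sample_id} (the profile name), \code{mean_intensity_keratin},
#'   \code{mean_intensity_vimentin} and \code{ratio_vim_k}.
#' @examples
#' cells <- generate_cellline_cells(cell_line_profiles()$MCF7, n = 50, seed = 7)
#' range(cells$ratio_vim_k)
#' @export
generate_cellline_cells <- function(profile, n, seed = NULL,
                                    max_attempts_per_cell = 1000) {
  stopifnot(inherits(profile, "cell_line_profile"))
  if (n < 1) stop("n must be >= 1")
  lo <- profile$ratio_range[1]; hi <- profile$ratio_range[2]

  if (profile$vimentin_mean == 0 && profile$vimentin_sd == 0) {
    if (lo > 0) stop(sprintf("profile '%s': vimentin-null profile but ratio_range excludes 0",
                             profile$name))
    pk <- lnorm_params(profile$keratin_mean, profile$keratin_sd)
    k <- with_seed(seed, exp(pk[["mu"]] + pk[["sigma"]] * rnorm(n)))
    return(data.frame(
      cell_id = sprintf("%s_%04d", profile$name, seq_len(n)),
      sample_id = profile$name,
      mean_intensity_keratin = k,
      mean_intensity_vimentin = 0,
      ratio_vim_k = 0,
      stringsAsFactors = FALSE
    ))
  }

  p <- compensate_for_rejection(profile)
  rho <- profile$marker_correlation
  with_seed(seed, {
    out_k <- numeric(0); out_v <- numeric(0)
    attempts <- 0
    budget <- max_attempts_per_cell * n
    while (length(out_k) < n) {
      if (attempts >= budget) {
        stop(sprintf("profile '%s': could not generate %d cells with vim/K in [%g, %g] within %d attempts",
                     profile$name, n, lo, hi, budget))
      }
      m <- min(max(2L * n, 100L), budget - attempts)
      z1 <- rnorm(m)
      z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(m)
      k <- exp(p$muk + p$sk * z1)
      v <- exp(p$muv + p$sv * z2)
      r <- v / k
      keep <- r >= lo & r <= hi
      out_k <- c(out_k, k[keep]); out_v <- c(out_v, v[keep])
      attempts <- attempts + m
    }
    k <- out_k[seq_len(n)]; v <- out_v[seq_len(n)]
    data.frame(
      cell_id = sprintf("%s_%04d", profile$name, seq_len(n)),
      sample_id = profile$name,
      mean_intensity_keratin = k,
      mean_intensity_vimentin = v,
      ratio_vim_k = v / k,
      stringsAsFactors = FALSE
    )
  })
}
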