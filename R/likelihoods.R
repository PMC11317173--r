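#' Beta-binomial likelihood of an alternate read count
#'
#' Probability of observing `n_alt` alternate reads among `n_total` under a
#' beta-binomial whose mean is pinned to the cluster centroid `mu`:
#' pseudo-counts are `alpha = mu * n_total * c_scale` and
#' `beta = (1 - mu) * n_total * c_scale`, the moment-matched approximation
#' that avoids a Newton-Raphson fit of the shape parameters. Computed in log
#' space so deep coverage (250x and beyond) cannot overflow.
#'
#' `mu` is clamped to `[1e-6, 1 - 1e-6]` because the pseudo-counts degenerate
#' at 0 and 1. Zero total depth carries no information and returns 1.
#'
#' @param n_alt,n_total Non-negative integer read counts, `n_alt <= n_total`.
#' @param mu Cluster centroid (expected VAF) in `(0, 1)`.
#' @param c_scale Pseudo-count multiplication constant (default 1).
#' @return Probability mass, recycled over the longest argument.
#' @export
#' @examples
#' betabin_likelihood(1, 2, 0.5) # alpha = beta = 1: uniform, 1/3
betabin_likelihood <- function(n_alt, n_total, mu, c_scale = 1) {
  if (any(n_alt < 0) || any(n_alt > n_total)) {
    stop("need 0 <= n_alt <= n_total", call. = FALSE)
  }
  mu <- pmin(pmax(mu, 1e-6), 1 - 1e-6)
  a <- mu * n_total * c_scale
  b <- (1 - mu) * n_total * c_scale
  lp <- lchoose(n_total, n_alt) + lbeta(n_alt + a, n_total - n_alt + b) -
    lbeta(a, b)
  p <- exp(lp)
  p[n_total == 0] <- 1
  p
}

#' Binomial sequencing-error likelihood
#'
#' Likelihood that `n_alt` alternate reads arise purely from sequencing
#' error at per-read error probability `p_se`; used for clusters whose
#' centroid is zero in a sample (the false-variant cluster).
#'
#' @param n_alt,n_total Non-negative integer read counts, `n_alt <= n_total`.
#' @param p_se Per-read error probability (0.01 at Phred base quality 20).
#' @return Binomial probability mass.
#' @export
binom_error_likelihood <- function(n_alt, n_total, p_se) {
  if (any(n_alt < 0) || any(n_alt > n_total)) {
    stop("need 0 <= n_alt <= n_total", call. = FALSE)
  }
  dbinom(n_alt, n_total, p_se)
}
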