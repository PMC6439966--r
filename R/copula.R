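#' Gaussian mixture copula parameters for one condition
#'
#' The reproducible (`rep`) component is Gaussian with common mean `mu1 > 0`,
#' variance `sigma1_sq` and exchangeable inter-replicate correlation
#' `0 < rho1 <= 1`; the irreproducible (`irep`) component is fixed at the
#' standard normal with zero correlation (`mu0 = 0`, `sigma0^2 = 1`,
#' `rho0 = 0`), which makes the mixture identifiable. `q` is the mixing
#' proportion of reproducible signals.
#'
#' @param mu1 reproducible-component mean, `> 0`.
#' @param sigma1_sq reproducible-component variance, `> 0`.
#' @param rho1 reproducible-component correlation, in `(0, 1]`.
#' @param q mixing proportion of reproducible signals, in `(0, 1)`.
#' @return An object of class `copula_params`.
#' @export
copula_params <- function(mu1 = 1, sigma1_sq = 1, rho1 = 0.5, q = 0.3) {
  stopifnot(is.finite(mu1), is.finite(sigma1_sq), is.finite(rho1), is.finite(q))
  if (mu1 <= 0) stop("mu1 must be positive")
  if (sigma1_sq <= 0) stop("sigma1_sq must be positive")
  if (rho1 <= 0 || rho1 > 1) stop("rho1 must be in (0, 1]")
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  structure(list(mu1 = mu1, sigma1_sq = sigma1_sq, rho1 = rho1, q = q),
            class = "copula_params")
}

#' @export
print.copula_params <- function(x, ...) {
  cat(sprintf("copula_params: mu1=%.4g sigma1_sq=%.4g rho1=%.4g q=%.4g\n",
              x$mu1, x$sigma1_sq, x$rho1, x$q))
  invisible(x)
}

#' Marginal mixture density
#'
#' `q * N(x; mu1, sigma1^2) + (1 - q) * N(x; 0, 1)`: the density of a
#' pseudo-value under the two-component mixture, used as the denominator of the
#' copula emission ratio.
#'
#' @param x numeric vector of pseudo-values.
#' @param params a [copula_params].
#' @param log return log density?
#' @return Numeric vector of (log) densities.
#' @export
marginal_pdf <- function(x, params, log = FALSE) {
  if (any(!is.finite(x))) stop("non-finite pseudo-value")
  l1 <- stats::dnorm(x, params$mu1, sqrt(params$sigma1_sq), log = TRUE) + log(params$q)
  l0 <- stats::dnorm(x, log = TRUE) + log1p(-params$q)
  out <- logsumexp2(l1, l0)
  if (log) out else exp(out)
}

#' Marginal mixture cumulative distribution
#'
#' `q * Phi((x - mu1)/sigma1) + (1 - q) * Phi(x)`; strictly increasing in `x`.
#'
#' @inheritParams marginal_pdf
#' @return Numeric vector of probabilities in (0, 1).
#' @export
marginal_cdf <- function(x, params) {
  if (any(!is.finite(x))) stop("non-finite pseudo-value")
  params$q * stats::pnorm(x, params$mu1, sqrt(params$sigma1_sq)) +
    (1 - params$q) * stats::pnorm(x)
}

#' Invert the marginal mixture CDF
#'
#' Maps scaled ranks `v` to Gaussian-scale pseudo-values `x = F^{-1}(v)` by
#' bracketed bisection on the monotone mixture CDF (bracket
#' `[-10, mu1 + 10*sigma1]`, widened as needed), to an accuracy of
#' `|F(x) - v| <= 1e-9`. Values of `v` outside `(0, 1)` are an error; values
#' supplied exactly at 0 or 1 should be avoided upstream by the `N + 1` rank
#' denominator.
#'
#' Vectorized: duplicate values of `v` are inverted once.
#'
#' @param v numeric vector of values in (0, 1).
#' @param params a [copula_params].
#' @return Numeric vector `x` with `marginal_cdf(x) == v` up to tolerance.
#' @export
invert_cdf <- function(v, params) {
  if (any(!is.finite(v)) || any(v <= 0) || any(v >= 1))
    stop("v must lie strictly inside (0, 1)")
  u <- unique(v)
  lo <- rep(min(-10, params$mu1 - 10 * sqrt(params$sigma1_sq)), length(u))
  hi <- rep(max(10, params$mu1 + 10 * sqrt(params$sigma1_sq)), length(u))
  # widen bracket in the (rare) extreme-tail case
  while (any(bad <- marginal_cdf(lo, params) > u)) lo[bad] <- lo[bad] - 10
  while (any(bad <- marginal_cdf(hi, params) < u)) hi[bad] <- hi[bad] + 10
  for (it in seq_len(100L)) {
    mid <- (lo + hi) / 2
    below <- marginal_cdf(mid, params) < u
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
    if (max(hi - lo) < 1e-13) break
  }
  x <- (lo + hi) / 2
  x[match(v, u)]
}

# log(exp(a) + exp(b)) elementwise, stable
logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  m + log1p(exp(pmin(a, b) - m))
}

# Log-density of an exchangeable multivariate normal: common mean mu, common
# variance sigma_sq, common pairwise correlation rho. `x` is an n x m matrix
# (rows = observations). Reduces to the bivariate Eq-1 form at m = 2 and to a
# product of independent normals at rho = 0.
ldmvn_exch <- function(x, mu, sigma_sq, rho) {
  x <- as.matrix(x)
  m <- ncol(x)
  if (m == 1L) return(stats::dnorm(x[, 1L], mu, sqrt(sigma_sq), log = TRUE))
  rho <- min(rho, 1 - 1e-10)  # guard the rho = 1 degenerate covariance
  d <- x - mu
  s <- rowSums(d)
  ss <- rowSums(d * d)
  a <- 1 + (m - 1) * rho
  quad <- (ss - rho / a * s * s) / (sigma_sq * (1 - rho))
  ldet <- m * log(sigma_sq) + (m - 1) * log1p(-rho) + log(a)
  -0.5 * (m * log(2 * pi) + ldet + quad)
}

#' Copula emission density ratio
#'
#' Evaluates `f_m(F^{-1}(v); mu_h, sigma_h^2, rho_h) / prod_k f_k(F^{-1}(v_k))`:
#' the conditional density of the scaled-rank vector `v` given the mixture
#' component, i.e. the multivariate normal density of the pseudo-values under
#' that component divided by the product of mixture marginal densities. The
#' `rep` component uses `(mu1, sigma1_sq, rho1)`; the `irep` component uses the
#' fixed null `(0, 1, 0)`. Generalizes the two-replicate formula to any number
#' of replicates via an exchangeable-correlation multivariate normal.
#'
#' @param v numeric vector (one position, replicates across entries) or matrix
#'   (positions x replicates) of scaled ranks in (0, 1).
#' @param component `"rep"` or `"irep"`.
#' @param params a [copula_params].
#' @param log return the log ratio? Default `TRUE`; all internal computation is
#'   in log space.
#' @return Numeric vector of one (log) density ratio per position.
#' @export
copula_emission <- function(v, component = c("rep", "irep"), params, log = TRUE) {
  component <- match.arg(component)
  v <- if (is.matrix(v)) v else matrix(v, nrow = 1L)
  if (ncol(v) < 1L) stop("at least one replicate value is required")
  x <- matrix(invert_cdf(as.vector(v), params), nrow = nrow(v))
  lnum <- if (component == "rep") {
    ldmvn_exch(x, params$mu1, params$sigma1_sq, params$rho1)
  } else {
    ldmvn_exch(x, 0, 1, 0)
  }
  ldenom <- rowSums(matrix(marginal_pdf(as.vector(x), params, log = TRUE),
                           nrow = nrow(v)))
  out <- lnum - ldenom
  if (log) out else exp(out)
}
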