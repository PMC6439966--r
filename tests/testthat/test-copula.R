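test_that("marginal mixture density matches its closed form", {
  # q ~ 0 collapses to the standard normal
  p0 <- copula_params(mu1 = 2, q = 1e-12)
  expect_equal(marginal_pdf(0, p0), dnorm(0), tolerance = 1e-9)
  # q ~ 1 with mu1 ~ 0, sigma1 = 1 is again (numerically) standard normal
  p1 <- copula_params(mu1 = 1e-12, sigma1_sq = 1, rho1 = 0.5, q = 1 - 1e-12)
  expect_equal(marginal_pdf(c(-1, 0, 2), p1), dnorm(c(-1, 0, 2)),
               tolerance = 1e-9)
  # symmetry of phi at +-1: 0.5 phi(1-2) + 0.5 phi(1) = phi(1)
  p <- copula_params(mu1 = 2, sigma1_sq = 1, rho1 = 0.5, q = 0.5)
  expect_equal(marginal_pdf(1, p), dnorm(1), tolerance = 1e-12)
  expect_equal(marginal_pdf(1, p), 0.2419707, tolerance = 1e-6)
  expect_error(marginal_pdf(NaN, p), "non-finite")
})

test_that("marginal CDF is a proper, strictly increasing distribution", {
  p <- copula_params(mu1 = 1.5, sigma1_sq = 0.64, rho1 = 0.5, q = 0.3)
  expect_equal(marginal_cdf(-40, p), 0, tolerance = 1e-12)
  expect_equal(marginal_cdf(40, p), 1, tolerance = 1e-12)
  sym <- copula_params(mu1 = 1e-12, q = 0.5)
  expect_equal(marginal_cdf(0, sym), 0.5, tolerance = 1e-9)
  # oracle: adaptive quadrature of the density
  quad <- integrate(function(x) marginal_pdf(x, p), -30, 1.0,
                    rel.tol = 1e-12)$value
  expect_equal(marginal_cdf(1.0, p), quad, tolerance = 1e-8)
  grid <- seq(-5, 8, length.out = 200)
  expect_true(all(diff(marginal_cdf(grid, p)) > 0))
})

test_that("CDF derivative matches the density on x in [-5, 8]", {
  set.seed(31)
  for (r in 1:5) {
    p <- copula_params(runif(1, 0.5, 3), runif(1, 0.5, 2),
                       runif(1, 0.1, 0.9), runif(1, 0.1, 0.9))
    x <- seq(-5, 8, length.out = 100)
    h <- 1e-4
    deriv <- (marginal_cdf(x + h, p) - marginal_cdf(x - h, p)) / (2 * h)
    expect_lt(max(abs(deriv - marginal_pdf(x, p))), 1e-6)
  }
})

test_that("invert_cdf is the inverse of marginal_cdf", {
  p <- copula_params(mu1 = 2, sigma1_sq = 1, rho1 = 0.5, q = 0.5)
  # median of a (numerically) symmetric mixture is 0
  expect_equal(invert_cdf(0.5, copula_params(mu1 = 1e-12, q = 0.37)), 0,
               tolerance = 1e-6)
  expect_equal(invert_cdf(marginal_cdf(1.234, p), p), 1.234, tolerance = 1e-6)
  # independent oracle: stats::uniroot on the same monotone function
  oracle <- uniroot(function(x) marginal_cdf(x, p) - 0.9, c(-10, 12),
                    tol = 1e-12)$root
  expect_equal(invert_cdf(0.9, p), oracle, tolerance = 1e-9)
  v <- seq(0.001, 0.999, length.out = 500)
  expect_lt(max(abs(marginal_cdf(invert_cdf(v, p), p) - v)), 1e-9)
  # monotone: sorting v sorts x identically
  set.seed(4)
  vv <- runif(200)
  expect_equal(order(invert_cdf(vv, p)), order(vv))
  expect_error(invert_cdf(c(0.5, 1), p), "inside")
  expect_error(invert_cdf(0, p), "inside")
})

test_that("copula emission ratios match direct density composition", {
  # null collapse: with q ~ 0 the irep ratio is 1 for any pair
  p0 <- copula_params(mu1 = 2, sigma1_sq = 1, rho1 = 0.5, q = 1e-12)
  for (v in list(c(0.3, 0.7), c(0.95, 0.95), c(0.5, 0.5)))
    expect_equal(copula_emission(v, "irep", p0), 0, tolerance = 1e-6)

  # single replicate, by-hand composition of invert_cdf and marginal_pdf
  p <- copula_params(mu1 = 2, sigma1_sq = 1, rho1 = 0.5, q = 0.5)
  x <- invert_cdf(0.8, p)
  expect_equal(copula_emission(0.8, "rep", p, log = FALSE),
               dnorm(x, 2, 1) / (0.5 * dnorm(x, 2, 1) + 0.5 * dnorm(x)),
               tolerance = 1e-9)

  # two replicates: numerator is the bivariate normal with correlation rho
  ph <- copula_params(mu1 = 2, sigma1_sq = 1, rho1 = 0.8, q = 0.5)
  v <- c(0.95, 0.9)
  x <- invert_cdf(v, ph)
  biv <- function(x, mu, s2, rho) {
    z <- (x - mu) / sqrt(s2)
    exp(-(z[1]^2 - 2 * rho * z[1] * z[2] + z[2]^2) / (2 * (1 - rho^2))) /
      (2 * pi * s2 * sqrt(1 - rho^2))
  }
  denom <- prod(marginal_pdf(x, ph))
  expect_equal(copula_emission(v, "rep", ph, log = FALSE),
               biv(x, 2, 1, 0.8) / denom, tolerance = 1e-8)
  expect_equal(copula_emission(v, "irep", ph, log = FALSE),
               biv(x, 0, 1, 0) / denom, tolerance = 1e-8)
  # monotone likelihood ratio: concordant high pair favours rep
  expect_gt(copula_emission(c(0.95, 0.95), "rep", ph),
            copula_emission(c(0.95, 0.95), "irep", ph))
  expect_error(copula_emission(numeric(0), "rep", ph), "at least one")
})

test_that("rep component converges to irep as (mu1, rho1) -> 0, sigma1 -> 1", {
  p <- copula_params(mu1 = 1e-9, sigma1_sq = 1, rho1 = 1e-9, q = 0.4)
  set.seed(8)
  v <- matrix(runif(40, 0.05, 0.95), 20, 2)
  expect_equal(copula_emission(v, "rep", p), copula_emission(v, "irep", p),
               tolerance = 1e-6)
})

test_that("two-component posterior is in (0,1) and increases with both ranks", {
  post_grid <- function(p, g) {
    outer(g, g, Vectorize(function(a, b) {
      lr <- log(p$q) + copula_emission(c(a, b), "rep", p)
      li <- log1p(-p$q) + copula_emission(c(a, b), "irep", p)
      exp(lr - idrhmm:::logsumexp2(lr, li))
    }))
  }
  g <- seq(0.05, 0.95, by = 0.05)
  # moderate correlation: monotone in each coordinate over the whole grid
  post <- post_grid(copula_params(mu1 = 2, sigma1_sq = 1, rho1 = 0.3, q = 0.3), g)
  expect_true(all(post > 0 & post < 1))
  expect_true(all(apply(post, 1, diff) > 0))  # increasing in second coordinate
  expect_true(all(apply(post, 2, diff) > 0))  # increasing in first coordinate
  # high correlation rewards concordance, so raising one rank against a low
  # partner can lower the posterior; monotonicity then holds along the
  # concordant diagonal and wherever the partner rank is itself high
  ph <- post_grid(copula_params(mu1 = 2, sigma1_sq = 1, rho1 = 0.8, q = 0.3), g)
  expect_true(all(ph > 0 & ph < 1))
  expect_true(all(diff(diag(ph)) > 0))
  expect_true(all(diff(ph[g >= 0.8, ncol(ph)]) > 0))
})
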