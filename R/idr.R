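#' Classic irreproducible discovery rate (no HMM)
#'
#' Fits the two-component Gaussian mixture copula to one condition's replicated
#' scaled ranks, treating positions as exchangeable (no positional dependency),
#' and reports each position's probability of arising from the irreproducible
#' component (local IDR) together with the expected irreproducible fraction
#' among positions ranked at or above it (global IDR). This is the standard
#' reproducibility score used for ChIP-seq peaks, applied per nucleotide, and
#' serves as a baseline for the HMM-based classifier.
#'
#' @param v `L x m` matrix of scaled ranks in (0, 1) (`m >= 2` replicates), or a
#'   `rank_data` object from which one condition's columns are taken.
#' @param condition which condition to use when `v` is a `rank_data`.
#' @param init initial [copula_params]; defaults to the conventional starting
#'   values `mu1 = 1, sigma1_sq = 1, rho1 = 0.5, q = 0.3`.
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @param maxit_inner Nelder-Mead iteration cap per M-step.
#' @return List of class `idr_fit`: `local_idr`, `global_idr`, `params`
#'   (fitted [copula_params]), `trace`, `n_iter`, `converged`.
#' @export
fit_idr <- function(v, condition = "case", init = copula_params(),
                    max_iter = 100L, tol = 1e-4, maxit_inner = 80L) {
  if (inherits(v, "rank_data")) v <- v$v[, condition_cols(v, condition), drop = FALSE]
  v <- as.matrix(v)
  if (ncol(v) < 2L) stop("IDR requires at least 2 replicate columns")
  if (any(v <= 0) || any(v >= 1)) stop("ranks must lie strictly inside (0, 1)")
  obs_ll <- function(theta) {
    terms <- cond_log_terms(v, theta)
    list(ll = sum(logsumexp2(log(theta$q) + terms$rep,
                             log1p(-theta$q) + terms$irep)),
         terms = terms)
  }
  params <- init
  trace <- numeric(0)
  w_rep <- NULL
  for (iter in seq_len(max_iter)) {
    o <- obs_ll(params)
    if (length(trace) && o$ll < trace[length(trace)] - 1e-6)
      stop("IDR log-likelihood decreased at iteration ", iter)
    converged <- length(trace) > 0 && abs(o$ll - trace[length(trace)]) < tol
    trace <- c(trace, o$ll)
    # responsibilities of the reproducible component
    lr <- log(params$q) + o$terms$rep
    li <- log1p(-params$q) + o$terms$irep
    w_rep <- exp(lr - logsumexp2(lr, li))
    if (converged) break
    # M-step: mixing weight and copula parameters maximize the expected
    # complete-data log-likelihood jointly (numerical, monotone-guarded)
    negq <- function(par) {
      th <- try(par_to_theta(par), silent = TRUE)
      if (inherits(th, "try-error")) return(1e300)
      terms <- cond_log_terms(v, th)
      val <- sum(w_rep * (log(th$q) + terms$rep) +
                 (1 - w_rep) * (log1p(-th$q) + terms$irep))
      if (!is.finite(val)) 1e300 else -val
    }
    par0 <- theta_to_par(params)
    q0 <- negq(par0)
    opt <- stats::optim(par0, negq, method = "Nelder-Mead",
                        control = list(maxit = maxit_inner, reltol = 1e-10))
    if (opt$value < q0) params <- par_to_theta(opt$par)
  }
  local_idr <- 1 - w_rep
  ord <- order(local_idr)
  global_idr <- numeric(length(local_idr))
  global_idr[ord] <- cumsum(local_idr[ord]) / seq_along(ord)
  structure(list(local_idr = local_idr, global_idr = global_idr,
                 params = params, trace = trace, n_iter = length(trace),
                 converged = length(trace) < max_iter),
            class = "idr_fit")
}

#' @export
print.idr_fit <- function(x, ...) {
  cat(sprintf("idr_fit: %d EM iterations, logLik %.4f\n", x$n_iter,
              x$trace[length(x$trace)]))
  print(x$params)
  invisible(x)
}

#' Write an IDR result table as TSV
#'
#' @param fit an `idr_fit`.
#' @param V the `rank_data` the fit used (for coordinates).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_idr <- function(fit, V, path) {
  utils::write.table(
    data.frame(transcript = V$transcript, position = V$position,
               local_idr = fit$local_idr, global_idr = fit$global_idr),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
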