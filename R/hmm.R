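#' Latent-class alphabet of the structure HMM
#'
#' Three classes: `loop` (accessible bases, enriched in case samples),
#' `stem_bg` (base-paired bases or background, enriched in control samples for
#' nuclease designs), `unmapped` (no usable signal).
#' @export
HMM_STATES <- c("loop", "stem_bg", "unmapped")

#' Hidden Markov model parameters
#'
#' Bundles the 3x3 row-stochastic transition matrix over
#' `(loop, stem_bg, unmapped)` with the per-condition copula parameters. In
#' single-condition designs `theta_cont` is `NULL` and the control emission
#' factor is dropped; `stem_bg` and `unmapped` are then emission-equivalent and
#' differ only through transitions.
#'
#' @param transition 3x3 non-negative matrix with rows summing to 1.
#' @param theta_case [copula_params] for the case condition.
#' @param theta_cont [copula_params] for the control condition, or `NULL`.
#' @return An object of class `hmm_params`.
#' @export
hmm_params <- function(transition = default_transition(),
                       theta_case = copula_params(),
                       theta_cont = copula_params()) {
  transition <- as.matrix(transition)
  stopifnot(identical(dim(transition), c(3L, 3L)), all(transition >= 0))
  if (any(abs(rowSums(transition) - 1) > 1e-8))
    stop("transition rows must sum to 1")
  transition <- transition / rowSums(transition)
  dimnames(transition) <- list(HMM_STATES, HMM_STATES)
  stopifnot(inherits(theta_case, "copula_params"),
            is.null(theta_cont) || inherits(theta_cont, "copula_params"))
  structure(list(transition = transition, theta_case = theta_case,
                 theta_cont = theta_cont),
            class = "hmm_params")
}

#' Default transition matrix
#'
#' Self-transition 0.9, off-diagonal 0.05: loop and stem segments occur as
#' sequential runs, so states are sticky.
#' @return 3x3 row-stochastic matrix.
#' @export
default_transition <- function() {
  m <- matrix(0.05, 3, 3, dimnames = list(HMM_STATES, HMM_STATES))
  diag(m) <- 0.9
  m
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("hmm_params\n  transition:\n")
  print(round(x$transition, 4))
  cat("  theta_case: "); print(x$theta_case)
  if (is.null(x$theta_cont)) cat("  theta_cont: (single-condition mode)\n")
  else { cat("  theta_cont: "); print(x$theta_cont) }
  invisible(x)
}

# Per-condition rep/irep log emission terms for all positions: list of two
# length-L vectors. v ranks of one condition (L x m matrix).
cond_log_terms <- function(v, theta) {
  x <- matrix(invert_cdf(as.vector(v), theta), nrow = nrow(v))
  ldenom <- rowSums(matrix(marginal_pdf(as.vector(x), theta, log = TRUE),
                           nrow = nrow(v)))
  list(rep  = ldmvn_exch(x, theta$mu1, theta$sigma1_sq, theta$rho1) - ldenom,
       irep = ldmvn_exch(x, 0, 1, 0) - ldenom)
}

# L x 3 matrix of log emission densities for all states.
# loop: case rep * cont irep; stem_bg: case irep * cont rep;
# unmapped: both irep. Single-condition mode drops the control factor.
emission_log_matrix <- function(V, params) {
  case <- cond_log_terms(V$v[, condition_cols(V, "case"), drop = FALSE],
                         params$theta_case)
  if (is.null(params$theta_cont)) {
    E <- cbind(loop = case$rep, stem_bg = case$irep, unmapped = case$irep)
  } else {
    cont <- cond_log_terms(V$v[, condition_cols(V, "cont"), drop = FALSE],
                           params$theta_cont)
    E <- cbind(loop     = case$rep  + cont$irep,
               stem_bg  = case$irep + cont$rep,
               unmapped = case$irep + cont$irep)
  }
  if (any(!is.finite(E))) {
    bad <- which(!is.finite(E), arr.ind = TRUE)[1L, 1L]
    stop("non-finite emission at position ", bad, " (degenerate parameters?)")
  }
  E
}

#' Log emission probability of one position
#'
#' The emission of the rank vector at a single position given a latent state:
#' the product of the per-condition copula density ratios, with the case factor
#' using the reproducible component exactly when the state is `loop`, the
#' control factor using it exactly when the state is `stem_bg`, and both using
#' the irreproducible component for `unmapped`.
#'
#' @param v_i numeric vector of scaled ranks at one position (all samples).
#' @param state one of `"loop"`, `"stem_bg"`, `"unmapped"`.
#' @param params an [hmm_params].
#' @param condition character vector assigning each entry of `v_i` to
#'   `"case"`/`"cont"`.
#' @return Log emission density (finite scalar).
#' @export
emission_log_prob <- function(v_i, state, params, condition) {
  state <- match.arg(state, HMM_STATES)
  V <- list(v = matrix(v_i, nrow = 1L), condition = condition)
  unname(emission_log_matrix(V, params)[1L, state])
}

# log-sum-exp of a vector
lse <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Apply boundary/reference masking to the log-emission matrix. boundaries are
# 0-based chain offsets; offsets >= 1 mask row i of E (only unmapped allowed).
# reference labels mask loop->loop, stem->stem_bg, unmapped->unmapped.
mask_emissions <- function(E, boundaries, reference = NULL) {
  b <- setdiff(boundaries, 0L)
  E[b, c("loop", "stem_bg")] <- -Inf
  if (!is.null(reference)) {
    if (length(reference) != nrow(E))
      stop("reference labels length (", length(reference),
           ") does not match data length (", nrow(E), ")")
    E[reference == "loop", c("stem_bg", "unmapped")] <- -Inf
    E[reference == "stem", c("loop", "unmapped")] <- -Inf
    E[reference == "unmapped", c("loop", "stem_bg")] <- -Inf
  }
  E
}

#' Forward-backward over the three-state structure HMM
#'
#' Log-space forward-backward on the chain `h_0 .. h_L`, where `h_0` carries no
#' emission and every position listed in `boundaries` (transcript starts, ends
#' and junctions; 0-based offsets) is constrained to the `unmapped` state.
#' Reference labels, when given, additionally restrict states at labelled
#' positions (supervised mode).
#'
#' @param V a `rank_data` object (see [rank_normalize()]).
#' @param params an [hmm_params].
#' @param boundaries integer vector of 0-based chain offsets forced to
#'   `unmapped`; defaults to `V$boundaries`.
#' @param reference optional `reference_labels` of length `L` for supervised
#'   masking (labels `loop`/`stem`/`unmapped` restrict the state; `unknown`
#'   leaves it free).
#' @return List with `loglik` (forward), `loglik_backward` (same quantity from
#'   the backward recursion), `posterior` (`L x 3` matrix, rows sum to 1),
#'   `expected_transitions` (3x3 matrix of summed transition posteriors).
#' @export
forward_backward <- function(V, params, boundaries = V$boundaries,
                             reference = NULL) {
  E <- mask_emissions(emission_log_matrix(V, params), boundaries, reference)
  L <- nrow(E)
  logR <- log(params$transition)
  alpha <- matrix(-Inf, L + 1L, 3L)
  alpha[1L, 3L] <- 0  # h_0 = unmapped with probability 1
  for (i in seq_len(L)) {
    ap <- alpha[i, ]
    alpha[i + 1L, ] <- c(lse(ap + logR[, 1L]), lse(ap + logR[, 2L]),
                         lse(ap + logR[, 3L])) + E[i, ]
  }
  loglik <- lse(alpha[L + 1L, ])
  beta <- matrix(-Inf, L + 1L, 3L)
  beta[L + 1L, ] <- 0
  for (i in L:1L) {
    be <- beta[i + 1L, ] + E[i, ]
    beta[i, ] <- c(lse(logR[1L, ] + be), lse(logR[2L, ] + be),
                   lse(logR[3L, ] + be))
  }
  loglik_backward <- beta[1L, 3L]
  if (!is.finite(loglik))
    stop("zero likelihood: some position has no admissible state")
  post <- alpha[-1L, , drop = FALSE] + beta[-1L, , drop = FALSE] - loglik
  post <- exp(post)
  post <- post / rowSums(post)
  colnames(post) <- HMM_STATES
  xi <- matrix(0, 3L, 3L, dimnames = list(HMM_STATES, HMM_STATES))
  for (i in seq_len(L)) {
    m <- outer(alpha[i, ], beta[i + 1L, ] + E[i, ], `+`) + logR - loglik
    xi <- xi + exp(m)
  }
  list(loglik = loglik, loglik_backward = loglik_backward,
       posterior = post, expected_transitions = xi)
}

# Expected complete-data log-likelihood contribution of one condition's copula
# parameters: sum_i w_rep_i log P(v_i | rep, theta) + (1 - w_rep_i) log P(v_i |
# irep, theta). v is the condition's L x m rank matrix.
copula_q_fn <- function(v, w_rep, theta) {
  terms <- cond_log_terms(v, theta)
  sum(w_rep * terms$rep + (1 - w_rep) * terms$irep)
}

# Unconstrained <-> natural parameter transforms for the copula M-step.
theta_to_par <- function(theta) {
  c(log(theta$mu1), log(theta$sigma1_sq),
    stats::qlogis(min(theta$rho1, 1 - 1e-6)), stats::qlogis(theta$q))
}
par_to_theta <- function(par) {
  copula_params(mu1 = exp(par[1L]), sigma1_sq = exp(par[2L]),
                rho1 = stats::plogis(par[3L]), q = stats::plogis(par[4L]))
}

# Numerical M-step for one condition: Nelder-Mead on transformed parameters,
# starting at the current value; the candidate is accepted only if it improves
# the expected complete-data log-likelihood, so each EM iteration is a
# generalized-EM step and the observed likelihood cannot decrease.
optimize_copula <- function(v, w_rep, theta, maxit = 60L) {
  par0 <- theta_to_par(theta)
  negq <- function(par) {
    th <- try(par_to_theta(par), silent = TRUE)
    if (inherits(th, "try-error")) return(1e300)
    val <- copula_q_fn(v, w_rep, th)
    if (!is.finite(val)) 1e300 else -val
  }
  q0 <- negq(par0)
  opt <- stats::optim(par0, negq, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-10))
  if (opt$value >= q0) return(theta)
  fitted <- par_to_theta(opt$par)
  for (nm in c("rho1", "q")) {
    if (fitted[[nm]] < 1e-5 || fitted[[nm]] > 1 - 1e-5)
      warning("copula parameter ", nm, " fitted near its bound (",
              format(fitted[[nm]]), ")")
  }
  fitted
}

#' Fit the structure HMM by expectation-maximization
#'
#' Alternates a forward-backward E-step with an M-step that re-estimates the
#' transition matrix from expected transition counts (closed form) and each
#' condition's copula parameters by numerical maximization of the expected
#' complete-data log-likelihood. When `reference` labels are supplied, the
#' E-step restricts hidden states at labelled positions to the matching class
#' (supervised training). The observed-data log-likelihood is guaranteed
#' non-decreasing; a decrease beyond numerical slack signals an M-step defect
#' and raises an error.
#'
#' @param V a `rank_data` object.
#' @param init initial [hmm_params]; defaults to sticky transitions
#'   (self-transition 0.9) with conventional copula starting values
#'   (`mu1 = 1, sigma1_sq = 1, rho1 = 0.5, q = 0.3` per condition).
#'   Single-condition mode is selected automatically when `V` has no control
#'   samples.
#' @param boundaries 0-based chain offsets forced to `unmapped`.
#' @param reference optional `reference_labels` for supervised training.
#' @param max_iter maximum EM iterations (default 100).
#' @param tol convergence tolerance on the log-likelihood increment (default
#'   1e-4).
#' @param maxit_inner Nelder-Mead iteration cap per copula M-step.
#' @return List of class `hmm_fit`: `params` (fitted [hmm_params]), `trace`
#'   (log-likelihood per iteration), `posterior` (final `L x 3` matrix),
#'   `loglik`, `n_iter`, `converged`.
#' @export
em_fit <- function(V, init = NULL, boundaries = V$boundaries, reference = NULL,
                   max_iter = 100L, tol = 1e-4, maxit_inner = 60L) {
  single <- !any(V$condition == "cont")
  if (is.null(init)) {
    init <- hmm_params(theta_cont = if (single) NULL else copula_params())
  }
  if (single && !is.null(init$theta_cont)) {
    message("no control samples: running in single-condition mode ",
            "(stem_bg and unmapped are emission-equivalent)")
    init$theta_cont <- NULL
  }
  params <- init
  v_case <- V$v[, condition_cols(V, "case"), drop = FALSE]
  v_cont <- if (single) NULL else V$v[, condition_cols(V, "cont"), drop = FALSE]
  trace <- numeric(0)
  fb <- NULL
  for (iter in seq_len(max_iter)) {
    fb <- forward_backward(V, params, boundaries, reference)
    if (length(trace) && fb$loglik < trace[length(trace)] - 1e-6)
      stop("log-likelihood decreased by ",
           format(trace[length(trace)] - fb$loglik), " at iteration ", iter,
           " (M-step defect)")
    converged <- length(trace) > 0 && abs(fb$loglik - trace[length(trace)]) < tol
    trace <- c(trace, fb$loglik)
    if (converged) break
    xi <- fb$expected_transitions
    rs <- rowSums(xi)
    R_new <- params$transition
    ok <- rs > 0
    R_new[ok, ] <- xi[ok, , drop = FALSE] / rs[ok]
    theta_case <- optimize_copula(v_case, fb$posterior[, "loop"],
                                  params$theta_case, maxit_inner)
    theta_cont <- if (single) NULL else
      optimize_copula(v_cont, fb$posterior[, "stem_bg"],
                      params$theta_cont, maxit_inner)
    params <- hmm_params(R_new, theta_case, theta_cont)
  }
  fb <- forward_backward(V, params, boundaries, reference)
  structure(list(params = params, trace = trace, posterior = fb$posterior,
                 loglik = fb$loglik, n_iter = length(trace),
                 converged = length(trace) < max_iter),
            class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("hmm_fit: %d EM iterations, logLik %.4f (%s)\n", x$n_iter,
              x$loglik, if (x$converged) "converged" else "max_iter reached"))
  print(x$params)
  invisible(x)
}

#' Supervised training followed by warm-started refitting
#'
#' Fits the model on a training transcript with its reference structure as a
#' supervision mask, then uses the trained parameters to initialize an
#' unsupervised fit on the test data; posteriors are decoded from the refit.
#' This transfers parameters learned on a well-characterized RNA (e.g. rRNA) to
#' transcripts without a reference.
#'
#' @param train_V,test_V `rank_data` objects for training and test data.
#' @param train_ref `reference_labels` for the training transcript.
#' @param ... passed to both [em_fit()] calls (`max_iter`, `tol`, ...).
#' @return The test-set `hmm_fit`, with the supervised training fit attached as
#'   `$train_fit`.
#' @export
train_then_refit <- function(train_V, train_ref, test_V, ...) {
  train_fit <- em_fit(train_V, reference = train_ref, ...)
  fit <- em_fit(test_V, init = train_fit$params, ...)
  fit$train_fit <- train_fit
  fit
}

#' Posterior class-probability table
#'
#' Assembles per-position posterior probabilities into a data frame in original
#' 1-based coordinates. The loop posterior is reported as the reactivity index.
#' When `full_lengths` gives original transcript lengths, positions removed by
#' trimming are restored with `p_unmapped = 1`.
#'
#' @param fit an `hmm_fit` (or an `L x 3` posterior matrix).
#' @param V the `rank_data` the model was fitted to.
#' @param full_lengths optional named vector of original transcript lengths.
#' @return `data.frame` with columns `transcript`, `position`, `p_loop`,
#'   `p_stem_bg`, `p_unmapped`, `reactivity`.
#' @export
posterior_table <- function(fit, V, full_lengths = NULL) {
  post <- if (inherits(fit, "hmm_fit")) fit$posterior else fit
  df <- data.frame(transcript = V$transcript, position = V$position,
                   p_loop = post[, "loop"], p_stem_bg = post[, "stem_bg"],
                   p_unmapped = post[, "unmapped"])
  if (!is.null(full_lengths)) {
    full <- do.call(rbind, lapply(names(full_lengths), function(tx) {
      data.frame(transcript = tx, position = seq_len(full_lengths[[tx]]),
                 p_loop = 0, p_stem_bg = 0, p_unmapped = 1)
    }))
    key <- paste(df$transcript, df$position)
    idx <- match(paste(full$transcript, full$position), key)
    hit <- !is.na(idx)
    full[hit, c("p_loop", "p_stem_bg", "p_unmapped")] <-
      df[idx[hit], c("p_loop", "p_stem_bg", "p_unmapped")]
    df <- full
  }
  df$reactivity <- df$p_loop
  rownames(df) <- NULL
  df
}

#' Write / read a posterior table as TSV
#'
#' The file carries fitted parameter summaries as `# key=value` comment lines
#' before the header.
#'
#' @param fit an `hmm_fit`.
#' @param V the fitted `rank_data`.
#' @param path output path.
#' @param full_lengths see [posterior_table()].
#' @return `path`, invisibly.
#' @export
write_posterior <- function(fit, V, path, full_lengths = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (l in params_to_lines(fit$params)) writeLines(paste0("# ", l), con)
  writeLines(paste0("# loglik=", format(fit$loglik, digits = 15)), con)
  utils::write.table(posterior_table(fit, V, full_lengths), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_posterior
#' @export
read_posterior <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

params_to_lines <- function(params) {
  ln <- c(paste0("transition=", paste(format(t(params$transition), digits = 15),
                                      collapse = ",")))
  for (cond in c("case", "cont")) {
    th <- params[[paste0("theta_", cond)]]
    if (is.null(th)) next
    ln <- c(ln, vapply(c("mu1", "sigma1_sq", "rho1", "q"), function(p)
      paste0(cond, "_", p, "=", format(th[[p]], digits = 15)), ""))
  }
  ln
}

#' Serialize / deserialize HMM parameters as key=value text
#'
#' @param params an [hmm_params].
#' @param path file path.
#' @return [write_hmm_params()] returns `path` invisibly; [read_hmm_params()]
#'   returns an [hmm_params].
#' @export
write_hmm_params <- function(params, path) {
  writeLines(params_to_lines(params), path)
  invisible(path)
}

#' @rdname write_hmm_params
#' @export
read_hmm_params <- function(path) {
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  tr <- matrix(as.numeric(strsplit(vals[["transition"]], ",")[[1L]]),
               3L, 3L, byrow = TRUE)
  get_theta <- function(cond) {
    keys <- paste0(cond, "_", c("mu1", "sigma1_sq", "rho1", "q"))
    if (!all(keys %in% names(vals))) return(NULL)
    copula_params(as.numeric(vals[[keys[1L]]]), as.numeric(vals[[keys[2L]]]),
                  as.numeric(vals[[keys[3L]]]), as.numeric(vals[[keys[4L]]]))
  }
  hmm_params(tr, get_theta("case"), get_theta("cont"))
}
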