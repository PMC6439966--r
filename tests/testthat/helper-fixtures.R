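# Shared fixtures and independent oracles, built in code at test time.

# Minimal rank_data from a matrix of values in (0,1).
make_rank_data <- function(v, condition, boundaries = c(0L, nrow(v))) {
  v <- as.matrix(v)
  structure(list(v = v, condition = condition,
                 transcript = rep("tx", nrow(v)),
                 position = seq_len(nrow(v)), boundaries = boundaries),
            class = "rank_data")
}

# Random valid model parameters for property tests.
random_hmm_params <- function(seed, single = FALSE) {
  set.seed(seed)
  R <- matrix(rgamma(9, 1), 3, 3)
  R <- R / rowSums(R)
  rtheta <- function() copula_params(mu1 = runif(1, 0.5, 3),
                                     sigma1_sq = runif(1, 0.5, 2),
                                     rho1 = runif(1, 0.2, 0.95),
                                     q = runif(1, 0.1, 0.6))
  hmm_params(R, rtheta(), if (single) NULL else rtheta())
}

# Random rank data (iid uniforms, no model structure) for oracle checks.
random_rank_data <- function(seed, L, m_case = 2L, m_cont = 2L) {
  set.seed(seed + 1000L)
  K <- m_case + m_cont
  make_rank_data(matrix(runif(L * K, 0.02, 0.98), L, K),
                 rep(c("case", "cont"), c(m_case, m_cont)))
}

# Exhaustive-enumeration oracle for the constrained HMM log-likelihood:
# sums emission x transition products over every admissible path h_1..h_L
# (h_0 fixed to unmapped), independently of the forward-backward recursion.
enum_loglik <- function(V, params, boundaries = V$boundaries,
                        reference = NULL) {
  L <- nrow(V$v)
  E <- sapply(HMM_STATES, function(s)
    sapply(seq_len(L), function(i)
      emission_log_prob(V$v[i, ], s, params, V$condition)))
  E <- matrix(E, nrow = L)
  allowed <- matrix(TRUE, L, 3)
  allowed[setdiff(boundaries, 0L), 1:2] <- FALSE
  if (!is.null(reference)) {
    allowed[reference == "loop", 2:3] <- FALSE
    allowed[reference == "stem", c(1, 3)] <- FALSE
    allowed[reference == "unmapped", 1:2] <- FALSE
  }
  logR <- log(params$transition)
  paths <- as.matrix(expand.grid(rep(list(1:3), L)))
  ll <- apply(paths, 1, function(h) {
    if (!all(allowed[cbind(seq_len(L), h)])) return(-Inf)
    prev <- c(3L, h[-L])
    sum(logR[cbind(prev, h)]) + sum(E[cbind(seq_len(L), h)])
  })
  m <- max(ll)
  m + log(sum(exp(ll - m)))
}

# Reference labels object from a character vector.
as_ref <- function(x) structure(x, class = "reference_labels")
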