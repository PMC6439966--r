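test_that("hmm_params validates the transition matrix", {
  expect_error(hmm_params(matrix(1, 3, 3)), "sum to 1")
  p <- hmm_params()
  expect_equal(rowSums(p$transition), setNames(rep(1, 3), HMM_STATES))
  expect_equal(diag(default_transition()), setNames(rep(0.9, 3), HMM_STATES))
})

test_that("emission maps case-rep to loop and cont-rep to stem_bg", {
  th <- copula_params(mu1 = 2, sigma1_sq = 1, rho1 = 0.8, q = 0.3)
  params <- hmm_params(theta_case = th, theta_cont = th)
  cond <- c("case", "case", "cont", "cont")
  v <- c(0.95, 0.95, 0.20, 0.25)  # concordant high case, low control
  e <- sapply(HMM_STATES, function(s) emission_log_prob(v, s, params, cond))
  expect_gt(e["loop"], e["stem_bg"])
  expect_gt(e["loop"], e["unmapped"])
  # oracle: direct composition from the copula emission ratios
  expect_equal(unname(e["loop"]),
               copula_emission(v[1:2], "rep", th) +
                 copula_emission(v[3:4], "irep", th))
  expect_equal(unname(e["stem_bg"]),
               copula_emission(v[1:2], "irep", th) +
                 copula_emission(v[3:4], "rep", th))
  expect_equal(unname(e["unmapped"]),
               copula_emission(v[1:2], "irep", th) +
                 copula_emission(v[3:4], "irep", th))
  # swapping the case and control blocks swaps loop and stem_bg exactly
  vs <- c(v[3:4], v[1:2])
  expect_equal(emission_log_prob(vs, "loop", params, cond), unname(e["stem_bg"]))
  expect_equal(emission_log_prob(vs, "stem_bg", params, cond), unname(e["loop"]))
  expect_equal(emission_log_prob(vs, "unmapped", params, cond),
               unname(e["unmapped"]))
})

test_that("single-condition mode makes stem_bg and unmapped emission-equivalent", {
  params <- hmm_params(theta_case = copula_params(2, 1, 0.8, 0.3),
                       theta_cont = NULL)
  v <- c(0.9, 0.85)
  cond <- c("case", "case")
  expect_equal(emission_log_prob(v, "stem_bg", params, cond),
               emission_log_prob(v, "unmapped", params, cond))
  # with q ~ 0 the irep ratio degenerates to 1, so those states emit log 0
  p0 <- hmm_params(theta_case = copula_params(2, 1, 0.8, 1e-12),
                   theta_cont = NULL)
  expect_equal(emission_log_prob(v, "unmapped", p0, cond), 0, tolerance = 1e-6)
})

test_that("a single free position has the closed-form posterior", {
  params <- random_hmm_params(1)
  V <- random_rank_data(1, L = 2)
  # boundaries {0, 2}: only position 1 is free
  fb <- forward_backward(V, params, boundaries = c(0L, 2L))
  e1 <- sapply(HMM_STATES, function(s)
    emission_log_prob(V$v[1, ], s, params, V$condition))
  R <- params$transition
  w <- R["unmapped", ] * exp(e1) * R[, "unmapped"]
  expect_equal(unname(fb$posterior[1, ]), unname(w / sum(w)), tolerance = 1e-10)
  expect_equal(unname(fb$posterior[2, ]), c(0, 0, 1))
})

test_that("forward-backward equals exhaustive path enumeration (20 seeds, L <= 8)", {
  for (seed in 1:20) {
    set.seed(seed)
    L <- sample(2:8, 1)
    params <- random_hmm_params(seed, single = seed %% 4 == 0)
    V <- random_rank_data(seed, L,
                          m_cont = if (seed %% 4 == 0) 0L else 2L)
    fb <- forward_backward(V, params)
    expect_lt(abs(fb$loglik - enum_loglik(V, params)), 1e-8)
    expect_lt(abs(fb$loglik - fb$loglik_backward), 1e-8)
  }
})

test_that("enumeration equivalence holds under supervised masking", {
  for (seed in 1:5) {
    set.seed(seed + 77)
    L <- 6L
    params <- random_hmm_params(seed + 77)
    V <- random_rank_data(seed + 77, L)
    ref <- as_ref(sample(c("loop", "stem", "unmapped", "unknown"), L,
                         replace = TRUE))
    ref[L] <- "unmapped"  # keep consistent with the boundary constraint
    fb <- forward_backward(V, params, reference = ref)
    expect_lt(abs(fb$loglik - enum_loglik(V, params, reference = ref)), 1e-8)
  }
})

test_that("posteriors normalize and boundaries are exactly unmapped", {
  sim <- simulate_counts(sim_config(L = 500, seed = 3))
  V <- rank_normalize(sim$counts)
  fb <- forward_backward(V, hmm_params())
  expect_lt(max(abs(rowSums(fb$posterior) - 1)), 1e-10)
  expect_identical(unname(fb$posterior[500, "unmapped"]), 1)
  expect_equal(sum(fb$expected_transitions), 500)  # one transition per step
})

test_that("expected transitions match posterior pair sums on a tiny instance", {
  # oracle: path enumeration of P(h_i = a, h_{i+1} = b | V)
  set.seed(12)
  params <- random_hmm_params(12)
  V <- random_rank_data(12, 4)
  fb <- forward_backward(V, params)
  E <- sapply(HMM_STATES, function(s)
    sapply(1:4, function(i) emission_log_prob(V$v[i, ], s, params, V$condition)))
  logR <- log(params$transition)
  paths <- as.matrix(expand.grid(rep(list(1:3), 4)))
  lp <- apply(paths, 1, function(h) {
    if (h[4] != 3L) return(-Inf)
    prev <- c(3L, h[-4])
    sum(logR[cbind(prev, h)]) + sum(E[cbind(1:4, h)])
  })
  w <- exp(lp - max(lp)); w <- w / sum(w)
  xi <- matrix(0, 3, 3)
  full <- cbind(3L, paths)  # prepend h_0 = unmapped
  for (i in 1:4) for (a in 1:3) for (b in 1:3)
    xi[a, b] <- xi[a, b] + sum(w[full[, i] == a & full[, i + 1] == b])
  expect_equal(unname(fb$expected_transitions), xi, tolerance = 1e-8)
})

test_that("parameter files round-trip", {
  params <- random_hmm_params(5)
  f <- withr::local_tempfile(fileext = ".txt")
  write_hmm_params(params, f)
  back <- read_hmm_params(f)
  expect_equal(back$transition, params$transition, tolerance = 1e-12)
  expect_equal(back$theta_case, params$theta_case, tolerance = 1e-12)
  expect_equal(back$theta_cont, params$theta_cont, tolerance = 1e-12)
  single <- random_hmm_params(6, single = TRUE)
  write_hmm_params(single, f)
  expect_null(read_hmm_params(f)$theta_cont)
})
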