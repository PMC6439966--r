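#' Simulation configuration
#'
#' Describes one synthetic probing experiment drawn from the model's own
#' generative process: a hidden loop/stem/unmapped path sampled from the
#' transition matrix (ends forced to `unmapped`), correlated Gaussian signals
#' emitted from the reproducible component at signal-bearing states, and a
#' monotone map from Gaussians to integer counts.
#'
#' @param L transcript length (positions with observations).
#' @param m replicates per condition.
#' @param conditions 1 (case only) or 2 (case + control).
#' @param theta_true an [hmm_params] holding the true transition matrix and
#'   per-condition copula parameters.
#' @param count_scale positive scale of the count map
#'   `round(count_scale * exp(x / 2))`.
#' @param control_signal `"stem_bg"` if control replicates draw reproducible
#'   signal at stem positions (nuclease V1-like), `"none"` if the control is
#'   structure-blind background (untreated-control designs).
#' @param seed integer; fully determines the output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(L = 500L, m = 2L, conditions = 2L,
                       theta_true = hmm_params(
                         default_transition(),
                         copula_params(mu1 = 2, sigma1_sq = 1, rho1 = 0.8, q = 1/3),
                         copula_params(mu1 = 2, sigma1_sq = 1, rho1 = 0.8, q = 1/3)),
                       count_scale = 100, control_signal = c("stem_bg", "none"),
                       seed = 1L) {
  control_signal <- match.arg(control_signal)
  stopifnot(L >= 3, m >= 1, conditions %in% 1:2, count_scale > 0,
            inherits(theta_true, "hmm_params"))
  structure(list(L = as.integer(L), m = as.integer(m),
                 conditions = as.integer(conditions), theta_true = theta_true,
                 count_scale = count_scale, control_signal = control_signal,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Preset simulation designs
#'
#' * `icshape_like`: two conditions; case replicates carry reproducible signal
#'   at loop positions, the untreated control is structure-blind background.
#' * `pars_like`: two conditions; case (S1 nuclease) signal at loops, control
#'   (V1 nuclease) signal at stems.
#' * `single_condition`: case replicates only.
#'
#' @param name preset name.
#' @param seed integer seed.
#' @param ... overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
make_preset <- function(name, seed = 1L, ...) {
  presets <- c("icshape_like", "pars_like", "single_condition")
  if (!is.character(name) || length(name) != 1L || !name %in% presets)
    stop("unknown preset '", name, "'; valid presets: ",
         paste(presets, collapse = ", "))
  switch(name,
    icshape_like = sim_config(conditions = 2L, control_signal = "none",
                              seed = seed, ...),
    pars_like = sim_config(conditions = 2L, control_signal = "stem_bg",
                           seed = seed, ...),
    single_condition = sim_config(conditions = 1L, seed = seed, ...))
}

# Draw n rows of an m-variate exchangeable Gaussian (common mu, sigma_sq, rho).
rmvn_exch <- function(n, m, mu, sigma_sq, rho) {
  shared <- stats::rnorm(n)
  own <- matrix(stats::rnorm(n * m), n, m)
  mu + sqrt(sigma_sq) * (sqrt(rho) * shared + sqrt(1 - rho) * own)
}

#' Simulate a probing experiment from the generative model
#'
#' Samples the latent path `h_0..h_L` from the transition matrix with the
#' boundary states forced to `unmapped`, emits per-condition replicate
#' Gaussians (reproducible component at the condition's signal state,
#' independent standard normals elsewhere), and converts them to integer counts
#' with the strictly monotone map `round(count_scale * exp(x / 2))`, whose
#' rounding deliberately induces ties at low counts.
#'
#' @param config a [sim_config].
#' @return List with `counts` (a [count_table]), `path` (character vector
#'   `h_0..h_L` of length `L + 1`), `labels` (the `L` emitting-position states,
#'   i.e. `path[-1]`), and `config`.
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$L
  R <- config$theta_true$transition
  h <- integer(L + 1L)
  h[1L] <- 3L  # h_0 = unmapped
  for (i in seq_len(L)) h[i + 1L] <- sample.int(3L, 1L, prob = R[h[i], ])
  h[L + 1L] <- 3L  # h_L = unmapped
  signal_state <- c(
    case = 1L,
    cont = if (config$control_signal == "stem_bg") 2L else NA_integer_)
  conds <- c("case", "cont")[seq_len(config$conditions)]
  blocks <- lapply(conds, function(cond) {
    th <- if (cond == "case") config$theta_true$theta_case
          else config$theta_true$theta_cont
    x <- matrix(stats::rnorm(L * config$m), L, config$m)
    s <- signal_state[[cond]]
    if (!is.na(s)) {
      rep_pos <- which(h[-1L] == s)
      if (length(rep_pos))
        x[rep_pos, ] <- rmvn_exch(length(rep_pos), config$m,
                                  th$mu1, th$sigma1_sq, th$rho1)
    }
    counts <- round(config$count_scale * exp(x / 2))
    colnames(counts) <- paste0(cond, "_", seq_len(config$m))
    counts
  })
  ct <- count_table(do.call(cbind, blocks),
                    rep(conds, each = config$m), transcript = "sim")
  path <- HMM_STATES[h]
  list(counts = ct, path = path, labels = path[-1L], config = config)
}

#' Simulate replicate rank pairs from the plain two-component mixture
#'
#' Positions are independent: with probability `q` a position draws its
#' replicate pseudo-values from the reproducible component, otherwise from
#' independent standard normals; columns are then rank-normalized. Used to
#' exercise the positional-independence IDR baseline.
#'
#' @param n number of positions.
#' @param params true [copula_params].
#' @param m replicates.
#' @param seed integer seed.
#' @return List with `v` (`n x m` rank matrix in (0,1)) and `reproducible`
#'   (logical truth per position).
#' @export
simulate_idr_pairs <- function(n, params = copula_params(mu1 = 2, sigma1_sq = 1,
                                                         rho1 = 0.8, q = 0.5),
                               m = 2L, seed = 1L) {
  set.seed(seed)
  rep_i <- stats::runif(n) < params$q
  x <- matrix(stats::rnorm(n * m), n, m)
  if (any(rep_i))
    x[rep_i, ] <- rmvn_exch(sum(rep_i), m, params$mu1, params$sigma1_sq,
                            params$rho1)
  v <- apply(x, 2L, function(col) rank(col) / (n + 1))
  list(v = v, reproducible = rep_i)
}
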