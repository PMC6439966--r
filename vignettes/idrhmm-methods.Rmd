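---
title: "Reproducibility-aware stem/loop classification: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reproducibility-aware stem/loop classification: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idrhmm)
```

## The problem

Structure-probing experiments (icSHAPE, PARS, and related protocols) read out
RNA secondary structure as per-nucleotide counts of reads truncated one base
downstream of a chemical or enzymatic probing event. Accessible (loop) bases
are enriched in the probed ("case") samples; for nuclease designs such as PARS
the control (V1) enzyme instead cuts base-paired (stem) bases. The raw counts
are noisy: random fragmentation and endogenous modification create false
signals that can be as large as true ones. The one property false signals lack
is *reproducibility across replicates*, and that is the signal this package
models.

`idrhmm` classifies each nucleotide into one of three latent classes —
`loop`, `stem_bg` (base-paired or background) and `unmapped` (no usable
signal) — by combining two ideas:

1. the **irreproducible discovery rate (IDR)**: a two-component Gaussian
   mixture copula over the replicate ranks of each position, separating
   reproducible, high-rank signal from irreproducible noise;
2. a **hidden Markov model (HMM)** along the transcript, because loops and
   stems occur as sequential runs of neighbouring bases, and because case and
   control conditions must be contrasted at every position.

## Data model

Counts are never modelled directly. Within each sample, the counts at the
`L` positions are replaced by their ascending midranks scaled by
`1 / (N + 1)`, giving values `v` strictly inside (0, 1) (function
`rank_normalize()`). Using `N + 1` rather than `N` keeps the later Gaussian
quantile transform finite; midranks make tied counts deterministic. Ranks are
computed across all concatenated transcripts by default, since the mixture is
fitted jointly; per-transcript ranking is available (`global = FALSE`), as is
seeded random tie-breaking (`ties = "random"`) for rank-plot style analyses.

For one condition with `m` replicates, the mixture copula assumes latent
pseudo-values `x` distributed as

* reproducible (`rep`, probability `q`): exchangeable multivariate normal with
  common mean `mu1 > 0`, variance `sigma1^2`, pairwise correlation
  `0 < rho1 <= 1`;
* irreproducible (`irep`, probability `1 - q`): independent standard normals
  (`mu0 = 0`, `sigma0^2 = 1`, `rho0 = 0`, fixed for identifiability).

The observed rank `v` is the value of the marginal mixture CDF at `x`, so
pseudo-values are recovered as `x = F^{-1}(v)` (`invert_cdf()`, bracketed
bisection to `|F(x) - v| <= 1e-9`). The density of a rank vector given its
component is the multivariate normal density at the pseudo-values divided by
the product of marginal mixture densities (`copula_emission()`); all of this
is computed in log space. The published two-replicate formulation is the
`m = 2` special case of the exchangeable form used here, which admits any
number of replicates.

## The HMM

A latent state `h_i` in `{loop, stem_bg, unmapped}` is attached to every
position, plus boundary states `h_0` and `h_L` that are forced to `unmapped`
(read mapping is unreliable at transcript ends); when transcripts are
concatenated, every junction is forced likewise. The emission at position `i`
factorizes over conditions:

* the **case** factor uses the `rep` component exactly when `h_i = loop`;
* the **control** factor uses `rep` exactly when `h_i = stem_bg`;
* `unmapped` uses `irep` in both factors.

In single-condition designs the control factor is dropped, which makes
`stem_bg` and `unmapped` emission-equivalent; they remain distinct only
through the transition structure, and the package says so loudly when it
happens. Transitions form a full 3x3 row-stochastic matrix initialized sticky
(self-transition 0.9) because structural elements are sequential runs.

Inference is exact forward–backward in log space (`forward_backward()`); the
output is the per-position posterior over the three classes, and the **loop
posterior is the reactivity index**. Decoding is posterior rather than
Viterbi, because a probability per base — not a single best path — is what
downstream structure prediction consumes.

## Fitting

`em_fit()` alternates:

* **E-step**: forward–backward, optionally with hidden states masked to match
  reference labels (supervised training). Masking is implemented as `-Inf`
  log-emissions for disallowed states, keeping the machinery uniform.
* **M-step**: transition rows are the normalized expected transition counts
  (closed form). Each condition's copula parameters maximize the expected
  complete-data log-likelihood numerically — Nelder–Mead on
  `(log mu1, log sigma1^2, logit rho1, logit q)` — because the pseudo-values
  themselves depend on the parameters, so no closed form exists. The
  pseudo-values are recomputed inside every objective evaluation; the
  candidate is accepted only if it improves the objective. Each iteration is
  therefore an exact generalized-EM step and the observed-data log-likelihood
  is non-decreasing by construction; the fitter treats any decrease beyond
  1e-6 as an internal error rather than tolerating it.

Defaults: `tol = 1e-4` on the log-likelihood increment, `max_iter = 100`, 60
Nelder–Mead iterations per inner step. The fit is deterministic — no random
initialization — so repeated runs are byte-identical. Parameters hitting the
`rho1`/`q` bounds (1e-6 from the edge) produce a warning; this is expected
for, e.g., the control condition of an icSHAPE-like design, where the
untreated control carries no structure signal and `q_cont` has nothing to fit.

`train_then_refit()` implements the transfer workflow: supervised fit on a
reference-annotated transcript, then an unsupervised refit on each test
transcript starting from the trained parameters.

The classic positional IDR (`fit_idr()`) is the same mixture without the
chain: positions are exchangeable, `q` doubles as the mixing weight, and the
per-position irreproducibility posterior is the local IDR (with the usual
running-mean global IDR). Note one behaviour documented by the tests: on pure
noise the mixture is unidentifiable in `q` — the fitted `rep` component
collapses onto the null (`mu1 -> 0`, `rho1 -> 0`) rather than `q` going to
zero. No position is confidently reproducible in that case, which is the
operationally relevant guarantee.

## Synthetic data

`simulate_counts()` draws from the model's own generative process: a hidden
path from the transition matrix (ends forced `unmapped`), exchangeable
Gaussian replicate signals from the `rep` component at each condition's
signal-bearing state, independent standard normals elsewhere, and the
strictly monotone count map `round(count_scale * exp(x / 2))` — exponential to
mimic heavy-tailed sequencing coverage, with rounding-induced ties at low
counts deliberately exercising the midrank policy. The reproducible fraction
is therefore encoded by state occupancy: with the default sticky-uniform
transition matrix the stationary distribution is 1/3 per class.

Three presets mirror common designs: `pars_like` (case signal at loops,
control signal at stems), `icshape_like` (case signal at loops,
structure-blind control), `single_condition` (case only). Defaults — `L = 500`
positions, 2 replicates per condition, `mu1 = 2`, `sigma1^2 = 1`,
`rho1 = 0.8`, self-transition 0.9, `count_scale = 100` — are one fixed choice
of a realistic desk-scale experiment: an rRNA-fragment-sized transcript with
moderate coverage and the strong replicate agreement typical of published
probing datasets.

What the simulator does **not** emulate: transcript-abundance variation, PCR
duplication, sequence-dependent probing bias, alignment artifacts. Passing
tests therefore demonstrate correctness of the estimator under its own model
assumptions — parameter recovery, classification of the true hidden path,
ranking behaviour — not performance on any real library.

## Numerical choices

* CDF inversion: vectorized bisection on unique rank values, bracket
  `[-10, mu1 + 10 sigma1]` (auto-widened), terminating below an interval width
  of 1e-13.
* All densities and emissions in log space; `rho1` is capped at `1 - 1e-10`
  inside the multivariate density to keep the covariance non-singular (the
  simulator still supports exact `rho1 = 1`).
* Ranks at exactly 0 or 1 are rejected rather than clamped; the `N + 1`
  denominator means they cannot arise from `rank_normalize()`.
* Ties: midranks everywhere in the model; random tie-breaking is opt-in and
  seed-controlled.
* Degenerate all-constant count columns are permitted (every rank 0.5) but
  reported.

## Evaluation

`score_count()` (mean raw case count) and `score_ratio()` (count over
pass-through coverage) are the two naive baselines. "Reads passing through a
position" is computed as the within-transcript suffix sum of truncation
counts — a read truncated at `j >= i` passed through `i`; if coverage tracks
from an aligner are available they could replace this convention, but that
input is out of scope. `roc_auc()` is an exact Mann–Whitney AUC with midrank
tie handling; unknown/unmapped labels and missing scores are excluded, not
imputed.

## Known limitations

* Emissions ignore base identity (A/C/G/U), which matters for
  chemistry-specific biases such as DMS.
* High replicate correlation makes the two-component posterior non-monotone
  in a single coordinate (concordance is rewarded), so single-replicate
  intuition does not transfer; this is a property of the model, not a defect.
* The copula M-step is numerical; with very short transcripts (tens of bases)
  the expected-likelihood surface is flat and parameters may drift to bounds.
* Supervised training constrains the E-step only; it cannot repair reference
  labels that disagree with the boundary rule (the last base of a transcript
  is always `unmapped`).

## Problem sizes used in the test suite

Unit and acceptance tests simulate transcripts of 150–2000 nt (5 seeds for
recovery and classification checks, 20 seeds for the exhaustive-enumeration
oracle at `L <= 8`), chosen as the smallest sizes at which the statistical
checks are stable.
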