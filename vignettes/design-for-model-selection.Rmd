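---
title: "Designing experiments that discriminate between models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing experiments that discriminate between models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A biochemical network can usually be formalized by several competing ODE
models that all describe the available time-series data to an acceptable
degree. Bayesian model selection compares such models by the Bayes
factor, the ratio of their marginal likelihoods
$B_{12} = p(y^D \mid M_1) / p(y^D \mid M_2)$, with $|\log_{10} B| \ge 2$
(a 100:1 ratio) conventionally decisive. When the data at hand leave the
Bayes factors indecisive, the question becomes *which new experiment
would most effectively separate the models*. This package ranks
candidate experiments — which observable to measure, at which time
point, under which stimulus condition, singly or jointly — by the
divergence between the models' posterior predictive distributions
(PPDs).

The reasoning: a new observation can only shift the Bayes factor where
the competing models predict *different* distributions for it. Joint
candidates matter because models can imply different correlations
between two predictions whose marginal distributions overlap almost
completely; measuring both then discriminates where measuring either
alone would not.

## The procedure

1. **Posterior inference per model.** `fit_posterior()` computes the
   posterior over $\theta = \{p, r, x_0\}$ (kinetic parameters,
   observation parameters, initial conditions), plus the noise sd
   $\sigma$ when it is inferred. Linear basis-function models
   $y(t) = \sum_i \theta_i B_i(t) + \varepsilon$ with known $\sigma$ and
   a $N(0, \xi^2)$ coefficient prior are conjugate: posterior and
   marginal likelihood are exact, which is what makes the validation
   studies below affordable. All other models are sampled by population
   MCMC on the power-posterior ladder $T_n = (n/N_T)^4$,
   $n = 0 \dots N_T$ (default $N_T = 40$), with one adjacent-pair
   exchange attempt per sweep. The same ladder yields the marginal
   likelihood by thermodynamic integration,
   $\log Z = \int_0^1 E_T[\log p(y^D\mid\theta)] \, dT$, evaluated by the
   trapezoidal rule over the ladder.
2. **Posterior predictive sampling.** `sample_ppd()` /
   `predict()` simulate every candidate observation for each posterior
   draw and add measurement noise — future observations are noisy, so
   noise is on by default; when $\sigma$ was inferred, each draw uses its
   own $\sigma$, propagating the full uncertainty.
3. **Divergence estimation.** `knn_jsd()` estimates the Jensen–Shannon
   divergence (JSD) between two models' predictive samples — the
   equal-weight average Kullback–Leibler divergence of each PPD to their
   mixture, in bits, bounded by 1 — directly from k-nearest-neighbour
   distances (default $k = 10$), with exact neighbour search by a k-d
   tree. No density is ever fitted; the estimator adapts to the local
   sampling density and needs only the two $N \times d$ sample matrices.
4. **Ranking and validation.** `compute_design_matrix()` fills the
   symmetric matrix of JSD values over all pairs of single measurements
   (`rank_candidates()` aggregates across model pairs, by worst case by
   default; `augment_design()` grows a candidate greedily). The
   validation yardstick is `expected_bf_update()`: the Monte-Carlo
   expectation of the change in $\log_{10} B$ toward the true model when
   the candidate is actually performed, with new data drawn from the
   true model's PPD.

## Tunable parameters

* `k` (neighbour rank, default 10): the density estimate uses the
  distance to the k-th neighbour. Small k is noisy; large k
  oversmooths. `jsd_k_sweep()` reports the estimate across
  $k \in \{1, 5, 10, 20, 50\}$; at the sample sizes used here the
  default sits on the stable plateau.
* `n_ppd` (predictive sample size, default 5000 for analytic fits): the
  estimator needs $N \gg 2^d$; the candidate dimension is capped at 3
  by default (`augment_design(max_d = )`) because kNN density estimates
  degrade as $d$ grows.
* `n_temps` ($N_T$, default 40): ladder resolution. The quartic
  schedule concentrates temperatures near the prior end where the
  thermodynamic integrand changes fastest; the trapezoid bias shrinks
  rapidly with $N_T$ (the test suite demonstrates the coarse-ladder
  bias at $N_T \in \{2, 8\}$).
* Priors: kinetic rate constants get Gamma(shape 1, scale 3) — mean 3,
  "relatively non-informative" while avoiding the Lindley-paradox
  regime of arbitrarily vague priors; the shape–rate convention is
  available via `prior_gamma(rate = )`. An inferred $\sigma$ gets a
  broad half-normal (scale 1) by default.
* `scale` in `knn_jsd()` (default off): per-column robust rescaling
  before the neighbour search. Raw Euclidean distances are the default;
  the switch exists because a high-variance coordinate otherwise
  dominates the metric for mixed-scale candidates. The JSD itself is
  invariant under per-coordinate rescaling; only the estimator is
  affected.

## The synthetic benchmarks

Two benchmark families double as the validation studies; both generate
all data in code.

**The regression quartet** (`linear_quartet()`): nested models
$\theta_1 t$, $+\,\theta_2 t^2$, $+\,\theta_3 \sin(15t)/3$,
$+\,\theta_4 \sin(2t)\,t$, with the third as data-generating truth.
`run_linear_study()` generalizes it: random true/competitor pairs drawn
from a registry of monomials and modulated sinusoids, noisy data
($D = 10$ points, $\sigma = 0.2$, coefficients from the $N(0,1)$ prior)
in a window redrawn until the initial Bayes factor is indecisive
($|\log_{10} B| < 1$ — model selection must fail *a priori* for design
to be interesting), candidates on a grid extending two window-widths
beyond the data on both sides. For every candidate the study computes
both the kNN-JSD between the two models' PPDs and the expected
Bayes-factor update over 100 predictive replicates, then the Spearman correlation between
the two rankings. Pairs whose maximum candidate JSD stays below 0.05 —
the estimator's documented tolerance band — are skipped as predictively
indistinguishable: for them both ranking axes are pure Monte-Carlo
noise and all true values are tied at zero, the same degeneracy as an
identical competitor. `scripts/acceptance.R` reruns this study from
scratch.

**The feedback-motif quartet** (`motif_quartet()`): a mass-action
phosphorylation cascade (stimulus $u$ drives B phosphorylation, Bp
phosphorylates C, Bp and Cp bind into the complex BpCp, BpCp
phosphorylates D, first-order dephosphorylations) with four negative
feedback variants differing in origin and point of action, implemented
as $1/(1 + k_f X)$ multipliers: Dp on the input step (the truth), Dp on
complex formation, BpCp on the input, Cp on the input. The equations
are this package's own reconstruction of this motif family. The default
inference design measures Bp in three replicates and Dp in two at
$t = 0, 2, 5, 10, 20, 40, 60, 100$ under $u = 1$, with Gaussian noise
of sd 0.03 and $\sigma$ inferred; the true rate constants were chosen so that Bp shows a
visible overshoot above the noise level (the signature transient of
negative feedback). Because the reconstruction is not the original
equation set, the quartet's *qualitative* design conclusions
(which steady-state combinations separate which feedback variants) are
properties of this reconstruction, and the study functions report them
rather than assume them.

What passing these studies shows — and what it does not: the generator
produces i.i.d. Gaussian noise, a known truth inside the candidate set,
and low-dimensional, well-specified models. Real data bring
misspecified error models, unidentified scaling/offset parameters, and
model sets that exclude the truth; the JSD ranking is still computable
there, but the monotone link to Bayes-factor updates is only
demonstrated under the benchmark conditions.

## Numerical choices

* **ODE integration**: `deSolve::ode` (lsoda) with absolute tolerance
  $10^{-8}$ and relative tolerance $10^{-9}$; the motif right-hand
  sides are compiled C. A steady-state request integrates to ten times
  the largest measured time (at least the model horizon), accepts when
  the state drift over the last 5% of the horizon falls below
  $10^{-8}$ relative to the state magnitude — with an
  absolute-tolerance floor so that states decaying to zero, where the
  integrator's own error dominates, still converge — and doubles the
  horizon up to three times before failing.
* **Sampler details**: positivity-constrained parameters are sampled on
  the log scale with the Jacobian correction (rate constants span
  decades under the gamma prior). The Gaussian proposal is initialized
  from a Hessian approximation built from a finite-difference Jacobian
  of the model predictions, falling back to the prior covariance when
  that matrix is not positive definite; per-temperature proposal scales
  adapt toward 23% acceptance during burn-in only, so the retained
  chains are Markovian. Thermodynamic-integration standard errors scale
  each temperature's variance by an autocorrelation-corrected effective
  sample size.
* **Estimator degeneracies**: the JSD estimator is undefined at zero
  neighbour distances (at least $k$ replicated predictions), so
  distances are floored at $10^{-12}$ times the pooled per-column scale
  and the floored count is reported. Neighbour ties need no tie-break:
  only the k-th distance value enters the formula.
* **Estimator bias**: at fixed $k$ the estimate carries a negative
  finite-$k$ bias of order $\psi_1(k)/(4 \ln 2)$ bits (about 0.04 at
  $k = 10$) for strongly overlapping densities, vanishing as the
  densities separate; it is a property of the log-mixture form, not of
  the neighbour search. The estimator is consistent in the standard
  kNN-density regime $k \to \infty$, $k/N \to 0$; the test suite
  demonstrates shrinking error with $k \propto \sqrt{N}$. Rankings —
  the quantity that drives design — are far less affected than absolute
  values, which is why the Spearman validation holds at $k = 10$.
* **Replicate candidates**: a candidate measuring the same point twice
  shares the model trajectory but carries independent measurement
  noise; design matrices therefore draw two independent noise
  realizations per axis point, and predictive-sample noise streams are
  keyed to the design point (not the column position), which also makes
  column order an exact permutation contract.
* **Degenerate inputs**: an empty dataset returns the prior (and log
  evidence 0); a posterior whose profile of likelihood times prior
  flattens at the grid ends is flagged improper by
  `check_propriety()` before sampling; simulation failures during PPD
  sampling drop the draw, with a hard error above 1% drops.

## Design choices where the design was open

* Gamma priors are shape–scale (mean 3), matching the stated intent of
  a wide admissible range; the convention is switchable.
* The exchange kernel is the simplest valid one — one random adjacent
  pair per sweep — and the documented schedule exponent (4) is
  configurable.
* Candidate enumeration is exhaustive over the grid with a configurable
  cap; a stochastic search over large design spaces is out of scope,
  and greedy augmentation (`augment_design()`) covers the sequential
  use case: start with two or three experiments and extend while the
  JSD is low.
* Across model pairs, `rank_candidates()` aggregates by the minimum
  (worst-case discriminability) because design aims at separating
  specific pairs; models are weighted equally in the mixture — weighting
  by current evidence would let the complexity penalty silently remove
  models from consideration at the design stage.
* The expected Bayes-factor update draws new data from the true model's
  PPD by default (the best available estimate given current
  uncertainty), with fixed true parameters plus noise as an option;
  for MCMC-fitted models the update needs a thermodynamic-integration
  run per replicate and is gated behind an explicit `expensive = TRUE`.

## Problem sizes

The bundled studies run at sizes chosen for routine re-execution: the
linear study at 30 model pairs, 5000 predictive draws, 21 candidates
and 100 update replicates per candidate; the motif study at an
$N_T = 8$ ladder, 2000–2500 retained sweeps, and 400–500 predictive
draws over a 4–6 point time grid plus steady state per observable and
condition. Production analyses would scale the ladder to $N_T = 40$ and
the thinned posterior to 10000 draws (the package defaults).

## Known limitations

* The kNN-JSD estimator's absolute values at $k = 10$ are biased low by
  a few hundredths of a bit for strongly overlapping densities (see
  above); treat absolute JSD values near zero as "indistinguishable at
  this sample size", not as exact divergences.
* Candidate dimension beyond 3 is refused by default; density
  estimation in higher dimension needs larger samples than the default
  settings provide.
* Only pairwise model comparison (K = 2) is implemented; the mixture
  definition generalizes to K models, noted as an extension point.
* Non-Gaussian error models, SBML import, stochastic simulation, and
  gradient-based samplers are out of scope.
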