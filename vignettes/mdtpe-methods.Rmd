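---
title: "Safe offline sequence design with a mean-deviation TPE"
author: "mdtpe package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Safe offline sequence design with a mean-deviation TPE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdtpe)
```

## The problem

Directed-evolution and affinity-maturation campaigns routinely end with a
static dataset: a few hundred to a few thousand variant sequences of a parent
protein, each with one measured property (brightness, binding affinity), and
no budget for further measurements during the computational design step. The
goal is to propose new variants that improve the property — *offline*
model-based optimization (MBO). The standard approach trains a proxy model
f̂(x) on the dataset and optimizes it in place of the oracle.

The failure mode of naive offline MBO is overestimation out of distribution:
valid, functional proteins occupy a thin manifold, the training data covers a
small neighbourhood of the parent, and a flexible proxy extrapolates
confidently into regions where its predictions are meaningless. Proteins
sampled there typically do not even express. A safe optimizer must therefore
trade predicted value against evidence that the prediction can be trusted.

## The method

`mdtpe` implements this trade-off with three components.

**A Gaussian-process proxy** (`gp_fit()`). Sequences are embedded as fixed
vectors (one-hot over the mutable positions by default, or externally
computed protein-language-model embeddings via `load_embedding_table()`), and
an exact GP with a Matérn(ν = 5/2) + linear sum kernel is fitted to the
measurements. The GP supplies both a predictive mean μ(x) and a predictive
standard deviation σ(x); σ grows with distance from the training data, which
is exactly the out-of-distribution signal needed.

**A mean-deviation objective** (`mean_deviation()`, `md_objective()`). A
candidate is scored as

MD(x) = ρ·μ(x) − σ(x),

where ρ > 0 is the risk tolerance. As ρ → ∞ this reduces to plain
mean-maximization (conventional MBO); ρ < 1 weights the uncertainty penalty
heavily and keeps the search inside the training envelope. At ρ = 1 the
ranking is the classical lower confidence bound. The package's `mean_only`
mode scores candidates by μ(x) alone and serves as the conventional-TPE
baseline throughout.

**A categorical tree-structured Parzen estimator** (`propose()`, `mdtpe()`).
The search space is the Cartesian product of per-position candidate-residue
sets, built from the data by `build_search_space()`: the mutations carried by
the top-n measured variants (n = 30 or 100 in the published campaigns) define
the mutable positions and allowed residues. TPE splits the trial history at
the γ-quantile into good and bad sets (internally negating the objective so
the minimization convention y ≤ γ applies verbatim), builds a smoothed
categorical density per position from each set, draws `n_ei_candidates`
residues from the good density, and keeps the draw maximizing
log p(c | good) − log p(c | bad) — the categorical expected-improvement
surrogate. Positions are sampled independently (univariate TPE), matching the
default behaviour of the widely used TPE framework. The optimizer warm-starts
the history with the top measured sequences, scored by the run's own
objective so the history lives on a single scale.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `rho` | 0.15 | risk tolerance; the published working point found by grid calibration |
| `n_trials` | 1000 | sampler budget (3000–5000 in the published campaigns) |
| `warm_start_k` | 10 | top measured sequences seeding the history |
| `gamma` rule | min(⌈0.1 n⌉, 25) | good-set size; framework default |
| `n_startup_trials` | 10 | uniform-random trials before TPE proposals |
| `n_ei_candidates` | 24 | residue draws per position per proposal |
| `prior_weight` | 1.0 | uniform pseudo-observation smoothing the densities |
| `matern_smoothness` | 5/2 | GP kernel smoothness |

`calibrate_rho()` reproduces the published selection procedure: for each
candidate ρ it runs a brief MD-TPE optimization (300 trials by default,
roughly a tenth of a production budget) and checks whether the median σ of
the sampled sequences stays within the training deviation envelope,
operationalized as the 90th percentile of σ over the training sequences. The
largest ρ passing is returned — the most exploratory value that still
respects the envelope; if none passes, the smallest grid value is returned
with a warning flag in the diagnostics table. The envelope rule is this
package's own formalization: the source procedure is described only
qualitatively ("deviation levels comparable to the training data"), and a
scale-free percentile rule is robust to outliers and to the units of the
measured property.

## Design decisions

**Kernel combination and hyperparameters.** The published description says
only that a combination of Matérn and linear kernels was used. We default to
the *sum*: the linear term captures the global additive trend of mutational
effects, the Matérn term local smoothness, and a sum keeps both visible in
the predictive variance. Targets are standardized before fitting;
`"learned"` hyperparameters maximize the log marginal likelihood from a
fixed, data-driven start (L-BFGS-B), so fits are deterministic.

Two defaults are deliberately conservative rather than fully learned:

* the Matérn amplitude is fixed at 1 in standardized units. When the linear
  kernel alone explains the training data, unconstrained likelihood
  maximization drives the stationary amplitude to zero — and with it the
  deviation's response to distance from the data, which is the very signal
  the MD penalty needs. Pinning the amplitude at the target variance keeps
  the far-field deviation at the prior scale.
* the Matérn lengthscale is bounded above by the maximum pairwise training
  distance. Beyond that range the likelihood contains no information about
  the lengthscale, and the optimizer otherwise drifts to the
  infinitely-smooth ridge, again flattening σ.

Learned noise is floored at 10⁻⁶ (standardized units); Cholesky
factorizations retry on a jitter ladder (0, 10⁻¹⁰ … 10⁻⁴) before failing.
The reported σ(x) is the posterior sd of the latent function, excluding
observation noise.

**Sampler tie-breaks and weighting.** All sorting is stable (objective, then
trial index, then candidate order), making runs bit-reproducible under a
seed. One exception is deliberate: among equally scored acquisition draws the
*earliest draw* wins. Breaking such ties by a fixed candidate order would
collapse proposals onto the first candidate whenever the good and bad
densities coincide; draw-order tie-breaking is equally deterministic given
the seed and keeps null proposals uniform over the space. Observation sets
larger than 25 apply the framework-default recency ramp (`tpe_weights()`):
the oldest observations decay linearly toward 1/n. This matters
scientifically: without it, a residue tried and discarded early keeps a
permanently inflated bad-density count and can never be re-proposed, and the
sampler visibly fails to converge on separable landscapes.

**Duplicates.** Duplicate proposals are evaluated and recorded, matching
plain TPE dynamics; deduplication happens only in `top_k()`.

**Coordinates.** All human-facing coordinates (reports, the search-space
TSV) are 1-based, as are the package's internals — R is a 1-based language
and a dual convention invites off-by-one errors.

**Degenerate spaces.** A zero-position space is legal; optimization then
returns the parent on every trial, which avoids special-casing upstream.

## The synthetic landscape

`generate_landscape()` supplies a ground-truth oracle so every claim is
testable without external datasets or embedding models:

* additive per-mutation effects, i.i.d. N(0, `effect_sd`²), parent residues
  at zero;
* `n_epistasis` random pairwise interaction terms between non-parent
  residues;
* Gaussian observation noise;
* a hard loss-of-function collapse: any sequence more than
  `collapse_distance` mutations from the parent scores `collapse_value`,
  emulating variants that no longer express. The default `collapse_value` is
  a cheap lower *bound* on in-radius values (the `collapse_distance` most
  negative per-position minima plus all negative epistasis terms) minus
  3·`effect_sd`, guaranteeing collapsed sequences score below every
  functional one without enumerating the radius.

The default test scenario uses 10 mutable positions with 4 candidate
residues each (about 10⁶ combinations), 200 training variants within two
mutations of the parent, collapse beyond four mutations, and ρ = 0.15 —
a deliberately scaled-down analogue of the published campaigns (25–42
positions, 10⁸–10¹⁸ combinations, 1128 training variants at ≤ 2 mutations).
A GP trained on the near-parent data extrapolates a rising mean along
beneficial additive directions; the unpenalized sampler follows it across
the collapse boundary, while the deviation penalty holds MD-TPE inside the
functional region. This reproduces, at desk scale, the mechanism behind the
published result: conventional TPE proposes high-mean/high-deviation
sequences that fail to express, MD-TPE proposes lower-deviation, near-parent
sequences that do.

What the simulation does *not* model: biophysical structure in the effects
(effects are exchangeable Gaussians), embedding geometry of real protein
language models (one-hot blocks have constant norm and bounded pairwise
distance), measurement heteroscedasticity, and soft rather than hard loss of
function. Passing the simulation therefore demonstrates the *mechanism* —
deviation penalization prevents out-of-distribution drift — not calibrated
performance on any real assay.

## Verification and problem sizes

The test suite checks, among others: exact hand values of the MD formula;
noise-free GP interpolation, the far-field prior limit, and agreement with a
dense-matrix oracle at n = 50 to 10⁻⁸; brute-force density-ratio maximality
of TPE proposals on an enumerable two-position space over 100 seeds; χ²
uniformity of proposals under equal good/bad densities (10⁴ draws);
recovery of the enumerated optimum of a 729-variant separable landscape in
at least 18 of 20 seeds at 500 trials; and the paired safe-exploration
comparison (20 seeds, 1000 trials each, top-48 selection) requiring MD-TPE
to win on median deviation, median mutation count, and functional fraction
in at least 18 of 20 pairs. These sizes keep the whole suite around two
minutes on one CPU while leaving each property statistically sharp.

## Worked example

```{r example, eval = FALSE}
parent <- parent_sequence("parent", strrep("A", 30))
space <- search_space(parent, seq(2, 29, 3),
                      rep(list(c("A", "V", "K", "D")), 10))
land <- generate_landscape(space, n_epistasis = 10, effect_sd = 0.5,
                           collapse_distance = 4, noise_sd = 0.1, seed = 1)
train <- generate_training_set(land, 200, max_d = 2, seed = 2)

feat <- onehot_featurizer(space)
X <- t(vapply(train$sequence, feat, numeric(200)))
proxy <- gp_fit(X, train$value)

run <- mdtpe(space, md_objective(proxy, rho = 0.15), featurizer = feat,
             n_trials = 1000, warm_start_data = train, warm_start_k = 10,
             seed = 3)
summary(run, k = 48, landscape = land)
plot(run)
```

## Known limitations

* Univariate TPE ignores epistatic coupling between positions when
  proposing; the objective sees epistasis only through the proxy.
* The GP is exact (no sparse approximation), so fitting is cubic in the
  training size; thousands of training points are comfortable, hundreds of
  thousands are not.
* `calibrate_rho()` inherits the stochasticity of short TPE runs; its chosen
  ρ can vary between neighbouring grid values across seeds, as the
  published grid search's qualitative criterion would.
* Only substitution variants are supported; indels would break the
  fixed-coordinate search space and the Hamming-distance geometry.
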