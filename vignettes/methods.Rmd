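---
title: "Models and methods in coevotrait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in coevotrait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

coevotrait asks two questions about a pair of discrete cultural traits
observed across societies related by a language phylogeny — here a binary
trait (kava drinking) and five-level ordinal traits (political complexity,
social stratification on the Murdock–Provost scales):

1. **Association**: is the binary trait associated with the ordinal traits
   once spatial proximity, shared ancestry, and environment (atolls) are
   controlled for?
2. **Coevolution**: does change in one trait *precede* change in the other
   along the phylogeny, in the Granger sense?

This vignette records the models, the priors, the numerical choices, and
what the synthetic-data tests do and do not establish.

## Data model

A `society_table` has one row per society: `kava` (0/1), two ordinal traits
coded 0–4, an atoll indicator in {0, 0.5, 1} (0.5 = "almost atoll", which
can be excluded or merged with atolls — both conventions are exposed since
neither is canonical), and coordinates in decimal degrees. Missingness is
explicit `NA`, never a sentinel; each model stage states whether it
excludes incomplete rows (regressions: complete-case, with a message) or
marginalizes them (signal and coevolution models: the society stays in the
random-effect/latent structure, only its observation term is dropped).

Trees are rooted with branch lengths (Newick/NEXUS via ape). Societies map
to tips through an explicit two-column taxon map — one tip per society —
because choosing among multiple candidate languages is an ethnographic
judgement, not something a heuristic should do. Pruning collapses
degree-two nodes, summing branch lengths, so patristic distances among
retained tips are preserved (tested against an independent path-traversal
oracle).

## Structured covariances

*Spatial.* Haversine great-circle distances (R = 6371 km) are max-scaled
to [0, 1] — normalization happens after subsetting to the analysis sample —
and pushed through a Matérn 3/2 kernel,

k(d) = σ² (1 + √3 d/ρ) exp(−√3 d/ρ).

ρ is interpreted on the normalized scale; ρ = 0.02 corresponds to strong
covariance within an overnight sailing voyage (~160 km on a Pacific-wide
sample) and near-zero beyond ~1000 km. Because the appropriate reach of
spatial dependence is unknowable, `rho_sensitivity()` refits over a grid
(0.02, 0.04, 0.06, 0.08 by convention).

*Phylogenetic.* The correlation between two tips is their shared
root-to-tip path length divided by the geometric mean of their depths —
the standard variance-covariance-to-correlation conversion, which keeps
the diagonal at exactly 1 even for non-ultrametric posterior trees. A
1e−9 diagonal jitter is added before any Cholesky factorization, escalating
×100 on failure.

## Regressions

Ordinal responses use a cumulative-logit likelihood: the observed category
results from thresholding a latent logistic variable at four ordered
cutpoints (parameterized as a free first cutpoint plus log-increments).
Binary responses use Bernoulli-logit. Society-level random effects
z = σ L u (non-centered; L the Cholesky factor of the correlation matrix)
enter the latent predictor additively, one scale per structure.

Priors, logged with every fit: slopes and intercepts Normal(0, 2.5);
cutpoints Normal(0, 4) under the ordering constraint; random-effect scales
half-Normal(0, 1). These are "regularizing" defaults in the brms sense;
no single canonical set of widths exists for this model family, so they
are exposed as a sensitivity axis (`prior_cfg`).

The effect on the original five-point scale is the sample-average marginal
contrast: per posterior draw, the expected scale value Σk·P(k) is computed
for every fitted society with the predictor set to 1 and to 0 (keeping the
society's fitted random effects), and the difference is averaged over
societies. This mirrors averaging model fitted values under presence vs
absence.

Sampling is static HMC with jittered leapfrog length, dual-averaging step
size (target acceptance 0.8), and diagonal mass estimation during warmup.
Two chains by default; split-R̂ > 1.01 on any core parameter raises a
convergence warning.

## Phylogenetic signal

A bivariate latent multilevel model: kava (Bernoulli-logit) and one ordinal
trait (cumulative-logit) with correlated phylogenetic random effects,
z₁ = σ₁ v₁ and z₂ = σ₂ (r v₁ + √(1−r²) v₂), v = L u, giving cross-trait
phylogenetic correlation r. Scales are half-Normal(0, 2) — wider than the
regression prior because a tighter scale prior mechanically caps the
variance-partition signal (below) around 0.6, which would make strongly
heritable traits unrepresentable; r has an LKJ(2)-equivalent prior.

Phylogenetic signal is a latent-scale variance partition,

λ = σ²_phylo / (σ²_phylo + π²/3),

with π²/3 the logistic-link residual variance. The residual convention is
not dictated by the field for discrete traits; this package always uses
the latent-logit convention and reports it. λ ∈ [0, 1] by construction.

Tree uncertainty is propagated by fitting per tree and concatenating
per-tree posteriors with equal weight. Each tree's fit is seeded from a
hash of its Newick string, so the pooled posterior is exactly invariant to
the order trees appear in the file.

## The dynamic coevolution model

Latent traits η(t) ∈ R² evolve along each branch as a bivariate
Ornstein–Uhlenbeck process

dη_t = (b + A η_t) dt + G dW_t,  G G′ = Q = diag(σ) R diag(σ),

with selection matrix A (diagonal: autoregressive selection, constrained
negative; off-diagonal: cross-trait selection), intercepts b, and
correlated drift Q. Observation layers at the tips: kava ~
Bernoulli(logit⁻¹ η₁), ordinal trait ~ cumulative-logit(η₂, α).

Priors follow the printed model: b ~ N(0,1); diag(A) ~ N(0,1) truncated
negative; off-diagonals ~ N(0,2); σ ~ N⁺(0,1); R ~ LKJ(4); cutpoints
α ~ N(0,2); root states η_root ~ N(η_anc, 1) per trait with η_anc = −2
("informed": ancestral societies unlikely to show either trait) or 0
("default"). Stability (tr A < 0, det A > 0) is enforced by rejection —
the truncated-diagonal prior alone does not guarantee a stationary system
when off-diagonals are large.

Over a branch of length t the transition is Gaussian:
mean θ + e^{At}(η_parent − θ), covariance S − e^{At} S e^{A′t}, where
θ = −A⁻¹b and S solves the Lyapunov equation A S + S A′ + Q = 0. The
compiled core evaluates e^{At} by the closed 2×2 form; the R-side
`ou_transition_moments()` uses `Matrix::expm` and the two are cross-checked
to machine precision, and both are checked against an Euler–Maruyama
simulation oracle.

*Numerical choices.* Trees are rescaled to unit height (A and Q are per
tree height; logged in fit metadata) and branch lengths floored at 1e−6 of
height to avoid singular transitions. Latent states are sampled, not
marginalized — the observation layers are non-Gaussian, so Kalman-style
integration does not apply. The sampler is non-centered: per-node
innovations u are standard normal and η is reconstructed by a forward pass;
this removes the scale/latent funnel. Each iteration interleaves three
kernels: (i) `rw_reps` adaptive random-walk Metropolis updates of the
global OU parameters in the *non-centered* parameterization (Haario
proposal covariance, scale adapted to 0.23 acceptance during warmup only);
(ii) one Hamiltonian trajectory over all innovations, cutpoints and
spatial innovations, with reverse-mode gradients computed by
backpropagation through the tree recursion in C++; (iii) an interweaved
(ASIS-style) Metropolis block that updates the OU globals in the
*centered* parameterization — latent states held fixed, conditional equal
to the process density alone — and then maps the states back to
innovations. The two parameterizations have complementary conditional
geometries, and the no-data prior-recovery test passes only because all
three kernels are individually valid. Divergent trajectories are counted;
more than 10% after warmup triggers a warning. Even so, the effective
sample size per draw for the cross-selection parameters is low (their
marginal posterior is wide while both conditional views are narrow);
real analyses should use several thousand iterations per tree and check
the reported ESS.

*Directionality summary.* For draws of (A, latent tip states), the
equilibrium shift of trait j per standardized increase of trait i is

Δθ_{i→j} = −A_{ji} δ_i / A_{jj},

where δ_i is the median absolute deviation (consistency-scaled; `"sd"`
optional) of trait i's latent tip values in that draw. The MAD of *latent
tip values per draw* is one reading of "scaled by the median absolute
deviation"; the algebra is not printed anywhere, so both the scale choice
and this conditional-equilibrium formula are package decisions, and the
sign of Δθ always equals the sign of A_{ji} (antisymmetry under sign flips
is a tested invariant). PPM is the fraction of draws above zero; when the
cross-selection is identically zero PPM is reported as 0.5. Spatial
control adds per-society Matérn 3/2 GP intercepts to both observational
predictors, with half-Normal(0,1) scales.

## The synthetic world

`simulate_dataset("dataset-s1-like")` emulates the *statistical shape* of
the study data: 83 societies; binary kava; two 5-level ordinals; exactly 5
missing kava values and 1 missing stratification value; seven 0.5 atoll
codes, with kava suppressed on atolls; island-cluster coordinates in a
Pacific-like box; and 100 trees of 95 tips of which 83 map to societies
(so pruning is always exercised). Kava and political complexity come from
the latent OU model itself (A = [[−1, 0.25], [0.75, −1]], σ = 1.2, r = 0.3,
root mean −2, equilibrium ≈ (0.3, 0.8)): moderate reciprocal coevolution
with the stronger direction kava → complexity, spread over all five
categories. Social stratification is the political-complexity latent plus
logistic noise — correlated ordinals without a third OU dimension, which
the model class does not include.

What the generator does **not** emulate: real posterior tree samples are
correlated perturbations of one inferred history, whereas the preset's 100
trees are independent pure-birth draws (the first is the generating
history); real ordinal codings have coder error and source bias; real
missingness is not random (it concentrates where ethnography is thin). A
green recovery test therefore establishes that the estimators work when
their assumptions hold — not that the original study's data meet those
assumptions.

Seeds are split hierarchically (tree / latent / observation / geography),
so components vary independently and every artifact is bit-reproducible
from (config, seed).

## Calibration findings worth knowing

* **Directional power is intrinsically low for discrete tips.** With a
  binary and a 5-level trait at 80 tips, the marginal information about
  cross-trait selection after integrating out the latent states is on the
  order of 1–2 nats even when the latent trajectories themselves identify
  it overwhelmingly (a brute-force importance-sampling check on small
  trees makes this vivid). Posterior PPMs for a true A₂₁ = +1.5 typically
  land between 0.5 and 1.0 across replicates, and the package's acceptance
  harness documents exactly this. Interpret single-dataset PPMs near 0.9
  with corresponding humility.
* **A spatial control can only remove confounding it can see.** A
  confounder drawn with decay ρ = 0.02 on a Pacific-scale sample is
  numerically white between societies; no spatially structured random
  effect can absorb it. The confounding harness therefore generates smooth
  confounders (ρ = 0.15).
* **Sampler validation.** All gradients are finite-difference checked; the
  compiled non-centered likelihood equals the pure-R joint density through
  an exact change-of-variables identity; and with all observations deleted
  the sampler reproduces its priors (including the stability truncation)
  to KS ≈ 0.02.

## Known limitations

Two traits only; OU latent dynamics only; one language per society;
fit-per-tree-and-concatenate (no joint tree-and-trait inference);
regression and signal models use a single summary tree per fit unit rather
than integrating topological uncertainty within a fit; static HMC rather
than NUTS (trajectory lengths are jittered, not adapted). Runtime-scaled
test designs are marked in the test sources; the full-size designs pass
the same code paths.
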