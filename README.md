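# coevotrait

Bayesian tools for testing whether discrete cultural traits are
**associated** and whether they **coevolve** across societies related by a
language phylogeny. The motivating setting is Oceania: does kava drinking
(binary, presence/absence) go together with sociopolitical complexity
(five-level ordinal scales for political complexity and social
stratification), and does change in one trait precede change in the other
over cultural-evolutionary time — once spatial proximity, shared linguistic
ancestry, and island environment are accounted for?

The package is self-contained: it implements its own Hamiltonian Monte
Carlo and adaptive Metropolis samplers (no Stan/brms dependency), with the
dynamic-model likelihood in compiled code, and ships a synthetic-data
generator with known ground truth so the whole inferential stack is
testable offline.

## Models

**Structured ordinal/Bernoulli regressions.** An ordinal response y ∈
{0,…,4} follows a cumulative-logit model: P(y = k) = F(α_{k+1} − μ) −
F(α_k − μ), with four ordered cutpoints α and latent predictor
μ = Xβ + Σ_s σ_s L_s u_s, where each random-effect structure s is a
society-level Gaussian effect with correlation matrix from either the
phylogeny (shared-path correlation) or geography (Haversine distances,
max-normalized, Matérn 3/2 kernel k(d) = σ²(1+√3d/ρ)e^{−√3d/ρ}).
Slope effects are translated back to the original five-point scale as a
sample-average marginal contrast, and a ρ-sensitivity grid (0.02–0.08)
probes the assumed reach of spatial dependence.

**Phylogenetic signal.** A bivariate latent multilevel model with
correlated phylogenetic random effects yields the cross-trait phylogenetic
correlation r and, per trait, the variance-partition signal
λ = σ²_phylo / (σ²_phylo + π²/3) on the latent logit scale.

**Coevolution.** A generalized dynamic phylogenetic model: latent traits
η(t) ∈ R² evolve along branches as a bivariate Ornstein–Uhlenbeck process
dη = (b + Aη)dt + G dW (Q = GG′ = diag(σ) R diag(σ)), observed at the tips
through Bernoulli-logit (kava) and cumulative-logit (ordinal trait)
layers. The off-diagonals of the selection matrix A carry directionality,
summarized as the equilibrium shift Δθ_{i→j} = −A_{ji} δ_i / A_{jj} per
MAD-standardized increase in the source trait, with its positive posterior
mass (PPM). Optional Matérn Gaussian-process intercepts control spatial
autocorrelation; the root prior is N(−2, 1) ("informed") or N(0, 1).
Posterior tree samples are integrated by fitting per tree and pooling
draws.

## Worked example

Simulate a study-shaped dataset (83 societies, 5 missing kava values, one
missing stratification value, 100-tree posterior-style sample) and fit the
no-controls regression:

```r
library(coevotrait)
sim <- simulate_dataset("dataset-s1-like", n_trees = 3, seed = 42)
tab <- binarize_atolls(sim$table, "half_as_atoll")
fit <- fit_structured_regression(
  tab,
  regression_spec("political_complexity", "kava",
                  sampler_cfg = list(chains = 2, warmup = 400, iter = 400)),
  seed = 7)
fit
#> Structured cumulative_logit regression: political_complexity ~ kava
#> 78 societies ( 5 excluded )
#>   parameter   mean median ci66_lo ci66_hi ci95_lo ci95_hi    ppm rhat ess
#> 1      kava  0.259  0.260  -0.216   0.743  -0.775   1.225 0.7113    1 520
#> 2      cut1 -0.392 -0.392  -0.638  -0.156  -0.861   0.128 0.0625    1 478
#> 3      cut2  0.642  0.630   0.381   0.896   0.150   1.221 0.9925    1 569
#> 4      cut3  1.721  1.712   1.395   2.028   1.085   2.406 1.0000    1 637
#> 5      cut4  3.159  3.137   2.625   3.645   2.195   4.407 1.0000    1 641

predicted_contrast(fit, "kava")$summary
#>       parameter  mean median ci66_lo ci66_hi ci95_lo ci95_hi   ppm
#> 1 contrast_kava 0.176  0.171   -0.14   0.486  -0.452   0.789 0.711
```

Read: the 5 societies with unknown kava status are excluded (complete-case,
always announced); the log-odds slope of kava on political complexity is
0.26 with a 95% credible interval straddling zero, i.e. an expected
increase of about 0.18 levels on the original five-point scale in
kava-drinking societies — positive but uncertain, as expected for this
generator's modest kava→complexity coupling at n = 83. `rhat`/`ess` are
split-R̂ and effective sample size across the two chains.

Coevolution on the same data:

```r
coev <- fit_coevolution(tab, sim$pruned,
                        coevolution_spec("political_complexity",
                                         root_prior = "informed"),
                        n_trees = 3, seed = 8)
delta_theta(coev, "kava", "political_complexity")  # Δθ, CI, PPM
```

Other entry points: `fit_bivariate_latent()` / `phylogenetic_signal()`,
`rho_sensitivity()`, `run_pipeline()` (full model menu with manifest and
JSON-lines log), and a CLI dispatcher
`Rscript -e 'coevotrait::coevotrait_cli()' simulate --seed 1 --out dir/`.

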