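# pestphylo

Phylogenetic comparative analysis of binary invasion outcomes in species
assemblages, built around the question of why some crop pests — the motivating
case is the global rice pest fauna — become invasive while close relatives do
not. The package treats invasiveness as a joint product of shared evolutionary
history and measurable life-history traits, and provides every stage of that
analysis as tested, reusable functions exercised end to end on synthetic data
with known ground truth.

## What it does

Given a dated phylogeny, a taxonomy, feeding-guild membership, a 0/1 invasion
status and a trait table (continuous life-history traits plus categorical
traits, with missing values), the pipeline:

1. **Grafts** species that lack molecular data into the tree next to their
   nearest taxonomic relatives (genus, then family, then order), placing the
   attachment at the mean crown age of same-rank clades and preserving
   ultrametricity and all original pairwise distances
   (`graft_missing_species()`).
2. **Quantifies phylogenetic signal**: Blomberg's
   *K* = (MSE₀/MSE) / [(tr C − n/(1ᵀC⁻¹1))/(n−1)] with a randomization test,
   Pagel's λ by profile maximum likelihood with a χ²(1) likelihood-ratio test
   (λ̂ may exceed 1 up to the positive-definiteness bound), and Fritz–Purvis
   *D* = (d_obs − d̄_B)/(d̄_R − d̄_B) for binary traits, with
   permutation and Brownian-threshold nulls (`blomberg_k()`,
   `pagel_lambda_ml()`, `fritz_purvis_d()`).
3. **Imputes** missing continuous traits under a joint Gaussian model
   vec(Y) ~ N(μ, R ⊗ C_model), where the species covariance C_model follows
   Brownian motion, Pagel's λ, Ornstein–Uhlenbeck or Early-Burst transforms;
   models are compared by AIC and missing cells filled with conditional means
   (`compare_evomodels()`, `impute_missing()`).
4. **Fits the Bayesian phylogenetic Bernoulli mixed model**
   logit P_j = α + Σᵢ βᵢ X_ij + u_phylo(j) + u_guild(j),
   with u_phylo ~ N(0, σ²_phylo A) on the standardized phylogenetic
   covariance A and weakly informative Normal(0, 0.5) coefficient priors,
   using a tuning-free slice-sampling MCMC scheme with split-R̂ and bulk/tail
   ESS diagnostics, plus the non-phylogenetic GLMM counterpart
   (`fit_bernoulli_mixed()`, `convergence_report()`).
5. **Decomposes variance** on the logit scale (residual variance π²/3) into
   fixed, phylogenetic and guild components with marginal and conditional R²
   (`variance_decomposition()`), and ranks traits by Chevan–Sutherland
   hierarchical partitioning over Laplace-approximation GLMM fits
   (`hierarchical_partition()`).
6. **Generates synthetic assemblages** matching the study structure — 129
   species in 7 orders and 7 feeding guilds, 29.5% invasive prevalence, 9.08%
   missingness, log-scale traits with strong phylogenetic signal — so every
   stage can be validated against known truth (`simulate_study()`).

`run_pipeline()` orchestrates all stages from a single (YAML-able)
configuration and writes delimited reports.

## Worked example

```r
library(pestphylo)

sim <- simulate_study(seed = 42, beta = c(fecundity = 1.5),
                      sigma_phylo = 1, missing_rate = 0)
spec <- build_design(sim$truth$continuous, sim$truth$categorical,
                     sim$guild, sim$invasion,
                     phylo_vcv(sim$tree, standardize = TRUE))
fit <- fit_bernoulli_mixed(spec)
ps <- posterior_summary(fit)
ps[ps$parameter %in% c("b_fecundity", "sigma_phylo", "sigma_guild"), 1:3]
#>      parameter  mean    sd
#>    b_fecundity 1.030 0.263
#>    sigma_phylo 0.663 0.497
#>    sigma_guild 0.359 0.300
```

The generating fecundity coefficient was 1.5 on the standardized log scale;
its posterior concentrates on positive values (the shrinkage toward zero is
the Normal(0, 0.5) prior at work), and the phylogenetic SD is detected
alongside the guild SD. `variance_decomposition(fit)` then reports how much
of the invasion-status variance each component explains:

```r
round(variance_decomposition(fit)$summary["R2_conditional", ], 3)
#>                mean lower upper
#> R2_conditional 0.45 0.275  0.65
```

At this budget (4 chains x 6000 iterations) every monitored parameter had
split R-hat at most 1.003 and effective sample sizes above 1300.

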