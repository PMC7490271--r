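# spfldyn

Does the allele occupying a protein site become *more* fit the longer it
has been there (entrenchment), or *less* fit (senescence)? The two regimes
leave opposite phylogenetic footprints. After an amino-acid gain A → B on
an internal branch, the *substitution subtree* of B is the contiguous part
of the tree whose internal nodes still carry B; under entrenchment, losses
of B cluster right after the gain, under senescence they cluster on late
branches. `spfldyn` is for molecular evolutionists who have a rooted
phylogeny (branch lengths in dS, the time for one neutral substitution)
and per-node ancestral amino-acid states, and who want to quantify these
dynamics.

The package implements:

* a forward-time simulator of single-site evolution on single-position
  fitness landscapes (SPFLs) — flat, rugged, or gamma-distributed log
  fitness — that are static, change randomly as a Poisson process (rate
  λ per dS), or whose resident-allele log fitness drifts linearly,
  f_B(t + Δt) = f_B(t) + k·Δt with Δt = 0.01 dS. Substitutions follow the
  mutation–selection kernel g(S) = S / (1 − e^(−S)) on a uniform mutation
  kernel (rate μ, default 1/dS);
* substitution-subtree extraction from per-node states, with per-branch
  loss indicator s, branch length, and allele age (distance from the gain
  node);
* the pooled replacement regression
  `s = a·length + b·age + c` (OLS), whose coefficients (a, b) are the ABC
  summary statistics, plus age-binned replacement profiles;
* rejection ABC with local ridge-regression adjustment for
  (α, k[, fraction]): α is the shape-and-rate parameter of the gamma
  fitness distribution, k the drift rate of the resident's log fitness
  (k > 0 entrenchment, k < 0 senescence), fraction the share of affected
  alleles. Priors: k ~ U(−100, 100), log₁₀α ~ U(−1.5, 1),
  fraction ~ U(0, 1); tolerance 0.01; cross-validation, sign-confusion and
  rate-robustness diagnostics;
* a per-allele binomial logistic scan
  (`s ~ age + offset(log(length))`) with Benjamini–Hochberg FDR control,
  classifying individual alleles as senescing or entrenched.

## Worked example

Recover an injected entrenchment rate from a synthetic dataset. The
fixture subtree list is 500 substitution subtrees extracted from static
gamma(α = 1) simulations on the package's 64-tip model phylogeny; the
"observed" data are then re-simulated on those subtrees with k = +40:

```r
library(spfldyn)
set.seed(1)
pooled <- fixture_subtree_list(n = 500, alpha = 1, seed = 101)
ref <- simulate_reference(pooled, prior_spec("two_param"),
                          n_sims = 3000, seed = 202)
obs <- summary_regression(
  simulate_subtree_branches(pooled, alpha = 1, k = 40, fraction = 1))
print(obs)
#> Replacement regression (n = 3356):
#>   s = -0.0091 * length + -0.0582 * age + 0.0399
fit <- abc_fit(obs, ref, tolerance = 0.01)
print(fit)
#> ABC posterior (two_param, tolerance 0.01, adjustment ridge)
#>   alpha    median    0.475  95% PPI (0.117, 4.869)
#>   k        median   49.862  95% PPI (27.189, 89.407)
```

The negative age coefficient b = −0.058 says replacements get rarer with
allele age; the posterior median k ≈ 50 with a 95% interval excluding 0
correctly recovers entrenchment of roughly the injected strength (the true
k = 40 lies inside the interval). `plot(fit)` draws the posterior
histograms; `allele_scan()` runs the per-allele detector on an extracted
`subtree_set`.

A command-line wrapper is installed as `exec/spfldyn` with subcommands
`simulate`, `rescale-branches`, `extract-subtrees`, `summarize`,
`abc-fit`, `abc-validate`, `allele-scan`, `make-fixtures`.

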