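# famliab

Familial liability models for register-based comorbidity studies.

`famliab` is for epidemiologists and quantitative geneticists who study
how a rare index disorder (modelled here on borderline personality
disorder, BPD) co-occurs with other conditions within individuals and
co-aggregates in families, and how much of each association is genetic
versus environmental — the kind of analysis national patient registers
support, but whose person-level data are legally restricted. The package
implements the complete analytic chain and couples it to a synthetic
multigenerational registry generator, so every estimator is verifiable by
closed-form oracles and parameter recovery at desk scale.

## The model

Each binary lifetime diagnosis indicates that a latent standard-normal
liability exceeds a threshold τ. Liability decomposes as

    L = a·A + c·C + e·E,   a² + c² + e² = 1

into additive-genetic (A), common-environment (C) and unique-environment
(E) components. A relative pair of kinship *g* shares fractions α_g of A
and γ_g of C (full siblings ½/1, maternal half-siblings ¼/1, paternal
half-siblings ¼/0, cousins ⅛/0), so the cross-relative liability
correlation is α_g·a² + γ_g·c². For two traits, correlated factors
rA, rC, rE give the phenotypic correlation

    r_ph = a₁a₂·rA + c₁c₂·rC + e₁e₂·rE

whose pathway shares are reported as bivA, bivC, bivE (summing to 1,
negatives allowed). Estimation: lifetime phenotypes and relative pairs
from register-style tables; odds ratios by logistic models with
cluster-robust sandwich variance (family components as clusters, 5-df
natural cubic spline of birth year); latent correlations by two-step
tetrachoric ML with probit thresholds; ACE parameters by weighted least
squares over the kinship-group correlation structure with delta-method
Wald intervals. See the methods vignette
(`vignettes/familial-liability-methods.Rmd`) for the full account.

## Worked example

Simulate a 20,000-family registry under the default study conditions
(exposure prevalence 0.9% with a −0.6 probit female threshold shift,
outcome prevalence 8.9%, a² = 0.5, c² = 0.05, rA = 0.74) and run the full
pipeline:

```r
library(famliab)
cfg <- pipeline_config(
  simulation = simulation_config(n_families = 20000, seed = 11),
  out_dir = "run", seed = 11)
bundle <- run_pipeline(cfg)
cat(render_tables(bundle), sep = "\n")
```

```
== Cohort descriptives ==
block        label               total  unexposed (  pct%)  exposed (  pct%)
total        N                   38453      38108 ( 99.1%)      345 (  0.9%)
sex          male                19093      19029 ( 99.7%)       64 (  0.3%)
sex          female              19360      19079 ( 98.5%)      281 (  1.5%)
...
phenotype    depression           3462       3272 (  8.6%)      190 ( 55.1%)

== Odds ratios (adjusted, cluster-robust 95% CI) ==
depression     within_individual    11.74 (9.47-14.56)     n=38453
depression     full_sib             2.67 (1.87-3.83)       n=22582
depression     MZ_twin              NA                     n=314
...

== ACE decomposition of the phenotypic correlation ==
r_ph = 0.527
bivA     72.3% (95%CI  -50.3% to  195.0%)
bivE     27.7% (95%CI  -38.4% to   93.7%)
bivC      0.0% (95%CI  -59.8% to   59.8%)
genetic correlation rA = 0.76 (95%CI 0.13 to 1.39)
```

Reading the output: the simulated cohort reproduces the configured 0.9%
exposure prevalence and its female preponderance (1.5% vs 0.3%); the
within-individual odds ratio (11.7) exceeds every between-relative odds
ratio, which decline with genetic relatedness; twin strata are too sparse
at this scale and render as `NA` (suppressed). The bivariate ACE fit
recovers a genetic correlation of 0.76 against the generating 0.74 —
with wide intervals, as expected for a 0.9% trait at this sample size —
and the decomposition attributes about three quarters of the phenotypic
correlation to the genetic pathway. Each output directory also carries a
provenance record (config hash, seed, versions); reruns with the same
configuration are byte-identical.

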