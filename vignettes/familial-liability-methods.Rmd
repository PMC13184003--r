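---
title: "Familial liability models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Familial liability models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famliab)
```

## The problem

National patient registers make it possible to ask two linked questions
about a rare index disorder — here modelled on borderline personality
disorder (BPD), a psychiatric diagnosis with strong female preponderance
and a register prevalence below one percent. First, how strongly does the
disorder co-occur with other psychiatric, somatic and behavioral
conditions, within individuals and across relatives of varying
relatedness? Second, how much of each phenotypic association is carried by
shared genes versus shared or individual environment? `famliab` implements
the full analytic chain for both questions and pairs it with a synthetic
registry generator whose latent structure is exactly the model the
estimators assume, so every stage can be verified by closed-form oracles
and parameter recovery without access to restricted person-level data.

## The liability-threshold ACE model

Each binary lifetime diagnosis is modelled as the indicator that a latent
standard-normal *liability* exceeds a threshold $\tau$. The liability of
trait $t$ decomposes into uncorrelated standardized components,

$$L_t = a_t A_t + c_t C_t + e_t E_t, \qquad a_t^2 + c_t^2 + e_t^2 = 1,$$

where $A$ is additive-genetic, $C$ common (family) environment and $E$
unique environment. A relative pair of kinship $g$ shares a fraction
$\alpha_g$ of additive-genetic variance and $\gamma_g$ of
common-environment variance:

| kinship | $\alpha$ | $\gamma$ |
|---|---|---|
| MZ twins | 1 | 1 |
| DZ twins / full siblings | 1/2 | 1 |
| maternal half-siblings | 1/4 | 1 |
| paternal half-siblings | 1/4 | 0 |
| parent–child | 1/2 | 0 |
| aunt/uncle | 1/4 | 0 |
| first cousins | 1/8 | 0 |

The same-trait cross-relative liability correlation is
$\alpha_g a^2 + \gamma_g c^2$. Setting $\gamma = 1$ for maternal but 0 for
paternal half-siblings operationalizes the assumption that the shared
rearing environment follows the mother; it is what lets a three-group
sibling design (full, maternal-half, paternal-half) separate $a^2$ from
$c^2$ without twins.

For two traits the *correlated factors* parameterization adds factor
correlations $r_A, r_C, r_E$ between the trait-specific components. The
implied within-person cross-trait (phenotypic) correlation is

$$r_{ph} = a_1 a_2 r_A + c_1 c_2 r_C + e_1 e_2 r_E,$$

and a cross-relative cross-trait correlation replaces the three weights by
$(\alpha_g, \gamma_g, 0)$. The bivariate decomposition reported as
`bivA`, `bivC`, `bivE` divides the three pathway products by $r_{ph}$;
the proportions sum to one and individual terms may be negative when a
pathway works against the net correlation.

## Synthetic registry generator

`simulate_registry()` produces register-style tables (persons, parent
links, twin zygosity, ICD-coded diagnosis events) from a configurable mix
of family structures. Liabilities are *gene dropped*: founders draw
additive-genetic 2-vectors from $N(0, R_A)$ with $R_A$ the $2\times2$
correlation matrix with off-diagonal $r_A$; each child receives the
parental mean plus segregation noise with covariance $\tfrac12 R_A$ (no
inbreeding), which reproduces not only the sibling coefficients but also
the cousin coefficient 1/8 through the transmission recursion. MZ co-twins
receive identical genetic vectors. One common-environment vector is drawn
per household — all children of one mother — so paternal half-siblings
never share $C$ by construction; unique-environment vectors are drawn per
person. Binary diagnoses arise by thresholding, with probit-scale female
and birth-year threshold shifts; the base threshold is recalibrated
against the realized covariate mix so the marginal prevalence always hits
its target. Death and first emigration are sampled from constant yearly
hazards and censor both follow-up and event emission.

Default study conditions mirror a register birth cohort: children born
1973–2001; family mix dominated by full-sibling families (62%) with 10%
maternal and 10% paternal half-sibling, 3% twin and 15% cousin families;
exposure-trait prevalence 0.9% with a $-0.6$ probit female threshold
shift (yielding roughly the 5:1 female-to-male ratio seen for BPD);
outcome-trait prevalence 8.9%; generating ACE structure
$a^2 = 0.5, c^2 = 0.05$ per trait with $r_A = 0.74$, $r_C = 0.5$,
$r_E = 0.25$ — the additive share sits in the middle of the 46–69%
heritability range reported for BPD by twin and family studies, and the
genetic correlation equals the strongest somatic-domain overlap the
estimators are expected to detect. Every stage draws from its own RNG
stream seeded by the configuration seed plus a fixed offset, so stages are
independently reproducible and the whole run is byte-identical under a
fixed seed.

What the generator does *not* emulate — assortative mating, dominance
genetic effects, age-of-onset hazard structure, diagnostic drift beyond a
linear probit trend, realistic demography, migration histories — bounds
what passing tests show: they verify the estimators against the model they
assume, not robustness to its violations on real data.

## Cohort, phenotypes, pairs

`apply_cohort_exclusions()` keeps persons born in the window with a known
mother and no congenital-malformation flag, and drops anyone dead or
emigrated before their 18th birthday (calendar arithmetic; a February 29
birthday rolls to March 1). Follow-up runs from the latest of birth, first
immigration and the register start (1987-01-01) to the earliest of first
emigration, first matching diagnosis, death and 2020-12-31; intervals are
closed, so a diagnosis on the start date counts. Phenotypes are lifetime
indicators defined by ICD code prefixes per revision era; death by suicide
is ascertained exclusively from cause-of-death rows; female-only
phenotypes carry `NA` indicators for males.

`enumerate_relative_pairs()` classifies kinship from parent links and the
zygosity table. Twin pairs with unknown zygosity are excluded from the
MZ/DZ sets but remain eligible as full siblings (zygosity comes from a
separate source and its absence should not delete a genuine sibling pair).
Within-generation pairs are emitted in both orientations ("double
entry") — the point estimate is unaffected by which member is exposure and
which outcome, while the cluster sandwich absorbs the induced dependence;
between-generation pairs are emitted once with the older relative on the
exposure side and restricted to relatives born 1933 or later.

For the quantitative-genetic stage, `select_unique_sibling_pairs()` keeps
one pair per kinship type per *independent family cluster*, defined as a
connected component of the full/half-sibling graph (the source analyses do
not define the term; a component is the weakest notion that guarantees
selected pairs share no member). Selection is (1) closest in age, (2) the
pair whose older member is oldest, (3) a seeded uniform draw. MZ twin
pairs are never full-sibling candidates (their genetic sharing is wrong
for the $\alpha = 1/2$ group); DZ twins are genetically ordinary full
siblings and are included by default.

## Odds-ratio models

Within-individual and familial co-aggregation odds ratios come from
logistic models estimated by IRLS. With an independence working
correlation the estimating-equation point estimates coincide with ordinary
logistic ML, so the clustering enters only through the variance: the
sandwich sums scores within extended-family components (connected
components of the person–parent graph, which automatically span both
members of every pair) and applies no small-sample factor. Wald 95%
intervals are $\exp(\hat\beta \pm 1.96\,\widehat{se})$. Covariates are
sex(es) and natural cubic splines of birth year with five degrees of
freedom, boundary knots at the data extremes and interior knots at
equally spaced quantiles (the conventional placement; the source analyses
do not state one). For female-only outcomes the outcome side is
restricted to females and only the exposure relative's sex is adjusted.
Estimates with fewer than five doubly-diagnosed observations are
suppressed and rendered as `NA`, mirroring the "too few observations"
cells of register-study figures.

## Tetrachoric correlations

Latent correlations are estimated in two steps: thresholds first, then the
correlation by profile ML with thresholds fixed. Covariate adjustment
enters through person-specific thresholds (the negated probit linear
predictor), which keeps the binary-data likelihood exact instead of
residualizing. The likelihood kernel is the bivariate-normal quadrant
probability, evaluated by a deterministic Gauss–Legendre rule (6/12/20
nodes by correlation magnitude) with a series expansion near $|\rho| = 1$;
absolute accuracy is about $10^{-14}$, verified against the closed form
$P(X>0, Y>0) = \tfrac14 + \arcsin(\rho)/2\pi$. No Monte-Carlo integration
is used anywhere in the likelihood. Estimates with $|\hat\rho| \ge
1-10^{-6}$ carry a boundary flag; empty margins raise degeneracy errors.

For each kinship group of selected pairs the package estimates the four
latent correlations the bivariate model constrains: within-person
cross-trait (both pair positions pooled), the two cross-person same-trait
correlations, and the cross-person cross-trait correlation, whose two
symmetric orientations are estimated separately and averaged without an
information gain (they share the same pairs).

Because those four estimates per group share pairs, their sampling errors
are correlated. The package therefore assembles the full within-group
moment covariance from per-pair influence values (score over observed
information, summed over a pair's contributions) and carries it into the
fit. This was a genuinely open design point: fitting with a purely
diagonal moment covariance was tried first and produced confidence
intervals for $r_A$ about 1.65 times too wide, with empirical coverage
near 100% in calibration runs — the correlated errors partially cancel in
the $r_A$ direction, and a diagonal approximation cannot see that. With
the influence-function covariance the reported standard errors track the
Monte-Carlo spread and coverage sits in the mid-90s.

## ACE model fitting

**Univariate.** The same-trait correlations of the three sibling groups
give the linear system $r_g = \alpha_g a^2 + \gamma_g c^2$, solved by
inverse-variance weighted least squares in closed form, *unconstrained* —
negative $\hat a^2$ or $\hat c^2$ are reported as such, since the
univariate stage is diagnostic (it decides the fixed-C retry).

**Bivariate.** $\theta = (a_1, c_1, a_2, c_2, r_A, r_C, r_E)$ minimizes
the weighted squared discrepancy between observed and implied
correlations, with loadings bound to $[0, 1]$, factor correlations to
$[-1, 1]$ and $e_t = \sqrt{1 - a_t^2 - c_t^2}$ enforcing unit liability
variance ($a_t^2 + c_t^2 > 1$ is handled by a smooth quadratic penalty, so
boundary solutions are exact and flaggable rather than hidden by a
squared-parameter reparameterization). Weights are inverse moment
variances. The search runs L-BFGS-B from eight deterministic starts (a
grid over loading magnitude, $r_A$ sign and a third coordinate) followed
by a damped Gauss–Newton polish whose projected step norm is the
stationarity diagnostic; on noiseless input this recovers generating
parameters to machine precision. When the free fit fails and both
unconstrained univariate $\hat c^2$ are non-positive, the model is
automatically refitted with the C pathway fixed to zero and $r_C$
dropped — the same remedy register analyses apply when optimization fails
for phenotypes with no detectable shared-environment variance.

Parameter covariance uses the WLS sandwich
$(J^\top W J)^{-1} J^\top W \Sigma W J (J^\top W J)^{-1}$ with $J$ the
numerical Jacobian at the optimum and $\Sigma$ the influence-function
moment covariance above; derived quantities ($r_{ph}$, `bivA/bivC/bivE`,
variance shares, factor correlations) get delta-method standard errors.
Wald intervals are deliberately *not* truncated to the parameter space, so
an estimate near a bound can report an upper limit beyond 1 — informative
about precision where a truncated interval would not be.

**Screening.** A phenotype enters bivariate modeling only when its
within-individual tetrachoric correlation with the exposure is at least
0.1 and at least five concordant and five discordant sibling pairs exist
(boundaries inclusive). Counts are pooled across the three kinship groups
by default; a per-group mode is available, and the screening tetrachoric
can be computed with or without covariate-adjusted thresholds — the
sources are silent on both points, so both are exposed with the pooled,
adjusted variant as default.

## Numerical and testing choices

Problem sizes in the test-suite and acceptance runs were picked so each
check is decisive at desk scale: liability-correlation invariants use
50,000 pairs per kinship (three Monte-Carlo standard errors separate the
competing hypotheses), the zero-residual inversion property uses 50 random
parameter draws with $c^2$ sampled in $[0.05, 0.3]$ (as $c \to 0$ the
factor correlation $r_C$ loses identifiability, so draws near that
boundary would test ill-posedness rather than the optimizer), and the
genetic-correlation recovery study runs one study at 50,000 pairs plus 100
replicates at 20,000 pairs per kinship type. The recovery study thresholds
both traits at 20% prevalence — a common-outcome scenario comparable to
fall injuries or infections in a register cohort; at the exposure
disorder's own 0.9% prevalence the binary data at these pair counts simply
do not carry enough tetrachoric information for a sub-0.05 recovery error,
which is itself a finding the end-to-end run reflects in its wide
intervals. The end-to-end pipeline demonstration uses 30,000 families
(about 58,000 cohort children) under the default register-like conditions.

## Limitations

Estimates inherit every limitation of the generating assumptions:
equal-environment-style reasoning for the $\gamma$ pattern, no assortative
mating, no dominance, lifetime indicators that ignore differential
follow-up (a time-to-event sensitivity analysis is out of scope here), and
two-step tetrachorics that treat estimated thresholds as known — the
threshold-estimation error is not propagated into the moment covariance,
which is visible as mildly conservative-to-nominal coverage rather than a
bias. The bivariate fit is method-of-moments over pairwise latent
correlations, not full-information ML over the raw four-variate binary
vectors; with rare traits and boundary solutions its intervals should be
read qualitatively, exactly as register studies themselves caution.
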