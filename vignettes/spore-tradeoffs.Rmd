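---
title: "Methods: trade-offs, hierarchy and realized social fitness in spore-forming amoebae"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trade-offs, hierarchy and realized social fitness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sporefit)
```

## The scientific question

*Dictyostelium discoideum* strains that contribute a disproportionate share
of spores to a chimeric fruiting body look like social cheaters when spore
count is the only currency. `sporefit` implements the quantitative-genetic
argument that this currency is incomplete: spore number trades off against
spore size, size buys viability, and a strain's realized social fitness —
its sporehead representation multiplied by the viability of its spores —
can therefore be flat across strains even when representation varies
heritably. The package provides the full chain of that argument as tested,
seeded code: a generative simulator, a Bayesian multi-trait variance
component model, a dominance-hierarchy linearity test, and selection-surface
fits.

## The model

Each strain $i$ has a latent genetic value $g_i \in \mathbb{R}^4$ for the
traits (N, S, V, C) = (log total spore number, log spore size in µm, logit
spore viability, logit competitiveness). Replicate assays give

$$y_{itr} = \mu_t + g_{it} + e_{itr}, \qquad g_i \sim \mathcal{N}_4(0, G),
\qquad e_{itr} \sim \mathcal{N}(0, E_t).$$

Assumptions worth making explicit:

* **Strains are unrelated isolates.** There is no pedigree or relatedness
  matrix; among-strain variance is interpreted as broad-sense genetic
  variance, so the heritabilities are $H^2$, not $h^2$.
* **Residuals are independent across traits.** Number, size and viability
  are assayed on different cells (and competitiveness on different
  chimeras), so replicate-level cross-trait covariance is not identifiable
  and is fixed at zero; all cross-trait covariance lives in $G$.
* **Viability and competitiveness are binomial.** Hatch counts out of
  `n_plated` spores, and focal-spore counts out of `n_counted` spores, enter
  the Gaussian model through the empirical logit
  $\log\{(x + 0.5)/(n - x + 0.5)\}$, which is finite at $x = 0$ and $x = n$.
  With the default assay sizes (100 plated, 500 counted) the transform's
  binomial noise is small relative to the replicate-level residual variance.

### Estimation

`mtmm()` is a conjugate Gibbs sampler: strain effects from their
multivariate-normal full conditionals (strains sharing a replicate-count
pattern are drawn in one vectorized block, so balanced designs cost one
4×4 Cholesky per sweep), $G$ from an inverse-Wishart, each $E_t$ from a
scaled inverse-chi-squared, and $\mu$ from normals. Defaults, all exposed:

| parameter | default | why |
|---|---|---|
| $G$ prior | inverse-Wishart, $\nu_0 = 5$, $\Psi_0 = 0.1 I$ | weakly informative at one-more-than-the-trait-count degrees of freedom; scale small relative to unit phenotypic variance |
| $E_t$ prior | scaled inv-$\chi^2$, 1 df, scale 0.5 | centred on an even genetic/residual split, nearly flat |
| $\mu$ prior | $\mathcal{N}(0, 10^8)$ | effectively flat on every modelling scale used |
| chain | 20,000 iterations, 5,000 burn-in, thin 10 | 1,500 stored draws give stable 95% intervals at the default data sizes; a full fit takes seconds |

Convergence is screened by split-chain $\widehat{R}$ on every genetic and
residual variance; any value above 1.1 flags the fit as non-converged
(reported, not fatal — the draws are still returned for inspection).

$H^2_t$ and $r_{ij}$ are computed **per draw** as
$G_{tt}/(G_{tt} + E_t)$ and $G_{ij}/\sqrt{G_{ii}G_{jj}}$, so every draw —
and hence every equal-tailed 95% credible interval — is bounded in $[0,1]$
and $[-1,1]$ respectively. Analyses that instead interval-estimate variance
components separately and form ratios afterwards can report $H^2$ intervals
exceeding 1; the per-draw ratio is used here precisely because it cannot.
Credible intervals are equal-tailed (2.5%/97.5% quantiles) throughout.

## The generator

`trait_params()` fixes phenotypic variance at 1 per trait on the modelling
scale, so a heritability target fully determines the split
$G_{tt} = H^2_t$, $E_t = 1 - H^2_t$, and correlation targets scale as
$G_{ij} = r_{ij}\sqrt{G_{ii}G_{jj}}$. The default targets are the published
strain-panel estimates ($H^2$ = 0.25, 0.59, 0.62, 0.35; $r$ = −0.72 (NS),
0.86 (SV), −0.54 (NV), 0.50 (NC), −0.55 (SC), −0.69 (VC)); that correlation
matrix is positive definite (smallest eigenvalue 0.078), so the generator
reproduces it exactly. Printed pairwise estimates need not form a jointly
valid matrix in general, so a repair path exists: a smallest eigenvalue in
$(-0.05, 0)$ triggers eigenvalue clipping at zero plus re-normalization to
unit diagonal (recorded in the object and in pipeline reports); anything
below −0.05 is rejected.

**Competitiveness is Bradley–Terry.** In a 50:50 chimera of strains $i$ and
$j$, the focal spore count is binomial with success probability
$\mathrm{plogis}(\eta_i - \eta_j)$, $\eta = \mu_C + g_C + e$. A latent-
strength model is the simplest mechanism that (a) makes the dominance
hierarchy probabilistically transitive, matching a near-1 triangle
transitivity at low noise, and (b) makes representation a genuine fourth
trait whose genetic correlations with N, S, V are set by $G$. The replicate
noise in $\eta$ is drawn once per strain *per replicate* and shared across
that strain's mixes in the replicate: this represents the strain's
competitive state in that assay batch, and it is what makes the
replicate-level variance $E_C$ (and hence $H^2_C$) identifiable from the
per-replicate partner-mean empirical logits that `mix_phenotypes()`
computes.

**Scale choices.** Defaults are desk-scale stand-ins, not estimates from any
particular panel: 24 strains, 4 replicates per trait, 100 spores plated per
viability replicate, 500 spores counted per chimera replicate. Trait means
are $\mu_N = \log 2\times10^5$ (spores per clonal plate),
$\mu_S = \log 6.5$ µm, $\mu_C = 0$ (symmetric mixes). The viability
baseline $\mu_V = 1.1$ (mean hatch ≈ 0.75) deserves a note: the two
population-level correlations $\mathrm{cor}(w, N)$ and $\mathrm{cor}(w, S)$
under the trade-off G-matrix cross zero at different baselines (≈0.8 and
≈1.45 on the logit scale), because the logistic link sets how strongly
viability differences propagate into $w = C \cdot V$. The default 1.1 is
the realistic hatch rate at which both correlations stay small (|r| ≤ 0.15),
i.e. at which the generator actually exhibits the flat-fitness-surface
regime it is meant to emulate. Under this mechanism the size–fitness
surface retains a weak positive population trend (r ≈ 0.15) while the
number–fitness surface is flat (r ≈ 0.06); at very large strain counts a
surface fit will detect the former, so the defining flatness contrast is on
the spore-number axis.

**Determinism.** Everything is seeded; `stage_seeds()` derives per-stage
sub-seeds ($97 \cdot \mathrm{seed} + \mathrm{offset} \bmod 2^{31}-1$) so any
stage can be re-run in isolation, and identical seeds give byte-identical
CSV/JSON output. Spore counts round half-to-even after exponentiation for
cross-platform determinism.

### What the generator does *not* emulate

Real strain panels have unbalanced replication, plate and batch effects,
non-Gaussian residuals, measurement error correlated across traits measured
on the same plate, and possibly frequency-dependent mixing success that a
single latent strength cannot express. Passing recovery tests therefore
shows that the estimators are correct *under the stated model*, not that
the model captures every feature of real assay data.

## Hierarchy statistics

`chimeric_representation()` pools counts over replicates within each pair
(the binomial MLE — replicates with more spores counted weigh more), and
averages the pairwise proportions unweighted across partners for $C_i$.
`tournament()` binarizes at a strict majority by default (`tie_tol = 0`);
pairs within the tie band are recorded and excluded, and only triads with
all three pairs decided enter the census. A triad is transitive iff it is
not a 3-cycle, $t_{\mathrm{tri}} = 4(p_t - 0.75) \in [-3, 1]$, and the null
re-orients every decided pair independently with probability 1/2 (each
triad is then cyclic with probability 1/4, so $E[p_t] = 0.75$ exactly).
The one-sided p-value uses the add-one correction
$(1 + \#\{t^{\mathrm{null}} \ge t^{\mathrm{obs}}\})/(n_{\mathrm{perm}}+1)$,
so it can never be exactly zero.

## Fitness surfaces

Realized fitness is the exact product $w_i = C_i \cdot V_i$, with $V_i$ the
pooled hatch fraction and $C_i$ the mean representation; $w$ is left on its
natural $[0,1]$ product scale while the trait axes are standardized
genotypic means (z-scored with the sample SD, matching "standard deviation
units" on plot axes). "Flat" is operationalized as *every non-intercept 95%
confidence interval contains zero* — a deliberate, simple definition
declared by this package, not a formal equivalence test. Surfaces can be
fitted to observed genotypic means or to posterior-simulated strains
(`simulate()` on a fitted model); the input source is recorded in the
report, and the pipeline's default report uses observed genotypic means,
which are the verifiable desk-scale quantity.

Two properties anchor the interpretation and are exercised in the tests at
fixed problem sizes chosen as the package's own conventions:

* under the trade-off G-matrix at the default 24-strain study scale, both
  quadratic $w$-surfaces are flat in the large majority of seeds;
* removing the viability trade-off ($V \equiv 1$, so $w \equiv C$) restores
  the representation–number slope, which is detected essentially always at
  the 200-strain recovery scale. The contrast needs that larger scale: with
  24 strains the inherited slope (genetic correlation 0.5, attenuated by
  measurement) is underpowered, which is itself a useful reminder of what a
  small panel can and cannot show.

## Numerical and design choices

* Zero spore counts are guarded as $\log(\max(x, 0.5))$ when entering the
  modelling scale; with the default $\mu_N$ this path is never exercised.
* A trait with zero variance, a strain with no observations of some trait,
  a single-strain standardization, an empty triad census, a mismatched
  strain set, and a zero-variance predictor all raise explicit errors
  rather than producing silent numbers.
* The one-trait model reduces to the balanced one-way random-effects
  decomposition; the test suite checks the Gibbs posterior mean against the
  closed-form ANOVA intraclass correlation within ±0.05 at 200 strains × 8
  replicates.
* Parameter-recovery tests run at 200 strains × 8 replicates with the full
  default chain and assert that posterior means fall within the run's own
  95% credible half-widths of the generative truth. With 200 strains the
  *realized* sample correlations of the drawn effects deviate from the
  generative values with SD ≈ 0.07; the posterior tracks the realized
  values, which is the correct behaviour and bounds how closely any single
  run can match the targets.

## Known limitations

* No pedigree/relatedness, fixed effects, or non-diagonal residual
  covariance; the model is intentionally the minimal multi-trait
  variance-component decomposition.
* The inverse-Wishart prior mildly shrinks small variance components at
  small strain counts (visible in the 24-strain worked example), a known
  property of this prior family.
* The Bradley–Terry mechanism cannot generate genuinely intransitive
  hierarchies; datasets with strong intransitivity would be evidence
  against the generator, not handled by it.
* `mix_phenotypes()` treats partner-mean empirical logits as Gaussian
  observations; with very small `n_counted` or very few partners the added
  counting noise would bias $E_C$ upward and $H^2_C$ downward. At the
  default sizes the bias is negligible (≈0.005 added variance).
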