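---
title: "Modelling genotype-by-environment interaction along a continuous
  socioeconomic gradient in extended pedigrees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling GxE along a continuous socioeconomic gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxevc)
```

## The scientific problem

Quantitative metabolic traits (glucose, insulin, lipids, blood pressure,
adiposity) aggregate in families, and a classical variance-components
analysis of extended pedigrees partitions their variance into an additive
genetic component shared between relatives in proportion to kinship, an
optional household component shared by co-residents, and a residual.
`gxevc` extends this machinery to ask a sharper question: does the
*genetic architecture itself* change along a continuous environmental
axis?  The motivating application is socioeconomic status (SES) in large
multigenerational family studies, where the environment index is the
standardized sum of a standardized occupational prestige score and
education years (zSES).  The same machinery applies to any standardized
continuous exposure.

## The model

Write $z_i$ for individual $i$'s environment index.  The phenotypic
covariance between individuals $i$ and $j$ is assembled from three
components:

$$
\Omega_{ij} = K_{ij}\,
  \sqrt{\sigma_g^2(z_i)\,\sigma_g^2(z_j)}\;\rho_g(z_i, z_j)
  + H_{ij}\, \sqrt{\sigma_c^2(z_i)\,\sigma_c^2(z_j)}\;\rho_c(z_i, z_j)
  + \mathbf{1}[i = j]\,\sigma_e^2(z_i),
$$

where $K$ is the additive relationship matrix ($2\phi$, computed by the
standard recursion over the pedigree), $H$ the household indicator, and

$$
\sigma_g^2(z) = e^{\alpha_g + \gamma_g z}, \quad
\sigma_e^2(z) = e^{\alpha_e + \gamma_e z}, \quad
\sigma_c^2(z) = e^{\alpha_c + \gamma_c z},
$$
$$
\rho_g(z_i, z_j) = e^{-\lambda_g |z_i - z_j|}, \quad
\rho_c(z_i, z_j) = e^{-\lambda_c |z_i - z_j|}, \quad \lambda \ge 0 .
$$

The exponential variance functions guarantee positivity; the exponential
decay correlations equal 1 exactly when $\lambda = 0$ or $z_i = z_j$.
"No GxE" means the genetic variance is flat ($\gamma_g = 0$) *and* the
genetic correlation across environments is 1 ($\lambda_g = 0$); each is a
testable sub-hypothesis, and rejecting either demonstrates covariance
heterogeneity along the environmental continuum.  A residual
environmental correlation function is excluded by the standard assumption
that residual effects are uncorrelated between individuals.  Each
individual's own environment enters cross terms through the geometric
mean of the two variance-function values, the only construction
consistent with a per-individual variance function.

With all slopes and decay rates at zero the model collapses to the
homogeneous polygenic decompositions
$\sigma_p^2 = \sigma_g^2 + \sigma_e^2$ (model 1) and
$\sigma_p^2 = \sigma_g^2 + \sigma_c^2 + \sigma_e^2$ (model 2), and
heritability is $h^2(z) = \sigma_g^2(z) / \sigma_p^2(z)$ with the
household share $c^2(z)$ defined analogously.

## Likelihood and fitting

The likelihood is multivariate normal and factorizes over the connected
components of the union of the parent-offspring graph and the
shared-household graph (household effects correlate individuals across
nuclear families, so components of the pedigree graph alone would not be
independent).  `gxe_data()` builds these blocks once, computing kinship
per block; `fit_ml()` maximizes the profile log-likelihood over the
variance-function parameters with the mean coefficients solved by
generalized least squares at each step — exact for maximum likelihood,
and it reduces the search dimension substantially.  The optimizer is
bounded quasi-Newton (`L-BFGS-B`) with an analytic score assembled
block-by-block from the component summands of $\Omega$.

Numerical choices that matter:

* **Decay rates are bounded at zero, not log-transformed.**  $\lambda = 0$
  is itself a null hypothesis, so the boundary must be attainable
  exactly; a log parameterization would push it to $-\infty$.
* **Log-variance intercepts are bounded at $\pm 30$.**  $e^{-30}$ is an
  effective zero, letting "component absent" solutions be reached
  smoothly while keeping $\Omega$ numerically positive definite.
* **Multiple starts.**  A moment-based start (OLS residual variance split
  across active components) plus seeded jitter; nested fits are
  warm-started from the parent model's optimum, which also guarantees
  non-negative likelihood-ratio statistics.  Negative statistics from
  residual optimizer noise are clipped at zero with a warning beyond
  `1e-6`.
* **Standard errors** come from the inverse negative Hessian of the
  profile log-likelihood at interior optima (finite differences of the
  analytic score); parameters on a bound are flagged and get no SE.
  $h^2$ and $c^2$ SEs use the delta method on the fitted
  parameterization.

## The three-stage testing procedure

1. **Heritability and household screening.**  $\sigma_g^2 = 0$ and
   $\sigma_c^2 = 0$ are boundary hypotheses: their likelihood-ratio
   statistics are referred to the half-mixture
   $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$, whose p-value is exactly 0.5
   when the estimate sits on the boundary.  The working model is model 2
   when the household test is significant, else model 1.
2. **Joint GxE test.**  The full GxE model (free $\gamma_g, \lambda_g,
   \gamma_e$, plus $\gamma_c, \lambda_c$ under model 2) against the
   homogeneous base, referred to $\chi^2_3$ (or $\chi^2_5$).  Because the
   decay rates sit on a boundary under the null, this reference is
   conservative; the simulation suite quantifies the conservatism rather
   than asserting an untracked mixture.  Joint p-values are
   Bonferroni-adjusted across the trait panel (capped at 1), the
   convention that produces the familiar `1.00000` entries in multi-trait
   screens.
3. **Component tests** for the survivors: each of $\gamma_g, \gamma_e,
   \gamma_c$ against $\chi^2_1$ and each $\lambda$ against the
   half-mixture, all versus the full fit.  A decay rate already estimated
   at the boundary needs no refit — its statistic is exactly 0 and its
   p-value exactly 0.5.  Component p-values are reported per test
   (multiplier 1) by default: the within-trait rows of published
   component tables show unadjusted boundary values of exactly 0.50000,
   which a row-wise multiplier would destroy; the multiplier is
   configurable.

Gatekeeping is at $\alpha = 0.05$ per stage by default.  Stage-3 rows
exist only for stage-2 survivors; the pipeline records every decision in
its manifest.

## Preprocessing

Traits are prepared the way pedigree studies usually prepare them:
individuals flagged for disease or medication use are excluded (a pure
filter); the trait is residualized on its covariate list by OLS (the
share of variance explained is reported); residuals are mapped to normal
scores by the rank-based inverse normal transform with the Blom offset
$(r - 3/8)/(n + 1/4)$ — the quantitative-genetics default, configurable.
The covariate list is supplied per trait; model selection over covariates
is out of scope.  zSES is standardized post-exclusion by default (the
alternative is a configuration choice), enters the variance functions
untransformed, and is also included in the mean model by default so that
variance-function estimates are not confounded by a mean trend in the
environment.  A mediation screen (regressing the SES index on each diet
or alcohol covariate, Bonferroni-adjusted) checks that candidate
covariates are not proxies for the environment itself.  Missing values
are never imputed.

## The synthetic-data generator

No raw family data ship with the package, so validation rests on a
generator that emulates the structure of the motivating study: 42
three-generation families (founder couple; sibship of $1 +
\mathrm{Poisson}(3.5)$; each offspring marries in a founder spouse with
probability 0.9 and has a sibship of the same law), nuclear-family
household assignment, and a household-clustered SES index
$z = \mathrm{standardize}(u_{\mathrm{household}} + v_i)$ with
$u \sim N(0, \tau^2)$, $\tau = 1$ by default (SES plausibly clusters
within households; no published within-household SES correlation exists
to calibrate against, so $\tau$ is a documented convention).  The
defaults yield roughly 1,100–1,350 individuals across seeds, bracketing
the motivating study's recruited and analyzable counts.  Ages are uniform
on 18–94 and sex is Bernoulli with 57% female, matching the study's
descriptive margins; SEI and education columns are affine in the latent
SES value so the scoring pipeline reproduces the simulated index exactly.
Traits are drawn per family block as $y_b = X_b\beta + L_b\varepsilon$
with $L_b$ the Cholesky factor of the model covariance at the true
parameters, so simulation truth and fitted model share one covariance
implementation only at the interface level — moments are verified against
theory (sib-pair covariance $0.5\,h^2\sigma_p^2$) and the likelihood
against an independently coded dense density.

What the generator does *not* emulate: ascertainment through probands,
assortative mating, secular trends, non-normal trait scales (the
pipeline's inverse normalization makes fitted traits near-normal by
construction), or missingness mechanisms.  Passing recovery tests
therefore demonstrates correctness of the estimator and tests under the
model, not robustness to real-data pathologies.

Presets fix the study conditions used throughout the validation suite:
`polygenic` ($h^2 = 0.45$, the fasting-glucose-like anchor),
`variance-het` ($\gamma_g = -0.5$, $\lambda_g = 0.3$ — genetic variance
higher at the low end of the environment, the direction reported for
glucose traits), `corr-decay` ($\lambda_g = 0.5$), `household-het`
($h^2 = 0.31$, $c^2 = 0.11$, $\gamma_c = -0.5$, the systolic-blood-
pressure-like anchor) and `null`.

## Problem sizes used by the validation suite

Monte-Carlo checks run at sizes chosen to make their reference
distributions meaningful: heritability and GxE recovery use 50 replicates
of the 42-family default (the study scale); the global-null calibration
of the component tests uses 200 replicates of 120 families.  The larger
size for the null calibration is deliberate: the half-mixture for a decay
rate tested at its boundary is an asymptotic reference, and at the
42-family scale the statistic's point mass at zero is measurably elevated
(about 0.62 versus the asymptotic 0.5; about 0.49 at 120 families).  The
practical reading is that at study scale the boundary tests are
*conservative* — decay rates are declared at the boundary somewhat more
often than the asymptotic mixture predicts, so half-mixture p-values err
on the side of non-rejection.  The slope tests show no such distortion
(type-I error within the binomial confidence band at every size
measured).

## A worked example

```{r example, eval = FALSE}
library(gxevc)

# a synthetic cohort under genetic variance heterogeneity
sc <- scenario_presets(seed = 11)[["variance-het"]]
d <- simulate_dataset(sc)
dat <- gxe_data(d$ped, d$pheno, trait = "trait")

s1 <- test_heritability(dat, seed = 1)
s1$fit            # h2 near 0.4 with SE near 0.06
s2 <- test_gxe_joint(dat, s1, seed = 2)
s2$test$p_raw     # joint GxE p-value
s3 <- test_gxe_components(dat, s2, seed = 3)
s3[, c("label", "stat", "p_raw")]

# figure-ready variance functions and covariance surface
fg <- function_grid(s2$fit_full$params, s2$fit_full$spec)
head(fg$curves)
```

A whole-panel run (`run_panel()` or the `inst/scripts/gxevc-panel.R`
wrapper) adds exclusions, residualization, normalization, panel-wise
adjustment and CSV/manifest export around the same calls.

## Known limitations

* The joint stage-2 reference $\chi^2_{3/5}$ ignores the boundary mass of
  the decay rates and is conservative; simulated size is about 0.03 at
  nominal 0.05.
* Boundary half-mixture p-values are additionally conservative at small
  family counts (see above).
* Single-trait analysis only; no multivariate traits, dominance,
  epistasis, marker-based relatedness, X-linkage, or
  ascertainment-correction.
* Families are assumed non-overlapping apart from household links; the
  likelihood factorizes only over the combined graph's components.
* The $h^2$ SE uses the delta method from the fitted log-variance
  parameterization; a direct variance-scale Hessian can differ slightly
  in small samples.
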