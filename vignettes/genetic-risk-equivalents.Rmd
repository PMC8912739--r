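---
title: "Genetic risk equivalents: model, methods and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic risk equivalents: model, methods and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genriskeq)
```

## The scientific problem

Odds ratios are a poor vehicle for communicating how much of a person's
modifiable risk compares with their inherited risk. For diseases with a
well-established polygenic risk score (PRS) — colorectal cancer being the
motivating example, with on the order of 140 independent risk loci — an
exposure effect can instead be expressed on the genetic scale: *by how many
PRS percentiles would your genetic risk have to be higher to match the risk
conferred by this exposure?* That quantity is the **genetic risk equivalent
(GRE)**, a descendant of the risk/rate-advancement-period idea (exposure
effects expressed as equivalent years of age).

## Model

All estimation happens in one unconditional logistic model on case–control
data,

$$\operatorname{logit} P(D=1\mid E, G, X) =
  \alpha + \beta_{E_k}\,[E = k] + \beta_G\, G + \gamma' X ,$$

where $E$ is a 4-level intake-frequency exposure (reference: lowest
category), $G$ is the PRS *percentile* (a continuous term), and $X$ collects
adjustment covariates — always the frequency-matching factors age and sex,
plus covariates chosen by AIC-based forward–backward selection. For each
non-reference exposure level the GRE is the coefficient ratio

$$\mathrm{GRE}_k = \beta_{E_k} / \beta_G ,$$

in units of PRS percentiles. Because both coefficients come from the same
fit, their sampling covariance matters for the interval.

Key identities the implementation maintains (and the tests assert):

* `gre_point(bE, bG) * bG == bE` exactly;
* GREs are invariant to rescaling the percentile axis — fitting the PRS per
  10 percentiles or per single percentile yields identical GRE tables,
  because the ratio rescales with the coding;
* the reference category has no GRE (reported as absent, not 0).

## Confidence intervals for a coefficient ratio

The exact distribution of a ratio of correlated normal estimates is
heavy-tailed, so the package offers three methods:

* **Delta method** (default): first-order variance
  $\mathrm{SE}^2 = v_E/\beta_G^2 + \beta_E^2 v_G/\beta_G^4
  - 2\beta_E c_{EG}/\beta_G^3$, normal critical values. The interval is
  symmetric about the point estimate by construction — which matches the
  structure of published GRE intervals and is why delta is the default
  reconstruction; the published description of the interval method is a
  summary rather than a formula, so this choice is an inference from that
  symmetry, not an established fact.
* **Fieller**: the exact quadratic confidence set
  $\{\rho : (\beta_E-\rho\beta_G)^2 \le z^2(v_E - 2\rho c_{EG} + \rho^2
  v_G)\}$. When the denominator is significantly nonzero at the level this
  is a finite interval; otherwise the set is returned with
  `bounded = FALSE` (a complement of an interval, or the whole line).
* **Parametric bootstrap**: percentile interval over ratios of draws from
  the asymptotic bivariate normal of $(\hat\beta_E,\hat\beta_G)$. This is
  the package's independent cross-check, never the default.

The precision of the PRS coefficient, summarised by
$t = |\beta_G|/\mathrm{SE}_G$, governs how the methods relate. The Fieller
set tracks the bootstrap essentially exactly wherever it is bounded; the
first-order delta width degrades as $t$ falls (the ratio distribution grows
skew), so the cross-method agreement checks in the test-suite compare delta
to the bootstrap only at clearly strong denominators ($t \ge 8$) while
Fieller is also checked at weaker ones. At the precision typical of a
well-powered PRS this distinction is immaterial, and all three methods
agree to within a few percent of interval width.

## PRS construction and stratification

The score is the plain (optionally weighted) sum of risk-allele dosages;
with unit weights it ranges over $[0, 2\cdot n_\text{loci}]$. Percentiles
use mean ranks for ties; scores beyond the reference maximum cap at 100.
The five risk categories cut at percentiles 10/25/75/90 (lower tail
closed), giving 10/15/50/15/10% occupancy on the reference set up to
tie-induced deviation.

Which population defines the percentile scale is genuinely open: the
published analyses do not state whether percentiles were computed on
controls, the pooled sample, or an external reference. The package defaults
to **controls only** (`reference = "controls"`), because at low disease
prevalence the control distribution approximates the source population that
the generative model acts on; the pooled case–control sample, being roughly
half cases, is markedly case-enriched and a worse stand-in. The pooled
option is retained (`reference = "all"`) and the choice is recorded in the
report provenance.

## The synthetic cohort generator

No individual-level data from the motivating study are available, so the
package validates its whole chain on a generator that emulates the study's
statistical structure:

* a source population with age $\sim N(69.5, 9^2)$ truncated to [30, 95],
  61.4% male, binary covariates at control-population prevalences (see
  `default_covariates()`), and a 4-category intake exposure at control
  prevalences 0.117/0.608/0.244/0.031;
* Hardy–Weinberg dosages at 140 loci with risk-allele frequencies drawn
  from U(0.1, 0.9), optional clamped-Gaussian jitter standing in for
  imputation error (default off — no error model is published);
* a logistic disease model on the *within-population* PRS percentile,
  exposure, age, sex and covariates, with default effects
  $\beta_E = \log(1.19, 1.41, 1.73)$ and
  $\beta_G = \log(1.74)/42.3 \approx 0.0131$ per percentile — the published
  adjusted estimates, so that recovery runs target the realistic regime;
* the intercept is calibrated by root-finding so the overall disease
  probability is 0.05, a realistic cumulative colorectal-cancer risk at
  these ages;
* retrospective sampling: all required cases are drawn from the diseased
  pool, controls from the non-diseased pool either at random or
  frequency-matched on age decade × sex (proportional allocation, largest
  remainder). Infeasible targets raise errors — never silent truncation.
* optional knobs: exposure missingness (the pipeline drops and counts such
  rows), and an exposure–covariate cumulative-logit shift to induce
  confounding (default off — only marginal covariate distributions are
  published).

County of residence, a third matching factor in the motivating design, is
omitted: it plays no analytic role here. Tumour site and stage are assigned
to cases at published marginal prevalences, independently of all risk
factors — consistent with the published finding of no site/stage variation,
and meaning site/stage-specific analyses on synthetic data test machinery,
not biology.

**What passing simulations do and do not show.** The generator has
independent loci (no LD), covariates independent of exposure unless the
confounding knob is set, exactly logistic disease risk, and
non-differential, complete genotyping. Passing recovery and calibration
suites therefore demonstrates that the estimators are correct under the
model they assume — not that the model captures real dietary measurement
error, selection effects, or residual confounding.

## Numerical and design choices

* Logistic fits use IRLS to tolerance 1e-10 (cap 100 iterations) with
  observed-information covariance; non-convergence, (quasi-)separation and
  rank deficiency are errors naming the offending terms, and every model
  drops incomplete rows per-model with exact bookkeeping
  (`n_used + n_dropped = n`).
* Stepwise selection is greedy bidirectional AIC search with forced terms
  protected; a pure-noise candidate enters with asymptotic probability
  $\Pr(\chi^2_1 > 2) \approx 0.157$, which the calibration suite checks.
* Interaction tests default to the likelihood-ratio test on the full block
  of product terms (df 3 for 4-level exposure × continuous PRS, df 12
  against the 5-level PRS category), with a Wald variant provided; which
  was used for the published p-values is unstated, and the two agree
  asymptotically.
* The per-category trend within PRS strata codes the exposure 0–3 linearly,
  matching the usual "per category increase" column.
* Subgroup models reuse whole-sample percentiles and drop the stratifier
  from their own covariate set; strata with an empty exposure level are
  flagged and skipped rather than failing the report.
* Age enters models continuously; categorical covariates enter at their
  generated (binary) coding.

## Validation problem sizes

The test-suite's stochastic suites run at sizes chosen to make Monte Carlo
error small relative to the tolerances they assert: parameter/GRE/coverage
recovery uses 200 replicates of 2500 cases + 2500 controls (60 loci);
interaction-test size uses 500 replicates of 1000 + 1000 (40 loci);
stepwise calibration uses 200 replicates of 2500 + 2500 (16 loci). The
locus count is scaled per suite because those checks concern the
regression/GRE layer — the percentile distribution, not the dosage
dimension, is what matters — while dosage-level properties are tested
directly against closed-form binomial moments at 140 and other panel
sizes.

## Known limitations

* No LD structure or external-weight PRS; the score is an unweighted allele
  count by design.
* Only multiplicative-scale interaction is assessed; no additive-scale
  (RERI) or absolute-risk translation of the GRE.
* Fieller sets are reported but the bootstrap percentile interval can be
  erratic when the denominator distribution crosses zero; in that regime
  only the Fieller set is trustworthy, and it is unbounded.
* The generator's covariates are mutually independent unless the single
  confounding knob is used; real diet–lifestyle correlation structures are
  richer.

## A minimal session

```{r, eval = FALSE}
dat <- simulate_cohort(sim_config(n_cases = 2000, n_controls = 2000,
                                  seed = 1))
cohort <- add_prs(dat$cohort, dat$dosages, dat$panel)
m <- gre_fit(cc_status ~ exposure + prs_percentile + age + sex +
               family_history + colonoscopy, data = cohort)
summary(m)
confint(m, "gre")
report <- run_study(dat$cohort, dat$dosages, dat$panel, seed = 1)
report
```
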