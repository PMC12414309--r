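---
title: "Modeling night-to-night sleep variability and adolescent psychopathology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling night-to-night sleep variability and adolescent psychopathology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nightvar)
```

`nightvar` implements a two-step analysis linking adolescent psychopathology
to actigraphy-derived nightly sleep. Step one is a bifactor s-1 confirmatory
factor model of eight psychopathology facets; step two is a Bayesian
mixed-effects location-scale model (MELSM) in which each person's mean *and*
night-to-night variability of sleep duration, bedtime and waketime are
regressed on the factor scores and demographic covariates. A synthetic-cohort
generator with the same latent structure makes every stage testable offline
and drives the package's parameter-recovery experiments.

## The measurement model

Eight facets are measured by two informants (caregiver and youth): anxious/
depressed (ad), withdrawn/depressed (wd), somatic complaints (som),
oppositional defiance (odd), conduct problems (cd), hyperactivity (hyp),
inattention (at) and emotion dysregulation (eri). `aggregate_raters()`
z-scores each informant column over available cases, averages the available
z-scores per facet, and re-standardizes; a single available informant stands
alone. This available-case rule is a package choice — averaging conventions
with one missing rater are not uniquely determined by the aggregation idea.

The bifactor s-1 structure loads every indicator on a general factor of
dysregulation and psychopathology; ad/wd/som additionally load on a specific
internalizing factor and odd/cd/hyp/at on a specific externalizing factor.
Emotion dysregulation is the *reference indicator*: it loads only on the
general factor, which pins the general factor's meaning and avoids the
estimation pathologies of the symmetrical bifactor model. Factor variances
are fixed at 1 and all factor covariances at 0 — with the loading pattern and
the three modifications below, orthogonal factors are the unique
specification consistent with 10 model degrees of freedom
(36 unique moments − 15 loadings − 8 residual variances − 3 covariances).
Three structured covariances are freed: residuals of (hyp, at) and (wd, hyp),
and a covariance between the externalizing factor and the ad residual. The
last is estimated freely; we impose no sign constraint.

Estimation is full-information maximum likelihood: the casewise Gaussian
log-likelihood is accumulated per missingness pattern and maximized with a
quasi-Newton optimizer (`nlminb`), so persons with any subset of indicators
contribute exactly their observed margin. Residual variances are
unconstrained; a negative estimate (Heywood case) raises a warning rather
than being silently truncated. Fit indices use the plain ML discrepancy — no
robust (MLR-type) scaling correction is applied, because every downstream
quantity here consumes loadings and factor scores, which the correction does
not change:

* CFI $= 1 - \max(\chi^2_M - df_M, 0) / \max(\chi^2_B - df_B,\ \chi^2_M - df_M,\ 0)$,
  with an independence baseline (free variances and means, zero covariances);
* RMSEA $= \sqrt{\max(\chi^2_M - df_M, 0) / (df_M \cdot n)}$ — we use $n$,
  not $n-1$, and fix that choice for determinism;
* SRMR = root mean square of the standardized residuals over the 36 unique
  (co)variance elements, standardized by the FIML-saturated variances. The
  saturated model under missingness is estimated by an EM algorithm for the
  unrestricted multivariate normal.

Factor scores are regression-method (posterior-mean) scores,
$\hat\eta_i = \mathrm{Cov}(\eta, y_{o}) \Sigma_{oo}^{-1} (y_{o} - \mu_{o})$,
computed per missingness pattern. We prefer them to Bartlett scores because
they feed a downstream regression: when all factors' posterior-mean scores
enter jointly, the regression of an external outcome on the scores is
consistent for the latent coefficients, which is exactly how they are used
here. Persons with no observed indicator keep their row with missing scores.

## The location-scale model

For person $i$, outcome $s \in \{\text{duration, bedtime, waketime}\}$ and
observed night $t$:

$$y_{sit} = \alpha_{si} + \gamma_{s1}\,\text{night}_{it} +
            \gamma_{s2}\,\text{weekend}_{it} + \varepsilon_{sit},
  \qquad \varepsilon_{sit} \sim N(0, e^{\omega_{si}}),$$

so each person owns a mean level $\alpha_{si}$ and a log residual variance
$\omega_{si}$; the latter is the intraindividual-variability outcome, net of
the linear night trend and the weekend shift. The six-vector
$\eta_i = (\alpha_i, \omega_i)$ is multivariate normal with mean $B x_i$ —
$x_i$ stacking the three factor scores, standardized age, sex (0/1),
standardized maternal education and standardized income-to-needs — and
residual covariance $\Psi$, which correlates the six sleep outcomes at the
between-person level. Persons with no valid nights contribute only through
the between-level model and are never dropped. The within-level slopes are
fixed (non-random) effects, and within-level residuals are independent
across the three outcomes given $(\alpha_i, \omega_i)$: the between level is
where cross-outcome covariance lives, and we document this independence as a
simplification. Bedtime variability uses the same log-variance transform as
the other outcomes; the sign convention of bedtime (negative before
midnight) only shifts $\alpha$.

Priors are deliberately diffuse: $N(0, 10^6)$ on every regression
coefficient and within-level slope, inverse-Wishart with identity scale and
dimension + 1 degrees of freedom on $\Psi$. Sampling is Gibbs: the
$\alpha_i$ block, the within-level slopes, $B$ (via its Kronecker-structured
normal full conditional) and $\Psi$ are conjugate draws; $\omega_{si}$ has a
non-conjugate full conditional and uses a componentwise random-walk
Metropolis step whose step sizes adapt toward a 0.25–0.5 acceptance rate
during burn-in only, so the retained chain is a valid time-homogeneous
sampler. Two chains run by default from dispersed, seeded starts; the first
half of each chain is discarded. Convergence is monitored by the
Gelman–Rubin potential scale reduction,
$\sqrt{((L-1)/L \cdot W + B/L)/W}$; `converge_and_double()` refits with
doubled iterations until every parameter's PSR is below 1.05 (a fixed
numeric stand-in for "near 1.0"), then doubles once more as a stability
check and reports both PSR snapshots. Inference uses equal-tailed
(linear-interpolation) quantile intervals of the pooled retained draws;
an interval excluding zero is flagged "significant".

Standardized effects are computed within each retained draw as
$\beta = b \cdot SD(x)/SD(y)$, where $SD(y)$ is the model-implied SD of the
between-level outcome in that draw (explained variance from the draw's
coefficients plus its $\Psi$ diagonal element); draws with non-positive
implied variance are dropped with a recorded count. Factor scores enter the
MELSM as known predictors (the two-step approach); score uncertainty is not
propagated, a known limitation discussed below.

Missing person-level covariate cells are mean-imputed with a logged message;
missing nights are simply absent rows, and because age — which drives the
missingness in the generator and plausibly in adolescent actigraphy — is
always in the between-level design, the mechanism is missing-at-random with
respect to the model.

## The synthetic cohort

`default_paper_config()` encodes the study conditions the package is
calibrated to:

* **Measurement.** Generating standardized loadings equal the reported
  bifactor s-1 solution (eri 0.918 on the general factor). Each facet has a
  common signal plus informant-specific noise, split so that (i) the two
  informant scores correlate at `rater_reliability` and (ii) the
  re-standardized mean of the two z-scored informant reports carries exactly
  the target loadings. That split requires
  $\text{rel} \ge L/(2 - L)$ with $L = \lambda_g^2 + \lambda_s^2$; the odd
  facet ($L = 0.865$) forces rel ≥ 0.762, so the default is 0.80. This is
  higher than typical raw caregiver–youth agreement; it is the price of
  making the *aggregate* carry the published loadings exactly, and it is the
  regime in which the aggregation strategy is most defensible.
* **Between-level coefficients.** The 6 × 7 generating matrix equals the
  published unstandardized estimates (e.g. general factor →
  log-variance of duration = 0.121; sex → mean duration = −27.8 minutes).
  Demographic predictors are standardized against their generating
  distributions (age uniform on 14–18; sex Bernoulli(0.534), 1 = female;
  maternal education categorical on {10, 12, 14, 16} years matching the
  reported percentages; income-to-needs lognormal with mean 2.53, SD 1.84).
* **Scale anchors.** Intercepts put mean duration at 389.5 min, bedtime at
  −3.8 min, waketime at 463.1 min (for the reference covariate pattern), and
  $\exp(\omega_0/2)$ at the reported mean person-level SDs (79.1, 74.2,
  91.9 min). The total SDs of the $\omega$ outcomes (0.63, 1.00, 0.70) were
  chosen once from the dispersion of the reported person-level SDs after
  removing the sampling noise a ~12-night SD estimate carries; with the
  generating coefficient 0.121 this implies a standardized duration-
  variability effect of about 0.19, consistent with the published
  standardized estimate. The $\alpha$ variances are then solved from the
  target unconditional ICCs (0.17, 0.42, 0.29), and modest between-level
  residual correlations (−0.3 duration–bedtime, +0.4 bedtime–waketime,
  +0.2 duration–waketime, +0.3 among the variabilities) complete $\Psi$,
  which is checked for positive definiteness before any sampling.
* **Within-level effects.** Night trend (−0.5, +0.5, +0.2) min/night and
  weekend shifts (+15, +45, +60) min for duration/bedtime/waketime — typical
  adolescent weekend delay magnitudes. Weekend nights are those beginning
  Friday or Saturday (the nights preceding non-school days).
* **Missingness.** Per-night missingness is logistic in standardized age
  with intercept −1.90 and slope −0.3 (younger adolescents miss more),
  giving ≈ 12.1 observed nights of 14 among compliant persons; independently,
  a 34/238 fraction of persons contributes fewer than 3 nights and is masked
  by the validity filter while remaining in the analysis.

The generator draws the three nightly metrics independently given
$(\alpha_i, \omega_i)$; it does not impose the mechanical
duration ≈ waketime − bedtime constraint, does not simulate epoch-level
accelerometry or item-level questionnaires, and its facet distributions are
clean Gaussians. Passing recovery tests therefore demonstrates that the
estimators recover the stated latent structure — not that real actigraphy
data satisfy it.

## Numerical choices and problem sizes

Degenerate inputs: a cohort needs two persons with two observed nights for
the MELSM and two persons for standardization; a facet with no observed
value in either informant column is an error naming the facet; a night table
referencing an unknown person is an error naming the id. $\omega$ proposals
are clamped to ±40 to keep $e^{\omega}$ finite. The CFA optimizer retries
from a jittered start if the first run reports non-convergence; further
random starts are available and seeded.

The test-suite experiments use sizes chosen to make Monte-Carlo noise small
relative to the tolerances they assert: loading recovery at n = 2000,
fit-index calibration over 100 replicates at n = 500, coefficient recovery
and null calibration over 20 replicates of 200 persons × 14 nights with
1500 iterations × 2 chains, and ICC recovery at 500 × 14.

## Known limitations

* The two-step design (scores as known predictors) slightly understates
  posterior uncertainty. In our recovery experiments the 95% intervals for
  the headline general-factor effect are essentially nominal, but
  coefficients on the lower-reliability specific-factor scores and on
  skewed, sample-standardized covariates (income-to-needs) can dip mildly
  below nominal coverage. Joint one-step estimation would address this and
  is out of scope.
* Within-level residuals are independent across outcomes; shared nightly
  shocks (e.g. one late night moving bedtime and shortening duration) load
  onto the between-level covariances instead.
* The robust (MLR) chi-square correction is not implemented; fit indices are
  plain ML and will be liberal under strong non-normality.
* The correlated-factors supplement identifies the single-indicator
  dysregulation factor by fixing its loading to 1 and the eri residual to 5%
  of the indicator variance — a documented convention, not an estimate. The
  supplement keeps the same demographic covariates as the primary model.
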