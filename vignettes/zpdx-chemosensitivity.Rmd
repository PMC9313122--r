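---
title: "Modelling zPDX chemosensitivity: from embryo areas to avatar response calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling zPDX chemosensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(zpdxscreen)
```

## The screening problem

A zebrafish patient-derived xenograft (zPDX) screen implants fragments of a
patient's tumor into the perivitelline space of 2-dpf zebrafish embryos,
images the fluorescently stained graft at 2 hours and 48 hours post
injection, and exposes groups of embryos to chemotherapy regimens in the
fish water. Each patient contributes one avatar (a zPDX line), each avatar
spreads its embryos over five arms — an untreated control plus 5-FU, FOLFOX,
FOLFIRI and FOLFOXIRI — with on the order of ten embryos per arm. The
questions the analysis must answer are (i) whether each regimen shrinks
tumors on average, (ii) whether a *particular* avatar responds to a
*particular* regimen, and (iii) whether the avatar's call agrees with the
clinical outcome of the donor patient.

## From areas to an outcome

Only a 2-D stained area is measured. The graft is treated as a sphere whose
equatorial cross-section is the measured area, so with
$r = \sqrt{A/\pi}$ the equivalent volume is $V = \tfrac{4}{3}\pi r^3
\propto A^{3/2}$, and the percent volume change between the two timepoints is

$$\%\Delta V = 100\left[\left(\frac{A_{48h}}{A_{2h}}\right)^{3/2} - 1\right],$$

bounded below by $-100$ (complete regression). `percent_delta_v()` computes
this directly from the area ratio; the explicit volume route is exposed too
(`equivalent_radius()`, `sphere_volume()`) and the two are tested for
equality. Raw percent changes are strongly right-skewed — untreated grafts
can triple while responders bottom out at $-100$ — so the modelled outcome is

$$y = \log_{10}(\%\Delta V + 110) \ge 1,$$

which is monotone and invertible; the offset of 110 keeps the argument at
least 10 for any attainable change. A "no change" response sits at
$y_0 = \log_{10}(110) \approx 2.041$.

The sphere assumption is screened, not enforced: when start perimeters are
available, `derive_volume_changes()` computes the isoperimetric shape factor
$4\pi A/P^2$ and flags grafts below 0.6 with a warning. Flagged records are
never excluded, because circularity justifies the volume conversion rather
than defining a quality gate; the threshold is a configurable screening
convention, not an estimate.

## The mixed model

`zpdx_lmm()` fits, via `lme4`,

$$y_{ijk} = \beta_0 + \beta_{t(j)} + \gamma z_{ijk} + b_{0i} + b_{t(j),i} +
\varepsilon_{ijk},$$

with treatment (CONTROL baseline) as a five-level fixed factor, $z$ the
standardized cube of the equivalent start radius (a proxy for initial graft
volume, standardized because only its inclusion, not its scale, is part of
the design), a random intercept $b_{0i}$ per avatar and, when selected,
four per-arm random slopes $b_{ti}$. The forward stepwise selection
(`random = "auto"`) fits the intercept-only model first, then adds the
slopes, compares by a maximum-likelihood LRT (AIC optionally) and keeps the
slopes only when the data support them; ties keep the simpler model. The
reported fit uses REML.

Two structures are offered for the slope covariance. The general
(unstructured) $5\times 5$ covariance is the default, but with ~10 embryos
per arm it is frequently estimated as singular; in that case the fit falls
back automatically to a diagonal covariance with a warning, and the fallback
is recorded in the object. The diagonal structure can also be requested
directly, and is what the package's own simulation studies use, since the
generator draws uncorrelated random effects.

### Decision rules

Three per-avatar flags are derived from the fit (`avatar_calls()`):

* **significant_reduction** — the upper confidence limit of the predicted
  response for that avatar-arm lies below the no-change point $y_0$;
  equivalently the back-transformed percent volume change is confidently
  below 0. A literal comparison of the predicted interval "with 0" on the
  transformed scale would be vacuous ($y \ge 1$ always), so the package
  reads the rule as no-volume-change, the only interpretation under which
  the flag can ever fire.
* **beats_control** — the avatar-arm interval and the same avatar's control
  interval are disjoint, with the treated interval entirely lower.
* **differs_from_population** — the avatar's random effect for that arm has
  a conditional interval excluding zero (`random_effect_cis()`), i.e. the
  avatar's response deviates detectably from the cohort mean.

Predicted values add the conditional modes (BLUPs) to the fixed-part fit at
the cohort-mean covariate; the interval variance adds the fixed-effect Wald
variance and the conditional variance of the random part, including the
intercept–slope conditional covariance. The covariance between fixed
estimates and conditional modes is ignored, the standard conservative
simplification; this is recorded in the pipeline's fit metadata. Intervals
use normal quantiles: with cohorts of ~1800 embryos the residual degrees of
freedom make $t$ and normal quantiles indistinguishable.

Note one deliberate asymmetry: shifting every $y$ by a constant shifts only
the intercept and leaves contrasts, random effects and the two *relative*
flags untouched, but `significant_reduction` compares against the absolute
anchor $y_0$ and therefore moves with the outcome scale. That is inherent
to an absolute threshold, not an artifact.

### Post-hoc contrasts

`posthoc_contrasts()` computes the least-square means of the five arms at
the covariate mean and all ten pairwise differences, with family-wise
adjustment by the studentized range (Tukey HSD): $p = P\{Q_{5,\nu} \ge
\sqrt{2}\,|t|\}$ with $\nu$ the residual-df approximation
(`df = "normal"` switches to the asymptotic reference). The implementation
is from scratch and is cross-checked in the test suite against `emmeans`
with Tukey adjustment, agreeing to $10^{-6}$.

## Clustering avatars

The per-avatar slope modes form a response-profile matrix (avatars × four
regimens, on the $y$ scale); `hartigan_wong()` clusters it with a
from-scratch Hartigan–Wong k-means: optimal-transfer sweeps over all
clusters alternate with quick-transfer sweeps over each point's recorded
second-closest cluster, both using the size-weighted
$n_b d^2/(n_b+1) < n_a d^2/(n_a-1)$ test, with incremental center updates
(every accepted transfer strictly lowers the within-cluster sum of
squares). The best of 50 seeded restarts is kept, cluster ids are
canonicalized by first-occurring member, and an empty cluster during
initialization is re-seeded with the farthest point. Correctness is
anchored to an exhaustive-partition oracle on small fixtures. By default the
matrix is the four slope columns only (the intercept captures overall graft
growth, not differential drug response) and columns are not rescaled since
they already share a scale; both choices are arguments.
`cluster_avatars()` runs candidate $k \in \{4,5\}$ and reports singleton
clusters explicitly, so an outlier avatar that "clusters alone" — the
situation that motivates moving from four to five groups — is diagnosed
mechanically. `pca_project()` supplies sign-stabilized SVD scores for
display. Joint clustering of the full matrix is the default; per-regimen
grouping can be had by clustering single columns.

## Adapted RECIST classification

Independently of the mixed model, each avatar-arm is classified on the
*area* scale (the two scales are never mixed within one decision): the
arm's mean relative stained area (48h/2h per embryo, averaged — the
"mean-of-ratios" convention, with "ratio-of-means" available) is referenced
to the same avatar's control arm, and the percent change classifies as

| class | condition |
|---|---|
| PD | change $\ge +20\%$ |
| SD | $-30\% <$ change $< +20\%$ |
| PR | $-90\% <$ change $\le -30\%$ |
| CR | change $\le -90\%$ |

Boundary values are read inclusively toward the more responsive class at
$-30$ and $-90$ and toward PD at $+20$, which makes the four intervals
partition $[-100, \infty)$ exactly — the property the tests assert on a
dense grid. Arms with fewer than 5 embryos (configurable) are skipped as
low-engraftment rather than classified.

## Patient–avatar concordance

`build_pairs()` inner-joins clinical records to avatar calls on patient and
first-line regimen, logging every exclusion (no first-line therapy, regimen
not tested, no valid avatar call). Clinically administered capecitabine maps
to the 5-FU arm through an editable alias table
(`inst/extdata/regimen_aliases.csv`) — it is an oral fluoropyrimidine
metabolized to 5-FU. Agreement is summarized as percent concordance and by
`kendall_tau_b()`, a from-scratch tie-corrected Kendall rank correlation:
classes are coded in clinical-benefit order PD < SD < PR < CR (the sign of
$\tau$ depends on this coding, which is why it is fixed and documented),
$\tau_b = S/\sqrt{(n_0-n_1)(n_0-n_2)}$, and the two-sided p-value uses the
normal approximation with the full tie-corrected variance (both
higher-order joint-tie terms) and a continuity correction
$z = (|S|-1)/\sqrt{\operatorname{Var}S}$. The continuity correction
matters: on the packaged eight-pair comparison it is the difference between
$p = 0.085$ and $p = 0.058$, and the test suite pins the corrected value.
The tie-corrected variance is cross-checked against `cor.test`'s z
statistic.

The packaged co-clinical table (`coclinical_fixture()`) is a
*reconstruction*: five clinical partial responses (avatars: four PR, one
CR) and three stable diseases (avatars: two SD, one PR). Patient identities
other than the capecitabine case are synthetic labels, and the discordance
pattern is the one jointly consistent with 6/8 concordance,
$\tau = 11/\sqrt{255} = 0.689$ and $p = 0.085$.

## The synthetic cohort generator

Raw screen measurements are not publicly deposited, so `simulate_cohort()`
generates cohorts with the full statistical structure the analysis assumes,
and is itself first-class, tested code. Noise is placed on the $y$ scale —
where the model lives — and inverted through the exact pipeline transform
to end-point areas, so a simulated cohort round-trips through
`derive_volume_changes()` bit-exactly. Defaults define the study
conditions: 36 avatars × 5 arms × 10 embryos; control mean $\beta_0 = 2.18$
(≈ +41% growth, untreated grafts must grow); arm effects $-0.22$ to
$-0.30$ on the $y$ scale, which land treated arms in the SD/PR range with
rare CRs, qualitatively matching a colorectal screen's class mix; random
intercept SD 0.08 and slope SDs 0.12 (avatar heterogeneity visibly larger
than arm separation, as a patient-specific-response screen requires);
residual SD 0.15; lognormal start areas (meanlog $\log 3\times10^4$,
sdlog 0.35 — graft size distributions are unpublished, lognormal is the
conventional choice for areas spanning a factor of a few); 5% engraftment
failure. Simulated responses below $-100\%$ are clamped to complete
regression; the clamp rate is recorded and a warning fires above 5%,
because clamping bends normality in the left tail.

What the generator does *not* emulate: segmentation error correlated
between the two images of one embryo, dose–response pharmacology, death or
toxicity dropout correlated with treatment, and non-lognormal graft-size
mixtures. Passing recovery and calibration tests therefore validate the
estimator under the model's own assumptions, not robustness to real-image
artifacts.

## Calibration results and problem sizes

The test suite runs three simulation studies at the study design size
(36×5×10), chosen to keep the whole suite around two minutes: parameter
recovery over 100 seeded cohorts (mean treatment-effect error on the $y$
scale below 0.05; observed ≈ 0.006), Wald CI coverage of the four
treatment effects over 500 cohorts (each inside 93–97%), and the
family-wise type-I error of the Tukey contrasts under a global null over
1000 cohorts, asserted at ≤ 7% — the nominal 5% plus roughly three binomial
standard errors of Monte-Carlo slack at that replicate count; repeated
3000-replicate measurements place the true rate at 5–6%. The recovery and
coverage fits use the diagonal slope covariance, which matches the
generator's uncorrelated truth and avoids the singular-fit fallback inside
a tight loop. `scripts/acceptance.R` recomputes scaled versions of the same
quantities from a fresh seed.

## Numerical and degenerate-input choices

* Optimization is deterministic: no multi-start in `lme4`, seeded restarts
  in k-means, and the simulator and k-means save and restore the global RNG
  state rather than leaking it.
* A single-avatar dataset refuses to fit (random effects inestimable); an
  unknown avatar id or treatment label errors at lookup; an all-tied margin
  makes $\tau_b$ undefined and errors rather than returning NaN.
* A constant response matrix yields all-zero PCA scores with a message.
* `k = n` returns the trivial zero-WCSS solution; `k = 1` the column means.
* Percent changes at exactly $-100$ (end area 0) are valid inputs
  throughout ($y = 1$).

## Known limitations

The conditional random-effect intervals use conditional SDs from the REML
fit and do not propagate variance-component uncertainty; with 36 avatars
this is the conventional but slightly anti-conservative choice. The
significant-reduction rule tests each avatar-arm marginally, with no
multiplicity adjustment across the 144 avatar-arm combinations — by design,
since the screen's output is a per-patient report, but worth remembering
when counting flags cohort-wide. RECIST calls compare arm means without
embryo-level uncertainty, so a 5-embryo arm classifies as confidently as a
15-embryo one. The stepwise LRT uses a naive chi-squared reference at a
boundary null, which is conservative toward the intercept-only model.
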