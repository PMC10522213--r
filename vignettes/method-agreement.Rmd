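---
title: "Agreement of skinfold, bioimpedance and DXA body-fat estimates: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Agreement of skinfold, bioimpedance and DXA body-fat estimates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcagree)
```

## The problem

Percent body fat (%BF) in adult women can be estimated by dual-energy X-ray
absorptiometry (DXA, the clinical reference), by bioelectrical impedance
(BIA), or from skinfold (SF) calipers via population-specific regression
equations. The three routes disagree systematically, and skinfold
measurement itself is sensitive to who holds the caliper. `bcagree`
implements the full quantitative chain of a method-comparison study in this
setting: the prediction equations, the conversion to %BF, the agreement
statistics that compare methods pairwise and against the gold standard, and
the reliability analysis of repeated observer sessions.

## Prediction equations

Two body-density equations for adult women are implemented, both functions
of a skinfold sum (mm) and age (years, fractional allowed):

* **3-site (Jackson-Pollock-Ward)**, sum $S_3$ = triceps + suprailiac +
  medial thigh:
  $$D = 1.0994921 - 0.0009929\,S_3 + 0.0000023\,S_3^2 - 0.0001392\,\text{age}.$$
  The quadratic is strictly decreasing in $S_3$ up to its vertex at
  $0.0009929/(2 \cdot 0.0000023) \approx 215.9$ mm, far above any
  realistic 3-site sum, so density decreases with adiposity throughout the
  working range.
* **4-site (Petroski)**, sum $S_4$ = average axillary + suprailiac +
  medial thigh + medial calf:
  $$D = 1.19547130 - 0.07513507\,\log_{10} S_4 - 0.00041072\,\text{age}.$$

Density converts to %BF by the Siri two-compartment model
$\%BF = 495/D - 450$, which is exactly invertible; the package round-trips
density through %BF to within $10^{-12}$. Full double precision is carried
everywhere; rounding happens only in printed output. Very lean inputs can
drive the 3-site %BF negative — such values are *flagged* by
`check_percent_fat()` and never clipped, because clipping would bias every
downstream agreement statistic toward optimism. The subscapular site is
accepted in all input schemas although neither equation uses it: the
six-site measurement record is kept intact.

## Agreement statistics

**Lin's concordance correlation coefficient** measures agreement with the
identity line for pairs of methods where neither is privileged:
$$\hat\rho_c = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2},$$
with *n*-denominator (biased) moments as in Lin's original estimator —
descriptive SDs elsewhere in the package use the usual $n-1$ denominator;
both conventions are deliberate and documented. $\hat\rho_c$ factors into
precision (Pearson $r$) times an accuracy factor $C_b \in (0, 1]$, so
$|\hat\rho_c| \le |r|$ always. The confidence interval uses the Fisher
$z$-transform with Lin's corrected asymptotic variance
$$\sigma_Z^2 = \frac{1}{n-2}\left[\frac{(1-r^2)\rho_c^2}{(1-\rho_c^2)r^2}
 + \frac{4\rho_c^3(1-\rho_c)u^2}{r(1-\rho_c^2)^2}
 - \frac{2\rho_c^4 u^4}{r^2(1-\rho_c^2)^2}\right],
 \quad u = \frac{\bar x - \bar y}{\sqrt{s_x s_y}},$$
back-transformed to the coefficient scale. Two numerical edge cases are
handled explicitly: $\hat\rho_c = \pm 1$ makes the transform degenerate and
the CI is returned as a point mass with a warning; and perfectly collinear
but biased samples ($r = 1$, $u \neq 0$) cancel the variance exactly, so
the tiny negative residue left by floating-point cancellation is clamped to
zero. Simulation at $n = 90$ (1,000 bivariate-normal replicates, checked in
the test suite) puts empirical coverage of the 95% interval within
93–97%.

**The St. Laurent gold-standard coefficient** is used where one method
(DXA) is the reference. With deviations $D_i = \text{test}_i -
\text{gold}_i$,
$$\hat r_G = \frac{S_{GG}}{S_{GG} + S_{DD}}, \qquad
 S_{GG} = \sum_i (g_i - \bar g)^2, \quad S_{DD} = \sum_i D_i^2 .$$
$S_{DD}$ is deliberately *uncentred*: a systematic bias inflates it and
penalises agreement, exactly as a gold-standard comparison should. Although
the coefficient is sometimes described as ranging over $[-1, 1]$, this
estimator is a ratio of non-negative sums and lives in $[0, 1]$; we
implement and document that range. Its CI is a seeded percentile bootstrap
over subject pairs (default $B = 2000$): the original exact interval
construction is not reproduced in the source literature available to the
package, and the bootstrap is distribution-light, testable, and can be
replaced behind the same interface later. Percentile intervals need not
bracket the plug-in estimate at extreme values, so the interval is clamped
to contain it.

**Bland-Altman analysis** reports bias, SD of differences and limits of
agreement bias $\pm m \cdot$SD. The default multiplier is the conventional
$m = 1.96$; `run_config(reproduction_mode = TRUE)` sets $m = 2$, matching
the "two SDs from the mean" convention some studies use in figures. LoA
confidence intervals use the standard approximation
$SE = s_d\sqrt{1/n + m^2/(2(n-1))}$.

**Sample-size planning** for reliability uses Bonett's precision formula
for the ICC,
$n = \lceil 1 + 8 z_{1-\alpha/2}^2 (1-\rho)^2 (1+(k-1)\rho)^2 /
(k(k-1) w^2) \rceil$: at $\rho = 0.70$, target CI width $w = 0.20$ and
$k = 2$ raters this gives 101 subjects (some published applications quote
100 for the same inputs; the one-subject difference comes from rounding
conventions and an unstated $k$, and we keep the conservative ceiling).
Estimating the ICC from data is deliberately out of scope — the
coefficient appears here only for planning.

**Qualitative labels** ("poor"/"moderate"/"good"/"excellent") attached to
coefficients are annotation with configurable thresholds; no published
consensus defines them, and nothing downstream consumes them.

## Observer reliability

The measurement design is three passes over each subject on the same day:
observer A first (A1), observer B second, observer A again (A2), each pass
recording three caliper readings per site whose arithmetic mean is the
analysed value. Inter-observer agreement (reproducibility) compares A1
with B; intra-observer agreement (repeatability) compares A1 with A2. For
each of the triceps, suprailiac and medial thigh sites, their 3-site sum,
and the %BF derived through the 3-site density chain, Lin's CCC is
computed across subjects for both comparisons. Where the pipeline needs a
single intra-method skinfold value, it uses pass A1 (configurable).
Subjects missing any pass are dropped with a logged count, and at least
three complete subjects are required.

## What the synthetic generator emulates — and what it does not

No subject-level data ships with the package, so `generate_cohort()` and
`generate_observer_sessions()` produce seeded cohorts with the *structure*
of a reproductive-age female method-comparison study:

* **Marginals.** Ages, heights and BMI come from truncated normals (defaults:
  age mean 29.1, SD 5.0, range 18.3–37.8 y; BMI mean 26.9, SD 5.9, range
  16.1–41.4 kg/m²; weight is derived as BMI × height²). Note the BMI range
  deliberately extends beyond the nominal 18–39.9 inclusion window, as
  observed cohorts do; validation warns rather than rejects there. Skinfold
  sites are a truncated multivariate normal (every site > 2 mm, rejection
  sampling with an iteration cap) with per-site means/SDs around 18–35 mm
  and an **exchangeable correlation of 0.6** between sites. That
  correlation is a modelling default, not an empirical claim: no
  between-site correlation structure is available to calibrate against.
  The subscapular site has no published marginals in this setting, so its
  default (mean 20 mm, SD 7.5) is a choice made once for record
  completeness; it feeds no equation.
* **Method panels.** Each subject's 3-site %BF acts as the latent
  reference; DXA = latent + 5.4 + noise (SD 6.8) and BIA = latent + 0 +
  noise (SD 4.0). This reproduces the qualitative structure that motivates
  the analysis — DXA reads highest, BIA sits level with the 3-site
  estimate, the 4-site estimate reads lowest, and all paired differences
  against DXA are strongly significant at n = 90 — without inventing joint
  structure the marginals cannot support. The offsets and noise SDs are
  configuration, chosen once from the reported mean gaps and
  paired-difference spreads; this simple additive model cannot match every
  printed marginal SD simultaneously (real DXA is not latent-plus-noise),
  and no attempt is made to force it.
* **Observer error.** Readings get iid Gaussian noise (default SD 0.5 mm
  per reading, which puts intra-observer CCCs near 0.999 at realistic
  site SDs). Observer B additionally reads with a fixed per-site bias
  (largest at the suprailiac, +3.68 mm) and a subject-level random
  deviation (SDs ~1–5.6 mm by site). The subject-level term is a design
  decision: with a fixed bias alone, the inter-observer CCC ranking would
  be driven purely by bias/SD and the medial thigh would implausibly rank
  best; the extra scatter — calibrated from the observed inflation of
  observer B's per-site SDs — restores the realistic ordering in which
  the triceps is the most reproducible site.

Consequently, passing tests demonstrate that the estimators, the pipeline
and the directional structure behave correctly under a faithful stochastic
emulation — they do not certify the numeric coefficients any particular
real cohort would produce, which depend on joint features (skewness,
heteroscedastic observer error, DXA's independent error process) the
generator does not model.

## Problem sizes and numerical choices

The shipped test suite exercises: equality with independently coded
arithmetic oracles at $10^{-12}$ over hundreds of random evaluations;
Lin-CCC/moment-oracle equivalence over 1,000 random paired samples;
parameter recovery at n = 5,000 (±0.02 of the closed forms
$2\rho\sigma_1\sigma_2/(\sigma_1^2+\sigma_2^2+(\mu_1-\mu_2)^2)$ and
$\sigma_G^2/(\sigma_G^2+\sigma_D^2+\delta^2)$); CI coverage over 1,000
replicates at n = 90; LoA coverage at n = 10,000; moment convergence of
the generator at n = 20,000 (on a truncation-negligible configuration, so
the check isolates the sampling machinery from the intended truncation
shift); and the full pipeline at the study sizes n = 90 and n = 59. Ties
in the median use the average of the central order statistics. Missing
data are handled by pairwise deletion with logged counts — never
imputation. All generators and bootstraps are reproducible from explicit
integer seeds, and report emission is byte-deterministic.

## A worked run

```{r, eval = FALSE}
co <- generate_cohort(cohort_config(seed = 42))
report <- run_intermethod(co$subjects, run_config(seed = 7, boot = 500))
print(report)
write_reports(report, "out/")

subjects <- generate_cohort(reliability_cohort_config(seed = 5))$subjects
sessions <- generate_observer_sessions(subjects, observer_error_config(seed = 6))
run_reliability(sessions, subjects, run_config(seed = 8))
```

## Known limitations

* Only the two female-specific equations above; no male or alternative
  skinfold equations, and no unit auto-detection (mm, kg, m only).
* The St. Laurent CI is bootstrap-only; the exact F-based construction is
  a possible future addition behind the same interface.
* No Deming or Passing-Bablok regression, no kappa statistics, no
  repeated-measures Bland-Altman extension, no technical error of
  measurement, and no ICC estimation from data.
* The generator reproduces marginals, mean offsets and observer-error
  structure, not the full joint distribution of a real cohort; BMI
  subgroup structure is intentionally absent.
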