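---
title: "Segmentation dispersion, confidence bands and RECIST cut-offs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmentation dispersion, confidence bands and RECIST cut-offs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recistvar)
```

## The measurement model

A reader manually contours a lesion on one CT slice; the RECIST metric
is the longest chord of that contour (and, as a secondary metric, its
area). Across readers the measurement of a lesion of true size $x$
scatters with standard deviation $\sigma(x)$. The package's central
object is the empirical dispersion law: per organ and metric, ordinary
least squares of the per-tumour between-reader SD on the per-tumour
mean size,

$$\hat\sigma(s) = a + b\,s \quad (\text{linear}), \qquad
  \hat\sigma(s) = b\,s \quad (\text{through-origin}),$$

with quadratic and power forms available. Predictions are clamped at
zero: a dispersion cannot be negative, and a fitted negative value
simply means the law is extrapolating below the sizes that informed it.

The 95% uncertainty band around the stable-disease line $y = x$ at
baseline size $x$ has half-width $z\,\hat\sigma(x)$ with $z = 1.96$.
RECIST's limit lines are $y = k\,x$ with $k = 1.2$ (PD) and $k = 0.7$
(PR) for diameter; extending the limits to area via $A = \pi r^2$
squares them to $1.44$ and $0.49$. Bands overlap where the gap

$$g(x) = |k - 1|\,x - z\left[\hat\sigma(x) + B_k(x)\right] \le 0,$$

with $B_k(x)$ the half-width (divided by $z$) of the band around the
limit line. Where $g$ crosses zero is the cut-off size: above it (for a
dispersion law that grows with size) a PD or PR call is confounded by
segmentation noise.

## The two band variants

The half-width of the band carried by the limit line is genuinely
ambiguous — a limit measurement of a lesion whose baseline is $x$ has
size $k\,x$, so one can evaluate the dispersion law *at the limit value*,
$B_k(x) = \hat\sigma(k\,x)$, or *scale* the baseline dispersion,
$B_k(x) = k\,\hat\sigma(x)$. For a linear law the two differ only
through the intercept. Both are implemented (`variant = "evaluated"`,
the default, and `"scaled"`); neither is claimed to be uniquely
correct. On the bundled liver diameter summaries
($\hat\sigma(s) = 0.1675\,s - 2.99$ mm) the closed-form roots are:

| limit | evaluated | scaled |
|-------|-----------|--------|
| PD ($k=1.2$) | 22.46 mm | 24.71 mm |
| PR ($k=0.7$) | 45.45 mm | 38.63 mm |

```{r cutoffs}
ref <- reference_summary()
sub <- ref[ref$organ == "liver" & ref$metric == "diameter_mm", ]
m <- fit_sd_regression(sub$mean, sub$sd, form = "linear",
                       organ = "liver", metric = "diameter_mm")
solve_cutoff(m, recist_limits("diameter_mm"), "PD")
```

For a linear, unclamped law the root is closed-form
($x^\* = 2za/(|k-1| - zb(1+k))$ for the evaluated variant); otherwise
`solve_cutoff()` brackets a sign change on a dense grid and bisects
(`uniroot`, tolerance $10^{-10}$). The two routes agree to $10^{-6}$,
which the test suite checks explicitly. Overlap over the evaluation
range — by default the observed per-organ size range — is classified as
`none`, `above_cutoff`, `below_cutoff` or `everywhere`. `below_cutoff`
(overlap only at *small* sizes, produced by a constant or decreasing
dispersion law) has no analogue in the usual three-way description but
arises naturally, e.g. for the lung diameter summaries below.

## Regression-form defaults

`fit_sd_regression()` defaults to the linear form. The pipeline-level
default (`fit_summary_models()`) keeps linear for **diameter** but uses
the through-origin form for **area**. This is a deliberate, documented
choice: the linear fit to the bundled liver area SDs has intercept
$-0.42$ cm², i.e. a negative predicted dispersion over part of the
observed range, and under it the smallest observed areas would show no
band overlap — contradicting the qualitative result that area bands
overlap the limits at every observed liver size. The through-origin
form encodes proportional dispersion (constant coefficient of
variation), which is what the area summaries show (SD/mean ≈ 0.08–0.25
with no size trend), respects positivity, and reproduces both the
liver-area "overlap everywhere" and the lung-area "no overlap" results:

```{r report}
overlap_report(fit_summary_models(ref))
```

The lung **diameter** row is the known awkward case: the linear fit to
the seven lung summaries has a positive intercept and near-zero slope,
which makes the bands overlap *below* ~24 mm — whereas no overlap is
the expected lung result. A through-origin lung fit (slope 0.043)
yields no overlap at any size. The package does not silently switch
forms for lung diameter; the default output reports the `below_cutoff`
classification honestly and the form can be overridden via
`forms = list(diameter_mm = "through_origin")`.

The area PR multiplier is $0.7^2 = 0.49$ by construction; an
alternative printed value of $0.47$ circulates for the area PR line and
is selectable with `area_pr = "printed"`.

## The aberrant-segmentation rule

Under free slice choice (method 1) a contour is aberrant when drawn at
least two slices from the slice most often selected by all readers
(inclusive: $|\Delta| \ge 2$), or not on the pre-identified lesion.
Modal-slice ties are broken towards the median slice, then to the lower
index — the rule itself does not address ties, so this is a fixed
package convention. The wrong-target check is operationalised as a
bounding-box intersection with an optional per-lesion reference region;
with no reference supplied the check is skipped and logged. Imposed
slice contours (method 2) pass by construction.

## Agreement and tests

The intraclass correlation is computed from the two-way
repeated-measures ANOVA mean squares with tumours as subjects and
readers as random raters: ICC(2,1), absolute agreement, single rater —
readers are treated as a sample of possible observers. ICC(3,1)
(consistency) is available by argument. Bins: poor < 0.50 ≤ moderate
< 0.75 ≤ good < 0.90 ≤ excellent, with boundary values assigned to the
higher class (the conventional bin phrasing leaves the boundaries
open). Between- and within-subject SDs come from the one-way
decomposition.

The χ² independence test on the aberrant-vs-adequate split uses the
Yates continuity correction (terms $\max(0, |O-E|-\tfrac12)^2/E$); on
the 4-vs-9 split out of 260 contours per group this gives $p = 0.261$,
where the uncorrected statistic would be 1.97 ($p \approx 0.16$).

The Wilcoxon signed rank test is exact for up to 25 informative pairs —
the full null distribution of the positive-rank sum is built by dynamic
programming over doubled midranks, so ties are handled exactly — and
uses a tie- and continuity-corrected normal approximation beyond. Zero
differences are dropped. Group and method comparisons run per organ ×
metric stratum: the method comparison pairs each reader × tumour
reading across methods; the group comparison pairs per-tumour arm means
(or per-reader means by rank, as an alternative pairing — the original
pairing choice is not recoverable, so both are provided and neither is
claimed to reproduce any particular published p-value). No
multiple-testing correction is applied; all raw p-values are reported.

## The synthetic cohort generator

The generator emulates the study design: 6 liver + 7 lung lesions, 20
readers (10 physicians, 10 scientists), both methods, 520 contours.
Lesions are star-convex — a circle perturbed by 2–3 low-order Fourier
harmonics (amplitudes ≤ 0.08) — rescaled so the maximum polygon chord
equals the drawn true diameter (64 vertices). Reader variation acts
multiplicatively on the radial function: the contour is the truth
scaled by $1 + \varepsilon$, $\varepsilon \sim N(0, \sigma(d)/d)$, so
the measured diameter has SD $\sigma(d)$ and the area CV is about twice
the diameter CV, consistent with the relation between the diameter and
area dispersion summaries. A small per-vertex radial jitter (SD 0.1 mm)
roughens the boundary without materially changing the law.

Defaults, chosen once as the study conditions: liver noise law
$(a, b) = (-3, 0.17)$ mm over true diameters $U(18, 77)$ mm (the lower
edge keeps $\sigma \ge 0$); lung law $(0.3, 0)$ mm over $U(7, 49)$ mm —
small and size-independent, the regime in which lung bands never reach
the limit lines; slice jitter $(0.15, 0.7, 0.15)$ over offsets
$-1, 0, +1$ for method 1; aberrant rate 2.5% of all contours, planted
only among method-1 contours as slice offsets of 2–4 plus a spatial
displacement (a wrong-structure segmentation), either as a
Binomial(520, 0.025) count or exactly 13 (`aberrant_mode = "fixed"`)
for deterministic headline counts.

What the generator does **not** emulate: lobulated or spiculated lesion
shapes, partial-volume and reconstruction-kernel effects,
reader-specific bias (every reader is exchangeable), and correlated
errors between the two methods. Passing tests therefore demonstrate the
pipeline's statistical correctness under the stated dispersion
structure, not performance on clinical CT data. The simulated
inter-observer ICC on default cohorts is ~96–97% for diameter —
"excellent", but not calibrated to reproduce any particular published
ICC, since that depends on the exact lesion-size spread of the cohort.

## Numerical choices and degenerate inputs

* Polygon cleanup is vertex de-duplication only; a polygon still
  self-intersecting afterwards is rejected, never repaired.
* Diameters are computed over hull vertices (the polygon diameter is
  attained at vertices); the rotating-calipers scan is checked against
  the brute-force pairwise maximum on 1,000 random polygons.
* Units are fixed: vertex coordinates mm, diameters mm, areas cm²
  (conversion ÷100 inside `polygon_area()`).
* Dispersion predictions clamp at 0; bands of zero width are legal and
  produce `overlap = "none"` for a noise-free model.
* Table rendering rounds to two decimals for display only (`sprintf`
  C-rounding; 0.2539 prints as "0.25"); CSV/JSON artefacts carry full
  precision.
* Simulation sizes used by the test-suite: up to 500 replicate cohorts
  for the dispersion-law recovery check, 200 replicates for planted
  shift power and the ICC variance-components limit, 1,000 random
  polygons for the calipers equivalence.

## Known limitations

* The dispersion-law recovery check fits 6 liver lesions per cohort
  with per-tumour SDs estimated from 40 readings. The SD estimate's
  sampling error is proportional to $\sigma(d)$, i.e. strongly
  heteroscedastic across the size range, while the OLS intervals assume
  homoscedasticity: the joint 95% coverage of (intercept, slope)
  intervals is empirically ~92%, short of nominal. This is a property
  of small-cohort SD regression generally, worth remembering when
  interpreting the fitted laws' confidence intervals.
* Single lesions only: no sum-of-lesions RECIST evaluation, no
  longitudinal response classification, no volumetric extension.
* The per-tumour summary route (fitting to published summary tables)
  cannot recover reader-level quantities; agreement statistics and
  group comparisons need contour- or measurement-level input.
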