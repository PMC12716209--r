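---
title: "Screening for therapy-induced senescence with a lamin reporter: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for therapy-induced senescence with a lamin reporter: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senoscreen)
```

## The problem and the model

Therapy-induced senescence (TIS) is a durable cell-cycle arrest of cancer
cells after DNA-damaging treatment. Classical senescence stains (SA-β-Gal)
require fixation; live-cell reporters that express fluorescent lamin A and
lamin B1 fusions make senescence visible in living cultures: per-nucleus
mean intensities of both transgenic lamins rise in senescent cells, and the
tight coupling between the two channels seen in proliferating cells breaks
down.

`senoscreen` models the proliferating ("control") state as a per-cell
linear law

$$B1_i = \beta_1 A_i + \beta_0 + \varepsilon_i, \qquad
  \varepsilon_i \sim N(0, \sigma^2),$$

where $A_i$ and $B1_i$ are the per-nucleus mean intensities of the lamin A
and lamin B1 channels. A cell from any condition of the same experiment is
called **senescent** when at least one of three rules fires against the
control fit:

1. $A_i > \bar A + 2\,\mathrm{sd}(A)$ — high lamin A;
2. $B1_i > \overline{B1} + 2\,\mathrm{sd}(B1)$ — high lamin B1;
3. $B1_i$ falls outside the two-sided $1-\alpha$ **prediction band**
   $$\hat y(a) \pm t_{1-\alpha/2,\,n-2}\; s\,
     \sqrt{1 + \tfrac1n + \tfrac{(a-\bar x)^2}{S_{xx}}}$$
   — deviation from the linear correlation.

Otherwise the cell is non-senescent: within the normal intensity range and
on the control correlation. Each senescent call carries reason flags
(`high_a`, `high_b1`, `off_line` with the side of the band), so downstream
analyses can distinguish the "bright" from the "decorrelated" phenotype.

### Why a prediction band, not a confidence band

The deviation rule is stated in the source methodology only as "the 95%
confidence interval of the linear correlation". A mean-response confidence
band shrinks as $O(1/\sqrt n)$: with thousands of control cells it would
collapse onto the line and flag essentially every cell, control included.
A prediction band for a *new single observation* is the only reading under
which roughly $1-\alpha$ of control cells lie inside by construction,
independent of control size. We therefore implement the prediction band and
expose $\alpha$ (default 0.05) only for sensitivity analysis; the deviation
is two-sided, so abnormally *low* B1 at a given A also counts as deviating,
with the side recorded.

Under the three-rule OR the control's own flagged fraction is the union of
a 5% band violation and two ~2.3% upper intensity tails on two strongly
correlated channels. It is therefore bounded between ~5% (complete overlap)
and ~9.5% (no overlap); the acceptance suite verifies it stays within
4–10% on on-model populations of n = 5000 across 20 seeds.

### Regression direction and thresholds

Lamin B1 is regressed on lamin A. Lamin A is the segmentation channel and
serves as the reference measurement; this also matches how the scatter is
usually drawn (B1 against A). Both mean + 2 SD thresholds use the sample SD
(n − 1 denominator) of the *post-correction* control subset, never a pooled
or cross-experiment estimate: every experiment carries its own control, and
in the live-imaging mode every well's t = 0 image is its own control.

### Heterogeneity correction

$R^2$ of the control fit measures how homogeneous the proliferating
control is. Untreated cultures contain a small spontaneously senescent
fraction (e.g. when reaching over-confluence), which inflates the residual
scale and biases the fit. When $R^2 < 0.95$ the model is corrected by
iterative trimming: each round removes the control cells the screening
rules themselves would flag against the current fit — internally
studentized residual $|r_i| > 2$ (off the correlation) *or* intensity above
the current subset's mean + 2 SD in either channel (high lamin) — then
refits, for at most 5 rounds or until $R^2 \ge 0.95$. If the target is
never reached the last fit is kept and the model is marked
`heterogeneous`.

Trimming on the screening rules rather than on residuals alone is a
deliberate design choice. Residual-only trimming leaves behind the few
contaminants whose decorrelated B1 happens to land near the control line;
those cells sit at extreme lamin A and therefore have high leverage, and a
handful of them measurably tilts the slope. Adding the intensity-threshold
rule removes exactly the cells the classifier would call senescent anyway,
and on contaminated controls (5% decorrelated, fold-3 cells) restores the
fit of the clean subset to within OLS sampling error — the property the
acceptance suite asserts.

## Segmentation

The pipeline reproduces the standard Fiji idiom for nuclear segmentation
on the lamin A channel:

1. Gaussian blur (`blur_sigma`, default 2 px);
2. Li minimum cross-entropy threshold on the blurred image → foreground;
3. Laplacian-of-Gaussian blob response (`log_sigma`, default 8 px ≈ the
   expected nucleus radius) → local maxima → seeds, greedily suppressed to
   a minimum mutual distance (`min_seed_distance`, default 10 px), ties
   broken by (row, col) lexicographic order;
4. seeded watershed (priority flood, 4-connected, compiled) on the
   *inverted blurred* image restricted to the foreground;
5. area filter (default 50–10 000 px²) and border policy (default: drop
   nuclei touching the border).

The region-growing rule is not printed in the source methodology; a seeded
watershed constrained to the threshold foreground is the standard choice
and guarantees a partition — every foreground pixel belongs to exactly one
label. None of the numeric defaults is a published value; all are exposed
in `segmentation_config()` and should be tuned to the magnification at
hand. Coordinates are 1-based (row, column), R's native convention; areas
are raw pixel counts.

Two implementation details deserve a note:

* **Li threshold.** The iterative scheme (shift image to a zero minimum,
  start at the mean, update
  $t \leftarrow (\mu_{bg}-\mu_{fg})/(\ln\mu_{bg}-\ln\mu_{fg})$, stop at
  $|\Delta t| < 10^{-8}$) matches an independent published implementation
  to $10^{-10}$ on a frozen fixture; the test suite pins that value. The
  threshold scales with the image, which makes the whole mask invariant to
  positive rescaling of the segmentation channel (tested at ×2 and ×10).
  Constant images raise a degenerate-input error.
* **Empty-foreground guard.** A global threshold always "finds" foreground,
  even in pure noise, where it would shatter the image into hundreds of
  plausible-area watershed cells. `segmentation_config(min_separation = 4)`
  guards against this with a two-class separation index: the gap between
  foreground and background means of the blurred image divided by the
  pooled within-class SD. Blurred Gaussian noise scores ≈ 2.6 *regardless
  of its scale* (the statistic is scale-free), while scenes with genuine
  nuclei score above 5 even at one-tenth of the default contrast. Below
  the guard the segmenter reports zero nuclei.

### Partial-volume bias of pipeline masks

Mean intensities measured over a *segmentation-derived* mask are biased
low at the boundary: wherever the thresholded blurred edge sits even one
pixel outside the true nucleus, that pixel contributes background instead
of signal, shifting the per-nucleus mean by (background − signal)/area per
pixel — over an order of magnitude larger than the noise-driven standard
error $\sigma/\sqrt{\text{area}}$ at the package's default contrast. This
is a property of every global-threshold pipeline, not of this
implementation. Consequently the tight 3·SEM recovery bound in the tests
and the acceptance report is asserted for means measured over the
*ground-truth* mask (which isolates the noise model), while the
segmentation itself is held to exact count and ≤ 2 px centroid recovery.
Comparisons between conditions are unaffected, since the bias is shared;
absolute intensity calibration would require erosion or model-based edge
correction, which is out of scope.

## The synthetic stated world

The source data distributions are not published; the generator's
distributions are stand-ins chosen once for testability and realism, and
documented here rather than tuned:

* Control lamin A ~ N(100, 20²) intensity units, B1 = 0.8·A + 5 + ε.
  The default residual scale is σ = 4 (population R² ≈ 0.94, which
  *intentionally* exercises the heterogeneity-correction path on default
  populations); tests that need an on-model control within the R² ≥ 0.95
  regime use σ = 2 (R² ≈ 0.985), the configuration used for all
  calibration claims.
* Senescent cells multiply a control draw in both channels by
  `senescent_fold` (default 3); a `decorrelate_prob` subset (default 0.5)
  instead draws B1 from the scaled *marginal* control distribution,
  breaking the correlation without changing the marginals.
* All counts are deterministic: `floor(n · frac)` with membership assigned
  by a seeded shuffle — senescent counts, decorrelated subsets, marker
  positives, sorted-population compositions. This makes count-based tests
  exact instead of binomial. Intensities are redrawn until strictly
  positive (at most 100 rounds, then an error).
* Induction kinetics are logistic,
  $f(t) = b + (p-b)/(1+e^{-k(t-t_{50})})$, with the midpoint
  $(b+p)/2$ at $t_{50}$; a dose with $p = b$ is exactly constant. The
  default test kinetics (base 0.02, plateau 0.9, k = 0.1 h⁻¹, t₅₀ = 84 h
  over 0–156 h) mirror a strong-induction time course with significance
  emerging around 84 h.
* Scenes render nuclei as axis-aligned ellipses with radii jittered in
  8–12 px, non-overlapping by rejection sampling (center spacing ≥ 28 px
  by default), on a flat background of 10 with per-pixel Gaussian read
  noise; nucleus fill values are the truth-table intensities, so noise-free
  renders reproduce the truth exactly as per-mask means. A capacity error
  names the limiting parameter when placement fails.

What the generator deliberately does **not** emulate: photophysics (PSF,
bleaching, bleed-through), illumination fields, 3-D stacks, cell motion or
tracking, confluent/overlapping monolayers, and apoptosis beyond reducing
cell counts. A green test therefore establishes correctness of the
computational pipeline under its stated assumptions — not robustness to
microscope artefacts, which must be assessed on real data.

## Metrics

Validation uses the exact 2×2 confusion tabulation with "senescent" as the
positive class and
$\mathrm{accuracy} = (TN+TP)/(TN+TP+FP+FN)$. Growth is summarized by the
OLS slope of ln(count) against time, expressed in percent per unit time so
that the rule-of-70 doubling time $70/\text{rate}$ applies as printed in
the source methodology; the exact value $100\ln 2/\text{rate}$ is reported
alongside (the two differ by < 1.1% for rates ≤ 10%/unit). Constant or
shrinking cultures raise a domain error rather than returning a negative
doubling time.

## Numerical and interface choices

* Positivity is strict (`value > threshold`); a cell exactly at threshold
  is negative.
* Per-FOV marker fractions and cell-pooled per-condition fractions are both
  emitted, since dot-per-FOV plots and pooled counts answer different
  questions and the source convention is unstated.
* RNG: every simulation entry point takes an explicit seed and restores the
  caller's RNG state; sub-streams (wells, timepoints) are derived by fixed
  offsets. Identical spec + seed ⇒ bit-identical tables, scenes and report
  files.
* Serialization: cell tables are plain CSV; control models and marker
  thresholds are audit JSON; scenes are uncompressed 16-bit multi-page
  grayscale TIFF (one page per channel, order recorded in a JSON sidecar)
  plus a 16-bit label-mask TIFF. The bundled TIFF codec covers exactly that
  baseline profile and rejects anything else explicitly.

## Known limitations

* The trimming scheme is a documented stand-in: the original software's
  "correction of the used parameters" at $R^2 < 0.95$ is unspecified.
* The classifier is binary; pre- vs deep-senescence grading, soft scores
  and FACS gate optimization are out of scope.
* Segmentation is 2-D, assumes largely non-confluent monolayers, and does
  not correct illumination; foci counting inside nuclei is delegated to
  dedicated tools.
* Absolute per-nucleus intensities from pipeline masks carry the
  partial-volume bias discussed above.
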