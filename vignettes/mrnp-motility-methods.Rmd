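---
title: "Models and methods for single-molecule mRNP motility analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for single-molecule mRNP motility analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrnpmotility)
```

This vignette documents the statistical models behind the package, the
parameters that matter and their defaults, what the simulator does and does
not emulate, and the numerical choices made where more than one defensible
option existed.

## The two-color copy-number model

A dimeric adaptor can recruit one or two copies of a labeled subunit
(motor, adaptor or mRNA). When the preparation mixes two colors of label at
fractions $r$ and $g = 1 - r$, a complex with two copies shows both colors
only when its two copies happen to differ, so the observable spot
categories are

$$f_1 = s r + d r^2, \qquad f_2 = s g + d g^2, \qquad f_{12} = 2 d r g,$$

with $s + d = 1$. These sum to one identically. The inversion implemented
by `correct_copy_number()` uses the dual observable alone,

$$\hat d = \frac{f_{12}}{2 r g},$$

because with the two sum constraints the three equations are overdetermined:
$f_1$ and $f_2$ carry no information about $d$ that $f_{12}$ does not,
and they are retained instead as a model check. `consistency_check()` plugs
$\hat d$ back into the forward model and reports the $f_1$, $f_2$ residuals
and the deviation of $f_1 + f_2 + f_{12}$ from one; a persistent deficit
suggests unlabeled copies, which the model deliberately does not estimate —
the correction assumes every copy carries a label, and that assumption is
surfaced rather than patched.

Sampling noise can push $f_{12}$ above $2 r g$; the estimate is then
clipped to $[0,1]$ and flagged rather than raised as an error, since the
condition arises legitimately at small counts. Uncertainty comes from a
category-multinomial bootstrap (default $10^4$ resamples, seeded): spot
counts are resampled, each resample re-inverted, and the percentile
interval reported. Equimolar labels ($r = g = 0.5$) are the default, the
usual experimental design, making $\hat d$ exactly twice the dual fraction.

## Per-run motility statistics

**Speed** is the magnitude of the OLS slope of position against time over
the whole run. Against the alternative — net displacement over duration —
the regression uses every frame and so is far less sensitive to
localization error at the two endpoints; on noiseless tracks the two
coincide. Runs with fewer than three frames are rejected and counted.

**Run length** is the net start-to-end displacement. Pauses are not
excised and trajectories are assumed pre-segmented into single runs;
splitting or merging is out of scope.

**Color class** compares the two channels at shared frames: a run is dual
if the median inter-channel distance is within the colocalization radius,
default one camera pixel (0.1066 µm). Two channels that co-move but never
colocalize are flagged as coincident single-color runs rather than
silently merged. The median is used so a few frames of tracking glitch in
one channel cannot flip the class.

**Run frequency** is the count of runs divided by motor concentration,
total microtubule length and observation time, the normalization that makes
landing rates comparable across fields.

`summarize_runs()` computes all of this for a whole trajectory table with
grouped sufficient statistics (`rowsum()` on $n$, $\sum t$, $\sum p$,
$\sum t^2$, $\sum tp$), which is what makes $10^5$-run validation
experiments practical; a test asserts row-for-row agreement with the
scalar `estimate_speed()` / `measure_run_length()` / `classify_color()`
route so the fast path cannot drift from the reference definitions.

## Distribution fits

**Speed mixtures.** Speeds within a motor-number class are approximately
Gaussian, and a field mixing one- and two-motor complexes is bimodal, so
`fit_speed_mixture()` fits $k = 1$ and $k = 2$ Gaussian mixtures by maximum
likelihood and selects $k$ by BIC (2 parameters for $k=1$, 5 for $k=2$;
lower BIC wins, i.e. a $\Delta\mathrm{BIC} > 0$ threshold). The $k=1$ fit
is closed-form; $k=2$ uses EM with k-means initialization, 10 restarts
(later restarts jittered), convergence when the relative log-likelihood
change drops below $10^{-8}$, a cap of 500 iterations (best-so-far returned
and flagged on non-convergence), and a variance floor of $10^{-4}$ sample
SDs to exclude the degenerate one-point-spike likelihood maxima. MLE on raw
values was chosen over least squares on binned histograms to avoid
bin-width arbitrariness; the CDF-based cross-check below plays the
histogram-fit role where one is wanted. Components are reported in
increasing mean order, so label switching cannot affect downstream code.
Fits with a fixed seed are exactly reproducible; an independent
general-purpose mixture fitter reproduces the same maximized likelihood in
the test suite.

**Run lengths.** Runs shorter than the detection limit $x_0$ are never
scored, and an exponential conditioned on exceeding $x_0$ is $x_0$ plus an
exponential (memorylessness). The characteristic run length is therefore
estimated as $\hat\mu = x_0 + \overline{(\ell - x_0)}$ with
$\mathrm{se} = (\hat\mu - x_0)/\sqrt n$. Throughout the package the
*configured or reported* mean is this $\hat\mu$ — the number an exponential
fit to the survival curve would quote — not the mean of the un-truncated
law. A least-squares fit of the empirical CDF is reported alongside
(`mean_cdf`) as an independent route; the analytic se is validated against
a nonparametric bootstrap (agreement within 20% at $n \ge 100$ in the
suite). Inputs below $x_0$ are an error with the offending count named:
silently dropping them would bias $\hat\mu$ upward.

**Comparisons.** Speeds: two-sided Welch (unequal-variance) t-test —
variance equality across conditions is not defensible when motor number
changes. Run lengths: two-sample Kolmogorov–Smirnov, sensitive to the
shape differences that mean-based tests miss. Both reports carry the ratio
of means and its whole-percent difference (`percent_difference()`, half
away from zero with a floating-point guard digit), the convention in which
one condition is quoted as "53% longer" than another. Because these
p-values depend on the full per-run samples, printed p-values from summary
statistics alone are not reproducible; the tests are instead validated
against a permutation oracle (t) and a power check on known-different
exponentials (KS).

## What the simulator emulates

`simulate_field()` generates: Poisson run counts with expectation
$\text{coeff} \times \text{conc} \times L_{MT} \times T$; per-complex copy
numbers and colors from the models above; class-conditional speeds from
zero-truncated Gaussians (the physical positivity bound that plain
Gaussian fits ignore); run lengths from the truncated-exponential law;
positions $p(t_k) = v t_k + \varepsilon_k$ every 0.2 s with
$\varepsilon_k \sim N(0, \sigma_{loc}^2)$ shared across the channels of a
dual-labeled complex (a rigid complex imaged in two registered channels);
sampling until the drawn length is covered, so measured lengths are
quantized to whole frames.

Defaults and their provenance: frame interval 0.2 s and pixel 0.1066 µm
(the acquisition settings of the recordings this pipeline targets); speed
classes 0.40 ± 0.14 and 0.74 ± 0.13 µm/s and characteristic run lengths
5.8 and 8.9 µm (published one- vs two-motor fits); minimum detectable run
0.5 µm (≈5 pixels, a conventional scoring cutoff; no published value);
localization SD 0.03 µm (typical quantum-dot tracking precision; no
published value); one-/two-motor mixture weight 0.5/0.5 (population
weights are never published, only component parameters — the weight is an
explicit config parameter). All randomness flows from one seed through a
splitting scheme, so a single integer reproduces a whole pipeline run
bit-identically, and every dataset records its generating configuration.

Deliberately not modeled: PSF/camera-noise image formation, spot detection
and linking (kymographs are QC renderings, not re-detected), labeling
efficiency below one, photobleaching and blinking, pausing within runs,
run truncation at microtubule ends (runs are assumed short relative to
tracks), and diffusive events. Consequently, passing tests demonstrate
that the estimators recover the generating statistical structure — they do
not certify robustness to detection artifacts, incomplete labeling or
pause-rich trajectories, which real recordings can contain. The
`fit: drop below-x0` step in the pipeline exists precisely because frame
quantization and noise push some *measured* lengths below the cutoff even
though every *true* length exceeds it.

## Figure-condition fixtures

`generate_fixture()` regenerates the published experimental conditions —
sample sizes, class means/SDs, characteristic run lengths, copy-number
fractions — as synthetic datasets with their expected values attached
(e.g. the $n=505$ unimodal and $n=633$ bimodal speed conditions, the
22%-dual motor-counting condition, the 5.5%-dual mRNA condition). The raw
per-run measurements behind the published figures are not available, so
these printed fit parameters serve as *generating* truth for
parameter-recovery tests, never as independent targets.

## Problem sizes and numerical checks in the suite

The test suite validates, among others: dual-color fractions at $10^5$
complexes against 3-binomial-SE bands; the algebraic round trip
$d \to (f_1,f_2,f_{12}) \to \hat d$ exactly on a $d \times r$ grid;
end-to-end recovery of $d^\ast \in \{0.11, 0.44, 0.83, 0.867\}$ through
simulate → classify → count → correct at $\sim 10^5$ runs per condition
(short 0.8 µm runs to keep the trajectory tables near $10^6$ rows);
mixture $k$-selection and mean recovery over 100 regenerated fixtures;
run-length estimator bias over 500 replicates at $n = 142$; a
$10^4$-shuffle permutation oracle for the t-test; and KS detection power
over 100 seeds. These sizes were chosen to make the Monte-Carlo bands
(3 SE) decisive while keeping the full suite around two minutes on one
core.

## Known limitations

- The correction is defined for one or two copies only; three-plus copies
  or partial labeling would need a different observation model.
- BIC with $n \ge 500$ reliably separates one from two components at the
  published parameter spacings, but closely spaced components
  ($|\mu_2-\mu_1| \lesssim \sigma$) will collapse to $k=1$; no $k>2$
  option is offered.
- `estimate_speed` assumes unidirectional, single-segment runs; reversals
  or rebinding events inflate neither an error nor a flag, they simply
  lower the fitted slope.
- The bootstrap CI treats category counts as multinomial, ignoring any
  field-to-field overdispersion.
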