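# mrnpmotility

Quantitative analysis of single-molecule motility recordings of
dynein-driven mRNA transport complexes (mRNPs), with a matching stochastic
simulator. The package is aimed at single-molecule TIRF labs who track
labeled motor complexes moving along microtubules and need the standard
downstream statistics: per-run speeds and run lengths, normalized run
frequencies, one- vs two-component speed-distribution fits, exponential
run-length fits, and — centrally — the two-color correction that converts
an observed dual-color spot fraction into the true fraction of complexes
carrying two copies of a labeled subunit.

## The model

**Two-color copy-number correction.** Complexes carry one labeled copy
(fraction *s*) or two (fraction *d*, with *s* + *d* = 1); each copy is
independently color 1 with probability *r* or color 2 with probability
*g* = 1 − *r*. The observables are

    f1  = s·r + d·r²        (only color 1 visible)
    f2  = s·g + d·g²        (only color 2)
    f12 = 2·d·r·g           (both colors)

which sum to one. Single-colored spots mix one-copy complexes with two-copy
complexes whose copies happen to share a color, so the dual fraction alone
identifies the copy number:

    d = f12 / (2·r·g),    s = 1 − d.

With equimolar labels (r = g = 0.5) the dual fraction simply doubles: a 22%
dual-colored fraction implies 44% two-copy complexes. `correct_copy_number()`
performs the inversion, clips and flags estimates pushed outside [0, 1] by
sampling noise, and attaches a category-multinomial bootstrap confidence
interval when counts are supplied; `consistency_check()` verifies that the
single-color observables agree with the same *d* (they will not if, e.g.,
some copies are unlabeled).

**Motility statistics.** Speeds are the least-squares slope of position on
time over whole runs tracked at 0.2 s intervals; run lengths are net
start-to-end displacements fitted as detection-truncated exponentials
(`mean = x0 + mean(length − x0)`, `se = (mean − x0)/√n`); speed histograms
are fitted with one- or two-component Gaussian mixtures by EM, the
component count chosen by BIC — bimodal speeds are the signature of mixed
one- and two-motor populations. Conditions are compared with Welch t-tests
(speeds) and two-sample Kolmogorov–Smirnov tests (run lengths).

**Simulator.** `simulate_field()` generates whole imaging fields with the
same statistical structure: Poisson landing at a rate proportional to motor
concentration, microtubule length and time; class-conditional Gaussian
speeds (truncated at zero); exponential run lengths above a minimum
detectable length; positions sampled every frame with Gaussian localization
noise; and per-copy colors drawn from the label model, so every analysis
stage can be validated against known ground truth. `render_kymograph()`
quantizes trajectories to the 0.1066 µm camera pixel for visual QC.

**Coiled-coil geometry.** `coil_length()`, `residue_at()` and
`sum_segments()` convert between contour lengths and residue positions at
0.146 nm/residue, e.g. a 258-residue coiled-coil is 37.7 nm and a contact
16.5 nm from the N terminus maps to residue 113.

## Worked example

Simulate a field in which 44% of complexes carry two labeled dyneins, then
recover that fraction and the two-speed structure from the trajectories
alone:

```r
library(mrnpmotility)

field <- field_config(dynein_conc = 1, mt_total_length = 500,
                      duration = 100, landing_rate_coeff = 0.01)
fd <- simulate_field(field, copy_number_model(d = 0.44), label_model(),
                     motility_params(), link_dynein = TRUE, seed = 1)
runs <- summarize_runs(fd)
table(runs$color_class)
#> color1 color2   dual
#>    194    184    107

fit_speed_mixture(runs$speed_um_s, seed = 1)
#> Gaussian mixture fit (k = 2 selected by BIC)
#>   component 1: 0.396 +/- 0.147 um/s (weight 0.59)
#>   component 2: 0.746 +/- 0.132 um/s (weight 0.41)
#>   logLik 55.68, n = 485; BIC: k1 -70.8, k2 -80.4

cls <- runs$color_class
correct_copy_number(observed_fractions_from_counts(
  sum(cls == "color1"), sum(cls == "color2"), sum(cls == "dual")),
  label_model(), seed = 2)
#> Copy-number estimate: 44.1% two-copy, 55.9% one-copy
#>   95% bootstrap CI for two-copy fraction: [36.7%, 51.5%] (n = 485)
```

The mixture fitter selects two components whose means (0.40 and 0.75 µm/s)
are the one- and two-motor speed classes the simulator was configured with,
and the color-count correction returns the generating 44% two-copy fraction
with a binomial-scale confidence interval. A ready-made pipeline
(`run_pipeline()`, or `Rscript inst/cli/mrnp_pipeline.R --config cfg.yaml
--seed 1 --out outdir`) chains simulate → analyze → fit → stoichiometry and
writes CSV/JSON outputs plus a manifest sufficient to reproduce them
bit-identically.

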