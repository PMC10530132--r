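---
title: "Screening, Taguchi optimization and pellet morphometry with pelletr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening, Taguchi optimization and pellet morphometry with pelletr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pelletr)
```

## The problem

Edible fungi grown in submerged liquid culture form mycelial pellets --
roughly spherical aggregates of intertwined hyphae. For pellet production two
questions dominate: *which* medium components matter for biomass, and *at
what concentrations*; and whether the resulting pellets are round and uniform
enough to be attractive as a food product. pelletr implements the
corresponding three-stage computational chain:

1. a 12-run **Plackett-Burman screen** over ten candidate medium components,
   with a dummy-column ANOVA to separate real effects from noise;
2. a **Taguchi L9(3^4^) orthogonal-array** stage tuning the four retained
   components via larger-the-better signal-to-noise (S/N) ratios; and
3. **image morphometry** of the pellets themselves: counts, area, perimeter,
   maximal-caliper Feret diameter, circularity and the Christiansen
   uniformity coefficient.

A synthetic-data module generates both designed-experiment responses with
planted effect structure and pellet images with known ground truth, so every
stage can be benchmarked without wet-lab input.

## Screening model

Trials follow the two-level PB12 matrix: 11 balanced, mutually orthogonal
columns of +1/-1 codes over 12 trials; ten carry real factors, the eleventh
(`X11`) is left unassigned. With per-trial mean responses $\bar y_t$ (g/dL,
replicates collapsed first), a column's effect is the difference of group
means

$$\mathrm{effect}_j = \frac{1}{6}\sum_{t:\,c_{tj}=+1}\bar y_t \;-\;
  \frac{1}{6}\sum_{t:\,c_{tj}=-1}\bar y_t ,$$

its sum of squares is $SS_j = n\,\mathrm{effect}_j^2/4$ with $n = 12$ and one
degree of freedom, and each factor is tested against the dummy column's mean
square, $F_j = MS_j / MS_{\mathrm{dummy}}$, with a one-tailed upper-tail
p-value at (1, 1) df. Because the design is saturated, the eleven $SS_j$
decompose the total sum of squares of the trial means exactly (a property the
test suite asserts to 1e-9 relative tolerance).

Assumptions worth stating: effects are additive (no interactions -- PB
designs alias interactions onto main effects by construction), replicate
noise is homoscedastic, and the single dummy column is an honest error
estimate. One error degree of freedom makes the test very blunt: the
$\alpha = 0.05$ critical value of $F_{1,1}$ is about 161, and each null
factor still crosses it with 5% probability however small the noise is. The
package therefore reports effect *shares* -- each real factor's percentage of
the summed absolute effects, dummy excluded from both numerator and
denominator -- as the practical ranking alongside the significance flags.

The canonical 12-trial arrangement ships with the package; its dummy column
is the unique balanced column (up to sign) completing the ten assigned
columns to a mutually orthogonal set, with the sign fixed so the dummy's
effect on the bundled screening data is positive. A classical
cyclic-Hadamard arrangement (`pb12_design("cyclic")`) is also provided, and
every analysis function accepts any matrix that passes
`validate_design()`.

## Taguchi stage

Each L9 trial's replicates $y_1,\dots,y_n$ are condensed into the
larger-the-better S/N ratio

$$S/N = -10 \log_{10}\!\Big(\frac{1}{n}\sum_i \frac{1}{y_i^2}\Big)\ \mathrm{dB},$$

which increases with the mean and decreases with the spread; for identical
replicates it reduces to $20\log_{10} y$. Per factor, the mean S/N of the
three trials at each level is computed; the optimum picks the level with the
largest mean (exact ties break to the lowest level index, deterministically).
Factor sums of squares are $SS_i = 3\sum_k (\bar s_{ik} - \bar s)^2$ over the
three level means, $SST = \sum_t (s_t - \bar s)^2$ over trials, and
contributions are $SS_i/SST \times 100\%$; in the saturated array
$\sum_i SS_i = SST$, so contributions close to 100% before rounding. The
additive model predicts the S/N at any level combination as the grand mean
plus the selected levels' deviations from it.

When only per-trial means are available (as with the bundled printed table),
the S/N falls back to the identical-replicate form $20\log_{10}(\text{mean})$
and the fit is flagged `approximate`: replicate spread cannot be recovered
from a mean, so per-trial S/N values computed this way are not comparable to
ones computed from raw replicates.

## Morphometry

`segment()` thresholds a grayscale image (Otsu by default, dark-on-light
polarity), optionally fills enclosed holes, and labels foreground with
**8-connectivity** (run-length union-find; diagonal contact joins particles).
`measure_particles()` then reports, per particle:

* **area** -- pixel count times scale²;
* **perimeter** -- traced boundary chain with Kulpa weights (0.948 per
  straight step, 1.340 per diagonal), accurate to about 1% on smooth
  digitized outlines; plain chain weights (1, sqrt 2) are selectable;
* **Feret diameter** -- the maximal caliper: the largest pairwise distance
  over the convex hull of the particle's pixel centers, floored at one
  pixel. Empirically this sits within 2% of the true diameter for digitized
  disks of radius >= 10 px, where the pixel-corner alternative overestimates
  by ~5% at small radii. Only the maximum caliper is implemented, not the
  minimum;
* **circularity** -- $4\pi A/p^2$, clamped at 1 because discrete perimeter
  estimators overshoot slightly for near-circular shapes (a digitized disk
  should read as a circle, not 1.02). A single-pixel particle has perimeter
  4 px and Feret 1 px by convention, giving circularity $\pi/4$.

`filter_particles()` applies the particle-analysis convention of a minimum
area in calibrated units (default 0.01 mm², interpreted as area because that
is the "Size" semantics of the common particle analyzers) and an inclusive
roundness window (default 0.1--1.0) applied to the circularity value.
`uniformity_cu()` computes the Christiansen uniformity coefficient
$CU = 1 - \sum_i |x_i - \bar x| / (n\bar x)$ of the Feret diameters: 1 for
perfectly uniform sizes, scale-invariant, at most 1. `morph_summary()` adds
the five-number summary -- quartiles by linear interpolation between order
statistics (`quantile()` type 7, the common spreadsheet rule; other types
are selectable) -- and flags outliers beyond 1.5 IQR from the box edges.

Touching or overlapping pellets are *not* declumped: no watershed is
applied, so an overlapping pair counts as one particle. The practical
workflow this mirrors dilutes the sample before photographing instead.

## Synthetic data: what it does and does not emulate

`simulate_doe()` draws replicate responses from the additive effect model
plus Gaussian replicate noise, truncated to positive values by resampling
(clipping would pile probability mass at zero and bias the means). Defaults:
3 replicates per trial and Mersenne-Twister seeding, so identical seeds give
bit-identical tables.

`draw_pellet_image()` renders hard-edged disks (squares and ellipses are
available for circularity-filter tests) on a uniform background, by default
dark pellets (0.2) on a light tray (0.9) at 0.05 mm/px -- a typical macro
photograph resolution -- with diameters from a Normal(2.10, 0.52²) mm
distribution truncated positive, the distribution reported for
uniformity-optimized pellet cultures. Non-overlapping placement is
guaranteed by rejection sampling with a 2 px clearance so digitized
neighbors stay 8-disconnected.

The generator deliberately omits: hyphal "burr" texture and fuzzy pellet
boundaries, illumination gradients, camera noise beyond additive Gaussian,
partial pellets at image borders, and overlap in dense suspensions. Passing
the synthetic benchmarks therefore demonstrates the correctness of the
measurement chain (segmentation, geometry, statistics) -- it does not
certify accuracy on real photographs, where thresholding and boundary
fuzziness dominate the error budget.

## Numerical and design choices

* Effects are computed on trial **means**, not replicate-level responses:
  the screening convention this package reproduces reports one mean per
  trial, and the dummy column -- not replicate scatter -- provides the error
  term.
* Replicate SDs use the sample (n-1) convention; a single replicate reports
  SD 0.
* p-values are one-tailed upper-tail F probabilities.
* Effect shares exclude the dummy from the denominator; including it would
  shift the printed rankings by up to a percentage point.
* `pick_optimum()` and the filter bounds are deterministic and inclusive,
  respectively; tie-breaks are documented rather than random.
* Degenerate inputs error loudly (empty particle sets, all-zero effects,
  zero SST, dummy MS of exactly zero) except where a pipeline must carry
  on: a constant image yields zero particles with a warning, and a constant
  S/N table yields the tie-rule optimum with NA contributions.

Problem sizes in the test suite were chosen to keep the full run around half
a minute while leaving no property under-sampled: 2000 null simulations for
the type-I band, 200 seeds for effect-recovery bias, 100 seeds for optimum
recovery, and one 500-particle 1536² px image for the morphometry recovery
benchmark.

## Worked example

```{r screen}
fx <- load_fixture("table3")
fit <- pb_screen(pb12_design(), fx$dcw_mean)
fit$significant
glance(fit)
```

```{r taguchi}
t4 <- load_fixture("table4")
tfit <- taguchi_sn(l9_design(), sn = t4$sn)
tfit$optimum_label
tfit$predicted_sn
tidy(tfit)
```

```{r morph}
im <- draw_pellet_image(n = 50, width = 640, height = 640, scale = 0.05,
                        seed = 1)
ps <- filter_particles(measure_particles(segment(im$image), scale = 0.05))
morph_summary(ps)
```

## Known limitations

* The screening test inherits the bluntness of one error degree of freedom;
  with many factors, expect occasional false flags at $\alpha = 0.05$ even
  for pure noise. Ranking by effect share is the more stable readout.
* Means-only S/N values (the `approximate` flag) understate the spread
  component of the true S/N ratio.
* No declumping of touching pellets; dense images undercount.
* Circularity conflates "roundness" and "circularity" in the sense that the
  roundness filter operates on $4\pi A/p^2$; analyzers that define roundness
  via the major axis will filter slightly differently.
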