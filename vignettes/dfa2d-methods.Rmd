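---
title: "Two-dimensional detrended fluctuation analysis: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-dimensional detrended fluctuation analysis: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(dfa2d)
```

## The method

Detrended fluctuation analysis (DFA) quantifies long-range correlation in a
signal by how the root-mean-square residual of its integrated, locally
detrended profile grows with the observation scale.  For a series
$B(i)$, $i = 1 \dots N$, the profile is
$y(k) = \sum_{i \le k} [B(i) - \bar B]$; at window size $n$ the profile is
split into disjoint windows, a least-squares line is removed from each, and

$$F(n) = \sqrt{\tfrac{1}{nK} \textstyle\sum [y(k) - y_n(k)]^2}$$

over the $K$ complete windows.  A power law $F(n) \propto n^\alpha$ appears
as a straight line in $\log F$ vs. $\log n$, and the slope $\alpha$ is the
scaling exponent: about 0.5 for uncorrelated noise, larger for smoother,
positively correlated signals.  `dfa1d()` implements exactly this and
serves as the package's internal reference.

`dfa2d()` carries the same construction to images.  A color raster is first
collapsed to intensities with BT.601 luma weights
($0.299R + 0.587G + 0.114B$; configurable and recorded in provenance —
the exponents are affine-invariant in intensity, so any fixed convention
yields the same result for single-hue foregrounds).  The integrated surface
accumulates both directions at once:

$$y(m,n) = \sum_{i=1}^{m}\big[B(i,n) - \bar B^c_n\big]
         + \sum_{j=1}^{n}\big[B(m,j) - \bar B^r_m\big],$$

with $\bar B^c_n$ and $\bar B^r_m$ the full column and row means.  This
row-plus-column prefix form deliberately avoids the much costlier double
cumulative sum of matrix-style 2D DFA variants: each pixel's value depends
only on its row and column history, and the whole transform is two cumsum
passes.  The surface is partitioned into disjoint $s \times s$ segments
(top-left anchored, `floor` counts, trailing remainder discarded), an
additive plane $a + b\,o + c\,p$ is removed from each segment by least
squares — the two-directional analogue of linear detrending; no $op$ cross
term — and

$$F(s) = \sqrt{\tfrac{1}{M_s N_s} \textstyle\sum_{k,l} E_{k,l}}, \qquad
  E_{k,l} = \tfrac{1}{s^2} \textstyle\sum_{o,p} \text{residual}^2 .$$

Scales obey $4 \le s \le \min(M/4, N/4)$: below 4 a plane fit on $s^2$
pixels is nearly saturated, above $\min(M,N)/4$ fewer than 16 segments
remain and the segment average becomes noisy.

## Exponents and scale sets

Three slopes are fitted on $(\log s, \log F)$ by ordinary least squares,
one equally weighted point per scale (natural log internally; slopes are
log-base invariant):

* **alpha1** — every integer scale 4..11.  Eight points; this is the
  short-range exponent and the primary discriminative index for texture.
* **alpha2** — scales from 12 up to $\min(M/4, N/4)$.  The upper range can
  reach several hundred for large images, where a dense integer sweep
  buys nothing: the package evaluates about 8 log-spaced scales per octave
  (deduplicated after rounding).  The slope is insensitive to the sampling
  density; the density is configurable via `dfa_config()`.
* **alpha** — the union of both scale sets.

When fewer than two scales exist above 11 the long-range and global fits
are omitted with a warning rather than fitted on degenerate support.  A
constant image has $F \equiv 0$ at every scale and no exponent; the
analysis refuses it with a degenerate-fluctuation error.  Fluctuations
below `zero_tol` ($10^{-12}$ by default) are treated as exact zeros in
that check.

## Numerical choices

All computation is double precision.  The per-segment plane fit exploits
the orthogonality of $\{1, o - \bar o, p - \bar p\}$ on a square grid, so
coefficients are closed-form projections; residuals are then formed
explicitly and squared rather than via the one-pass sum-of-squares
identity, which keeps exactly planar segments at machine-epsilon MSE
instead of cancellation noise of order $\varepsilon \|y\|^2$.  Segment
sums use grouped row/column reductions, so one scale costs $O(MN)$ and a
full analysis of a 1020×768 image takes well under a second.  Coordinates
are 1-based, rows top-to-bottom; trailing remainder pixels are discarded
on the bottom/right only and the discarded counts are reported by
`segment_grid()`.  For convenience in small cross-check instances the
lower scale bound can be relaxed to 2 (`relax_min_scale`), but the
default enforces 4.

## The synthetic generators

The package analyses real PNG/TIFF rasters, but every claim in its test
suite is established on synthetic inputs generated in code:

* **Tiled shape images** (`shape_spec()`, `simulation_suite()`): circles
  or squares of one characteristic length $d$ (circle diameter = square
  diagonal) tiled at pitch $1.5d$ on a uniform background — white shapes
  on black, everything else on white, and a "mix" mode cycling
  red/green/blue in a seeded order.  The full factorial
  2 shapes × 6 colors × 2 sizes gives 24 images.  Full-resolution
  (3072×4080) defaults are $d = 600$ px (large) and $d = 120$ px (small);
  the default quarter-scale canvas is 768×1020.  The small class packs
  roughly 30× more shapes, so it is the geometrically *busier* image and
  gets the lower alpha1.  Squares are drawn with their diagonals along
  the image axes, sharing the circle's $d \times d$ bounding box.  This
  orientation matters and is a deliberate choice: axis-aligned square
  edges coincide with the row/column integration directions and depress
  the short-range exponent enough to drop below the circles (measured
  0.69 axis-aligned vs. 1.40 diagonal vs. 1.04 circle at quarter scale),
  whereas the diagonal orientation yields the expected contour-shape
  ordering.  Users probing orientation effects can rotate inputs.
* **fBm surfaces** (`surface_spec("fbm", H = …)`): spectral synthesis —
  white Gaussian noise shaped by the isotropic amplitude filter
  $|f|^{-(H+1)}$ (power spectrum $\propto |f|^{-2(H+1)}$), inverse FFT,
  linear rescale to 0–255.  Higher Hurst $H$ means smoother surfaces, so
  the estimated alpha1 must increase strictly with $H$; the suite checks
  this at 256×256 over 20 seeds per $H \in \{0.2, 0.5, 0.8\}$.
* **i.i.d. noise**: independent uniform intensities, the uncorrelated
  baseline (lag-1 autocorrelation checked at 512×512).

What the generators do **not** emulate: stained histology (nuclei,
chromatin texture, illumination and stain variation), JPEG artifacts, or
anisotropic real-world textures.  Passing the synthetic suite shows the
estimator is correct and well calibrated, and that the qualitative
size/shape/color behavior of the benchmark designs is reproduced; it does
not by itself validate any clinical discrimination threshold.

## Group statistics

`compare_groups()` performs the standard downstream comparison of
per-image exponents: one-way ANOVA followed by Tukey's studentized-range
test on all pairs, with the Tukey–Kramer correction for unbalanced groups
(an 18/10/10 design is the motivating shape).  Summaries report the
sample SD ($n-1$ denominator).  Exact adjusted p-values are emitted along
with significance flags at the 0.05 level (configurable).  When all
groups are internally constant but differ in mean, F is reported as
infinite with $p = 0$ and a warning instead of a division error.

## Problem sizes used by the test suite

The suite establishes oracle equivalence (naive triple-loop vs. vectorized
fluctuation, relative agreement $10^{-10}$) on images up to 32×32 over 50
seeds; calibration on 50 white-noise series of 4096 samples and 60 fBm
surfaces of 256×256; and the 24-image factorial at quarter scale.  These
sizes were chosen so the whole suite runs in about half a minute on one
core while every check retains comfortable statistical margin; all of
them scale up without code changes.

## Known limitations

* The row/column integration is a speed-motivated approximation to full
  matrix 2D DFA; exponents from the two constructions are not numerically
  interchangeable.  Double-cumulative-sum variants, detrending
  polynomials beyond the plane, sliding windows and multifractal
  generalizations are out of scope.
* alpha2 and the global alpha are frequently uninformative on
  shape-grid-like images whose fluctuation curve flattens at large
  scales; alpha1 is the index intended for discrimination.
* JPEG input requires the optional EBImage package; PNG and TIFF are
  supported natively.
* The shape generator's geometric defaults (d, pitch, backgrounds,
  square orientation, mix composition) are package choices; only the
  factorial structure and the qualitative orderings are inherent.
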