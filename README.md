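# dfa2d — two-dimensional detrended fluctuation analysis for images

`dfa2d` characterizes the fractal texture of raster images with a
two-dimensional extension of detrended fluctuation analysis (DFA).  It is
aimed at quantitative image analysts — in particular in digital pathology,
where section images of different disease states differ in textural
"busyness" — who need a single, illumination- and color-robust scaling
index per image plus the group statistics to compare cohorts.

## The method

DFA measures how the root-mean-square residual of an integrated, locally
detrended signal grows with scale.  For an `M × N` grayscale image
`B(i, j)`, the integrated surface accumulates mean-centered prefixes along
both axes:

    y(m, n) = Σ_{i≤m} [B(i, n) − B̄ⁿ_col] + Σ_{j≤n} [B(m, j) − B̄ᵐ_row]

The surface is split into disjoint `s × s` segments (`Ms = ⌊M/s⌋`,
`Ns = ⌊N/s⌋`, remainders discarded), a least-squares plane
`a + b·o + c·p` is removed from each, and the fluctuation function is

    F(s) = sqrt( (1/(Ms·Ns)) Σ_{k,l} E_{k,l} ),
    E_{k,l} = (1/s²) Σ residual²

over valid scales `4 ≤ s ≤ min(M/4, N/4)`.  A power law `F(s) ∝ s^α`
shows up as a line in log–log coordinates; the package fits

* `alpha1` — slope over the integer scales 4…11 (the short-range
  exponent, the main texture index: smooth/coarse images score high,
  busy/fine-grained images score low),
* `alpha2` — slope over log-spaced scales in `[12, min(M/4, N/4)]`,
* `alpha` — slope over the union.

Exponents are invariant under affine intensity changes `a·B + c`, which
makes the index robust to uniform recoloring and illumination gain.  The
classical 1D DFA (`dfa1d()`) is included as the conceptual reference, and
generators for benchmark shape grids, fractional Brownian surfaces and
i.i.d. noise make every claim testable without external data.  See the
methods vignette (`vignettes/dfa2d-methods.Rmd`) for the full account.

## Worked example

```r
library(dfa2d)

img <- generate_surface(surface_spec("fbm", H = 0.6, dims = c(256, 256), seed = 11))
fit <- dfa2d(img, id = "fbm-H0.6")
fit
#> 2D DFA fit of a 256 x 256 image (29 scales, s = 4..64)
#>   alpha1 = 1.1838  (s in [4, 11], 8 scales, R^2 = 0.9985)
#>   alpha2 = 1.0746  (s in [12, 64], 21 scales, R^2 = 0.9958)
#>   alpha  = 1.1063  (s in [4, 64], 29 scales, R^2 = 0.9981)
```

The Hurst parameter `H = 0.6` describes a moderately smooth surface, and
the short-range exponent `alpha1 ≈ 1.18` lands where such surfaces land on
this estimator (rough `H = 0.2` surfaces score near 0.86, smooth `H = 0.8`
near 1.41; alpha1 increases strictly with `H`).  `tidy(fit)` returns the
three fits as a tibble, `autoplot(fit)` draws the log–log curve with the
fitted slopes.

Comparing groups of images (here: three smoothness cohorts, six 128×128
surfaces each):

```r
cmp <- compare_groups(vals, alpha1, group)   # vals: tibble of alpha1 + group
cmp
#> Group comparison (one-way ANOVA + Tukey pairwise)
#>
#>   H0.3         n =  6   0.955 +/- 0.073
#>   H0.5         n =  6   1.130 +/- 0.084
#>   H0.7         n =  6   1.314 +/- 0.091
#>
#>   F(2, 15) = 28.21, p = 8.253e-06
#>   H0.5-H0.3        adj. p = 0.006197 *
#>   H0.7-H0.3        adj. p = 5.268e-06 *
#>   H0.7-H0.5        adj. p = 0.004199 *
#>   (* adjusted p < 0.05)
```

The per-group rows give mean ± SD of the exponent; the F row is the
one-way ANOVA; starred contrasts differ at the 0.05 level after the
Tukey–Kramer adjustment.

## Command line

A thin CLI wraps the same functions (installed under `exec/`):

```sh
dfa2d analyze  -i section.png -o section.json
dfa2d simulate -o sim/ --scale-factor 0.25          # the 24-image benchmark suite
dfa2d batch    -m manifest.csv -o exponents.csv --report report.json
dfa2d compare  -i exponents.csv --value alpha1 --group group
dfa2d dfa1d    -i series.txt
```

`analyze` writes one JSON document per image (exponents, diagnostics, the
full `(s, F)` table, provenance); `batch` writes a CSV row per image and a
group-comparison report, and keeps going past unreadable files.

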