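---
title: "Camouflage metrics and phylogenetic comparative methods in camophylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Camouflage metrics and phylogenetic comparative methods in camophylo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camophylo)
```

## The scientific problem

Cryptic (background-matched) coloration is expected to track the visual
properties of the substrate an animal rests on, and — where the sexes
differ in exposure to predation or in selection on signalling — to evolve
at different rates in males and females. Testing either idea across a
clade requires three ingredients that this package assembles into one
pipeline:

1. objective, calibrated measurements of color and marking pattern from
   photographs of animals and their backgrounds;
2. regression models that respect the non-independence of related
   species (phylogenetic generalized least squares with Pagel's
   $\lambda$); and
3. a symmetric line-fitting method for comparing evolutionary divergence
   between the sexes (major-axis regression on phylogenetic independent
   contrasts).

Because the motivating kind of field data set (photographs of grasshoppers
photographed on their natural backgrounds, one locality per species) is
rarely public, the package also ships a synthetic-data generator that
emulates every input, so that the full pipeline is testable and its
statistical behavior measurable.

## Image metrics

### Calibration

Cameras are assumed linear: each channel's raw value is proportional to
reflectance. `calibrate_from_gray_standards()` fits, per channel, a
least-squares straight line *through the origin* mapping the raw means of
gray-standard patches to their known reflectances, and applies it to the
image. There is no dark-offset term — the linear-sensor assumption for
RAW-derived data — and out-of-gamut results are clipped to $[0,1]$ with a
count kept in the `"clipped"` attribute. White is fixed at $(1,1,1)$ on
the $[0,1]$ reflectance scale; this makes saturation bounded by
$\sqrt 3$ and scale-free. (Whether a given study normalized channels to
$[0,1]$ or worked in raw counts changes absolute saturation values but is
immaterial for the ln-scale regressions downstream.)

### Color metrics

All four metrics are computed on the *mean* RGB of a masked region
(animal or background), which is stable to mask noise, rather than as
per-pixel metrics averaged:

* brightness $=(R+G+B)/3$ — achromatic intensity;
* saturation $=\sqrt{(1-R)^2+(1-G)^2+(1-B)^2}$ — Euclidean distance from
  pure white; large values mean little white light mixed in;
* hue1 $=R/G$ — opponent red–green ratio (high = red);
* hue2 $=(R+G)/B$ — opponent yellow–blue ratio (high = yellow).

hue1 and hue2 are undefined when the denominator channel is zero and
error out rather than returning infinities.

### Granularity (pattern-energy) analysis

Markings are analyzed on the mean of the red and green channels,
restricted to the mask's bounding box, with out-of-mask pixels filled by
the in-mask mean (the fill adds no spurious band energy). The raster is
mean-centered, zero-padded to the next power of two per axis, and Fourier
transformed; the wavelength of a frequency pair $(u, v)$ is the inverse
of the radial frequency $\sqrt{(u/W)^2+(v/H)^2}$.

The default scale bank is the field's standard: 15 band centers from 2 to
256 px in multiples of $\sqrt 2$, with band edges at geometric midpoints
(outermost edges at 2 px — the Nyquist wavelength — and 256 px). *Band
energy* is the sum of squared spectral amplitudes in the annular
wavelength band, normalized so that the energies of a complete bank plus
the out-of-bank residual equal the variance of the mean-centered raster —
an exact Parseval identity that the test suite verifies to $10^{-6}$
relative. The cited granularity literature also admits a
standard-deviation-of-filtered-image variant; it is available as
`energy = "sd"`, but the spectral-power form is the default precisely
because it makes the conservation check exact. A Hann window is available
(`hann = TRUE`) but off by default for the same reason.

Three descriptors summarize the spectrum: overall pattern contrast (total
energy), dominant marking size (the scale with maximal band energy; ties
broken toward the smallest scale so output is deterministic), and pattern
diversity (energy fraction at the dominant scale, in $(0,1]$). The
"proportion between dominant and rest" reading — max/(total − max) — is
available as `diversity = "of_rest"`; the bounded `of_total` form is the
default because it stays finite when one scale carries nearly all energy.
A constant region has zero total energy; its descriptors are flagged
undefined and the record is excluded downstream rather than silently set
to zero. Pattern analysis also requires at least 15 px/mm of resolution
(`check_pixel_scale()`); failing images keep their color metrics but are
logged and excluded from pattern metrics.

## Comparative models

### PGLS with Pagel's lambda

Under Brownian trait evolution the expected covariance of tip values is
proportional to shared branch length, $V_{ij}$ = depth of the most recent
common ancestor of tips $i,j$. The GLS estimator
$\hat\beta=(X^{\top}V^{-1}X)^{-1}X^{\top}V^{-1}y$ is computed through the
Cholesky factor of $V$ (no explicit inverse); residual variance uses the
unbiased divisor $n-p$, while the log-likelihood is evaluated at the ML
variance $r^{\top}V^{-1}r/n$.

Pagel's $\lambda$ multiplies the off-diagonal of $V$, interpolating
between a star phylogeny ($\lambda=0$, no signal) and full Brownian
covariance ($\lambda=1$). `estimate_lambda()` profiles the log-likelihood
over a 21-point grid on $[0,1]$ and refines the best cell with bounded
scalar optimization; both endpoints are admissible optima and a flat
profile triggers a warning. Estimation is by ML (not REML), matching the
default of the comparative packages this workflow mirrors.

Each study model regresses one ln animal metric on its own ln background
counterpart (never cross-metric) plus ln PDT and ln PWT, the
precipitation of the driest and wettest trimesters — covariates chosen
because they proxy substrate greenness at the times of year the animals
are active. All variables are ln-transformed, so non-positive inputs are
a validation error naming the taxon and column. Per term the package
reports the Wald $t=\hat\beta/\mathrm{SE}$ with $n-p$ residual df and a
type-II $F$ (the model with vs without the term at the fitted
$\lambda$); these are different statistics and are both printed — the
$F$ is *not* $t^2$. $R^2$ comes from GLS sums of squares against the
intercept-only model. With 17 taxa and three predictors every model
reports df $(3, 13)$.

Because each run fits 14 models, term-level p-values are adjusted by
Benjamini–Hochberg across *all term p-values of the run* (the pooling
scope is recorded in the run metadata; other poolings are defensible, and
the choice matters mainly to borderline terms).

### Independent contrasts and major-axis regression

Felsenstein's pruning algorithm produces $n-1$ standardized contrasts
that are i.i.d. with variance equal to the Brownian rate when the model
holds; the implementation rejects polytomies by default (random
zero-branch resolution is opt-in) and errors on zero-length cherries.
The classic equivalence — through-origin OLS on contrasts equals the
$\lambda=1$ PGLS slope — is used as a cross-module oracle in the tests.

Sex-specific divergence is summarized by the major-axis (MA) regression
of male contrasts on female contrasts: the line minimizing perpendicular
distances, appropriate because neither sex "predicts" the other. Fitting
is through the origin (contrasts have expectation zero; the package
records this convention as part of its output rather than centering).
Contrast signs are arbitrary, so pairs are first positivized on the
female axis — a paired sign flip that provably leaves the MA slope
unchanged. A slope above 1 means faster male divergence; under the
generator's sex-linkage model the expected slope is
$\sqrt{\text{rate ratio}}$.

The slope test statistic $r_w$ is the uncentered correlation between
residual-axis scores $v-b_0u$ and fitted-axis scores $u+b_0v$; it is
exactly zero at the fitted slope, and its t-transform with $n-1$ df gives
the p-value. The 95% confidence limits invert this test exactly: the
bounds solve a quartic in $b_0$ (found via `polyroot`), which enforces
test/interval duality by construction. When the data are too weakly
correlated to orient the axis, the interval is unbounded and the row is
flagged `independent_evolution` — reported, not suppressed, because "the
sexes' patterns evolve independently" is itself a finding.

Before fitting, pairs are screened once (no iteration) by studentized
residuals of the through-origin OLS fit of male on female contrasts,
discarding $|r|>3$. Internally studentized (standardized) residuals are
used: with the externally studentized variant the $3$-cutoff removes a
well-behaved point in roughly one sample in seven at $n=16$
($P(|t_{14}|>3)\approx 0.01$ per point), defeating the purpose of a
gross-error screen, whereas the standardized form keeps clean samples
intact about 99% of the time.

## The synthetic-data generator

`sim_study_traits()` emulates, per trait family on the ln scale:
background $\ln B = t_0 + g$ with $g$ a $\lambda$-scaled Brownian field;
female animal $\ln F = t_0 + s\,g + \varepsilon_f$ (so the
animal-on-background ln slope is exactly $s$); male animal
$\ln M = t_0 + \sqrt{\rho}\,(\ln F - t_0) + \delta$ with rate ratio
$\rho$ and an independent male increment $\delta$. Precipitation
covariates are log-normal, loaded on the background-brightness field.
Exponentiation guarantees the positivity the ln-scale analyses require,
and makes the generator's Gaussian scale coincide exactly with the
analysis scale, so parameter recovery is well-posed.

Defaults are fixed once as plausible field-study conditions: 17 taxa
(a small, fully sampled clade), unit-depth pure-birth trees,
$\lambda=1$, background rate $\sigma_{bm}=0.3$ (≈30% among-species
variation), residual rate $\sigma_{resid}=0.1$, male increment
$\sigma_{sex}=0.1$, precipitation baselines 50 mm (driest) and 600 mm
(wettest trimester) with ln-scale noise 0.3 — magnitudes typical of
seasonally dry tropical localities. `sim_pattern_image()` renders
band-limited isotropic Gaussian textures with an exactly zero-mean field
(region means recover the target color exactly) and a half-octave
spectral annulus at the requested wavelength, carried by the R and G
channels only, as granularity analysis expects.

What the generator does *not* emulate: real mask imperfections and
segmentation error, anisotropic markings, within-species variation and
unequal photograph counts, measurement error in climate covariates, and
any particular clade's trait distributions. Passing tests therefore
demonstrate that the machinery is correct and calibrated under its stated
assumptions — not that any biological conclusion from real data is
correct.

## Numerical choices and problem sizes

* Degenerate inputs error early and informatively: empty masks, < 2 gray
  standards, zero-variance standards, trees without branch lengths,
  duplicate tips, missing trait values (taxa listed), rank-deficient
  designs (collinear columns named), non-positive values under ln.
* Dominant-scale ties break toward the smallest scale; $\lambda$ ties at
  a flat profile report the boundary with a warning; MA exact fits
  ($v \equiv b_0u$) return $p=1$ with an exact-fit flag.
* The validation suite sizes its simulations to run on one CPU in a few
  minutes while keeping Monte-Carlo error well inside the asserted bands:
  $\lambda$ recovery uses 200-tip trees × 100 replicates per true value,
  the t-test size check 2,000 replicates at $n=17$, MA interval coverage
  1,000 replicates at $n=16$, and the end-to-end power/null/rate-ratio
  checks 500 replicates each.

## Known limitations

* With $\lambda$ estimated by ML at small $n$ (17 taxa), the per-term
  t-test is mildly anticonservative: the validation suite measures a
  rejection rate slightly above 7% at nominal 5% under the Brownian null,
  while the same test at a known $\lambda$ is exactly calibrated. This is
  a documented property of PGLS with estimated $\lambda$, worth
  remembering when interpreting borderline p-values at this sample size.
* MA regression assumes comparable error variance on both axes; it is the
  right summary for contrasts of equally-measured traits but not a causal
  regression.
* The granularity descriptors are isotropic by construction; oriented
  pattern statistics, edge-disruption metrics and visual-acuity
  corrections are out of scope, as are receptor-noise visual models — all
  metrics are defined in the camera's (human-visible) color space.
* Aggregation of individuals to species values is an unweighted mean (or
  median) per taxon × sex; weighting by per-species sample size is not
  attempted.

## Repository layout

The package exposes every computation as functions (this is what the
tests and the validation script exercise); the `analysis/` directory
holds four numbered narrative drivers — simulate, image metrics,
comparative analyses, rate-divergence experiment — that run the same
functions on the synthetic study and write their tables under
`results/`. This analysis-workflow shape was chosen because the artifact
is a study pipeline rather than a general-purpose library.
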