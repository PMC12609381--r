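---
title: "Egg-shaped fruit geometry from 2D profiles: model, pipeline and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Egg-shaped fruit geometry from 2D profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovogeom)
library(ggplot2)
```

## The model

Many fruits — egg-shaped tomato cultivars among them — are close to solids
of revolution: rotating their 2D profile about the pedicel–blossom axis
reproduces the 3D body. When that holds, a single calibrated photograph is
enough to estimate volume and surface area, replacing destructive water
displacement and expensive 3D scanning.

`ovogeom` models the half-profile with the explicit Preston equation (EPE),
an ellipse modulated by a cubic polynomial in the relative position
$u = x/b$:

$$y(x) = \pm\, a \sqrt{1 - u^2}\,\bigl(1 + c_1 u + c_2 u^2 + c_3 u^3\bigr),
 \qquad u = x/b,\; x \in [-b, b].$$

The $\pm$ branches are the upper and lower profile halves. The five
parameters have direct meanings: $a$ (cm) is approximately half the maximum
width, $b$ (cm) is half the length, and $c_1, c_2, c_3$ (dimensionless)
encode asymmetry and taper — all zero gives a spheroid; $c_1, c_3$ break
the left–right symmetry (pedicel vs blossom end). Parameters are valid when
the cubic factor stays strictly positive on $[-b, b]$, so the curve is a
simple closed profile; validity is checked on a fixed 2001-point grid in
$u$, which is exact enough for the coefficient magnitudes real fruit
exhibit ($|c_i| \lesssim 0.2$).

Because the polynomial multiplies the ellipse term, the solid-of-revolution
volume has a closed form,

$$V = \pi\int_{-b}^{b} y^2\,dx
 = \frac{4\pi}{315}\,a^2 b\,(105 + 21c_1^2 + 42c_2 + 9c_2^2 +
   18c_1c_3 + 5c_3^2),$$

which `volume_closed_form()` implements and `volume_quadrature()`
cross-checks by adaptive quadrature (the two agree to $10^{-8}$ relative
across the supported parameter domain; the suite verifies this on random
draws). The surface area

$$S = 2\pi\int_{-b}^{b} y \sqrt{1 + (dy/dx)^2}\,dx$$

has no convenient closed form. Its integrand is finite at the tips (where
$y \to 0$ while $y' \to \infty$), but the slope singularity defeats naive
quadrature, so `surface_area()` substitutes $x = b\sin t$: the surface
element becomes $y(t)\sqrt{(dx/dt)^2+(dy/dt)^2}\,dt$, smooth on
$[-\pi/2, \pi/2]$. Quadrature tolerances are fixed (relative $10^{-10}$)
rather than user-configurable: the geometry layer serves as the oracle for
the statistics above it and must be dependable.

Two limits anchor the implementation: the sphere ($a=b$, $c=0$) gives
$V = \tfrac{4}{3}\pi a^3$, $S = 4\pi a^2$ exactly, and any isometric family
(one shape scaled by $k$) obeys $S \propto V^{2/3}$ to machine precision —
the theoretical exponent that observed fruit cohorts, which vary in shape
as well as size, deviate from.

```{r isometric}
p <- epe_params(1.4, 1.6, 0.1, -0.05, 0.02)
fam <- purrr::map_dfr(seq(0.5, 2, length.out = 30), function(k) {
  q <- epe_params(k * p$a, k * p$b, p$c1, p$c2, p$c3)
  tibble::tibble(v = volume_closed_form(q), s = surface_area(q))
})
ols_with_ci(fam, v, s, scale = "log10")$slope # 2/3
```

## The digitization pipeline

`digitize_image()` emulates the photographic chain: a binary silhouette
(PNG, fruit phase auto-detected as the one not touching the border), outer
boundary extraction by Moore-neighbour contour tracing of the largest
connected component, scale calibration from a caliper length
(`scale = length / longest pixel chord`, the same factor in both axes),
and standardization.

`standardize_profile()` puts every profile in the frame the model assumes:
length axis on x, centered at the origin, resampled to 1000 (by default)
arc-length-equidistant points, counterclockwise from the leftmost point.
Design choices worth recording:

* **Axis by second moments, not the longest chord.** The longest-chord
  direction of a noisy, nearly round outline is ill-conditioned — its
  angle error grows like $\sqrt{\text{noise}/(L-W)}$, and tilts of 0.1–0.2
  rad appear at realistic noise on cohorts with $W/L \approx 0.9$. A
  tilted ellipse is outside the EPE family, so such tilts inflate fit
  errors several-fold. The principal axis of the boundary points averages
  every point and is exact for clean profiles. The longest chord is still
  what scale calibration uses, preserving the caliper-length semantics.
* **Alignment is not re-optimized during fitting**; the fit estimates the
  five EPE parameters only.
* **Centering**: tip midpoint in x; boundary centroid in y (the revolution
  axis of a mirror-symmetric profile sampled uniformly in arc length).
* **Resampling** interpolates linearly along the polygon; equidistance is
  within a max/min spacing ratio of 1.1, and exact on the polygon itself.
* **Idempotence**: a profile that is already standardized is returned
  unchanged. A second resampling pass cannot be an exact fixed point
  (chord length is not arc length, drift $\sim 10^{-6}$ cm at $n=1000$),
  so idempotence is guaranteed by recognising the canonical frame, not by
  re-running the transform.
* **No smoothing** of the boundary by default; the raw traced chain is
  what gets fitted.
* The pipeline assumes prolate fruit ($W \le L$): the silhouette's major
  axis is taken to be the revolution (length) axis, matching how fruit are
  positioned for photography. Oblate shapes would be rotated 90° and
  mis-measured; the cultivars this emulates have $W/L$ 0.89–0.97.

At 600 dpi (the default rendering scale, 2.54/600 cm per pixel) pixel
quantization biases recovered volumes by about $-0.4\%$; the full
render → trace → calibrate → standardize → fit round trip recovers volume
within 2%.

## Fitting and the adjusted RMSE

`fit_epe()` minimizes the residual sum of squares between observed and
predicted y-values with Nelder–Mead, as is standard for this model family.
Branch assignment follows the sign of the observed y (zero goes to the
upper branch). Since the simplex is a local optimizer, the fit starts from
`initial_params()` ($a$ = max height, $b$ = half the x-extent, $c$'s zero)
plus four restarts with the $c$'s jittered uniformly in $\pm 0.05$ under a
fixed seed (default 20241106); each start gets a second polishing pass and
the lowest RSS wins. Points that stray marginally beyond the current $b$
during optimization incur a smooth penalty rather than an error, keeping
the objective continuous. Convergence uses an absolute tolerance of
$10^{-10}$ on the RSS alongside a relative tolerance of $10^{-12}$, with
up to 5000 simplex iterations per pass; a degenerate-simplex code on the
polishing pass after a converged first pass is treated as convergence.

Fits are scored by the width-adjusted RMSE,

$$\mathrm{RMSE}_{adj} = \frac{\sqrt{\tfrac{1}{n}\sum_i (y_i - \hat y_i)^2}}
  {W/2},$$

with $W$ the fitted maximum width, making the score dimensionless and
unit-invariant; values below 0.05 conventionally indicate a good fit (mean
profile deviation under 5% of the half-width). Noiseless synthetic
profiles are recovered to 0.1% in $a, b$ and 0.005 absolute in the $c$'s.

## The synthetic cohorts

`generate_cohort()` draws complete study cohorts so the whole pipeline is
testable without fruit: EPE parameters per cultivar-like preset, noisy
digitized profiles, rendered silhouettes on demand, and simulated
water-displacement readings. Presets emulate three egg-shaped tomato
cultivars — cherry ($n=297$, median $W/L$ 0.90, $V$ 10.3–23.7 cm³),
Qianxi ($n=320$, 0.89, 9.9–30.9 cm³) and truss ($n=300$, 0.97,
5.0–12.1 cm³). With $a, b$ independent uniforms the presets are calibrated
to bracket those medians and ranges; they are convenience defaults, not
estimates of the true within-cultivar distributions (which are not
published). All randomness uses R's default Mersenne–Twister generator
under a mandatory per-spec seed; cohorts and written CSV bundles are
byte-reproducible.

Three error models, each a deliberate choice:

* **Digitization noise** is radial (from the profile centroid — boundary
  error acts along the silhouette normal) with pointwise sd
  `radial_noise_frac * a` (default 1%), but *smooth along the contour*: a
  random combination of the first 20 Fourier harmonics in contour
  position, scaled to the requested marginal sd. Multi-pixel boundary
  error comes from blur, shadows and thresholding, which displace the
  traced contour coherently over many pixels; independent per-point jumps
  of ~3 px between samples spaced ~0.4 px apart would be a physical
  impossibility and, incidentally, push fits far outside the good-fit
  regime. With the smooth field at 1% noise, cohort median
  $\mathrm{RMSE}_{adj}$ is ≈ 0.026 with 95–100% of fits below 0.05 —
  the regime real cohorts of these cultivars show (medians 0.026–0.048).
  Twenty harmonics put the correlation scale at a few percent of the
  perimeter; the EPE's five parameters cannot absorb such wiggles, so the
  injected amplitude is what the fit sees. What this generator does *not*
  emulate: locally rough or damaged fruit surfaces, pixel-level
  quantization (exercised separately via `render_image()`), and
  perspective/lens distortion. Passing tests therefore show pipeline
  correctness under a plausible error model, not performance on any real
  cultivar.
* **Volume measurement**: multiplicative Gaussian noise (default sd 2%)
  then rounding to the cylinder graduation (default 1 cm³, an optimistic
  reading of a 250 mL cylinder; configurable because coarse graduation is
  a real sensitivity for small fruit, where a one-graduation error is
  already ~10–20%).
* **Truncation**: shape coefficients are redrawn (up to 100 times) until
  the cubic factor is positive, so every generated fruit is geometrically
  valid.

## The statistical layer

`ols_with_ci()` is ordinary least squares with a t-based slope confidence
interval, on the linear or log10 scale; log-base choice does not affect
slopes, intervals or $r^2$. `allometric_fits()` estimates the three
power laws of the analysis — $S \propto V_{obs}^{\beta}$,
$V_{pred} \propto (LW^2)^{\beta}$, $S \propto (LW^2)^{\beta}$ — as
log–log slopes with intervals. Predicted-vs-observed volume is analyzed on
the linear scale; the log–log scale is reserved for the allometric fits.
The intercept is always estimated, and no multiplicity correction is
applied across response variables beyond Tukey's own adjustment, matching
standard practice for this kind of cohort description.

`revolution_test()` declares a cohort consistent with a solid of
revolution when the 95% CI of the volume-agreement slope includes 1. Which
variable is the regressor matters more than it looks: the
water-displacement measurement is the noisy one, and OLS assumes an
error-free predictor. Regressing $V_{pred}$ on $V_{obs}$ attenuates the
slope below 1 (classical errors-in-variables bias) by roughly
$\sigma^2_{obs}/\mathrm{Var}(V)$ — with a 300-fruit cohort's narrow CI,
a *perfect* solid of revolution is then rejected most of the time
(simulated strict-CI coverage ~32%, vs ~94% with the directions the other
way). The default is therefore `v_obs ~ v_pred`; the attenuation-prone
direction is available as `direction = "pred_on_obs"` for comparison with
published analyses, which often report slope CIs slightly below 1 for
exactly this reason. Because a tight CI just under 1 is still treated as
revolution-like in practice, a second verdict accepts intervals lying
within a configurable band around 1 (default ±0.1).

`group_compare()` wraps one-way ANOVA with Tukey HSD pairwise comparisons
and renders a compact letter display by the insert–absorb method from the
Tukey-adjusted p-values (keeping letters consistent with the reported
pairwise table), plus the per-group coefficient of variation.

## Problem sizes and reproducibility

The shipped test suite and the acceptance script run the study conditions
at sizes chosen to exercise every claim while staying quick on a single
core: 30-size isometric families, 100-shape quadrature cross-checks,
50-shape noiseless recovery, one 300-fruit noisy cohort with full fitting,
50 replicate cohorts for CI coverage, and 20 silhouette round trips at
600 dpi. `run_study()` writes its configuration verbatim into the output
bundle, formats all CSV numbers to 6 significant digits, and reproduces
every output byte-for-byte under a fixed seed.

## Known limitations

* The solid-of-revolution assumption is untestable from a single view;
  cohorts whose cross-sections are elliptic will pass the profile fit yet
  mis-estimate volume. No cross-section correction is attempted.
* The EPE cannot represent a tilted profile; alignment errors upstream
  become shape errors downstream.
* Presets pin only published medians and ranges; within-cultivar
  covariance of size and shape is invented (independent uniforms).
* The banded revolution verdict is a pragmatic device, not a formal test;
  its width is a user choice.
* Only PNG silhouettes are read; upstream color segmentation is out of
  scope.
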