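# ovogeom

Volume and surface area of egg-shaped fruit from a single calibrated
photograph.

Fruit volume and surface area predict size and quality better than length
and width, but measuring them directly is destructive (water displacement)
or expensive (3D scanning). For fruit that are solids of revolution — many
egg-shaped tomato cultivars, melons, olives — one 2D profile suffices.
`ovogeom` is for plant scientists, breeders and postharvest engineers who
want that pipeline end to end in R: digitize a binary silhouette, fit a
parametric egg curve, compute the rotation solid's volume and surface
area, and run the cohort-level statistics that validate the approach.

## The model

The half-profile is the explicit Preston equation (EPE), an ellipse
modulated by a cubic in the relative position `u = x/b`:

```
y(x) = ± a √(1 − u²) (1 + c₁u + c₂u² + c₃u³),   u = x/b,  x ∈ [−b, b]
```

`a` ≈ half the maximum width, `b` = half the length (cm); `c₁, c₂, c₃`
capture asymmetry and taper. Rotating the profile about its length axis
gives a closed-form volume

```
V = (4π/315) a²b (105 + 21c₁² + 42c₂ + 9c₂² + 18c₁c₃ + 5c₃²)
```

and a surface-area integral `S = 2π ∫ y √(1 + y′²) dx` evaluated by
singularity-free quadrature. Fits are scored by the width-adjusted RMSE
(root-mean-square y-residual over half the maximum width); values below
0.05 indicate a good fit. For any isometrically scaled shape, S ∝ V^(2/3)
exactly; observed cohorts, which vary in shape as well as size, show
smaller exponents.

## Worked example

Geometry of one fruit shape:

```r
library(ovogeom)
p <- epe_params(a = 1.4, b = 1.6, c1 = 0.1, c2 = -0.05, c3 = 0.02)
shape_metrics(p)
#> # A tibble: 1 × 5
#>   v_pred     s     l     w w_over_l
#>    <dbl> <dbl> <dbl> <dbl>    <dbl>
#> 1   12.9  26.7   3.2  2.81    0.879
```

A 12.9 cm³, 26.7 cm² fruit, 3.2 cm long, slightly elongated
(W/L = 0.88). A synthetic cherry-tomato cohort, fitted and analyzed:

```r
spec   <- cultivar_preset("cherry", n_fruits = 60, seed = 42)
cohort <- generate_cohort(spec)   # noisy profiles + simulated V_obs
fits   <- fit_cohort(cohort)      # Nelder-Mead EPE fit per fruit

glance(fit_epe(cohort$profile[[1]]))
#> # A tibble: 1 × 6
#>     rss rmse_adj n_points converged n_iterations good_fit
#>   <dbl>    <dbl>    <int> <lgl>            <int> <lgl>
#> 1  1.08   0.0194     1000 TRUE              3944 TRUE

revolution_test(fits)
#> # A tibble: 1 × 11
#>   slope intercept slope_ci_low slope_ci_high r_squared     n  p_value scale
#>   <dbl>     <dbl>        <dbl>         <dbl>     <dbl> <int>    <dbl> <chr>
#> 1  1.00     0.144        0.955          1.05     0.967    60 8.58e-45 linear
#> # ℹ 3 more variables: verdict_strict <lgl>, verdict_band <lgl>, band <dbl>
```

The fit is good (RMSE_adj = 0.019 < 0.05) and the slope CI
[0.955, 1.05] contains 1: the cohort behaves as solids of revolution.
Allometric scaling across the cohort:

```r
allometric_fits(fits)
#> # A tibble: 3 × 9
#>   relation      slope intercept slope_ci_low slope_ci_high r_squared     n
#> 1 s_vs_v_obs    0.635     0.720        0.604         0.667     0.966    60
#> 2 v_pred_vs_lw2 0.988    -0.271        0.964         1.01      0.992    60
#> 3 s_vs_lw2      0.654     0.512        0.638         0.670     0.991    60
```

Surface area scales as V_obs^0.64 — below the isometric 2/3 because the
cohort varies in shape, not just size. `run_study()` wraps the whole chain
(simulate or read profiles → fit → analyze) into one reproducible output
bundle; `autoplot()` on a fit overlays the fitted curve on the digitized
profile; `digitize_image()` takes a PNG silhouette plus a caliper length
to a standardized profile.

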