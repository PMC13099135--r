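# layervein

Layer-resolved (laminar) fMRI analysis with velocity-nulling gradients,
for researchers who need depth-specific BOLD activity and connectivity
from gradient-echo EPI despite draining-vein contamination.

## The problem and the model

Ascending cortical veins carry BOLD signal from deep layers toward the
pial surface, blurring depth profiles upward and inflating correlations
between depth bins that share drained blood rather than neural activity.
A small bipolar **velocity-nulling (VN)** gradient exploits the fact that
blood in a vessel network dephases like a pseudo-diffusion process (IVIM)
with coefficient

    D* = L * v / 10

where `L` is the mean vessel segment length and `v` the blood velocity:
capillaries (`L` = 100 µm, `v` = 1 mm/s) give `D* = 1e-8` m²/s, penetrating
veins (`L` = 1 mm, `v` = 2.5 mm/s) `2.5e-7`, arteries (`v` = 12 mm/s)
`1.2e-6`. Signal retention under diffusion weighting `b` is
`S/S0 = exp(-b (D* + D_blood)) ≈ exp(-b D*)`, so a small `b` suppresses
fast vein/artery signal while sparing capillaries — at `b = 7` s/mm²,
veins keep 17% of their signal and capillaries 93%.

The package implements, in idiomatic tidyverse R:

- **Gradient design**: compartment attenuation curves, the rectangular
  Stejskal–Tanner bipolar b-value `(2πγ)² G² δ² (Δ − δ/3)`, and the
  critical velocity `1/(2γGΔδ)` at which the bipolar pair accrues π
  radians of flow phase.
- **A synthetic laminar generator** with planted ground truth: double-peak
  neural depth profiles, an explicit lower-triangular draining-vein
  leakage operator `K = I + αW` with linearly increasing vein density,
  compartment-specific VN retention, double-gamma HRF block responses at
  TR = 4 s, magnitude-correlated macrovascular phase, and band-limited
  (0.01–0.1 Hz) resting-state series with an exact target covariance.
- **Phase regression**: temporal phase unwrapping and per-voxel OLS
  removal of the phase-coupled (macrovascular) magnitude component.
- **Depth profiles**: nearest-neighbour upsampling, 20 equidistant layers
  over normalised depth [−0.125, 1.0625], layer-averaged series, and
  per-layer GLM activation profiles in percent signal change with 95% CIs.
- **Layer FC**: zero-phase Butterworth filtering, layer-specific seed time
  courses by projection range, seed FC maps, intracortical depth×depth and
  ROI-pair depth Fisher-z matrices, and element-wise group t-tests with
  Benjamini–Hochberg FDR control.

## Worked example

```r
library(layervein)

# Which b suppresses veins below 20% while keeping capillaries above 90%?
curve <- attenuation_curves(preset_compartments(), seq(0, 10, by = 1))
recommend_b(curve, vein_max_retention = 0.2, capillary_min_retention = 0.9)
#> # A tibble: 4 × 3
#>       b vein_retention capillary_retention
#>   <dbl>          <dbl>               <dbl>
#> 1     7         0.174                0.932
#> 2     8         0.135                0.923
#> 3     9         0.105                0.914
#> 4    10         0.0821               0.905

# A concrete gradient realisation and its critical velocity
vn_gradient_spec(G = 40e-3, delta = 2e-3, Delta = 3e-3)
#> <vn_gradient_spec> G = 40 mT/m, delta = 2 ms, Delta = 3 ms, gamma = 42.58 MHz/T
#>   b = 1.069 s/mm^2, critical velocity = 48.9 mm/s

# End-to-end synthetic demonstration: simulate drainage, clean, recover
run_demo_pipeline(demo_config(seed = 1))
#> <vn_demo_report>
#>   b = 7 s/mm^2: vein retention 0.174, capillary retention 0.932
#>   profile-truth correlation: 0.964
#>   superficial inter-layer mean z: b0 0.961 vs VN 0.128
#>   checks passed: 5/5 ()
```

The admissible interval says `b = 7` s/mm² is the smallest grid value
meeting both thresholds — the sensitivity/specificity compromise. In the
demo, a double-peak neural profile pushed through drainage (α = 0.3) and
noise is recovered with correlation 0.96 to the planted truth after VN
retention and phase regression, and the mean superficial inter-layer
Fisher z drops from 0.96 (no VN, drainage intact) to 0.13 (VN applied) —
the paired group test across 14 synthetic subjects flags that reduction at
FDR q < 0.05.

Every result type has `autoplot()` (attenuation curves, depth profiles,
depth FC matrices, group tests), and fitted objects have broom-style
`tidy()`/`glance()` methods. A thin command-line wrapper is installed at
`exec/layervein` with subcommands `design-b`, `synth`, `phase-regress`,
`profile`, `fc`, and `demo`.

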