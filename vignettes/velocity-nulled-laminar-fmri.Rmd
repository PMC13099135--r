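---
title: "Velocity-nulled laminar fMRI: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Velocity-nulled laminar fMRI: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(layervein)
library(ggplot2)
```

## The problem

Gradient-echo BOLD fMRI measures cortical activity through its vascular
response, but the venous side of that response is not local: ascending
(penetrating) veins carry deoxyhemoglobin-weighted blood from deep cortical
layers toward the pial surface, so a voxel in the superficial cortex
contains BOLD signal that originated several layers below it. This upward
"draining-vein" blurring is the main obstacle to resolving layer-specific
activity and layer-specific functional connectivity (FC) with GE-EPI.

`layervein` implements the computational side of one countermeasure:
a small bipolar *velocity-nulling* (VN) diffusion gradient that
preferentially dephases fast-flowing spins in larger vessels, plus
*phase regression* against the macrovascular phase signal, followed by the
depth-resolved analysis chain (equidistant layering, layer-wise GLM
profiles, depth-by-depth FC matrices with group statistics). Because
in-vivo data cannot validate layer specificity directly — ground truth is
unknown — the package pairs the analysis chain with a forward simulator in
which the truth is planted and recovery can be measured.

## Vascular attenuation model

Blood moving through a randomly oriented vessel network loses coherence
under a diffusion gradient like a pseudo-diffusion process (the intravoxel
incoherent motion, IVIM, picture): the mean displacement equals the mean
vessel segment length \(L\) and the speed matches the blood velocity
\(v\), giving a pseudo-diffusion coefficient

\[ D^* = \tfrac{1}{10}\, L\, v . \]

The \(1/10\) proportionality constant reproduces the standard compartment
values — capillaries (\(L = 100\,\mu m\), \(v = 1\) mm/s,
\(D^* = 10^{-8}\) m\(^2\)/s), penetrating veins (\(L = 1\) mm,
\(v = 2.5\) mm/s, \(D^* = 2.5\times10^{-7}\)), arteries (\(v = 12\) mm/s,
\(D^* = 1.2\times10^{-6}\)). The random-walk IVIM convention \(L v / 6\)
found elsewhere in the literature is available through the `scale`
argument; we default to \(1/10\) for consistency with the compartment
values above, and expose the choice rather than hide it.

Signal retention under a b-value \(b\) follows
\(S/S_0 = \exp[-b\,(D^* + D_{blood})]\), simplified to
\(\exp(-b\,D^*)\) since \(D^* \gg D_{blood}\) for all flowing pools
(\(D_{blood} = 1.5\times10^{-9}\) m\(^2\)/s, typical blood water at body
temperature, is the default and is overridable). Units: `b` is entered and
reported in s/mm², coefficients in m²/s; one conversion constant (1e6)
lives in a single place in the code.

```{r attenuation}
curve <- attenuation_curves(preset_compartments(), seq(0, 10, by = 0.25))
autoplot(curve)
recommend_b(curve, vein_max_retention = 0.2, capillary_min_retention = 0.9)
```

At \(b = 7\) s/mm² the vein pool retains `r round(vn_attenuation(7,
preset_compartments()$vein), 3)` of its signal while capillaries keep
`r round(vn_attenuation(7, preset_compartments()$capillary), 3)` — the
selectivity window the VN gradient exploits.

Two gradient-design helpers connect hardware parameters to these numbers:
the rectangular-lobe Stejskal–Tanner b-value
\(b = (2\pi\gamma)^2 G^2 \delta^2 (\Delta - \delta/3)\) (ramp times
ignored; no waveform detail is modelled) and the critical velocity
\(v_c = 1/(2\gamma G \Delta \delta)\), the speed at which the bipolar pair
accrues \(\pi\) radians of flow phase. The two are cross-checked in the
test suite: the first-moment phase at \(v_c\) equals \(\pi\) exactly.

## The synthetic laminar generator

The generator is first-class, tested code: it defines the study conditions
under which every downstream claim is evaluated.

**Depth grid.** 20 equidistant bins over normalised depth
\([-0.125, 1.0625]\), 0 the GM/WM boundary and 1 the CSF/GM boundary;
the overshoot captures partial-volume bins at both borders. Layer 1 is the
deepest bin.

**Neural profiles.** Sums of Gaussian bumps over depth; the default
`double_peak` profile (peaks at depths 0.25 and 0.8, SD 0.08, unit
amplitude in percent signal change) emulates the hand-knob motor-cortex
hallmark: superficial input activity plus deep output activity with a
quiet middle.

**Leakage operator.** The draining-vein blur is modelled as the simplest
linear operator consistent with upward-only flow and a vein density that
increases linearly from deep to superficial cortex:
\(K = I + \alpha W\), with \(W_{lm} = w_l\) for \(m\) deeper than \(l\)
and zero otherwise, where \(w_l\) is the linear vein-density weight
normalised to mean 1. \(K\) is lower triangular in the deep-to-superficial
ordering (nothing drains downward; the deepest layer is untouched) and is
the identity at \(\alpha = 0\). No in-vivo value of \(\alpha\) is
established; the default 0.3 is illustrative — strong enough that the
drained profile loses its double-peak shape — and every result involving
\(\alpha\) is a comparison between conditions, not an absolute claim.

**VN composition.** The measured profile under retentions
\((r_{vein}, r_{cap})\) is
\(r_{cap}\, p + r_{vein}\, (K - I)\, p\): the local (capillary) term
survives almost intact while the drained (venous) term is suppressed. With
\(r = (1, 1)\) this is plain \(K p\) (no VN); as \(r_{vein} \to 0\) the
capillary-weighted truth is recovered.

**Task runs.** Magnitude = \(100 \times (1 + \text{profile} \cdot
x(t)/100) + \varepsilon\), where \(x(t)\) is a 30 s on / 30 s off boxcar
convolved with a unit-peak double-gamma HRF (peak delay 6 s, undershoot
delay 16 s, unit dispersions, undershoot ratio 1/6 — the common
convention; the HRF form itself carries no free parameters in the source
analyses, so defaults are exposed in the function signature) sampled at
TR = 4 s. The baseline of 100 makes profile amplitudes read directly as
percent signal change. The phase channel carries `phase_gain` times the
*venous* component of the signal only, plus Gaussian phase noise: phase
regression targets macrovasculature, and in this model the venous drained
term is exactly the macrovascular content.

**Rest runs.** Band-limited (0.01–0.1 Hz) Gaussian series over
`roi_count * n_layers` channels with an exact population correlation
target: white noise is brick-wall restricted to the band in the Fourier
domain, standardised, then mixed with the symmetric square root of the
target covariance. The brick-wall mask is deliberate for the *generator*
(the target correlation then holds exactly in population); the
*measurement-side* filter is a separate, realistic order-4 zero-phase
Butterworth (`bandpass_filter()`), mirroring the distinction between
simulating a band-limited brain signal and filtering noisy data. Non-PSD
targets are rejected with the offending eigenvalue reported.

**What the generator does not emulate.** No extravascular dipole fields
(the inverse-square pial falloff is handled analytically, not simulated),
no vessel-network Monte Carlo, no motion, no physiological noise spectra,
no spatial autocorrelation beyond the planted covariance, no surface
geometry. Passing tests therefore show that the analysis chain recovers
planted laminar structure under the stated noise model — not that it would
under scanner artefacts the generator omits.

## Phase regression

Per spatial unit: temporal phase unwrapping (successive differences mapped
into \((-\pi, \pi]\); temporal-only, never across voxels), then OLS of
magnitude on centred unwrapped phase, removing the fitted component:
`cleaned = magnitude - beta1 * (phase - mean(phase))`. The raw mean is kept
so downstream percent-signal-change is unaffected; the cleaned series is
exactly orthogonal to the centred phase regressor, and the operation is
idempotent. The slope is unconstrained by default — some of the literature
restricts it to the venous-consistent sign; that variant is available via
`sign =` but OLS is the default for simplicity and testability. The step
sits early in the chain, before temporal filtering, to keep magnitude and
phase processing aligned.

One caveat the simulator makes visible: in a block task the neural and
macrovascular responses share a time course, so phase regression removes
some true response along with the macrovascular excess. The relevant
criterion — tested over 100 seeds — is that superficial-layer GLM
estimates move *closer to the planted truth*, not that they are untouched.

## Layering and depth profiles

Equidistant layering uses half-open bins \([lo, hi)\) with the deepest
edge inclusive, after optional nearest-neighbour in-plane upsampling
(e.g. 5x, taking 0.9 mm voxels to an effective 0.18 mm grid) — upsampling
replicates values and never invents new ones. Layer series are unweighted
means over units; empty layers propagate as missing values with a warning,
never silently interpolated or zeroed. The per-layer GLM regresses the
layer series on an intercept plus the HRF-convolved boxcar; the response
amplitude is reported as percent signal change against the intercept with
a 95% t-interval on the residual degrees of freedom. Confidence intervals
are across time within the layer fit (the across-run alternative is noted
but not implemented — single runs are the simulated unit).

## Depth-resolved connectivity

All correlations are Pearson, Fisher-z transformed with \(|r|\) clipped to
\(1 - 10^{-7}\) so self-correlations sit at a finite ceiling
(`fisher_z_ceiling()`, ~8.4) rather than infinity; intracortical diagonals
are excluded from group tests. Seed FC via correlation is equivalent to
the single-regressor GLM formulation up to a monotone map, which is why
both views appear in the field; the package computes the correlation form.
Layer-specific seeds use projection ranges on normalised depth (deep
0.10–0.15, middle 0.45–0.50, superficial 0.85–0.90, whole-depth 0.1–0.9).

The intracortical matrix averages each unit's depth-by-depth Fisher-z
matrix unweighted across units (constant series skip the unit, with a
count); the ROI-pair matrix correlates layer-mean series of ROI A at depth
i with ROI B at depth j — the cell from which feedforward/feedback
asymmetries are read. Group statistics are element-wise one-sample or
paired t-tests with Benjamini–Hochberg FDR over the tested element set
(upper triangle only for symmetric matrices). BH was chosen because the
alternative used on surfaces — Monte-Carlo cluster correction — is out of
scope without surface geometry. Degenerate elements with zero spread
across subjects get \(t = 0\) when their mean is also zero.

```{r demo}
report <- run_demo_pipeline(demo_config(seed = 1))
report
autoplot(report$profile)
```

The demo chains everything at a reduced size (6 task blocks, 12 units,
14 synthetic subjects, 150 rest volumes — sizes chosen so the full
pipeline runs in seconds while keeping the group test at the N = 14 the
resting-state analyses use): vein vs capillary retention at b = 7, a
double-peak profile recovered through drainage + phase regression, and a
paired group test showing the VN condition's superficial inter-layer
coupling significantly below the no-VN condition — with no spurious
difference when drainage is absent (tested separately).

## Numerical and design notes

- **Determinism.** Every stochastic operation requires an explicit seed
  and restores the caller's RNG state; identical seeds give bit-identical
  arrays, and two pipelines in one session cannot interfere through hidden
  state.
- **Filtering edges.** `signal::filtfilt` carries zero initial state, so
  the filter is applied to a demeaned, odd-reflection-padded copy and the
  pads are discarded; a constant series maps to (numerically) zero under
  the high-pass, as it should.
- **Critical-velocity reference values.** Printed per-protocol critical
  velocities for b = 6/7/8 s/mm² cannot be derived from b alone (they
  need the protocol's G, δ, Δ, which are not public); the calculator
  computes \(v_c\) from explicit gradient specs instead of reproducing
  those numbers.
- **On-disk format.** Paired magnitude/phase NIfTI plus a JSON manifest
  (TR, depth grid, ROI labels, simulation truth); round trips are
  bit-exact in double precision.
- **Indexing.** Arrays are unit x layer x time; layer numbers are 1-based
  with layer 1 deepest, matching the "20 layers" convention in user-facing
  tables.

## Limitations

The package analyses simulated or pre-extracted laminar data (voxel series
with a depth coordinate, or ROI-by-depth series); it does not reconstruct
surfaces, morph between subjects, or touch scanner raw data. The leakage
operator is a phenomenological linear blur, not a hemodynamic model: it
cannot speak to nonlinear vascular saturation or to the time-lag structure
of drainage. Group inference assumes exchangeable subjects and element-wise
normality of Fisher-z values — reasonable at z-scale, but cluster-aware
inference on real surfaces is out of scope.
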