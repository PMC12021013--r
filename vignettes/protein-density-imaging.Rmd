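---
title: "Label-free protein density from brightfield images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free protein density from brightfield images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tiettd)
```

## The measurement problem

Intracellular protein concentration `P` (g/ml) and its complement, the water
volume fraction `W`, are tightly regulated properties of living cells and the
direct drivers of macromolecular crowding. Both can be obtained label-free
from an ordinary transmission microscope by combining two channels:

* a **quantitative phase** channel: protein raises the refractive index of
  cytoplasm linearly, `Δn ≈ 0.185 P` (the refractive increment, 0.185 ml/g,
  holds for most proteins and nucleic acids up to at least 55% w/v), and the
  phase delay accumulated through the cell is `Δφ = (2π h / λ) Δn`. Summed
  over the cell footprint, the integrated phase is proportional to the total
  dry (protein) mass;
* a **volume** channel: an impermeant absorbing dye in the medium makes cells
  brighter in proportion to their thickness (dye exclusion), so the
  Beer-Lambert law converts the transmission image into a height map and,
  integrated over a region, into a volume.

Dividing the two gives concentration:
`P = s · ΣT / V`, `W = 1 − 0.7 P`, dry mass `= P·V`.
For an ideal phase reconstruction the coefficient is
`s = λ / (2π · 0.185) = 0.86 λ`; a practical, denoising reconstruction
underestimates phase by a solver-dependent factor, which is why `s` is
measured empirically (bead calibration, below).

## Phase retrieval

The phase channel uses two brightfield images, overfocused (`BF1`) and
underfocused (`BF2`), separated by the full axial distance `Δz′`. After dark
subtraction, mean equalization

```
BF1' = BF1 + (mean(BF2) − mean(BF1))/2,   BF2' = BF2 + (mean(BF1) − mean(BF2))/2
```

removes global exposure mismatch (the contrast of interest is a fraction of
a percent of the mean intensity). The transport-of-intensity relation then
poses a Poisson problem for the phase surrogate `T`:

```
−∇² T = (2π n_imm / λ) · (BF1' − BF2') / (Ī Δz′)
```

with `Ī` the pixelwise mean of the equalized pair. The refractive index of
the mounting medium cancels from this relation (the focal-plane shift inside
the sample compensates it exactly), so the solver never uses it. The
reconstruction fixes the additive gauge by zero mean and trims one border
pixel per side (the output is 2 px smaller than the input in each
dimension); quantification instead uses background-ROI subtraction, which
makes the per-cell integrals independent of the gauge choice altogether.

### The solver, concretely

The published workflow relies on a plugin whose numerical scheme is not
spelled out, so this package fixes its own, fully specified one:

* the source term uses the 5-point discrete Laplacian with mirrored
  (edge-replicated) boundaries;
* the inversion happens in a spectral basis obtained by even (mirror)
  extension of the field to a doubled periodic domain — equivalent to a DCT
  and consistent with Neumann boundaries, so no artificial periodic
  wrap-around enters at the image edges;
* the inverse of each squared-frequency eigenvalue `k²` is damped by
  `k²/(k² + ε·k²_max)`.

At `ε = 0` the inversion is the *exact* inverse of the package's own
discrete Laplacian. This is deliberate: the synthetic forward model
(`forward_tie_pair()`) renders defocus pairs with the same discrete
operator, so forward-then-inverse is an identity up to floating-point error,
and every downstream quantity can be tested against analytic ground truth
with no free parameters. The default `ε = 1e-3` reproduces the behaviour of
practical TIE solvers: inverting a Laplacian amplifies low-frequency noise
as `1/k²`, and the damping suppresses exactly those modes at the cost of a
low-frequency bias in `T`. That bias is the reason the empirical `s` exists,
and any quantitative use of `ε > 0` output should use an `s` calibrated at
the same settings.

Two practical consequences are worth stating. First, a constant intensity
offset on one image of the pair is removed from the *difference* by
equalization, but it shifts the mean intensity `Ī` by half the offset, so
the reconstruction is rescaled by a uniform gain `I₀/(I₀ + offset/2)`; a
50-count offset on a 1000-count background is a 2.4% gain error, absorbed by
calibration. Second, the defocus separation trades signal for validity of
the linear model: the forward model refuses to render contrast magnitudes
above 1 (negative light), and the tests use `Δz′` = 0.1 µm for beads (whose
rims are optically violent) and 0.5 µm for cell-like phantoms — within the
0.5-10 µm range used on real microscopes, where partial coherence smooths
the rims instead.

## Dye-exclusion volumetry

The dye channel is imaged at the dye's absorbance peak (~630 nm for Acid
Blue 9). With `ln I_bkg` the mean *logarithmic* background intensity (mean
of logs, not log of means — matching how the background is measured in
practice), thickness and volume follow as

```
h(x,y) = (ln I(x,y) − ln I_bkg) / α,      V = (A/α)(mean ln I − ln I_bkg)
```

Both are invariant under global exposure scaling. Pixels at or below the
dark level in a quantification path raise an error rather than being
clamped: a cell darker than the background indicates membrane damage or a
misconfigured dark level, and silently clamping would bias volumes. Local
illumination gradients can be compensated by restricting the background to a
window around each region (`local_background_margin`); the default uses the
whole background region.

Two helpers support planning: the maximum usable dye concentration for a
chamber of depth `h′` µm is `300/h′` mg/ml (the background must stay well
above the dark level; 7 mg/ml in a 40-µm chamber satisfies it), and the
osmolality added by the dye is `2.25` mosm/kg per mg/ml over 0-100 mg/ml,
which matters at the ~80 mg/ml concentrations bacteria require.

## Calibration

**Phase channel.** Silica beads of known mean volume (7.7 µm diameter,
`sphere_volume(7.7)` ≈ 239 µm³) are immersed in oils of known refractive
index and processed exactly like cells. The background-corrected integral
`T_bead = A(T̄ − T_bkg)` per bead, divided by the bead volume, is regressed
on `n_oil`; the negated slope `g` converts to `s = 1/(0.185 g)`. The
regression is deliberately on `n_oil` (not on `Δn`) so the bead's own index
— never certified precisely — affects only the intercept. A positive-`Δn`
bead must produce a positive integral; a fitted `g ≤ 0` therefore aborts
with a "swapped images" diagnosis rather than returning a nonsensical
calibration. In the synthetic end-to-end test (four oils spanning `Δn` from
−0.05 to +0.10, exact solver) the fitted `s` agrees with `0.86 λ` to well
within 5%, the residual being bead-discretization error.

**Dye channel.** A half-ball lens resting in a drop of dye creates a known
liquid depth `h(d) = R − sqrt(R² − d²)` at distance `d` from the touch
point. The radial intensity profile (annular means, 1-px bins), converted to
depths, gives a Beer-Lambert line `ln(I − dark) = ln I₀ − α h` whose slope
is `−α`. The innermost 5% of the lens radius is excluded (shallow depths are
dominated by centring error; the protocol only says "very low h values", the
5% default is this package's choice) as is the last profile point (a
documented artifact of the standard radial-profile plugin). The protocol's
quality bar, R² ≥ 0.9999, is enforced as a warning, not an abort, so batch
runs can flag rather than die. On noiseless synthetic half-ball images the
fit returns `α` to 0.1% with R² ≈ 1; with 0.5% multiplicative noise it stays
within 2%.

## Units

Internally everything is µm / g/ml / pg: `1 g/ml = 1 pg/µm³`, so
`dry mass [pg] = P [g/ml] · V [µm³]` with no conversion factors, and `s` is
in µm so that `s · (phase·µm²) / µm³` times the refractive-increment
relation yields g/ml. `W = 1 − 0.7 P` is dimensionless; values outside
[0, 1] (possible for noisy or non-cell regions) are reported unclamped and
flagged.

## What the synthetic data does and does not emulate

The generator produces: spherical-bead phase maps (chord-length profile,
analytic integral), smooth Gaussian phase bumps, dome (half-ellipsoid) cell
height fields with analytic volume, defocus pairs via the discrete forward
TIE, dye-exclusion images via exact Beer-Lambert, and half-ball absorption
images. Noise is multiplicative Gaussian (σ as a fraction of local
intensity, the natural description of camera noise) or Poisson, always
applied after the clean render and fully determined by a seed.

It deliberately does **not** model: partially coherent image formation or
the objective's transfer function (the forward model is the discrete TIE
itself, which is what makes the inverse exact and testable), vignetting,
dust, or the blotchy flat-field structure real cameras produce. Passing
tests therefore validate the *numerics* of the pipeline — operators,
integrals, regressions, unit bookkeeping — not robustness to optical
artifacts. On real data the documented mitigations are tight cropping
around isolated cells and the `ε`-damped solver with bead calibration at
matched settings.

Default phantom conditions: 256×256 px at 0.3 µm/px (128×128 in the heavier
end-to-end loops to keep the suite fast), background 1000-2000 counts,
bead diameter 7.7 µm, cell footprint radius 9 µm with 6 µm apex height
(volume ≈ 1018 µm³), `P₀` in the physiological 0.1-0.3 g/ml range, dye
α = 0.15 µm⁻¹ (a 7 mg/ml AB9 solution), 1% relative noise where noise is
tested.

## Numerical and degenerate-input choices

* Images are converted to double precision before any arithmetic; the dark
  level is subtracted first.
* `Ī` is floor-clamped at 1e-6 of its field mean purely to avoid division
  blow-ups; an input whose mean intensity is non-positive is rejected as
  degenerate rather than clamped.
* The DC (gauge) mode of the spectral inversion is set to zero; ROI
  quantification additionally subtracts the measured background, so results
  are invariant under `T → T + c`.
* Empty ROIs are skipped with a warning; an empty background region is an
  error (nothing can be background-corrected against it).
* A constant radial profile yields `α = 0` with `R²` reported as `NA` and a
  warning, rather than a spurious fit.
* CSV output formats numbers with a fixed `%.10g`, making repeated runs on
  identical inputs byte-identical.

## Known limitations

* The forward model's contrast cap (|c| ≤ 1) limits the defocus separation
  usable on sharp-edged phantoms well below what real optics tolerate.
* `ε > 0` reconstructions are biased low by design; their absolute scale is
  only meaningful together with a matched calibration.
* TTD volumetry applies to whole cells with intact membranes; organelles and
  permeabilized cells need other volume methods, and only the phase channel
  of this package applies to them.
* Registration between the phase and dye channels is assumed done (identical
  pre-aligned crops); no alignment algorithm is included.
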