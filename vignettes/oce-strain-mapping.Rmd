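---
title: "Phase-resolved OCE strain mapping: model, estimator design, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-resolved OCE strain mapping: model, estimator design, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the measurement
model, the estimator and why it is built the way it is, what the synthetic
data generator does and does not emulate, and the numerical choices a
maintainer would want written down.

## 1. Measurement model

A spectral-domain OCT B-scan is a complex matrix `a(m, j) = A e^{iφ}`, rows
sampling optical depth in air at pitch `dz_air` (µm/px), columns sampling
the lateral position at pitch `dx`. Between two frames, axial scatterer
motion `U` rotates the phase:

\[ U = \frac{\lambda_0 \Phi}{4\pi n}, \qquad
   \Phi(m,j) = \arg\{a_2 \cdot a_1^*\}. \]

The observable of interest is not `U` but the axial strain
`ε = ∂U/∂z`. Because one axial pixel spans `dz_air` of optical path and
`dz_air / n` of physical depth, the conversion from the phase slope `s`
(rad/px) to strain,

\[ \varepsilon = \frac{\lambda_0}{4\pi}\,\frac{s}{dz_\mathrm{air}}, \]

is independent of the refractive index `n`: the `n` in the displacement
relation and the `n` in the depth calibration cancel. The package records
this as `depth_convention = "optical"` on every strain map; `n` still
matters whenever depths are reported in physical micrometres
(`dz_phys = dz_air / n`) and is therefore required container metadata.

## 2. The vector estimator

`vector_axial_gradient()` never extracts a phase until the last step:

1. complex pre-averaging of `b = a₂a₁*` over `preavg_px × preavg_px`
   (default 4) — vector averaging that suppresses noise before any
   nonlinear operation;
2. axial lag products `d(m) = b̃(m + lag)·b̃*(m)`;
3. complex summation of `d` over the processing window (default
   100 × 100 µm, converted to odd pixel counts ≥ 3; the map resolution is
   about half the window, i.e. ~50 µm);
4. phase slope `= arg(Σd)/lag`, then the strain conversion above.

Amplitude weighting is intrinsic — bright pixels dominate `Σd` — and a
pixel whose phase is a ~π outlier contributes a near-random vector that
averages out. No unwrapping is needed at any cumulative displacement, since
only the per-lag phase increment must stay below π.

**Why the lag must span the speckle correlation length.** For a pixel pitch
that oversamples the axial PSF (4 µm/px vs ~8.3 µm FWHM), adjacent pixels
share the same speckle. The fourth-order moment of the lag product then
contains, besides the phase-carrying term, a pairing of per-frame axial
autocorrelations whose carrier phase cancels scatterer-by-scatterer — a
*real, positive* component that drags `arg(Σd)` toward zero. At lag 1 this
shrinks the estimated slope by tens of percent; it decays with the envelope
autocorrelation squared and becomes negligible once the lag exceeds the
correlation length. The default `lag_px = 6` (~1.5 PSF widths) keeps the
residual bias below the half-percent level that the unbiasedness property
test asserts. This is also why a literal adjacent-pixel product, however
natural it looks, is not a usable default.

**Coarse-to-fine wrap safety.** A long lag shrinks the wrap margin
(`|ε_interframe| < λ₀/(4·dz_air·lag)`). For `lag_px > 2` the estimator
therefore runs a wrap-safe 2-px-lag pass first, removes that ramp from the
long-lag products, measures the residual, and adds the ramp back: the wrap
limit is set by the coarse lag (ε ≈ 0.04 interframe at the default
geometry) while precision comes from the long lag. On a noise-free linear
ramp the whole scheme is exact to machine precision (asserted at 10⁻¹⁰).

**Least-squares cross-check.** `lsq_axial_gradient()` is the classical
alternative: per-column OLS slope of the (optionally unwrapped) phase over
the window's axial extent, averaged laterally — pooled OLS with per-column
intercepts. Two hard-won details: it uses the same complex pre-averaging
(raw speckle phase makes the equal-weight fit heavy-tailed), computed on
the valid sub-rectangle only (zero-filled edges would feed flat zero-phase
rows into the fit); and windows containing a post-unwrap jump above
`0.95π` are masked as unwrap failures. On 30 dB speckle the two estimators
agree within 1% on the window mean; on a 0.9π rad/px ramp the vector
method with lag 1 is exact while the no-unwrap fit collapses — the
documented failure mode that motivates the vector formulation.

## 3. Cumulative strain and the accumulation frame

`accumulate_strain()` sums interframe maps element-wise on the intersection
of validity masks — a fixed-pixel (Eulerian) frame, matching the standard
practice of summing interframe strains per pixel. A geometric consequence
worth stating precisely: at a fixed pixel the increment of a material
element already strained by `ε` is `dε/(1+ε)`, so the Eulerian sum
converges to the logarithmic (Hencky) strain `log(1+ε)` — for a cumulative
engineering strain of 0.3 that is 0.262, a 12% difference that has nothing
to do with estimator quality. The simulator's ground-truth bundle therefore
carries both the imposed engineering field (`eps_true`) and the Eulerian
reference (`eps_eulerian`, accumulated from the first frame), and
`engineering_strain()` (`exp(x) − 1`) converts the package's output back to
engineering strain, exactly for depth-uniform fields. No axial
re-registration of maps is attempted; for the ≤ 0.3 regimes validated here
the conversion suffices, and the recovery suite asserts 10% end-to-end
agreement across 10⁻⁴…0.3 after conversion.

## 4. Kinetics products

Depth profiles average the cumulative map over an 80 × 800 µm window below
the per-column detected surface (amplitude threshold 0.3 × column max after
5-column lateral median smoothing; the surface index is the count of air
pixels above the sample). Depth is physical µm, zero at the surface, capped
at 900 µm by default — deeper signal is unreliable in cleared tissue. When
the 95th percentile of |strain| falls below 2·10⁻⁴ the axial window widens
automatically to 160 µm, matching how weak-strain (near-isotonic) runs are
analyzed. Waterfall diagrams stack profiles over time. Extrema tracking
reports the global minimum and maximum per profile (ties broken toward the
shallower depth), flags extrema within one axial window of the deep limit
as unreliable (a too-deep minimum cannot be located), and interpolates the
neutral zero-strain depth at the first sign change walking from the
positive extremum toward the negative one — defined only when the extrema
bracket zero. Normalization divides a profile by its maximal positive
strain (an error when none exists, since the convention is undefined
there).

## 5. What the simulator emulates — and what it does not

`simulate_series()` draws unit-strength point scatterers (default 20 per
PSF length per column — unit strengths keep the summed field circular
Gaussian, hence Rayleigh amplitudes and uniform phases, already at moderate
density), renders them through a Gaussian axial PSF whose FWHM derives from
the source (`(2 ln 2/π)·λ₀²/Δλ` ≈ 8.3 µm at 1300/90 nm), attenuates
amplitudes with depth (default 1.5 mm⁻¹), and adds circular complex noise
at a configurable SNR (default 30 dB). Osmotic fields use the
constant-source half-space solution `C = C₀·erfc(z/2√(Dt))`; `√(Dt)` is the
penetration scale (~0.55 mm for glycerol's 10⁻⁹ m²/s after 5 min).
Templates map concentration to cumulative strain; the alternating-sign
template `ε = C(k_pos − k_neg(1−C))` reproduces the hypertonic phenomenology
(surface dilatation, deep shrinkage, sign change where `C = 1 − k_pos/k_neg`).
The `uniform`/`ramp` templates accept `time_profile = "linear"`, making the
coefficients rates (1/s), which is how constant-rate validation series are
built. Scatterers persist across frames and move by the integral of the
strain field, so interframe phase, decorrelation by motion, and
supra-wavelength cumulative displacement all emerge from the geometry
rather than being painted on.

Not modelled: lateral PSF (columns are independent speckle), multiple
scattering, refractive-index evolution during clearing, Brownian motion,
and sub-resolution scatterer reshuffling. Passing recovery tests therefore
demonstrate correctness of the phase-gradient chain under realistic speckle
and noise, not robustness to every contrast mechanism of real cleared
tissue — in particular, real data may show extra decorrelation at strains
approaching 0.4 that this model underestimates.

## 6. Study conditions and problem sizes

The validation scenarios fix their physics once:

* **Recovery ladder** — uniform fields accumulating 10⁻³…0.3 over 31
  frames, i.e. per-interval strains ≤ 0.01. This respects the sub-pixel
  interframe-motion regime (`ε_interframe · z < dz_phys` over the analyzed
  depth); experiments reach the same cumulative strain with ~10× more
  frames, so the scaled-down series is the harsher condition. At 0.01 per
  interval the motion reaches one pixel near ~500 µm depth and the pair
  decorrelates below it — visible as a depth-dependent roll-off, and the
  reason single-pair checks read the 80–190-row band.
* **Smallest strain** — 10⁻⁴ accumulated over 300 s (31 frames at 10 s),
  analyzed with the auto-widened 160 × 800 µm window and compared against a
  zero-strain run's noise floor.
* **Deepening front** — alternating-sign template with `k_pos = 0.05`,
  `k_neg = 0.2` and `D = 5·10⁻¹⁰ m²/s`, frames every 10 s from t = 30 s to
  600 s. `D` follows from the closed form for the strain-minimum depth,
  `z_min(t) = 2√(Dt)·erfcinv((k_neg−k_pos)/(2k_neg))`, chosen so the
  minimum migrates from ~200 µm to ~700 µm over 10 min — the regime in
  which shrinkage fronts are tracked experimentally. The series starts at
  30 s because the step from zero field to the first frame would otherwise
  deposit the entire near-surface field in one interval and alias any
  estimator; recovery is judged against `eps_eulerian` differenced from the
  first frame, which is the quantity an observer starting then can see.

Grids are 320–400 × 64–96 px (about 1–1.2 mm depth, 1–1.5 mm laterally) —
large enough for the 800 µm lateral averaging window with margin, small
enough that the full suite runs in a few minutes on one CPU.

## 7. Numerical choices and degenerate inputs

* Window sizes in µm convert to odd pixel counts ≥ 3 (physical pitch
  `dz_air/n` axially); averaging windows may be 1 px (no smoothing).
* Box sums use summed-area tables; "valid" regions only — edge pixels are
  masked, never extrapolated. All-invalid windows yield masked pixels; NA
  never leaks into sums.
* The interframe product of zero pixels contributes nothing (amplitude
  weighting); a window whose complex sum is exactly zero is masked.
* Optional lag-product magnitude clipping (`clip_quantile`) limits specular
  dominance; off by default. A single re-referencing iteration
  (`rereference`) is available but off by default — the coarse-to-fine pass
  already serves its purpose.
* Timestamps must be strictly increasing with 1% spacing tolerance;
  violations are contract errors, as are mismatched shapes or optics.
* All randomness lives in the simulator and derives from one master seed
  (scatterers from `seed`, per-frame noise from fixed offsets of it);
  identical seeds give bit-identical series.
* The B-scan container is a single binary file (JSON header + little-endian
  float64 real/imag planes) with a JSON sidecar; round trips are bit-exact.
  TIFF export rescales to [0, 1] (32-bit float TIFF is portable only
  there), recording offset/scale in a sidecar; CSVs carry raw values.

## 8. Known limitations

* No axial re-registration at large strain: above ~0.3 cumulative strain
  the Eulerian/engineering distinction grows and material tracking would be
  needed; the package stops asserting accuracy there.
* The least-squares oracle needs an unwrappable phase; it is a fair-weather
  cross-check, not a robust fallback.
* Surface detection assumes the sample is the first bright structure in
  every column; immersion layers brighter than tissue would need a
  different threshold.
* The speckle model's columns are statistically independent; lateral
  pre-averaging is therefore slightly more effective in simulation than it
  would be on real data with a finite lateral PSF.
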