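# vectorOCE

Phase-resolved optical coherence elastography (OCE) strain mapping in R:
from time series of complex-valued OCT B-scans to maps, depth profiles and
kinetics of cumulative axial strain, together with a point-scatterer OCT
speckle simulator that imposes known osmotic-diffusion strain fields so the
whole chain can be validated by parameter recovery.

## The problem

When a poroelastic tissue such as cartilage is put in contact with a
non-isotonic solution (saline, glycerol–water mixtures, iohexol contrast
agent), the diffusing agent excites transient, depth-inhomogeneous osmotic
strain fields: a thin subsurface shrinkage layer, broad dilatation behind
the diffusion front, and — for strongly hypertonic agents — an
alternating-sign profile whose shrinkage zone migrates hundreds of
micrometres into the bulk within minutes. These strains span four orders of
magnitude, from 10⁻⁴ (near-isotonic saline) to 0.4 (pure glycerol). OCE is
currently the only technique that resolves this evolution in depth and time
without contact.

## The method

Phase-resolved OCE compares consecutive complex B-scans `a = A e^{iφ}`.
The interframe phase variation is the argument of the element-wise
conjugate product,

    Φ(m, j) = arg{ a₂ · a₁* },

and relates to axial scatterer displacement through

    U = λ₀ Φ / (4 π n),

with `λ₀` the central wavelength and `n` the refractive index. Local axial
strain is the depth gradient `∂U/∂z`. The package estimates it with the
**vector method**: the interframe product is complex pre-averaged, axial
lag products `d(m) = b(m + lag) · b*(m)` are formed, summed over a
processing window (100 × 100 µm by default; resolution ≈ half the window),
and only then is a phase extracted — `arg Σd / lag`. Amplitude weighting is
intrinsic (bright pixels dominate the complex sum), isolated ~π phase
errors cancel, and no phase unwrapping is ever needed even when cumulative
displacement spans many wavelengths, because only the per-lag phase
increment must stay below π. The estimate uses a wrap-safe short-lag pass
followed by a precise long-lag pass (lag must exceed the axial speckle
correlation length; see the methods vignette). A classical least-squares
phase-slope fit (`lsq_axial_gradient`) is kept as an independent
cross-check. Interframe maps are summed into **cumulative strain** at every
timestamp; depth profiles (80 × 800 µm averaging, auto-widened to
160 × 800 µm below ~2·10⁻⁴), waterfall diagrams, and tracks of strain
extrema and the neutral zero-strain line mirror the standard analysis
products of osmotic-OCE experiments.

The simulator (`osmo_*`, `speckle_*`, `simulate_series`) renders fully
developed speckle from persistent point scatterers (Gaussian axial PSF,
~8.3 µm FWHM for a 1300/90 nm source), moves them with the displacement
field of a constant-source erfc diffusion front, and returns the imposed
concentration/strain/displacement fields as ground truth.

## Worked example

Simulate five minutes of a strongly hypertonic agent diffusing into
cartilage (alternating-sign field, D = 5·10⁻¹⁰ m²/s), recover strain, and
track the extrema:

```r
library(vectorOCE)
op   <- optical_params(lambda0_nm = 1300, n = 1.3, dz_air_um = 4, dx_um = 15.625)
spec <- strain_field_spec("alternating_sign", k_pos = 0.05, k_neg = 0.2,
                          diffusion = diffusion_params(D = 5e-10))
sim  <- simulate_series(spec, speckle_params(seed = 1, snr_db = 30), op,
                        n_frames = 31, dt = 10, n_rows = 400, n_cols = 64,
                        surface_px = 30, t_start = 30)
maps  <- strain_series(sim$series)                  # cumulative strain maps
surf  <- detect_surface(Mod(sim$series$frames[[1]]$data))
profs <- lapply(maps, depth_profile, surface = surf, optics = op,
                depth_limit_um = 900, auto_widen = FALSE)
track <- extrema_kinetics(strain_waterfall(profs))
tail(track[, c("time_s", "depth_max_um", "value_max",
               "depth_min_um", "value_min", "depth_neutral_um")], 3)
```

which prints

```
 time_s depth_max_um value_max depth_min_um value_min depth_neutral_um
    280     113.8462    0.0351     516.9231   -0.0275         269.4409
    290     113.8462    0.0356     523.0769   -0.0276         271.5184
    300     113.8462    0.0360     532.3077   -0.0276         273.5556
```

the signature of the alternating-sign regime: a stationary dilatation
maximum ~110 µm below the surface, a shrinkage minimum that has migrated
past 500 µm after 5 minutes, and the neutral (zero-strain) line between
them. `sim$truth` carries the imposed fields for quantitative comparison.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/oce.R simulate --template alternating_sign --out run/sim --seed 1
Rscript inst/cli/oce.R strain   --input run/sim/series.oce --out run/strain
Rscript inst/cli/oce.R kinetics --input run/strain --out run/kin
```

Each command writes its resolved YAML configuration next to its outputs;
maps export as 32-bit TIFF + CSV, kinetics as CSV + PNG.

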