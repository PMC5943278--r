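# serialfiber

Simulation and reduction of **single-shot X-ray fiber diffraction** from
helical filaments at free-electron lasers — for structural biologists and
beamline scientists working with non-crystalline filaments (virus rods,
amyloid protofibrils) deposited on low-background fixed targets.

A filament with helical symmetry confines its diffraction to *layer lines*
Z = l/c (c = axial repeat). Serial femtosecond exposures record one frame
per pulse from a few filaments at an unknown in-plane rotation φ and small
tilt β. `serialfiber` provides:

* **Generative models** — Cochran–Crick–Vand layer-line intensities for a
  u_t helix (G_{n,l}(R) = Σ_j f_j J_n(2πR r_j) e^{i(−nψ_j + 2πl z_j/c)},
  with the selection rule l = t·n + u·m), an empirical cross-β amyloid
  model (meridional orders of the 4.8 Å strand rise, Gaussian-mixture
  equatorial peaks), a polarized constant + power-law background, and
  Poisson frame sampling — plus a brute-force atomistic oracle used to
  validate the layer-line math to 1e-6.
* **Frame reduction** — photon-statistics classification into beam-off /
  sample-free / hit, average-background bookkeeping, automated (φ, β)
  estimation by layer-line sharpness, mapping onto a signed cylindrical
  (R, Z) grid, least-squares scaling and merging, four-quadrant
  symmetrization, circularly symmetric background subtraction.
* **Analysis** — layer-line detection, axial repeat from the Z_l = l/c fit,
  equatorial band profiles and peak tables with d-spacings, and left/right
  layer-line asymmetry with a Poisson null band.

Frames travel in CXI-style HDF5 (`/entry_1/data_1/data`); results are
tibbles with `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

Simulate a labeled serial data set (40 amyloid hits among background
frames), classify it, and run the merge pipeline:

```r
library(serialfiber)

res <- run_pipeline(demo_config(seed = 1, preset = "bombesin"))
glance(res$classification)
#> # A tibble: 1 × 7
#>   n_frames n_beam_off n_sample_free n_hit hit_fraction ...
#> 1       60          5            15    40        0.727 ...

res$peaks
#> # A tibble: 3 × 6
#>   axis      d  recip intensity prominence height
#> 1 R      10.6 0.0943 s              1.10   1.11
#> 2 R      34.5 0.0290 w              0.657  0.659
#> 3 R      23.8 0.0420 vw             0.429  0.553
```

The classifier recovers the simulated populations exactly (5 beam-off, 15
sample-free, 40 hits), and the peak table of the merged, symmetrized,
background-subtracted (R, Z) map puts the strongest equatorial maximum at
10.6 Å — the inter-sheet spacing built into the bombesin preset — with the
weaker 34.5 and 23.8 Å reflections alongside. `autoplot(res$subtracted)`
shows the merged map; `plot_equatorial_profile(res$profile, res$peaks)`
shows the profile the table came from.

For a single TMV-like frame, the axial repeat comes from layer-line spacing:

```r
geom <- demo_geometry()
qm   <- build_qmap(geom)
fr   <- simulate_frame(list(list(model = tmv_model(),
                                 orient = orientation(30, 3), psi0 = 1)),
                       geom, bg = NULL, qmap = qm,
                       cfg = sim_config(fluence = 5.5e3, noiseless = TRUE,
                                        disorientation_deg = 0))
lines <- detect_layer_lines(map_to_rz(fr, qm, orientation(30, 3)))
estimate_axial_repeat(lines)$c_A
#> [1] 68.70156
```

which recovers the 68.7 Å repeat of the TMV preset to 0.002%.

A thin command-line wrapper ships at `inst/cli/serialfiber`
(`serialfiber run --config run.yaml --seed 1 --out out/`).

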