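---
title: "Methods: simulating and reducing single-shot fiber diffraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and reducing single-shot fiber diffraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serialfiber)
```

## The problem

A filament with helical symmetry diffracts onto *layer lines*: planes
$Z = l/c$ in reciprocal space, where $c$ is the axial repeat and $Z$ is the
reciprocal coordinate parallel to the fiber axis. In a serial femtosecond
experiment each X-ray pulse produces one detector frame from the few
filaments that happen to sit in the focus, with an unknown in-plane rotation
$\varphi$ of the fiber axis about the beam and a small out-of-plane tilt
$\beta$. The reduction task is: classify the frames (beam-off / sample-free
/ hit), estimate $(\varphi, \beta)$ per hit, map pixels into cylindrical
reciprocal coordinates $(R, Z)$, merge, symmetrize, subtract the smooth
background, and read off the structural observables — the axial repeat from
layer-line spacing, the equatorial peak positions, and the left/right
asymmetry that signals a non-cylindrically-averaged exposure.

`serialfiber` implements both the reduction and a generative simulator, so
every stage can be validated against known ground truth.

## Diffraction models

### Helices (Cochran–Crick–Vand)

A discrete helix with $u$ subunits in $t$ turns per repeat $c$ confines its
transform to layer lines; on line $l$ only Bessel orders $n$ with
$l = tn + um$ ($m \in \mathbb{Z}$) contribute. With pseudo-atoms
$(r_j, \psi_j, z_j, f_j)$ per subunit,

$$G_{n,l}(R) = \sum_j f_j J_n(2\pi R r_j)\,
  e^{i(-n\psi_j + 2\pi l z_j / c)},$$

the oriented intensity for axial rotation $\psi$ is
$I = u^2\,\lvert\sum_n G_{n,l}(R)\, e^{in(\psi + \pi/2)}\rvert^2$ and the
cylindrical average (many filaments at random rotations) is
$I = u^2 \sum_n \lvert G_{n,l}(R)\rvert^2$. Both forms are validated to
$10^{-6}$ relative against `atomistic_oracle()`, a brute-force sum
$\lvert\sum f e^{2\pi i \mathbf{q}\cdot\mathbf{r}}\rvert^2$ over explicitly
built atoms — the oracle knows nothing about Bessel expansions, so the
agreement is a genuine cross-check.

The TMV preset is a $49_3$ helix with $c = 68.7$ Å. Four pseudo-atom shells
at 25–85 Å radius populate the near-meridional lines $l = 3k$ (lowest order
$n = k$) and push the other lines off the meridian ($|n| \ge 14$), as in
real TMV. The default `n_max = 55` retains two coexisting Bessel orders per
line (they are $u = 49$ orders apart); interference between them is what
makes a single-rotation pattern left/right asymmetric, so lowering `n_max`
below ~50 silently removes the asymmetry phenomenology.

### Cross-β amyloid protofibrils

The amyloid models are deliberately empirical: meridional layer lines at
$Z = n/h$ with $h = 4.8$ Å (the β-strand rise; the second order sits at
2.4 Å), and an equatorial band whose radial structure is a Gaussian mixture
at the published d-spacings (bombesin: 34.5, 23.8, 10.6 Å; β-endorphin:
40.0, 31.3, 12.3, 9.9, 8.1 Å). The pipeline's acceptance surface is peak
*recovery*, not structure prediction, so an atomistic β-solenoid would add
parameters without adding testability. Amplitudes make the 10.6 Å peak
strongest for bombesin and the 12.3/9.9/8.1 Å triplet the pronounced maxima
for β-endorphin, matching the published qualitative labels. The two lowest-q
β-endorphin peaks are given a narrower width (0.0015 vs 0.0025 Å⁻¹) so that
all five peaks are resolved, as they are in the published profiles;
long-range lamination order plausibly makes those reflections sharper.

### Finite size, disorientation, sampling

Layer lines get a Gaussian axial profile with $\sigma_Z = 1/(2L)$ for
filament length $L$ (TMV default 1000 Å — deposited rod fragments, not the
3000 Å virion; amyloid default 600 Å). Disorientation within one exposure is
a deterministic average over 11 orientations on a Gaussian grid of spread
0.3° (the support keeps misorientation low; the exact value is not published
and is configurable). Expected counts per pixel are
`fluence × intensity × (pixel area in reciprocal space)`, so the photon
budget is independent of detector sampling, and Gaussian features narrower
than one pixel are flux-conservingly widened to the pixel's RMS footprint —
a proxy for pixel-area integration that keeps coarse simulations honest.

Default fluences put ≈ 2 × 10³ signal photons in an amyloid hit and
≈ 2 × 10⁴ in a TMV hit on top of a 0.050 photons/pixel background — the
regime of the experiment (per-pixel signal on layer lines roughly two orders
of magnitude above background).

## Geometry

One flat panel; beam along $+z$; pixel centers at integer + 0.5; all $q$ in
Å⁻¹ without $2\pi$; $d = 1/|q|$; wavelength $\lambda = 12.3984/E$ keV·Å. The
fiber frame is $\hat f(\varphi, \beta)$ with
$Z = \mathbf q\cdot\hat f$ and signed
$R = \mathrm{sign}(\mathbf q\cdot\hat e)\sqrt{|q|^2 - Z^2}$,
$\hat e = \widehat{f \times b}$, so "right of the meridian" is
well-defined and $R^2 + Z^2 = |q|^2$ holds exactly. Polarization is
$P = 1 - (\hat k_{out}\cdot\hat p)^2$, horizontal by default.

The demonstration geometry is 512 × 512 pixels of 150 µm at 85 mm and 8 keV:
it reaches 3.7 Å at the center edge, samples one TMV layer-line spacing with
about 13 pixels, and keeps a full 40-frame pipeline under a few minutes on
one core. `cspad_geometry()` provides the experiment-scale 1516² (≈ 2.3 Mpx)
frame for budget arithmetic; the assembled frame size and beam center of the
real detector are configuration, not constants.

## Reduction choices

**Classification.** Frames with fewer than 100 photons are beam-off (the
background budget is ~10⁵ photons, so the dark threshold is orders of
magnitude below it). The sample-free/hit split thresholds the photon count
in a signal region (default: the 20–5 Å annulus) with a two-class
variance-maximizing split of $\log(1 + n_{signal})$; because that criterion
is flat across an empty gap between classes, the cut is taken mid-plateau.
An empty region (high-$q$ corners) is recorded for diagnostics.

**Orientation.** The score of a candidate $\varphi$ is the sharpness
(normalized squared deviation from a running-median trend) of the
Z-histogram of the frame's photons, polarization-corrected; $\varphi$ is
well determined even with $\beta$ fixed at 0 and is refined by coarse grid,
fine grid and three-point parabola. $\beta$ enters only through Ewald
curvature ($\partial Z/\partial\beta \approx -|q|^2\lambda/2$): at a wrong
tilt the equator *bends* quadratically with $|q|$. The tilt estimator makes
that horizontality criterion quantitative: regress the computed $Z$ of
equator-band photons on their $\partial Z/\partial\beta$ and subtract the
slope, iterating with a shrinking tube around the current equator curve so
the flat background does not attenuate the fit. A sharpness grid over
$\beta$ (±15° by default — the tilt "varies within a small range" on the
support) is the fallback for photon-starved frames. Median recovery errors
on simulated frames are ~0.01° in $\varphi$, ~0.3° (TMV) and ~1.4°
(cross-β) in $\beta$; sharpness alone cannot do better for cross-β because
a tilt error *displaces* the single meridional arc without smearing it.

**Mapping and merging.** Nearest-bin accumulation with weight counting (no
interpolation — it preserves counting statistics); bins default to one
central-pixel q-step. Pixels are divided by $P$ before accumulation so the
residual background in $(R, Z)$ is circularly symmetric. Scaling uses
least-squares overlap against the most-photon reference with one refinement
pass — the published procedure says only "scaled and averaged", so the
objective is a package decision, recorded per frame in provenance.
Four-quadrant symmetrization is the weight-weighted mean over $(\pm R, \pm
Z)$; it is idempotent and fills detector gaps. Background subtraction
estimates a radial median profile from bins away from every layer line
(half-width 3 fitted line widths) and subtracts it everywhere; the pipeline
symmetrizes first, then subtracts (the published order is unstated; the
order used is recorded in provenance). Negative residuals are clipped at
zero with the unclipped map retained for diagnostics.

**Layer lines and peaks.** Lines are maxima of the trend-flattened Z-marginal
that exceed their counting-statistics standard error sixfold; a MAD-based
empirical threshold was rejected because the lines themselves inflate it
when they occupy many rows, and it degenerates without background. Indices
are assigned from the smallest adjacent-line spacing (cluster median), so
absent low orders do not collapse the indexing; the repeat is a weighted
least-squares fit of $Z_l = l/c$ through the origin (the equator is pinned at
$Z = 0$ by orientation, so no intercept). Equatorial profiles average a band
whose width may be given in pixel-equivalent bins to honor the published
8-pixel and 22-pixel settings. Peaks are prominence-filtered local maxima of
the lightly smoothed profile, refined by a three-point parabola, with s/w/vw
labels by prominence terciles (the published labels come without thresholds).

**Asymmetry.** Per line, $A_l = \sum|I(R) - I(-R)| / \sum(I(R) + I(-R))$
over bins covered on both sides, with a 99% null band from weight-matched
Poisson resampling of the pooled counts. A symmetrized map gives $A_l = 0$
identically — a pipeline-order check. In simulation, a single-rotation TMV
exposure exceeds the null on at least one line while the cylindrically
averaged exposure does not, reproducing the logic by which single-rotation
exposures are recognized in the real data.

## What the simulator does not emulate

Multi-panel detector tiling (gaps are a mask), per-shot wavelength jitter,
detector distortion, solvent and support-membrane scattering physics (the
background is an empirical constant + power-law profile), atomistic amyloid
structure, and shot-to-shot fluence variation. Passing tests therefore
demonstrate that the *reduction* is correct and unbiased under the stated
generative model — not that the model captures every systematic of the real
instrument. Real-data reproduction (the deposited serial data set) needs
only `read_frames()` on the deposited CXI layout plus the same pipeline, but
is outside the desk-scale test surface.

## Problem sizes

Unit tests run on 64²–128² detectors where only bookkeeping is at stake and
on the 512² demonstration geometry where physics is; the acceptance analyses
use the 512² geometry with 40-hit frame sets per amyloid preset and 50
frames for orientation-recovery statistics. These sizes were chosen so the
full suite exercises every stage at the experiment's photon statistics while
remaining comfortable on a single core.
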