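---
title: "Acousto-holographic stiffness mapping: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acousto-holographic stiffness mapping: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

holostiff is a simulation and reconstruction pipeline for whole-cell
stiffness mapping by acoustic stimulation and phase-shifting
interferometry.  A transparent object (a reference microbead or an adherent
cell) sits in an immersion medium and is compressed periodically by a ~1 kHz
acoustic pressure wave; a phase-shifting Mach–Zehnder interferometer records
the resulting optical-path modulation as interferograms on a camera running
slightly off the acoustic frequency, so successive frames sweep slowly
through the vibration cycle (stroboscopic sampling).  From one second of
acquisition — 20 piezo reference-phase steps of π/10 rad with 50 frames each,
1000 interferograms in total — the pipeline reconstructs per-vibration-phase
thickness maps, fits a per-pixel displacement waveform, and inverts a
linear-elastic model into a stiffness map E(x, y) in pascals.

This vignette documents the forward model, each reconstruction stage, the
parameters that matter, and the design decisions taken where the problem was
genuinely open.  Every empirical number quoted here is computed by the test
suite or by `scripts/acceptance.R`; nothing is asserted that the code does
not itself measure.

## Forward model

**Phase object.**  A scene is a projected-thickness field $h_0(x,y)$ (µm)
with uniform internal refractive index $n_s$ in a medium of index $n_m$.
The optical phase is

$$\varphi(x,y) = \frac{2\pi\,(n_s - n_m)\,h(x,y)}{\lambda},$$

the single-Δn transmission relation; thicker sample means larger positive
phase (for $n_s > n_m$).  Beads use the projected chord of a sphere resting
on the substrate, $h_0(r) = 2\sqrt{(d/2)^2 - r^2}$, which is the correct
transmission geometry for a spherical particle.  Cell blobs are smooth
compact domes: an ellipse-like boundary built from low-order Fourier
perturbations of a circle (modes 2–5, amplitudes ∝ 1/m) and a
$(1-\rho^2)^{3/2}$ radial profile whose support-averaged thickness is the
`mean_thickness` parameter (the dome peak is 2.5× that value).  Material
presets carry the literature refractive indices (PS 1.5915, PAA 1.349,
agarose 1.3329, DI water 1.334, DMEM/F12 1.337, glycerol 1.4722).  Cytoplasm
has no tabulated index here; we use 1.375, a standard mid-range value, and
treat the cell interior as optically homogeneous — consistent with the
single-Δn thickness relation, which cannot resolve internal index structure.

**Stiffness field.**  Cell stiffness is log-normal with mean
`base_stiffness` and relative standard deviation `heterogeneity`, spatially
correlated with a Gaussian kernel of length `corr_length` (default one tenth
of the cell diameter).  Defaults emulate an epithelial colorectal-carcinoma
population: 1.08 kPa mean, 13 % heterogeneity, 16 µm diameter, 4 µm mean
thickness; the treated (mesenchymal-like) preset is 0.88 kPa with 18 %
heterogeneity.  Ensembles draw per-object diameter and stiffness jitter from
configured normal distributions through counter-derived child seeds, so any
single object can be regenerated in isolation.

**Elastic response.**  The sample is treated as an isotropic linear-elastic
layer under small indentation.  The default relation is the local elastic
column

$$w(x,y) = \frac{p_0\, h_0(x,y)\,(1-\nu^2)}{E(x,y)},$$

with deflection amplitude $w$, acoustic pressure amplitude $p_0$ and Poisson
ratio $\nu = 0.5$ (incompressible default; configurable).  This uses exactly
the observable the method measures — thickness change at each point — and is
the small-indentation surrogate of a half-space contact model.  An optional
membrane coupling term turns it into a two-dimensional response,

$$\frac{E}{(1-\nu^2) h_0}\, w \;-\; T\,\nabla^2 w \;=\; p_0,$$

solved on the support with zero-deflection boundary as a sparse SPD system
(`Matrix`).  $T$ is in N/m and is converted internally to Pa·µm because
grids are in µm.  Both variants sit behind one interface so a different
supplement-derived relation could be swapped in without touching the rest of
the pipeline.  The membrane solve is verified in the tests against an
independent dense assembly of the same PDE solved with base R.

**Vibration and acquisition.**  Pressure only compresses: instantaneous
thickness is $h = h_0 - w\,(1+\sin\psi)/2$, so thickness never exceeds
$h_0$, deflection peaks at $\sin\psi = +1$, and the undeformed instant is
$\sin\psi = -1$.  Any $w \ge h_0$ is rejected as unphysical full
compression.  Frame $j$ of step $k$ is rendered at time
$t = (kF + j)/f_\mathrm{cam}$ with reference phase $\theta_k = k\,\pi/10$
and vibration phase $\psi = 2\pi f_a t \bmod 2\pi$.  The camera rate is
$f_a + \Delta f$ with default $\Delta f = f_a/(F-1) \approx 20.4$ Hz, chosen
so the $F = 50$ frames of one step tile the vibration cycle uniformly
(per-frame slip $2\pi/F$).  The physical slip is negative with this
convention; the bin labels $\psi_j = 2\pi j/F$ therefore differ from the
physical phase by sign, which leaves every amplitude-based quantity
(displacement, thickness, stiffness) untouched and only flips the reported
oscillation phase.  An optional per-step cyclic start offset emulates steps
beginning at different points of the vibration cycle, exercising the frame
matcher.

**Detector and noise.**  Intensity is
$I = I_0\,[1 + V\cos(\varphi + \theta + \varphi_{bg})]$ with mean intensity
$I_0$ (default 1800 counts), visibility $V$ (0.9), optional low-order
background aberration $\varphi_{bg}$, Gaussian shot noise (variance ∝
intensity) plus additive read noise, clipped to a 12-bit full scale (4095).
Counts stay continuous in memory; quantization to integers happens only when
a stack is written to its 16-bit TIFF dialect.  `noise_for_snr()` splits a
target intensity SNR (dB, at $I_0$) evenly between the two noise sources;
the tests verify the per-pixel variance against the model to within 5 % over
1000 draws.  Diffraction, defocus, speckle and spatial pressure variation
are out of scope: the simulator is a pure phase-projection model with
uniform $p_0$.

## Reconstruction chain

**Frame matching.**  When acquisition steps start at unknown points of the
vibration cycle, each step's frame sequence must be cyclically aligned
before binning.  The temporally centered intensity of any pixel follows
$\mathrm{Re}\!\left(e^{i\theta_k} u_x(\psi)\right)$ for a step-independent
complex modulation $u_x$; because $\theta_k$ rotates this differently at
every step, directly correlating two steps' sequences is sign-ambiguous —
when the rotated modulation amplitudes have opposite signs, lags $s$ and
$s + F/2$ are indistinguishable to first order.  The matcher therefore
proceeds progressively: from the steps aligned so far it estimates both
quadratures of $u_x$ per pixel and vibration sample by least squares over
the known $\theta_k$, predicts the next step's centered sequence, and reads
the lag from the phase of the fundamental of the pixel-summed cyclic
cross-correlation between observation and prediction.  Each pixel
contributes a sign-definite (squared) amplitude to that fundamental, so the
pixel sum is coherent, and phase estimation resolves sub-lag detail that a
discrete correlation argmax cannot at realistic noise levels.  Leave-one-out
refinement passes re-estimate every shift against the model built from all
other steps until stable.  Ground-truth offsets are recovered exactly in
noise-free simulations (including strong-contrast PS beads) and with rare
±1-lag errors at 30 dB intensity SNR; a ±1 error misaligns one of 20 steps
by $2\pi/50$ of vibration phase, which is negligible after the waveform fit.
Vibration-free sequences are ambiguous by construction; they are flagged,
defaulted to zero shift, and warned about.  A periodic Daubechies-4 DWT
(`dwt_db4`) is exported as the feature transform for 1-D series work.

**Binning.**  Bin $j$ collects frame $(j + s_k) \bmod F$ from each step $k$:
50 bins × 20 interferograms under the default plan, each bin holding one
vibration phase at 20 reference phases.  Binning is a pure permutation; the
tests verify the round trip.

**Denoising.**  Filtering is applied to individual interferograms, never to
phase maps.  Two filters are provided.  `denoise_frame()` is a one-stage
block-matching collaborative filter (patch grouping within a search window,
2-D DCT per patch, 1-D orthogonal transform along the group,
hard-thresholding at 2.7σ, sparsity-weighted aggregation); σ = 0 is the
bit-exact identity.  Because that filter costs minutes per megapixel frame
in R, the 1000-frame noisy study runs use the second option: a Gaussian
low-pass of width 1.5 px applied per frame.  The fringes in these geometries
are heavily oversampled (phase gradients below ~0.1 rad/px for cells), so
the low-pass removes noise by roughly $2\sigma\sqrt{\pi}$ (≈ 5×) at
negligible signal cost.  Noise-free runs use no filtering.

**Phase retrieval.**  Per pixel, the least-squares fit
$I_k = A + B\cos\theta_k + C\sin\theta_k$ over the 20 reference phases gives
the wrapped phase $\operatorname{atan2}(-C, B) \in (-\pi, \pi]$, amplitude
$\sqrt{B^2+C^2}$, visibility (amplitude/$A$) and a quality weight
$\mathrm{amp}^2/(\mathrm{amp}^2 + \sigma_\mathrm{resid}^2)$; pixels below
the visibility floor (default 0.05) get quality 0 and stay masked
downstream.  The least-squares form tolerates non-uniform steps, and the
estimate is exactly invariant to global intensity offsets and scaling.  On
noiseless fringes the retrieval is exact to machine precision (the
acceptance script measures ~9e-16 rad at 128×128).

**Unwrapping.**  Unweighted least-squares unwrapping integrates the wrapped
phase gradients by solving the discrete Poisson equation with Neumann
boundaries — forward DCT, spectral division, inverse DCT.  When quality
weights below 1 are present, the weighted normal equations are solved by
conjugate gradients preconditioned with the same DCT solver (relative
residual 1e-8, cap 500 iterations; non-convergence is an error carrying the
residual).  The raw least-squares solution is then made *congruent* to the
input — output = wrapped input + exact per-pixel multiples of 2π — so
wrapping the output reproduces the input everywhere, a property the tests
assert on every field they touch.  The additive constant is fixed by a
zero-median background rule restricted to 2π multiples (congruence and a
free constant cannot coexist); the background defaults to the two-pixel
image border, which in these imaging geometries holds medium-only pixels,
and is overridable.  On residue-free fields the result matches Itoh
row/column path integration exactly up to that constant.

**Thickness and displacement.**  Phase converts to thickness by
$h = \varphi \lambda / (2\pi\,\Delta n)$ (rejected if $\Delta n = 0$); an
optional blank acquisition is subtracted beforehand to remove system
aberrations.  Per pixel, the per-bin thicknesses are fitted with
$h_j = c_0 + c_1 \sin\psi_j + c_2\cos\psi_j$; under the compression-only
convention the peak-to-trough amplitude is $\delta = 2\sqrt{c_1^2+c_2^2}$
and the undeformed thickness $h_0 = c_0 + \delta/2$.  The amplitude is
invariant to cyclic bin relabeling.

**Inversion and calibration.**  With $T = 0$ the inversion closes per pixel:
$E = p_0 h_0 (1-\nu^2)/\delta$.  With $T > 0$ a Laplacian-corrected
initializer is refined by damped fixed-point iteration through the forward
solver until the relative update falls below tolerance; the tests verify 1 %
pixelwise recovery of a smooth heterogeneous field.  Pixels whose $\delta$
falls below a noise floor — default 3× the median displacement-fit residual,
a data-driven rule — are masked, never extrapolated.  $p_0$ is never
hard-coded: it is user-supplied or recovered by `calibrate_pressure()` from
a reference object of known stiffness as the masked median of
$E_\mathrm{ref}\,\delta / ((1-\nu^2) h_0)$, with a dispersion diagnostic.
Simulated calibration closes to ~1e-13 relative noise-free.

## Statistics

Distribution similarity uses the coefficient of determination

$$R^2 = 1 - \frac{\sum_i (y_{i,\mathrm{obs}} - y_{i,\mathrm{calc}})^2}
                 {\sum_i (y_{i,\mathrm{obs}} - \bar y)^2},$$

evaluated over histograms of stiffness maps.  The statistic is deliberately
asymmetric — the observed slot belongs to the measurement being evaluated —
and the tests pin the argument order, $R^2(x,x) = 1$, $R^2$ against the mean
= 0, and a hand-worked three-point example (0.99).  Histogram edges come
from a shared Freedman–Diaconis rule computed on the pooled data of the two
sets under comparison (configurable override); every histogram carries the
rule's fingerprint and `pairwise_r2()` refuses mismatched binning.
Normalized frequencies are the default aggregation (raw counts available).
Ensemble comparisons of 35 vs 35 and 35 vs 25 objects yield the expected
1225 and 875 values.  Group-level `ensemble_summary()` reports mean ± SD of
per-object means.  Inferential statistics (ANOVA, t tests) are deliberately
not re-implemented here.

## Study sizes, runtimes and reproducibility

The closed-loop study conditions are: 5 µm PAA-stiffness bead
(1.94 kPa) in water at 0.532 µm, 256×256 px at 0.05 µm/px, $p_0$ = 150 Pa;
heterogeneous cell (1.08 kPa, 13 %) in DMEM/F12 at 0.527 µm, 256×256 px at
0.09 µm/px, $p_0$ = 60 Pa.  These pressures give sub-micron deflections
(4–6 % of thickness), squarely in the small-indentation regime.  A GPa-stiff
polystyrene bead deflects immeasurably (~1e-8 µm) at such pressures, which
is why the closed-loop recovery runs use the soft-bead preset; the PS preset
(1.05 GPa, 5 µm) serves the material table and the noise-free
thickness-fidelity checks, where a noise-free simulated PS bead
reconstructs to < 5 nm maximum thickness error.  One full 20×50 pipeline
run takes roughly a minute on one CPU; `scripts/acceptance.R` (three full
runs plus the small checks) takes about three minutes.

Measured recovery under these conditions (acceptance script, seed 1):
noise-free bead error ~7e-14 %, 30 dB bead error 0.03 %, cell pixelwise
Pearson r = 0.97, calibration error ~1e-13 %.

All randomness flows through explicit integer seeds; child streams are
derived by counter (`child_seed`), never from global RNG state, and
simulation is bit-reproducible from the recorded seed.

## What the simulator does and does not establish

Passing closed-loop tests shows the reconstruction correctly inverts the
forward model it is paired with, at realistic noise, sampling and geometry.
It does not validate the elastic model against living cells: real cells are
viscoelastic, internally heterogeneous in refractive index, and sit in
acoustic fields with spatial structure — none of which the simulator
emulates.  The absolute pressure-to-indentation link is absorbed into the
calibration step, mirroring reference-bead practice; absolute kPa agreement
with any particular instrument therefore depends on that calibration, not on
the code.  Known numerical limitations: the unwrapping congruence step can
propagate isolated 2π errors in regions that violate the Itoh condition
(steep bead rims are masked by the displacement noise floor); the frame
matcher needs a visible vibration modulation and degrades below ~25 dB
intensity SNR on small fields of view; and the membrane-coupled inversion
assumes a smooth stiffness field for its fixed-point refinement.
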