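---
title: "Designing learned-optics EDOF microscopes with edofscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing learned-optics EDOF microscopes with edofscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edofscope)
```

## The problem and the model

A microscope objective with numerical aperture NA resolves finely but
focuses shallowly: the depth of field scales as $\lambda/\mathrm{NA}^2$.
`edofscope` models a computational way around the trade-off: a 4f relay
whose Fourier plane carries a phase-coding mask, followed by a
convolutional deblurring network. Mask and network are optimized
*jointly*, end to end, so the optics learn a point spread function (PSF)
that is nearly depth-invariant — blurred, but blurred the *same way*
everywhere in the target range — and the network learns to undo exactly
that blur.

Image formation is incoherent and shift-invariant. A scene slice at
depth $z$ contributes its convolution with the depth PSF
$h_z = |\mathcal{F}\{P\}|^2$, where the pupil function
$P = A\,e^{i\phi}$ has a circular amplitude $A$ (the mask is modeled as
lossless unless a metalens transmission table says otherwise) and phase
$\phi = \phi^{DF}_z + \phi^M$. Defocus enters as a quadratic phase
$\phi^{DF}_z = \psi_z\,(x_1^2+y_1^2)/a^2$ with the dimensionless defocus
coefficient

$$\psi_z = \frac{\pi}{\lambda}\Big(\frac1z - \frac1{z_0}\Big)a^2 ,$$

$a$ the effective pupil radius and $z_0$ the in-focus depth. $|\psi|$ is
the single number that quantifies how hard an EDOF problem is; the
worst case over a depth range lies at one of its endpoints because $1/z$
is convex:

```{r}
design_row("mitutoyo50x", 1e-3)
```

Two sampling rules close the design calculus. The pupil radius must
reach $(f_1/k)\sqrt{k_x^2+k_y^2}$ to transmit a spatial frequency pair
(`min_pupil_radius()`), and the mask must be sampled at
$\Delta s \le a\pi/(8\psi_{\max})$ or the simulated defocus phase
aliases (`max_sampling_pitch()`). The second rule is what separates the
two hardware families: moderate $\psi_{\max}$ admits a diffractive
element (micron-scale cells), extreme $\psi_{\max}$ forces sub-micron
cells, i.e. a metalens. The package treats the catalog aperture column
as a *diameter* and uses $a = r/2$ in all formulas, together with
standard objective focal lengths (45 mm, 9 mm, 4 mm for the 4X/20X/50X
presets); this is the convention under which the published design table
reproduces to within 1 % (2 % for the 4X rows, whose focal geometry is
not printed), and it is re-verified in the test suite.

## Phase-mask parameterizations

Four families share one contract — `mask_phase(mask, system)` returns a
phase map on the pupil grid:

* **DOE height map** — $\phi^M = k(n-1)h$, refractive index 1.5 at the
  550 nm design wavelength. Heights are the fabricated quantity.
* **Metalens radius map** — each unit cell holds a nanopillar whose
  radius sets the local phase through a phase–radius lookup table
  (`phase_radius_lut`). Real tables come from full-wave unit-cell
  simulation and load from CSV (`read_lut_csv()`); since no tabulated
  response ships with the package, a clearly-labeled synthetic default
  (`default_lut()`: phase linear in radius, $0 \to 2\pi$, unit
  transmission, radii from 40 nm to half of $\Delta s - 50$ nm) stands
  in. The pillar diameter cap of $\Delta s - 50$ nm is a fabrication
  constraint enforced by the constructor.
* **Cubic mask** — the classical wavefront-coding profile
  $\bmod(\alpha/N^3(x^3+y^3), 2\pi)$ on integer grid coordinates, with
  $\alpha \in \{6\pi, 200\pi, 360\pi\}$ preset for full depth ranges of
  200 µm / 2 mm / 3 mm (`cubic_alpha_for_dof()`). It serves as the
  fixed-optics baseline.
* **Free phase** — the phase map itself, the parameterization actually
  optimized during end-to-end training. Conversion to hardware happens
  at export: `as_doe_mask()` wraps the phase into $[0, 2\pi)$ and
  divides by $k(n-1)$; `as_metalens_mask()` inverts the LUT
  (`phase_to_radius()`, monotone interpolation, exact at knots).

Training on the phase (or height) and quantizing to radii afterwards
keeps the optimization smooth; the LUT round-trip error is below
$10^{-3}$ rad, far under the fabrication noise studied below.

## Sensor model and the deblurring network

Scene patches are values in $[0,1]$; rendering convolves with the
unit-sum PSF on a zero-padded frame and center-crops, so borders carry
no wrap-around (`render_slice()`). Depth integration over multiple
slices is a *mean* — the package has no radiometric model, and averaging
keeps intensities in $[0,1]$; training uses single-depth patches so this
only affects the optional stack mode. Sensor noise is i.i.d. Gaussian
added after integration and clipped to $[0,1]$; its scale
$\sigma_s = 0.01$ (on the unit intensity scale) is a package default,
chosen as a typical read-noise level for a well-exposed scientific
sensor. Poisson noise is out of scope.

The deblurring network is a U-Net: five resolution levels of 32, 64,
128, 256, 512 channels, each level two 3×3 convolutions followed by
rectification and batch normalization, 2×2 max-pooling downward, 2×2
transposed convolutions and skip concatenations upward, and a 1×1
projection at the end. The layer tally — 10 encoder + 8 decoder
convolutions + 4 transposed + 1 final — is the canonical accounting that
reaches exactly 23 convolution layers over a 32-to-512 channel range.
The head is residual: the projection passes through $\tanh$ (residual
bounded to $[-1,1]$), is added to the sensor image, and clamped to
$[0,1]$ — zeroing the projection makes the network an exact identity,
which the tests exploit as a contract. Inputs must have sides divisible
by 16 (four poolings). Batch normalization uses batch statistics during
training and frozen running statistics at evaluation.

There is no autodiff framework underneath: forward and backward passes
are written directly (im2col convolutions as BLAS matrix products, and
the matching adjoints for every operator, including $|\mathcal F\{\cdot\}|^2$
pupil optics, the unit-sum PSF normalization, crops and the FFT
convolution). Every operator's gradient, and the end-to-end gradient of
the loss with respect to a mask parameter, is checked against central
finite differences to $10^{-3}$ relative error in the suite.

## Training procedure

Each step samples one augmented patch (random crop, quarter-turn
rotations, flips, ±10 % brightness — quarter turns avoid interpolation
artifacts), assigns it one of $M = 5$ depths uniform *in diopters*
(equal $1/z$ spacing, so $\psi$ is sampled linearly), renders the
sensor image and scores the depth-averaged root-mean-square error

$$L = \frac1M \sum_{i=1}^{M} \sqrt{\tfrac1N \lVert I - I_R^{(i)}\rVert^2} .$$

No PSF-similarity penalty exists — depth invariance emerges because a
single network must deblur all depths. Optimization is Adam (betas
0.9/0.999), two stages: `train_stage1()` trains the network against
frozen optics (their PSFs are precomputed once), then `train_joint()`
updates mask and network together at separate learning rates. Reference
learning rates are 1e-7 for the optics and 1e-4 for the network — the
values used in the original multi-day GPU-scale optimization — and are
the package defaults. Depths are cycled one per step; losses are
averaged across depths by that cycling, matching sequential per-depth
processing.

## Desk-scale study conditions

The package's end-to-end property checks run on a single CPU in minutes,
not GPU-days, so the demonstration configuration scales the problem
down; the choices (also used by `test-acceptance.R`) are:

* optics: Mitutoyo50X preset, ±100 µm target ($\psi_{\max} \approx 10.5$),
  64×64 pupil grid, pad factor 2, PSFs cropped to 33×33;
* data: six 256×256 synthetic `mixed` textures; 48×48 training patches;
* network: the same 23-layer topology *narrowed* to 16–256 channels —
  the full 32–512 network is exercised by the architecture-contract
  tests, while training-trend checks use the thin variant so three
  replicates of 200 + 300 steps finish in minutes;
* optics learning rate 5e-3 (phase radians): with Adam the per-step
  update magnitude is about the learning rate, so a 300-step run needs a
  rate at which the cumulative phase motion is $O(1)$ rad to show any
  optical trend; the reference 1e-7 belongs to runs five orders of
  magnitude longer.

Under these conditions (three fixed seeds) the two-stage run reduces the
training loss by more than half and reduces the MTF depth-invariance
score — the mean pairwise $L_2$ distance between the radially averaged,
DC-normalized MTFs of the five training depths
(`depth_invariance_score()`; 0 iff all MTFs coincide) — relative to the
initial mask. These are *trend* checks: desk-scale runs demonstrate that
the gradients drive both components in the right direction, not the
reconstruction quality of the full-scale system, which required the
external training corpus and multi-day optimization.

## What the synthetic data does and does not emulate

`generate_image()` builds textures from band-limited Gaussian random
fields stacked over at least three octaves, anisotropic Gaussian blobs
and random filament strokes, contrast-stretched into $[0,1]$ — matching
the *multi-scale feature statistics* that motivated the original mixed
corpus (fluorescence, histopathology, natural images) at the same
nominal size (1000×1000, split 1500/150/150 via `generate_split()`).
They do not emulate staining spectra, photon statistics, optical
sectioning or semantic structure; a passing trend on them says the
optimization machinery works, not that a trained checkpoint transfers to
real tissue.

## Evaluation and fabrication tolerances

`evaluate_depths()` assigns test images to depths uniform across the
target range and reports PSNR (peak 1; infinite values capped at 99 dB
in tables) and single-scale SSIM (11-tap Gaussian window, $\sigma = 1.5$,
$K_1 = 0.01$, $K_2 = 0.03$, unit dynamic range — the de-facto standard
constants, verified against an independent reference implementation).
`mtf_bandwidth()` reports the outermost radial frequency at which the
MTF stays above a threshold of 0.1, the conventional usable-contrast
limit.

`fabrication_robustness()` models fabrication error as zero-mean
Gaussian noise on the fabricated quantity — nanopillar radii
($\sigma_r$ = 5, 12 nm studied) or DOE heights ($\sigma_h$ = 30, 50 nm) —
applied at test time with the network left untouched, clipping to
physical bounds (non-negative heights, radii within the LUT and pitch
cap). Sensor-noise seeds are derived per trial, independent of the noise
level, so the $\sigma = 0$ row reproduces the unperturbed evaluation
bit-exactly and level-to-level differences isolate the fabrication
effect. Note the phase impact of a radius error scales with the LUT
slope $\mathrm{d}\phi/\mathrm{d}r \approx 2\pi/(r_{\max}-r_{\min})$:
nanometer errors matter on fine-pitch (sub-micron-cell) metalenses and
are negligible on coarse ones.

## Numerical conventions and edge cases

* Pupil grid: $N$ samples per side, optical axis at index
  $\lfloor N/2\rfloor + 1$; grid size from the aperture and pitch,
  rounded up to even (one sample per mask cell).
* PSFs: pupil zero-padded by a factor 2 before the FFT (no circular
  wrap-around), intensity centered with `fftshift2()`, center-cropped
  (odd crops keep the peak centered) and normalized to unit sum, making
  image formation flux-preserving and metrics scale-free. The absolute
  transform constant is not claimed — only unit-sum PSFs are ever used.
* MTFs: magnitude of the PSF's DFT, exactly 1 at DC by construction;
  radial profiles by nearest-integer-radius bin averaging into
  $\lceil N/2\rceil$ bins.
* Phase wrapping into $[0, 2\pi)$ uses the floored modulo; a phase of
  exactly $2\pi$ maps to 0, which the LUT inversion tests pin down.
* Degenerate inputs fail loudly: an all-zero pupil (no energy), a scene
  patch smaller than the crop target, a zero $\psi_{\max}$ in the pitch
  bound (unbounded pitch), non-monotone LUTs, and network inputs not
  divisible by 16 all raise errors naming the offending quantity.
* Perturbation clipping (rather than resampling) at physical bounds is
  the chosen contract for fabrication noise; it slightly biases extreme
  draws toward the bounds, which is the behavior of a real process spec.
* Determinism: all stochastic elements (data, initialization, noise,
  perturbations) run under derived sub-seeds (`derive_seed()`, kept
  below $2^{31}$); fixed-seed runs are bit-reproducible on one device.

## Known limitations

Scalar paraxial diffraction only (no vectorial high-NA model), single
wavelength, isoplanatic PSFs, Gaussian read noise without a photon
budget, and a linear-interpolation LUT without angular dispersion of the
meta-atoms. The Zernike-basis mask parameterization used by a competing
design is deliberately absent. Checkpoints are runtime artifacts (RDS);
the repository itself contains only code and small text fixtures.
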