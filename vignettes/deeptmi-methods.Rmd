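---
title: "Unrolled reconstruction and tumor-margin segmentation: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unrolled reconstruction and tumor-margin segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deeptmi)
```

# The imaging model

The package works with the stepped-frequency scattering model of near-field
millimeter-wave imaging. A scene is divided into pixels carrying a complex
reflectivity $s$, and each measurement at scan position $r$ and wavenumber
$k = \omega/c$ collects the round-trip phase of every pixel:

$$ S(r, k) = \sum_x s(x)\, e^{-2jk R^x(r)} \qquad\Longleftrightarrow\qquad
   \mathbf{S} = \mathbf{F}\mathbf{s}, $$

with $R^x(r)$ the distance between pixel $x$ and the scan position (a
transmit plus receive path in bistatic mode). The kernel is pure phase:
amplitude spreading, antenna patterns and multiple scattering are outside
the model. The matrix is column-normalized by $1/\sqrt{\text{rows}}$ so its
operator norm is $O(1)$; the same normalized matrix is used to synthesize
and to invert measurements, so the convention cancels out of every metric.

Three reconstruction routes share this operator:

* **Backpropagation (BP)**: the adjoint image $\mathbf{F}^H \mathbf{S}$,
  equivalent to delay-and-sum focusing. It is the conventional baseline and
  the network's input.
* **ISTA / forward–backward splitting** on the $\ell_1$-regularized
  least-squares cost
  $C(\mathbf{s}) = \tfrac12\lVert\mathbf{Fs}-\mathbf{S}\rVert_2^2
   + \lambda\lVert\mathbf{s}\rVert_1$:
  repeated gradient steps $\mathbf{s} - \alpha\mathbf{F}^H(\mathbf{Fs}-\mathbf{S})$
  followed by complex soft thresholding
  $\mathcal{P}_t(x) = x\max(1 - t/|x|, 0)$, the exact proximity operator of
  the $\ell_1$ norm for complex vectors (the phase is preserved, the
  modulus is shrunk). The step size defaults to $1/L$ with $L$ the largest
  eigenvalue of $\mathbf{F}^H\mathbf{F}$, estimated by power iteration,
  which guarantees a monotone cost.
* **The unrolled recurrent auto-encoder**: $N-1$ layers
  $\mathbf{s}^{k+1} = \mathcal{P}_{\lambda_k}(\mathbf{W}\mathbf{s}^k +
  \mathbf{B}\mathbf{S})$ with weights tied across layers, followed by a
  fixed decoder $\mathbf{F}$ that maps the image estimate back to data
  space. At initialization $\mathbf{W} = \mathbf{I} - \alpha\mathbf{F}^H\mathbf{F}$,
  $\mathbf{B} = \alpha\mathbf{F}^H$ and $\lambda_k = \alpha\lambda$, so the
  untrained network reproduces $N-1$ ISTA iterations exactly — the central
  correctness oracle of the test suite.

Training is unsupervised: the only objective is the normalized data
residual $\lVert\mathbf{F}\hat{\mathbf{s}} - \mathbf{S}\rVert_2 /
\lVert\mathbf{S}\rVert_2$, so no ground-truth image ever enters the
optimization. The decoder stays frozen; training it jointly with the
encoder would let the pair fit any data with meaningless images. Complex
weights are optimized by treating real and imaginary parts as independent
real parameters; the gradients are derived analytically with Wirtinger
calculus (validated against central finite differences in the tests) and
applied with Adam.

# The phase-error model and what is learnable

Trajectory inaccuracies corrupt each scan position's samples with the
phase factor $e^{-2jk\delta}$, $\delta \sim U[-w, +w]$. The package
distinguishes two readings:

* **Systematic** (default): one trajectory draw per dataset, shared by
  every training and test measurement. This models a miscalibrated
  acquisition system, and it is the regime in which training is
  meaningful: refining $\mathbf{B}$ (the learned adjoint) and the
  thresholds compensates a fixed model error.
* **Per-sample**: an independent draw per measurement. Fixed weights
  cannot compensate random per-measurement corruption; we verified that
  the fully converged classical solver reduces the residual by under 1%
  relative to the 8-layer network in that regime, leaving nothing for
  training to recover. The option exists for robustness experiments.

The half-width is dimensionally ambiguous in its original statement (a
uniform distribution with a "variance" quoted in meters), so it is an
exposed parameter. The desk presets use $w = \lambda_c/8$ (simulation,
phase excursions up to about $\pm\pi/2$) and $w = \lambda_c/6$ (phantom
analog). The phantom value was chosen as the strongest systematic error at
which the learned level-set output still identifies margins reliably; a
sweep shows both the learned and the conventional route collapse together
near $w \approx \lambda_c/4.5$, where the per-position phases decorrelate
and the measurements no longer determine the scene. At $\lambda_c/6$ the
conventional BP image is already degraded to a structural similarity of
roughly 0.28 against the truth while the level-set output remains above
0.94 — the qualitative contrast the method is designed to demonstrate.

# Desk-scale study conditions

Both bundled studies also exist as literal presets (`"paper-sim"`,
`"paper-phantom"`) carrying the printed scene sizes, counts and spacings.
The acceptance-scale presets keep every count that defines the studies —
30×30 pixels, 100 train / 30 test samples, 8 shrinkage layers,
$\lambda = 10^{-7}$, learning rate $10^{-4}$, 6 epochs, 50 phantom
arrangements — and redesign only the geometry, for two reasons.

First, invertibility. Whether $\mathbf{F}$ has full column rank is decided
by how much of the scene's spatial-frequency band the acquisition covers:
a monostatic/bistatic sweep over $[f_{\min}, f_{\max}]$ reaches the
annulus of radii $2k_{\min}$ to $2k_{\max}$, windowed by the aperture's
angular extent. At a 2 cm scene with 30×30 pixels and a 90 GHz center
frequency the pixel band exceeds what any aperture covers and the matrix
is numerically rank deficient (condition number about $10^5$); no solver,
classical or learned, can then reach sub-percent reflectivity error. The
simulation preset therefore uses a 4.9 × 4.9 cm scene surrounded by a
bistatic circular trajectory (128 positions, radius 12 cm, 16 frequencies
over 70–110 GHz), and the phantom preset a 2.4 × 2.4 cm scene with a
monostatic circular scan (96 positions, radius 8 cm, 12 frequencies over
75–110 GHz, 16×16 pixels).

Second, depth. The unrolled network exists because the classical
iteration "requires many iterations to converge"; if the operator is so
well conditioned that 8 iterations already converge, training has nothing
to accelerate and the loss curves are flat. The simulation scene extent
was placed just below the rank-deficiency transition (condition number
$\approx 28$, a single weak mode), where full iteration is still feasible
(a few thousand iterations) but depth-8 is genuinely short.

The phantom analog scales all phantom lengths by ten (tumor diameters
1–4 mm, center distances 5–10 mm, drawn uniformly) while keeping the
75–110 GHz band and the fitted Cole–Cole dielectrics literal: at the
printed 0.1–0.4 mm the tumors are deeply sub-wavelength
($\lambda \approx 3$ mm) and no aperture can separate two of them. The
aperture surrounds the scene instead of the printed 2 × 2-position planar
raster because four measurements cannot determine 256 pixels; the raster
survives in the literal preset and the aperture is a configuration field
throughout.

# Tissue model

Dispersive skin and tumor phantoms follow the single-pole Cole–Cole
model

$$ \varepsilon_r(\omega) = \varepsilon_{ro} +
   \frac{\Delta\varepsilon_r}{1 + (j\omega\tau)^{1-\alpha}} +
   \frac{\sigma_s}{j\omega\varepsilon_0}, $$

with the principal branch for the complex power and the
$\varepsilon' - j\varepsilon''$ sign convention. The bundled parameters
(`skin_cole_cole()`) are fits of fabricated skin-mimicking and malignant
(SCC-like) phantom materials: normal skin
$\varepsilon_{ro} = 4.25$, $\Delta\varepsilon_r = 45.02$,
$\tau = 5.96$ ps, $\sigma_s = 5\times10^{-4}$ S/m, $\alpha = 0.15$;
malignant skin $10$, $34.99$, $3.04$ ps, $4\times10^{-4}$, $0.05$. The
implementation is pinned against a 50-digit arbitrary-precision oracle at
several band frequencies.

The scalar reflectivity a pixel contributes to the forward model is the
Fresnel half-space contrast evaluated at the sweep's center frequency,
taken *differentially* against the intact normal slab: normal and
background pixels are zero, tumor pixels carry
$(\sqrt{\varepsilon_n}-\sqrt{\varepsilon_t})/(\sqrt{\varepsilon_n}+\sqrt{\varepsilon_t})$
(magnitude about 0.105 at 92.5 GHz). This mirrors the background
subtraction a calibrated system performs before inversion, keeps the scene
sparse (tumors are the only scatterers, which is the premise of the
$\ell_1$ machinery), and makes the tumor-to-clutter ratio meaningful: with
an air–skin surface reflection left in, normal pixels would reflect six
times more strongly than the tumor contrast and every tumor metric would
be dominated by the slab surface. The mapping is pluggable
(`contrast_fn`) for studies that want the surface term.

# Segmentation and figures of merit

The level-set rule labels a pixel tumor when its magnitude reaches half
the image maximum (scale invariant; an automatic bimodal Otsu rule is the
alternative). The reported quantities are:

* **IoU** and **shape error** $= 100(1-\text{IoU})$, computed between the
  half-maximum segmentation and the ground-truth mask;
* **rms relative error** $= 100\,\lVert\hat{\mathbf{s}}-\mathbf{s}\rVert_2
  / \lVert\mathbf{s}\rVert_2$ (the global norm ratio; a per-pixel reading
  of "relative error" is possible but not implemented);
* **SSIM** with a 7×7 uniform sliding window, stabilizers $(0.01)^2$ and
  $(0.03)^2$ on per-image max-normalized magnitudes, unbiased covariance;
* **normalized MSE**, the pixel mean of squared differences of the same
  normalized magnitudes;
* **T/C**, $20\log_{10}$ of the peak magnitude inside the ground-truth
  tumor region (dilated by one pixel to tolerate sub-pixel localization
  error) over the peak outside it. A clutter-free image is reported at the
  guard floor (240 dB) and flagged.

For the phantom comparison the conventional arm is the raw adjoint image,
while the learned arm's final output is its *level-set reconstruction* —
the image restricted to its half-maximum level set — because margin
identification, not amplitude mapping, is that method's product. This is
why the learned arm can be clutter-free by construction when its level set
stays inside the dilated tumor region.

# Numerical choices and degenerate inputs

* Step size: power iteration on $\mathbf{F}^H\mathbf{F}$ from a fixed
  deterministic start, relative tolerance $10^{-6}$; the Gram matrix is
  cached so solver iterations and cost evaluations are image-sized.
* The ISTA cost is recorded every iteration via the cached Gram identity
  $\lVert\mathbf{Fs}-\mathbf{S}\rVert^2 = \mathbf{s}^H\mathbf{Gs} -
  2\,\mathrm{Re}(\mathbf{s}^H\mathbf{F}^H\mathbf{S}) +
  \lVert\mathbf{S}\rVert^2$; a cost growth beyond $10^6\times$ aborts with
  a step-size diagnostic.
* Soft thresholding at $t = 0$ is the exact identity; a zero entry stays
  zero for any threshold.
* A scan position coinciding with a pixel center ($R = 0$) is flagged and
  its entry phase defined as 1.
* Adam uses $\beta_1 = 0.9$, $\beta_2 = 0.999$ and $\epsilon = 10^{-3}$.
  The large $\epsilon$ is deliberate: with 2.6 million dense parameters
  and minibatch gradients of rank a-few, most coordinates carry pure
  noise, and the canonical $\epsilon = 10^{-8}$ turns them into
  full-learning-rate sign steps that swamp the small informative signal (a
  visible warm-up bump in the loss). Batch size defaults to 10.
* Thresholds are clamped at zero after every update. Training is bit-for-bit
  deterministic given the seed; a single master seed fans out to stage
  seeds by stable string hashing.
* Tumor arrangements that overlap, leave the slab, merge on the grid, or
  cover no pixel center are rejected and redrawn; more than 1000
  rejections abort with an infeasibility error.

# What the synthetic data do and do not show

The generator emulates the two study conditions: a single stationary
point target with systematic trajectory phase error (simulation study) and
two-sphere Cole–Cole tumor phantoms in a skin slab (phantom study). It
does not emulate antenna patterns, amplitude decay, mutual coupling,
dispersion across the band (the reflectivity is frequency-flat, evaluated
at the center frequency), rough surfaces, or full-wave multiple
scattering. Passing tests therefore demonstrate that the algorithms invert
the stated linear phase-only model under the stated corruption — not that
the pipeline is validated on measured data. The two honest gaps against
the physical-experiment numbers are documented in the README's
reproduction section: a dense circular aperture focuses too well for the
conventional baseline to degrade to the measured 5.5 dB tumor-to-clutter
ratio, and a per-image max-normalized adjoint image cannot reach a
normalized MSE of 0.41 against a sparse truth (the stated value likely
reflects the 4-position physical aperture and/or a different
normalization, which its source leaves unstated).

# Problem sizes

The bundled acceptance-scale runs use a 900-pixel scene with 2048
measurements (simulation) and a 256-pixel scene with 1152 measurements
(phantom); training touches 100 × 6 and 50 × 6 sample visits respectively,
and the noise-free recovery iterates the solver to convergence (a few
thousand iterations). These sizes were chosen so that a complete
reproduction — both studies plus all property suites — runs in a few
minutes on a single CPU.
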