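# deeptmi

Reconstruction and tumor-margin segmentation for near-field
millimeter-wave (mmW) imaging of skin, built around a physics-unrolled
recurrent auto-encoder ("DeepTMI") and the classical solvers it descends
from.

Surgeons resecting skin tumors need the tumor/normal border, which mmW
imaging can supply non-invasively: malignant tissue has a markedly
different complex permittivity from normal skin at 75–110 GHz, so a
reconstructed reflectivity map can be segmented into tumor and normal
regions. The package provides the whole simulation-to-metrics chain for
that problem:

* **Forward model** — the stepped-frequency scattering operator
  `S = F s`, with entries `exp(-2jkR)` linking each scan position and
  wavenumber to each scene pixel, its adjoint (backpropagation /
  delay-and-sum), and a seeded uniform trajectory phase-error model.
* **Classical baselines** — the backpropagation image `F^H S` and ISTA
  (forward–backward splitting) on the l1-regularized cost
  `C(s) = 1/2 ||F s - S||² + λ ||s||₁` with complex soft thresholding and
  a power-iteration step size.
* **DeepTMI** — ISTA unrolled into `N - 1` weight-tied shrinkage layers
  `s ← P_λk(W s + B S)` plus a frozen forward-propagation decoder,
  initialized from the physics (`W = I - αF^H F`, `B = αF^H`) and trained
  *without ground truth* by Adam on the normalized measurement residual
  `||F ŝ - S|| / ||S||`. Analytic Wirtinger gradients; no deep-learning
  framework required.
* **Phantom simulator** — single-pole Cole–Cole dispersive permittivity
  for skin/tumor phantom materials, digital slab phantoms with spherical
  tumor inclusions, and seeded labeled datasets for the two bundled
  studies.
* **Metrics** — half-maximum level-set segmentation, IoU / shape error,
  rms relative error, SSIM, normalized MSE and tumor-to-clutter ratio
  (dB).

## Worked example

A point scatterer in a 4.9 × 4.9 cm scene (30 × 30 pixels), scanned by a
bistatic circular trajectory with a 40 GHz sweep, with a systematic
trajectory error of ±λ/8:

```r
library(deeptmi)

sweep <- frequency_sweep(70e9, 110e9, 16)
grid  <- imaging_grid(c(0.049, 0.049), c(30, 30))
scan  <- scan_circular(0.12, 128, "bistatic", rx_offset_deg = 12)
op    <- forward_operator(grid, scan, sweep)

truth <- rep(0i, grid$npix); truth[436] <- 1
S     <- apply_forward(op, reflectivity_map(truth, grid))
S_err <- inject_phase_error(S, op, phase_error_spec(3.33e-3 / 8), seed = 42)

# conventional image still localizes the target...
bp <- backprojection_image(S_err, op)
which.max(Mod(bp$values))
#> [1] 436

# ...and the sparse solver recovers the exact shape from clean data
res <- ista_solve(S, op, ista_config(lambda = 1e-7, iterations = 2000))
shape_error(levelset_segment(res$image), truth != 0)
#> [1] 0
rms_relative_error(res$image, truth)
#> [1] 0.49

# the unrolled network starts exactly at 8 ISTA iterations
alpha <- estimate_step_size(op)$alpha   # 0.4236
net   <- init_from_physics(op, n_layers = 9, alpha, lambda = 1e-7)
network_loss(net, S_err)
#> [1] 0.5493
```

The shape error of 0% means the half-maximum segmentation of the
reconstruction equals the true target mask exactly (IoU = 1); the 0.49%
relative error is the global norm ratio `100·||ŝ - s||/||s||` after 2000
solver iterations (it keeps falling to below 1e-5 % when iterated to
convergence). The 0.55 network loss is the residual floor set by the
phase corruption, which training then reduces.

The two bundled end-to-end studies are one call each:

```r
sim <- run_simulation_study(preset_config("desk-sim"), seed = 1)
ph  <- run_phantom_study(preset_config("desk-phantom"), seed = 1)
```

`sim` trains the 8-layer network on 100 seeded point-target measurements
(6 epochs, λ = 1e-7, learning rate 1e-4) and evaluates shape and
reflectivity recovery on 30 held-out samples; `ph` does the same for 50
two-tumor Cole–Cole phantom arrangements and reports backpropagation and
DeepTMI side by side (SSIM, normalized MSE, T/C).

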