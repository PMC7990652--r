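---
title: "Methods: simultaneous imaging and segmentation from plane-wave channel data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simultaneous imaging and segmentation from plane-wave channel data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A single 0° plane-wave transmission insonifies the whole field of view
at once, so a linear array can image at hundreds of frames per second —
at the cost of severe clutter and poor contrast compared with focused
transmissions. `pwnet` implements an end-to-end alternative to
delay-and-sum (DAS) beamforming followed by segmentation: a single
fully convolutional network consumes the raw (or partially beamformed)
IQ channel data of one plane-wave acquisition and emits, in parallel,

* `D` — a display-ready B-mode-like image on the `[0, 1]` scale, and
* `S_p` — a continuous cyst-segmentation map on the same grid,

targeting small anechoic structures (cysts, calyces, follicles) in
speckle-generating tissue.

## Data model and processing chain

**Simulator.** Tissue is a uniform random cloud of point scatterers
with standard-normal reflectivities; a cylindrical (in-plane:
circular) cyst multiplies reflectivities inside its disc by an
echogenicity factor (0 = anechoic). Each receive channel records the
superposition over scatterers of a Gaussian-windowed sinusoid at the
4 MHz transmit frequency arriving at `t = z_s/c + dist(s, e)/c`, with
1/dist spreading and optional two-way attenuation
`10^(-a f[MHz] path[cm] / 20)` at `a = 0.5` dB/cm·MHz. The pulse's
−6 dB spectral width matches the probe's 0.65 fractional bandwidth at
5.5 MHz; its support is bounded by the 4-cycle pulse length.
Internally the simulator accumulates linearly interpolated impulses on
a 4× oversampled time grid and convolves once per channel with the
sampled pulse via FFT; the triangular-kernel spectral error at the
pulse band is below 0.5 %.

Deliberate simplifications (each carried as configuration, none
affecting the learning task's structure): the elevational dimension is
collapsed (cyst targets are cylinders, so the in-plane field is
representative); a single effective two-way pulse replaces the
excitation ⊗ impulse-response chain of full acoustic-field simulators;
attenuation acts at the transmit frequency only; elements are ideal
points without directivity or apodization.

**Scatterer density.** Classical 3-D simulations use 50 000 scatterers
in a 40 × 50 × 7 mm volume "to ensure fully developed speckle"; an
elevation-focused beam integrates many of those out-of-plane
scatterers into every resolution cell. A 2-D in-plane simulator loses
that reservoir, and what governs Rayleigh statistics is the count per
resolution cell, not the total. Measured on this simulator, the
envelope signal-to-noise ratio of tissue is ≈ 1.44 at 20 000 in-plane
scatterers, ≈ 1.65 at 50 000 and ≈ 1.81 at 100 000 (the Rayleigh
limit is `sqrt(pi / (4 - pi)) ≈ 1.91`). The package default is
therefore 100 000 in-plane scatterers, fixed before the speckle test
was frozen; the test asserts envelope SNR in `[1.7, 2.1]` at the
default density.

**Beamforming chain.** `demodulate()` mixes the RF down by the probe
center frequency and low-pass filters with a 63-tap linear-phase
windowed-sinc FIR (cutoff at the −6 dB bandwidth,
`0.65 × 5.5 MHz`), scaled so the baseband magnitude matches the
analytic envelope. The unfocused network input `I_d` maps each channel
onto 256 (desk scale: 64) depth rows by linear interpolation under the
two-way rule `depth = c t / 2`, then normalizes by the global maximum
absolute value into `[-1, 1]`. The DAS image applies per-pixel dynamic
receive delays `t = z/c + dist(pixel, element)/c` with baseband phase
rotation `exp(+j 2π f_d t)`, one scan line per element lateral center,
uniform weights, and sums across the aperture; envelope detection and
log compression clip to a 60 dB dynamic range and the display map
`I_n = (I_dB + 60) / 60` rescales to `[0, 1]`. The subaperture input
`I_fds` keeps the delayed (unsummed) stack, sums it within 16 groups
of 8 contiguous elements, and interleaves real and imaginary parts
into 32 feature channels; the 16 complex subaperture images sum
exactly to the DAS image. Delays are evaluated directly at the grid
depths, which composes the "delay, then downsample" order in a single
step.

**Enhanced targets.** The image decoder is *not* trained to reproduce
the cluttered single-plane-wave DAS image. Instead the training target
`E` zeroes `I_n` inside the true cyst mask, restoring the anechoic
appearance while leaving tissue untouched. `E` is used only during
training.

## Network and training

The architecture is U-Net-like with one VGG-13-pattern encoder — ten
3×3 convolutions, each followed by batch normalization and a
rectified-linear activation (the VGG convention; unspecified in the
original description), interleaved with four 2×2 max-pools while
feature widths follow `(1, 2, 4, 8, 8) × base_width` — and one or two
mirrored decoders with 2×2 stride-2 transposed convolutions,
channel-concatenation skip connections at matched scales (the U-Net
convention), nine convolutions each, and a sigmoid head. The two
decoder heads produce `D` and `S_p`; a single-decoder variant with a
one-channel input is the classical U-Net baseline, and a 32-channel
first layer accepts the subaperture input. Convolutions use same
padding, so outputs keep the input's spatial shape (which must be
divisible by 2^4).

The loss is the unweighted sum (weights 1, 1) of the per-image mean
absolute error between `D` and `E` and a soft Dice loss
`1 − (2 Σ S_p S_t + ε) / (Σ S_p + Σ S_t + ε)` with `ε = 1e-6`
guarding empty masks. Optimization is Adam. The full-scale recipe is
learning rate 1e-5, 25 epochs, minibatch 16; the desk-scale profile
keeps the minibatch but uses a step schedule (5e-3 for 20 epochs,
then 1e-3 for 6 — about 650 iterations), because 1e-5 cannot move a
freshly initialized network measurably within a single-CPU iteration
budget (the full-scale runs take 27 625 iterations). Checkpoints keep final-epoch weights; there
is no early stopping. One master seed derives initialization, data
order and augmentation; batch-norm running statistics are tracked
with momentum 0.1 for inference.

Layers are implemented in RcppArmadillo (im2col + GEMM in single
precision; double precision elsewhere) because no deep-learning
framework is available to the package at run time; gradients are
verified against central finite differences in the test suite.

## Evaluation

All image metrics operate on uncompressed amplitudes recovered from
the display scale by `s = 10^(60 (pixel − 1) / 20)`, the inverse of
log compression plus display rescaling; pixels at the display floor
map to `10^-3` (the clipped value is used, a documented choice).

* **DSC** after binarizing `S_p` at 0.5; two empty masks score 1.
* **Contrast** `20 log10(S_i / S_o)` between a 2 mm-radius disc at the
  cyst center and a same-size, same-depth background region; bounded
  at −60 dB by the dynamic range.
* **SNR** `S_o / σ_o` of the background region (Rayleigh speckle
  ≈ 1.91).
* **gCNR** `1 − Σ min(p_i, p_o)` with PMFs estimated by 100
  equal-width shared histogram bins (bin count is a documented choice;
  sensitivity is mild — halving or doubling the bin count moves
  Gaussian-pair gCNR by < 0.01) over the full ground-truth mask and an
  equal-size, same-depth background.
* **PSNR** `10 log10(1 / MSE)` against `E`.
* **CV** `sd/mean × 100 %` across repeated acquisitions (sample
  standard deviation).

Background regions mirror the target region across the lateral
midline; if the mirror touches the cyst, a rigid lateral shift is
tried, and for large targets near the midline the same per-row pixel
count is taken from the non-cyst columns farthest from the cyst. A
detection filter excludes test cases with DSC < 0.05 (decided once on
the designated baseline test set) and a per-radius detection-rate
table is reported.

On enhanced images the inside-mask amplitudes sit exactly at the
−60 dB floor and gCNR is 1 up to histogram degeneracies: the
*amplitude level* inside the cyst is pinned to the floor, while the
ratio-based contrast of `E` additionally depends on the tissue level `S_o`
and is therefore around −35 to −45 dB rather than −60 (consistent
with published enhanced-image contrast curves). The acceptance test
asserts the floor-pinning and gCNR; treating "enhanced contrast
= −60 dB" literally would contradict the metric's own definition.

## Baselines

Binary thresholding (BT) labels pixels below `0.70 × mean(I_n)` as
cyst, removes 8-connected components under 50 px, closes with a
1 px-radius disk and dilates with a 2 px-radius disk. Non-local means
(NLM) uses a 21 px search window, 5 px comparison window and 0.1
smoothing on the `[0, 1]` image with Gaussian-weighted patch
distances (the classical formulation; the reference implementation is
identified only by its hyperparameter names). `das_nlm_bt()` composes
DAS → NLM → BT.

## Desk-scale profile and what a green test establishes

`desk_profile()` pins the single-CPU configuration: 64-row grid, base
width 8, 40 MHz sampling, 100 000 scatterers, 200 training phantoms
doubled to 400 by lateral flips (flips of unfocused representations
are materialized by mirroring, exact for every deterministic stage)
plus 50 test phantoms doubled to 100 examples, radii {3, 4, 6, 8} mm,
sound speeds drawn from the 1420–1600 m/s grid, minibatch 16, and the
Adam step schedule above, sized to the stated time budget. Lateral cyst centers are drawn
from the −16…0 mm grid conditionally on the radius so the disc stays
inside the ±20 mm phantom (the corner combinations of the full grids
would clip the phantom edge).

A green scaled-down learning test establishes that the pipeline's
pieces compose correctly and that the architecture can learn the
channel-data → (image, mask) mapping from this simulator's physics at
reduced capacity. It does not establish full-scale image quality,
robustness to experimental-scanner effects (element directivity,
fixed-pattern noise, tissue heterogeneity), or in-vivo performance —
the simulator contains none of those.

One acceptance-level quantity is known not to reach its full-scale
counterpart at this size: the mean detected-case segmentation DSC.
Training soft-Dice continues to fall while test DSC plateaus — a
generalization ceiling set by the 200 unique speckle realizations
(full-scale training uses tens of thousands), compounded by the
narrower network and coarser axial grid; the shortfall concentrates
in the smallest radii, and predictions under-segment the cyst rim
(the familiar small-structure bias of soft-Dice at low capacity),
while the radius trend itself reproduces the full-scale pattern. The
corresponding test reports the deviation rather than relaxing the
bound; gCNR, contrast-improvement and SNR-improvement criteria meet
their bounds at the same scale.

## Numerical choices and degenerate inputs

* Normalization of an all-zero grid, log compression of an all-zero
  image, contrast with a zero-amplitude background and CV with zero
  mean are errors by contract; a zero-variance SNR region reports
  infinite SNR with a warning, and identical images report infinite
  PSNR.
* gCNR of two identical degenerate (zero-range) distributions is 0.
* DSC of two empty masks is 1 (perfect agreement on absence).
* Max-pool ties take the first maximum in column order; this only
  affects gradient routing.
* The sound speed assumed for beamforming defaults to the true
  simulated value and is configurable (1540 m/s is the conventional
  assumption for unknown media).
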