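---
title: "Learned half-scan FBP for 3D photoacoustic tomography: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learned half-scan FBP for 3D photoacoustic tomography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pactfbp)
```

## The problem

In 3D photoacoustic computed tomography (PACT) of the breast, a pulsed
laser induces an initial acoustic pressure distribution $p_0(\mathbf r)$
whose outgoing waves are recorded by ultrasound transducers. Practical
breast imagers place their transducers on a *hemispherical* surface: an
arc-shaped probe of radius 85 mm spanning 90° is rotated about the
vertical axis, so the aperture covers only the lower half of a sphere.
Data acquired this way are *half-scan* data. The inverse problem — recover
$p_0$ from half-scan data — is known to be uniquely and stably solvable
when the object lies inside the convex hull of the aperture, but no
closed-form inversion formula is known. Standard filtered backprojection
(FBP) formulas derived for closed (full-scan) apertures produce concentric
arc-shaped artifacts, centered at the rim of the open surface, when
applied to half-scan data; iterative reconstruction is accurate but slow.

This package implements a *learned* half-scan FBP,

$$\hat{\mathbf f} = \mathbf H^\dagger \, F_\theta \, \mathbf p,$$

where $\mathbf H$ is a discrete-to-discrete imaging operator,
$\mathbf H^\dagger$ its exact algebraic adjoint (backprojection), and
$F_\theta$ a *strictly linear* convolutional network acting in the data
domain — the learnable surrogate for the unknown half-scan filter. The
filter is trained so that filtering followed by backprojection matches the
true object on supervised pairs $(\mathbf f^{(k)}, \mathbf H \mathbf
f^{(k)})$ under a mean-squared-error loss. Because the underlying inverse
mapping is well-posed and the physics enters through $\mathbf H^\dagger$,
the learned filter generalizes robustly beyond its training distribution —
the property the desk-scale studies in this package exercise.

## Discretization of the imaging model

The continuous model is the standard lossless, acoustically homogeneous
spherical-mean relation: the pressure at transducer position
$\mathbf r_q$ is $\tfrac{1}{4\pi c_0^2}\,\partial_t \int p_0(\mathbf r)\,
\delta(t - |\mathbf r_q - \mathbf r|/c_0)/|\mathbf r_q-\mathbf r|\,
d\mathbf r$. The discrete operator `apply_forward()` composes:

1. **Spreading.** Each voxel (center $\mathbf r_n$, value $f_n$, spacing
   $h$) deposits $f_n h^3 / (4\pi c_0^2 d\, \tau_k)$ onto the time bins
   around its arrival $\tau = d/c_0$, weighted by the triangle kernel
   $\lambda(u) = \max(0, 1-|u|)$ with $u = (w\,\Delta t - \tau)/\tau_k$.
2. **Differentiation.** A central difference in time,
   $(s_{w+1} - s_{w-1})/(2\Delta t)$, with signals taken as zero outside
   the recorded window (consistent with the zero padding the filter
   network applies on the time axis).

The kernel half-width is $\tau_k = \max(\Delta t,\ h/c_0)$. When the
sampling interval is no finer than the voxel transit time
($c_0 \Delta t \ge h$) this is exactly two-bin linear interpolation — the
familiar interpolated-delay model. At finer sampling, a fixed-width
two-bin kernel undersamples the spherical shell (the shell a single time
bin sees is thinner than a voxel) and point quadrature turns into noise;
widening the kernel to the voxel transit time restores a consistent,
mass-preserving quadrature. All desk-scale configurations in this package
satisfy $c_0\Delta t \ge h$, so they use the plain two-bin rule.

`apply_adjoint()` is the exact transpose: the transposed difference
stencil followed by a gather with identical weights. The dot-product
identity $\langle \mathbf H\mathbf f, \mathbf p\rangle = \langle \mathbf
f, \mathbf H^\dagger\mathbf p\rangle$ holds to ~1e-16 relative in double
precision (the test suite asserts 1e-10). Per-voxel accumulation order is
fixed (transducer index increasing), so an adjoint restricted to a y-slab
(`voxel_subset`) is *bit-identical* to the corresponding entries of the
full adjoint — the property the slab training loss relies on.

The global scale of $\mathbf H^\dagger$ is deliberately not normalized;
see the training section.

### Validating against the closed-form N-wave

A homogeneous sphere (radius $a$, amplitude $A$, distance $d$) produces
the N-wave $p(t) = A(d - c_0 t)/(2d)$ on $d-a < c_0 t < d+a$
(`analytic_sphere_signal()`). The simulated signal matches this closed
form to a fraction of a percent across the interior ramp; the *relative
L2* disagreement is concentrated entirely at the two edge
discontinuities. This is irreducible at a given resolution: the N-wave
has unbounded bandwidth, and any discretization supported on voxels of
size $h$ smooths the jumps over $\sim h/c_0$ in time, contributing a
relative L2 error that scales like $\sqrt{h}$ (about 15–20% for a 6 mm
sphere at $h = 0.5$ mm, for any choice of $\Delta t$). The package
therefore assesses forward-model fidelity two ways: raw error, which must
decrease monotonically under grid refinement, and error *within the band
the grid can represent* — both signals apodized by a Gaussian low-pass of
HWHM $h/c_0$ — which is a few percent at $h = 0.5$ mm. Matching the sharp
closed form to a few percent in raw L2 would require $h \approx 0.03$ mm
and is not a meaningful target for a voxel model at laboratory
resolutions.

## Standard FBP baseline

The baseline (`reconstruct_standard_fbp()`) is universal backprojection:
the filtration $b = 2p - 2t\,\partial p/\partial t$ (central difference,
zero-extended) followed by weighted backprojection with solid-angle-style
weights $\omega_{qn} = \Delta S_q\, |\hat{\mathbf n}_q\cdot(\mathbf r_n -
\mathbf r_q)|/d^2$ and linear temporal interpolation of $b$ at the
continuous arrival index. Each voxel is normalized by its own
$\sum_q \omega_{qn}$ rather than a fixed total solid angle: open apertures
have voxel-dependent angular coverage, and the voxel-wise normalization
puts half- and full-scan reconstructions on a common quantitative scale.
On full-scan data of a centered sphere this recovers the interior
amplitude essentially exactly; on half-scan data it exhibits the
characteristic arc artifacts, and the test suite asserts the resulting
MSE penalty on off-center phantoms. As in the reference pipeline, sharp
synthetic signals are apodized with the Gaussian low-pass before
filtration to suppress edge ringing.

## The strictly linear filtering network

`init_network()` builds a multi-resolution encoder–decoder ("U-Net"
style) with **no biases, no activations, no pooling** — the network *is*
a linear operator ($F(0) = 0$ exactly; homogeneity and additivity hold to
floating-point rounding; the tests assert 1e-4 relative). The full-scale
reference architecture has 7 levels starting at 8 channels and doubling
to 512 at the bottleneck; desk configurations shrink to 3 levels / 4 base
channels. Each level:

* a **ConvBlock**: physics-informed padding (below) followed by a 5×5×5
  convolution;
* **down**: 3×3×3 convolution, stride 2, channels preserved (channel
  doubling happens in the ConvBlocks);
* **up**: 2×2×2 transposed convolution, stride 2, channels halved, then
  concatenation with the encoder feature map of the same level;
* a final 1×1×1 projection to one channel.

### Physics-informed padding

The data tensor axes are (time, view, ring), and each axis is padded
according to what lies beyond its boundary in the physical acquisition:

* **view** — cyclic wrap: tomographic views are 2π-periodic;
* **time** — zeros: the measurement window is validated to be temporally
  untruncated (`validate_coverage()`), so traces outside it are
  negligible;
* **ring** — *learned*: beyond the transducer arc the field is unmeasured
  but not zero. The first and last five ring slices are treated as input
  channels to a small learned convolution (9 taps along the time axis,
  shared across feature channels), one per side, whose outputs are
  concatenated beyond the ring boundaries.

The 9-tap kernel is taken to span the *time* axis: wavefronts crossing
the aperture edge vary smoothly in time, so temporal context is what
extrapolation needs; the edge-slice index plays the role of the input
channel. Down/up layers use cyclic view padding only (zeros elsewhere).
The edge-slice count is clamped to the ring extent at coarse levels.

The stride-2 tower requires the time and view extents to be divisible by
$2^{L-1}$. A ring extent that is not divisible (for example the
full-scale 107) is right-padded *at network entry* by the same learned
mechanism to the next multiple and cropped at exit — the choice keeps the
learned-extrapolation semantics instead of mixing in zeros.

Cyclic view padding makes the whole network exactly equivariant to view
shifts that are multiples of the total downsampling factor; this is
asserted numerically and is a useful canary for padding bugs.

## Training

`train_filter()` approximately solves

$$\hat\theta = \arg\min_\theta \frac{1}{K}\sum_{k=1}^K
\mathcal L\!\left(\mathbf f^{(k)},\ \mathbf H^\dagger F_\theta\,
\mathbf p^{(k)}\right),\qquad \mathcal L = \text{MSE},$$

with Adam (reference learning rate 1e-4, batch size 1). To keep each step
cheap the loss is evaluated on a **random y-slab** of a quarter of the
volume: the slab-restricted adjoint computes only those voxels, and the
gradient with respect to the filtered data applies $\mathbf H$ to the
slab-supported volume gradient — the backward pass of the custom linear
operators is simply the partner operator. The network backward pass is
implemented layer-by-layer (the architecture is static), and the full
composite gradient is verified against central finite differences to
better than 1e-4 relative in the test suite. Slab starts are uniform over
the valid range, one draw per step; training is deterministic given the
seed. Validation MSE (full volume) is recorded per epoch and the
best-epoch parameters are retained, a standard model-selection choice.

**Output-gain calibration.** Since $\mathbf H^\dagger$ is unnormalized,
the composite of a freshly initialized filter is off from the object
scale by a large constant factor (two to three orders of magnitude at
desk scale). At full scale, tens of thousands of optimizer steps absorb
this invisibly; at desk scale it would dominate the step budget. The
network being linear, `calibrate_filter_gain()` folds the least-squares
scalar $\alpha = \langle \mathbf H^\dagger F\mathbf p, \mathbf f\rangle /
\|\mathbf H^\dagger F\mathbf p\|^2$ into the final 1×1×1 projection at
initialization. This changes only the starting scale, not the filter
shape, and is deterministic. Training data are noiseless, as in the
reference protocol; robustness to noise at test time comes from the
Gaussian low-pass apodization applied before reconstruction.

## Synthetic phantoms

`generate_phantom()` produces seeded initial-pressure volumes: smooth
Gaussian-profile ellipsoids ("blobs") plus random-walk tubes ("vessels"),
clipped to a support ball strictly inside the aperture's convex hull,
optionally modulated by $\exp(-\text{depth}/\lambda)$ to emulate the
decay of optical fluence with depth. These are stand-ins for anatomically
realistic numerical breast and mouse phantoms: they reproduce the
features the method actually depends on — compact support inside the
hull, smooth structures spanning several voxels, depth-dependent
amplitude, ensemble diversity — but not anatomy, tissue-realistic optics,
or acoustic heterogeneity. Passing the desk studies therefore
demonstrates the *mechanism* (a linear data filter learned through a
matched operator pair corrects limited-view artifacts and generalizes
across structure types), not clinical image quality. An
out-of-distribution variant (for example vessels-only) shifts ensemble
structure statistics and supports scaled-down generalization checks.

## Desk-scale study conditions

`desk_study_conditions()` fixes the package's default virtual study, with
the full-scale proportions at sizes a single CPU handles in minutes:
half-scan probe 85 mm / 90° / 8 ring elements, 16 views, 64 time samples
at 2 µs (so $c_0\Delta t \ge h$), full-scan reference 16 elements / 180°,
grid 32×32×16 at 3 mm, phantoms in a 42 mm support ball with a 60 mm
depth-decay, 3-level / 4-channel filter, Adam at 1e-3 for 25 epochs over
12 training phantoms with 3 validation and 4 test phantoms.
`run_desk_study()` executes the whole pipeline and compares learned FBP
with standard FBP on half- and full-scan data of the held-out phantoms.
The expected (and asserted) outcome is the qualitative ordering
*standard-full ≲ learned < standard-half* in MSE, with SSIM ordered the
opposite way. The learning rate is larger than the full-scale reference
value because the optimizer takes three orders of magnitude fewer steps;
all reference-scale constants remain available through the configuration
objects.

## Numerical conventions and degenerate inputs

* Distances and accumulations in double precision; fixed summation order
  (voxel-major spreading, per-voxel transducer-ordered gather) for exact
  reproducibility.
* A transducer coinciding with a voxel center raises `"singular
  distance"`; a recording window too short for the farthest voxel raises
  `"temporal truncation"`; support outside the hemisphere or probe radius
  raises `"object outside convex hull"`.
* The Gaussian low-pass kernel uses $\sigma = \text{HWHM}/\sqrt{2\ln 2}$,
  truncated at ±4σ and renormalized to unit sum, so constant traces pass
  through unchanged.
* Noise is referenced to the *ensemble* maximum amplitude (stored in the
  `noise_spec` object), not per-sample maxima, so noisy datasets share
  one physical noise level.
* Ring-axis padding when adapting mismatched acquisitions is symmetric,
  with the odd extra slice at the far end; which side the reference
  pipeline pads is not documented, and the choice is recorded here.
* SSIM uses a 7×7×7 uniform window over fully interior positions,
  unbiased local (co)variances, $K_1 = 0.01$, $K_2 = 0.03$, and data
  range $\max(\text{ref}) - \min(\text{ref})$; MSE and SSIM are computed
  over the full grid without masking.

## Known limitations

* Homogeneous speed of sound, no attenuation or dispersion, idealized
  point transducers with flat frequency response.
* The voxel-as-point quadrature limits raw time-domain fidelity for
  discontinuous objects to the $\sqrt{h}$ edge-smoothing law discussed
  above.
* The desk-scale filter is trained on tens of phantoms for minutes; it
  demonstrates the ordering of methods, not the near-reference image
  quality achievable at full scale.
* Checkpoints are R serializations; the geometry, grid, and data formats
  (YAML, raw float32 + JSON sidecar, CSV) are language-neutral.
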