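---
title: "Generative active-learning design of graded gyroid scaffolds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generative active-learning design of graded gyroid scaffolds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The design problem

Bone-implant scaffolds must match the elastic modulus *E* of the
surrounding bone (a much stiffer implant shields the bone from load and
causes resorption), carry as much load as possible (maximal yield strength
*Y*), and stay light (a mass cap). `gyrodesign` searches the space of
*graded gyroid scaffolds*: cubes of `s x s x s` gyroid subunits whose
per-subunit porosity is the design variable, collected in a small
**porosity matrix**. Against a fixed modulus target, the package maximises
strength under the mass constraint with a generative-model-assisted,
surrogate-screened active-learning loop.

## Geometry: porosity matrices realised through a level set

A gyroid is approximated by the triply periodic level set
`sin X cos Y + sin Y cos Z + sin Z cos X = c` with `X = 2*alpha*pi*x` and so
on; the solid network is the strict super-level set (field value above the
local isovalue `c`). Lowering `c` thickens the solid network, so `c`
controls porosity. A graded scaffold varies `c` across space.

The porosity-to-isovalue map has no closed form. `calibrate_isovalue()`
solves it numerically: bisection on the voxel-counted solid fraction of one
periodic unit, to an absolute tolerance of `1e-3` on the fraction, at a
calibration resolution of 40 voxels per unit, cached per porosity level.
The admissible porosities form a discrete ladder, 20% to 90% in 10% steps;
its lower end keeps struts printable and its upper end keeps the network
connected.

Between subunit centers the isovalue field interpolates linearly along each
axis (separable trilinear interpolation, constant beyond the outermost
centers). This generalises a single-axis linear profile `c = A x + B` to
arbitrary three-dimensional gradings while keeping the transition between
neighbouring subunits smooth — abrupt isovalue jumps would create stress
concentrators and unprintable thin walls at subunit boundaries.

Voxelisation samples voxel *centers* at `(i + 0.5)/voxels_per_unit` in cell
units. The symmetric sampling means the gyroid field values on the grid
come in `+/-` pairs, so the isovalue `c = 0` yields a 50% solid split at any
even resolution — a property the tests rely on. Ties (`field == c`) break
to void, matching the strict inequality of the level-set definition. The
default scaffold is 3 subunits of 2 mm per edge at 20 voxels per unit: a
6 x 6 x 6 mm cube on a 60^3 occupancy grid, the resolution used throughout.
Surfaces are extracted by marching tetrahedra (each grid cube split into
six tetrahedra, crossings linearly interpolated) and written as binary STL;
tetrahedral decomposition avoids the ambiguous-face cases of cube-based
marching at the cost of more, smaller triangles.

## Synthetic corpus: what it emulates and what it does not

The autoencoder trains on an unlabeled corpus of porosity matrices in four
arrangement families — `central` (core/shell by Chebyshev distance from the
scaffold center), `vertical` (one value per z-layer), `horizontal` (one
value per x- or y-layer), and `random` (i.i.d. ladder values) — in shapes
2^3, 3^3 and 4^3, all expanded by block replication to a common 12^3 array.
Matrices are generated per mean-porosity interval ([0.2, 0.3) ... [0.8,
0.9]); draws inside an interval come from a soft window around a target
mean whose width scales with the ladder spacing, so coarse and fine ladders
mix porosity values comparably. Duplicates are removed by exact equality,
which on coarse ladders makes small families (a 2^3 central family has only
as many members as the ladder has levels) saturate — the generator then
simply yields fewer matrices of that family rather than padding with
repeats.

The corpus emulates the *combinatorial structure* of graded designs, not
real bone anatomy: real defect sites have irregular outer shapes,
spatially correlated density fields, and fabrication artefacts
(partially molten powder, strut thinning) that the generator does not
model. Tests passing on this corpus demonstrate that the pipeline learns
and searches the design representation correctly; they say nothing about
clinical performance.

## The generative model

The encoder is three 3D convolution stages (3^3 kernels, 'same' padding,
ELU, max-pool 2) with 60, 30 and 15 filters, mapping 12^3 inputs to a 3^3
map; a final convolution and global average pooling produce an
8-dimensional latent code. Eight dimensions balance reconstruction accuracy
against search-space size: each extra dimension doubles the volume the
sampler must cover. The decoder mirrors the spatial path — broadcast the
code to 3^3, convolve, upsample twice — with channel widths tapering toward
the single-channel reconstruction (15, 30, 1); since the target is one
channel, mirroring the encoder's widest (60-filter) layer at full
resolution would add an order of magnitude of compute for no measurable
reconstruction gain at these corpus sizes. The model is a plain
autoencoder, not a variational one: with a mixture model fitted to the
embedding cloud providing the sampling distribution, the extra KL
regularisation only inflates reconstruction loss.

Training uses Adam (learning rate `1e-3`, multiplicative decay 0.97 per
epoch, batch 8, 60 epochs by default) on mean squared reconstruction error
in porosity units squared, with a 10% held-out split and best-weights
restore. The default acceptance threshold of 0.004 (root error ~0.06, less
than one ladder step) is reached with margin on a ~500-array mixed corpus.
A latent Gaussian mixture (full covariance, EM) is selected by held-out
average negative log-likelihood over component counts, then refitted on all
embeddings; `sample_latent()` draws from it reproducibly.

Decoded 12^3 arrays are contracted to the design shape by block means (the
exact inverse of the block replication used for expansion), clipped to the
admissible range, and snapped to the ladder so that every candidate the
loop scores is also the design the oracle labels and a printer could build.

## Property surrogates and activation maps

Twin 3D convolutional regressors (filters 8, 4, 2 with max-pooling; dense
128, 64, 32; exponential linear units; mean squared error loss) predict *E*
and *Y* from the binary 60^3 occupancy grid. Labels are standardised
internally; training is Adam with per-epoch learning-rate decay and
optional early stopping on a held-out split (for very small labeled sets
the split is disabled and the best training epoch is kept — a 10-point
validation set selects weights by noise). The flatten width follows from
the architecture (7^3 x 2 = 686 at 60^3 input).

The regression activation map (RAM) explains a prediction by
gradient-weighted activation mapping on the last convolution stage: the
map is the rectified per-voxel sum over channels of gradient times
activation, trilinearly upsampled to the input grid and min-max
normalised. A gradient-based form is required because the architecture has
dense layers after flattening (projection-style class-activation maps need
a global-average-pooling head), and the weighting is per voxel rather than
a per-channel spatial average: exponential-linear activations take both
signs, and collapsing the gradient to one scalar per channel misattributes
locally negative evidence — on a controlled set whose labels depend on a
single octant, the per-channel form highlights the complement while the
per-voxel form concentrates on the causal octant.

## The mechanics oracle

Real labels would come from calibrated explicit finite-element compression
simulations. The package's default oracle is an analytic stand-in with the
same interface (`function(matrix) -> list(E, Y, mass_fraction)`), built
from porous-mechanics scaling: per-subunit modulus `e = E0 (1 - p)^q`;
load-axis columns compose in series (`s / sum(1/e)`), and the scaffold
modulus is the column mean; per-layer strength is the mean of
`Y0 (1 - p)^r` over the transverse layer, the scaffold yields at its
weakest layer, and material at the six face centers adds a reinforcement
factor `1 + lambda * fc` (with `fc` the mean face-center solid fraction) —
mirroring the observation that face-centered material placement strengthens
these lattices. Constituent defaults are `E0 = 5000` MPa and `Y0 = 120`
MPa, with exponents 2.0 (modulus, the classic porous-solid scaling) and 2.1
(strength) and `lambda = 0.1`. The form is deliberately simple: monotone in
material (adding material never weakens), equivariant under the cube
symmetries that fix the load axis, and exactly `E0 (1-p)^q` on uniform
designs — properties the tests verify. Fidelity to any particular
finite-element model is *not* claimed; `command_oracle()` adapts an
external solver (design CSV in, stress-strain CSV out) for real labels.

Stress-strain post-processing: the modulus is the least-squares slope of
the longest initial window whose linear fit keeps R^2 >= 0.999, grown
greedily from the first 10 points; because R^2 alone tolerates a few
post-yield points, the window end is then trimmed while the final point's
residual exceeds twice the window's root-mean-square residual (a no-op on
clean linear data). Yield is the stress at the first intersection with the
elastic line translated by 0.2% strain, linearly interpolated between
samples. The Gibson-Ashby strength law `Y = C (1 - p)^alpha * Y0` is fitted
by ordinary least squares in log space, which recovers noise-free
generating constants to machine precision.

## The active-learning loop

Each round samples 2000 latent points from the mixture, decodes and snaps
them, voxelises the distinct designs, and predicts *E* and *Y* with the
surrogates. Selection applies the mass cap first (reject above
`mass_criterion x 1.15`), then the modulus band (predicted *E* within
+/- 5% of target), ranks survivors by predicted *Y*, and fills up to `k = 6`
slots epsilon-greedily: each slot takes the next-best candidate predicted
to beat the current best in-band strength, except with probability
`epsilon = 0.05` it takes a uniformly random non-improving band survivor.
When no candidate is predicted to improve, slots can still be filled only
by these exploration draws — so a mispredicting surrogate cannot
permanently freeze the search. Selected designs are labeled by the oracle,
and both surrogates are retrained from scratch on the augmented set every
round (from-scratch retraining avoids drift on small data; retraining on
null rounds re-initialises the fit so a persistent misprediction does not
lock the selector). The benchmark is the *golden criterion*: the uniform
design whose oracle modulus matches the target (found by bisection), whose
strength the loop must beat and whose mass becomes the default mass
criterion. The loop stops on success (best in-band strength at least
`1 + margin` times the golden strength, default margin 10%), stagnation
(no improvement for `patience` rounds; an empty selection counts), or a
round cap.

Two baselines share the oracle budget: random search (uniform admissible
designs, mass-filtered) and Bayesian optimisation in the latent space
(full-covariance RBF Gaussian processes for *E* and *Y* on the labeled
embeddings; expected improvement on *Y* multiplied by the probability of
the modulus band under the *E* process).

## Numerical and reproducibility choices

All network code is a compact 3D convolution engine compiled with the
package (im2col + GEMM convolutions, single precision, Adam); weight
initialisation, shuffling and sampling use an explicit seeded Mersenne
Twister with Box-Muller normals and Fisher-Yates shuffles, so training is
bit-reproducible for a given seed on a given BLAS. R-side randomness
(corpus generation, splits, selection, mixture sampling) goes through
`set.seed()`. Each loop round derives its seed from the run seed and round
index. Voxelised grids may be memoised by design content (`grid_cache`);
caching cannot change results.

Degenerate inputs are handled explicitly: constant labels train to an
exact constant predictor (labels are standardised; zero variance maps to a
unit scale); zero-variance test labels flag R^2 as undefined rather than
dividing by zero; single-porosity Gibson-Ashby fits and zero-variance
embeddings are errors; a mixture component whose covariance fails a
Cholesky factorisation is discarded during model selection.

## Problem sizes in the tests and acceptance script

The test-suite and acceptance-script sizes are chosen as the smallest
instances that still exercise every mechanism end to end: a ~500-array
mixed corpus for the autoencoder; 500 oracle-labeled 3^3 designs (400/100
split) on full 60^3 grids for the surrogate accuracy checks; and for loop
optimality a fully enumerable toy landscape — 2^3 designs on the 3-level
ladder {0.3, 0.6, 0.9} (6561 designs, brute-forced exactly), 16^3 grids,
a modulus target of 800 MPa (the uniform p = 0.6 design), 60 initial
labels and up to 8 rounds of 6 queries (at most 108 oracle calls), with
the generative model trained once and shared across seeded runs, as it
would be in a real campaign. On this landscape the loop reliably reaches
the global in-band optimum and beats random search's mean best under the
same budget.

## Known limitations

* The analytic oracle is a structural stand-in; absolute property values
  and discovered designs depend on it. Conclusions about real scaffolds
  require the external-solver adapter and experimental validation.
* The latent space is trained per corpus; transferring a trained
  autoencoder to a different ladder or shape family requires retraining.
* Strut-level printability (minimum wall thickness, overhang angles) is
  not modelled; the porosity ladder bounds are a proxy.
* The loop optimises a single strength objective inside a modulus band; it
  does not produce a Pareto front.
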