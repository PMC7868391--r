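---
title: "Electrical source imaging with a sparse rat cortical montage: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electrical source imaging with a sparse rat cortical montage: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`ratesi` implements the complete evaluation chain for electrical source
imaging (ESI) with a sparse (12-electrode) cortical EEG system in the rat:
a finite-element forward model, four inverse solvers, a surrogate-data
benchmarking protocol, a simulated phantom (model-mismatch) experiment, a
synthetic multi-subject auditory steady-state response (ASSR) generator, the
matching analysis pipeline, and non-parametric cluster statistics in source
space. This vignette explains the models, their assumptions, the parameters
that matter, and the numerical choices, in that order.

## The forward model

The discretized forward problem is `X = K Y + e`, with `X` the `N x T`
matrix of electrode potentials, `Y` the `3P x T` dipole moment time courses
on a volumetric grid of `P` free-orientation dipoles, and `K` the `N x 3P`
lead field. `K` is computed with linear (P1) Lagrange finite elements on a
single-compartment tetrahedral head model with homogeneous isotropic
conductivity 0.33 S/m — the standard brain-tissue value, and appropriate for
a cortical (intracranial) montage where the skull does not sit between
electrode and source.

Three choices are worth calling out:

* **Meshing.** Labeled voxel masks are tetrahedralized by Kuhn subdivision:
  each labeled voxel cube is split into six tetrahedra through its main
  diagonal. The subdivision conforms across neighbouring voxels, conserves
  the mask volume exactly at the meshing resolution, and cannot produce
  inverted elements. A dedicated layered-icosphere mesher builds the
  sphere used for validation. Delaunay meshing with boundary smoothing
  would give smoother surfaces; the structured mesh was chosen because it
  is robust, dependency-free, and its discretization error is adequately
  controlled by the edge length (see the validation numbers below).
* **Dipole loads.** Dipoles are represented by St. Venant monopole load
  clusters on the mesh node nearest the dipole and its edge neighbours.
  The monopole (zero total current) and dipole (first moment) conditions
  are enforced exactly; the second moments of the cluster are suppressed
  by a strong quadratic penalty. The quadrupole suppression matters: with
  only the first-moment constraints the load cluster carries an
  uncontrolled quadrupole whose potential decays one order slower in
  `h/d`, and forward errors at eccentric dipoles stop converging under
  mesh refinement.
* **Units.** Mesh coordinates are millimetres; internally all lengths are
  converted to metres, so with conductivity in S/m and dipole moments in
  A·m the potentials are volts.

The lead field uses the transfer-matrix scheme: one sparse Cholesky
factorization, one solve per non-reference electrode (the singular Neumann
system is deflated by grounding the reference electrode's node), and
lead-field entries as inner products of transfer vectors with the load
vectors. Average referencing is the default; raw (reference-electrode)
rows are available.

**Validation.** Against the truncated-series analytic solution for a dipole
in a homogeneous conducting sphere (radius 10 mm, series until terms fall
below 1e-10), the FEM solution at 0.75 mm edge length has relative L2
errors of 0.2–3.3 % for dipoles at relative eccentricities 0–0.6 in both
radial and tangential orientations. The extreme near-boundary case — a
tangential dipole 2 mm under the surface (eccentricity 0.8) — reaches
about 10 %, the expected first-order behaviour when the source-to-surface
distance is only ~3 element edges; grid dipoles in the shipped models stay
clear of this regime.

## The inverse solvers

Four solvers operate on the same lead field:

* **LCMV**: minimum-variance spatial filters
  `w_p = (K_p' C^{-1} K_p)^{-1} K_p' C^{-1}` with unit gain `w_p' K_p = I`;
  scalar activity is the neural activity index (NAI), the source variance
  `tr[(K_p' C^{-1} K_p)^{-1}]` normalized by its value under an identity
  noise covariance. Regularization is diagonal loading `C + gamma I` with
  `gamma = 0.003 lambda_max(C)`.
* **DICS**: the same algebra with the complex cross-spectral density at one
  frequency in place of `C`; activity is the real part of the trace
  quantity (the imaginary part carries no power and is discarded).
* **sLORETA**: the minimum-norm estimate standardized by the 3x3 diagonal
  blocks of the resolution matrix. Default `gamma` is 5 % of the mean
  diagonal of the data covariance; at `gamma -> 0` single sources are
  localized exactly.
* **eLORETA**: the weighted minimum-norm estimator whose 3x3 SPD weight
  blocks solve `W_p = [K_p'(K W^{-1} K' + gamma I)^{-1} K_p]^{1/2}` by
  fixed-point iteration (identity start, relative Frobenius tolerance
  1e-6, cap 500 iterations — the iteration converges slowly for very small
  `gamma`, and non-convergence is an error). eLORETA localizes single
  sources exactly at any noise-free regularization.

The scalar map for the minimum-norm family is the time-summed squared
moment norm per dipole; for LCMV/DICS it is the NAI. This keeps every
solver's output a single non-negative scalar per dipole, which the error
metrics and the cluster statistics require. `gamma` for eLORETA can be
selected by leave-one-out cross-validation over electrodes
(`reg_loocv()`): sources are estimated from `N-1` channels and the held-out
channel predicted through its lead-field row; candidates whose weight
iteration stalls are simply excluded. Matrix inverses fall back to
pseudo-inverses when rank-deficient (the average-referenced lead field has
rank `N-1`).

## Surrogate benchmarking

The surrogate protocol simulates, for every grid dipole, every one of
three fixed orientations and every SNR in {5, 10, 15, 25} dB, a 100-sample
white-Gaussian moment time course at 1 kHz projected through the lead
field, with white sensor noise added at the same variance on every channel
(noise power set from the pooled mean signal power; a per-channel mode
exists). Each map is scored by:

* **ED1** — distance from the map's global maximum to the true dipole
  (ties to the lowest index);
* **ED2** — the activation-weighted sum of distances of *all* local maxima
  (26-neighbourhood; equal-valued plateaus collapse to their lowest-index
  representative), each weighted by its value relative to the global
  maximum;
* **reliability** — the mean absolute difference between unit-normalized
  estimated and simulated activation vectors over the whole simulation
  family, a `[0, 1]` per-dipole trustworthiness score.

Summaries are the mean and population SD over all `P x 3` cells per solver
and SNR. All randomness derives from one master seed by counter-based
substreams, so any subset of the sweep reproduces bit-identically. The
per-SNR eLORETA `gamma` is the mean of LOOCV selections over 8 evenly
spaced probe dipoles (a subsample of the across-dipole mean; the grid is 4
log-spaced values times the mean covariance diagonal).

On the bench-scale ellipsoid model (67 dipoles at 1.5 mm), eLORETA mean
ED1 falls monotonically from ~1.3 mm at 5 dB to 0 at 25 dB and LCMV ED2
falls monotonically with SNR. One benchmark feature does **not** reproduce
at any synthetic scale we tested (67, 461 and 1541 dipoles): the sharpness
of the LCMV ED2 drop between 5 and 25 dB is about 2x here, not the >= 5x
seen on a real MRI-derived head model. The difference traces to lead-field
dynamic range: on smooth ellipsoid geometry a single-dipole blob keeps
peak-to-background NAI contrast even at 5 dB, which caps the number of
heavily weighted spurious maxima and therefore caps ED2 at low SNR. The
corresponding acceptance check is left failing rather than weakened; the
directional trend is asserted and holds.

## The simulated phantom (model mismatch)

The phantom experiment separates the generative from the inverse model:
recordings are simulated in a perturbed copy of the head model (geometry
scaled by 1.8, electrode positions jittered with 0.3 mm SD before
re-snapping, conductivity off by 2 %, optionally a different mesh
resolution) and localized with the unperturbed model. The source is a
1 kHz harmonic dipole sampled at 5 kHz for 60 s, cut into 1 s segments;
eLORETA (pooled covariance) and DICS (pooled CSD at the excitation
frequency) maps give ED1 and signed per-axis errors after mapping
positions back through the scale factor. The mismatch preset is a
heuristic stand-in for fabrication and registration error in a physical
phantom; with it, mean ED1 lands at a few grid steps, the same order as a
physical-phantom experiment, and vanishes continuously as the perturbation
is removed. An amplitude sweep over 6–200 mV verifies the linear operating
regime (straight-line fit with R² > 0.999).

## The synthetic ASSR experiment

Each simulated subject receives 120 one-second 43-Hz click trains with
2–4 s randomized inter-stimulus intervals at 1 kHz sampling. Three
components are planted through the lead field, each with a
unit-channel-RMS spatial pattern and unit-peak time course so amplitudes
are sensor-level peak microvolts directly comparable to the background
(10 µV RMS of half 1/f, half white noise per channel):

* a **thalamic burst** at the deep-region centroid: a 300 Hz carrier under
  a 1.2 ms Gaussian envelope centred 7 ms post-onset (4 µV). The carrier
  sits mid-band in 100–400 Hz and clear of the 110–130 Hz artifact
  detection band;
* a **late slow wave** (150–600 ms, Gaussian peak at 350 ms, 15 µV) at two
  shallow frontal dipoles sharing one time course;
* **43-Hz entrainment** from 400 ms (50 ms raised-cosine ramp) at two
  shallow bilateral "auditory" dipoles, dominantly unilateral (right 1 :
  left 0.6) with independent per-trial phase jitter (SD 0.6 rad) per
  hemisphere, so the pair is only partially coherent — fully coherent
  bilateral sources would cancel under beamforming, and real steady-state
  responses are not perfectly interhemispherically coherent.

Between-subject amplitude variability is lognormal (CV 0.3). Ground-truth
artifact injection adds windowed broadband bursts of known position and
amplitude and returns the exact mask. The generator emulates the
*statistical structure* of an evoked-response experiment — phase-locked
components, 1/f background, inter-subject amplitude spread — and not
volume-conduction of real anatomy, electrode drift, chewing/movement
artifact families, or anaesthesia effects; passing recovery tests
therefore demonstrate pipeline correctness, not expected in-vivo accuracy.

## The analysis pipeline

Artifact rejection follows the three-criterion scheme: (i) 110–130 Hz
bandpass, channel-averaged Hilbert envelope, z-score over time, trials
with samples above `z_thresh = 4` dropped (on clean white noise this
flags ~2 % of trials — the envelope's right tail is heavier than
Gaussian); (ii) a configurable peak-to-peak limit; (iii) manually marked
intervals. Preprocessing is a least-squares 50 Hz sine/cosine fit-and-
subtract notch, a 6th-order Butterworth low-pass at 100 Hz, and average
re-referencing. Zero-phase filtering is the default so component
latencies are not shifted; it is applied in the frequency domain as the
squared magnitude response with reflective padding, which is equivalent
to forward-backward filtering away from the edges and filters all
channels in one FFT. A single-pass causal mode exists.

Epochs pair each 1-s stimulus window with the preceding 1-s prestimulus
window; the analysis windows are 0–150 ms (early), 150–400 ms (late),
400–950 ms (entrainment) and 5–9 ms (thalamic), with the prestimulus
counterpart occupying the same relative samples. Source contrasts use
**common filters**: one set of filters from the pooled (prestimulus +
stimulus) covariance or CSD, applied to each condition separately, so
condition differences cannot arise from filter differences. The
entrainment window is analysed at 43 Hz in the frequency domain (DICS or
eLORETA on the CSD), the late window in the time domain (LCMV or
eLORETA). The contrast is the relative change `(stim - pre)/pre` per
dipole by default, with a difference mode available. For eLORETA in the
pipeline, `gamma` is scaled to the lead-field Gram matrix
(`1e-3 * mean(rowSums(K^2))`), not to the data covariance — the weight
equation lives on the lead-field scale and the two can differ by many
orders of magnitude.

The thalamic component takes a dedicated route: 100–400 Hz bandpass
instead of the low-pass chain, 5–9 ms epochs, time-domain eLORETA, and
the **raw power** of the estimated moments as the per-subject quantity
(the relative-change contrast is deliberately not the default here: with
a 4-sample window its denominator is dominated by whichever dipoles have
incidentally low prestimulus power, and the planted deep source is then
out-ranked; raw power and the difference contrast both localize it
exactly at high SNR).

The subject-count curve repeatedly subsamples `n` of the `N` subjects
(100 draws per `n`), correlates the subsample grand-average map with the
full grand average, and reports mean ± SD per `n` — the practical answer
to "how many animals do I need".

## Cluster statistics

Because a steady-state stimulus raises activity globally, each dipole's
NAI is tested against the subject's whole-brain mean (broadcast to all
dipoles) with a paired one-sided t-test. Clusters are 26-connected
components above the one-sided t quantile at `p < 1e-3` (late,
entrainment) or `p < 1e-9` (thalamic); the null distribution of the
maximum cluster mass comes from 1000 within-subject condition exchanges
(sign flips of the paired differences), and cluster significance is the
Monte Carlo p `(1 + #{null >= mass})/(1 + 1000)` at alpha 0.05 (the +1
avoids p = 0). Zero-variance differences get a signed infinite-t sentinel
with a warning rather than NaN. Under an exchangeable Gaussian null (100
replicates of 20 subjects x ~330 dipoles) the measured family-wise error
rate is 0.06–0.07, within Monte Carlo error of the nominal 0.05.

## Problem sizes and determinism

The shipped bench models are geometrically similar scaled-down versions of
the rat-like geometry (about 2 cm³, 1 mm grid, ~1550 dipoles after
restricting to the electrically active regions): `"small"` (0.4 cm³,
1.5 mm grid, 67 dipoles) for fast iteration and `"medium"` (0.85 cm³,
1.25 mm grid) for group-level work. The test suite runs the full surrogate
crossing on the small model, the LCMV sweep additionally at full rat
scale, the sphere validation at 0.75 mm edge, the family-wise error study
at 100 x 1000 permutations, and a complete 20-subject ASSR study — chosen
so the whole suite completes in minutes while every assertion runs at a
scientifically meaningful size. Every stochastic stage takes one master
seed and derives per-task substreams by counter-based splitting, so reruns
are bit-identical and any subset of a sweep is reproducible in isolation.

## Known limitations

* The ellipsoidal geometry is a stand-in: lead-field dynamic range, and
  with it the low-SNR behaviour of beamformer ED2, differs from a real
  MRI-derived model (see the surrogate section). Atlas NIfTI ingestion
  (`read_labeled_volume()`) is provided but not exercised by the tests.
* Single-compartment conductor only: no skull or scalp, isotropic
  conductivity, as appropriate for cortical electrodes.
* Near-surface dipoles (within ~2 elements of the boundary) carry larger
  forward error; the source grid's voxel-ownership rule keeps dipoles
  inside the volume but not at a guaranteed distance from it.
* Beamformers cannot separate fully coherent sources; the generator
  deliberately plants only partially coherent bilateral pairs.
* EDF support covers the plain 16-bit EDF core (one data record), not
  EDF+ annotations; events travel in a sidecar TSV.
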