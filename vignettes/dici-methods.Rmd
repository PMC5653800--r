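---
title: "Discriminability-index-based component identification: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminability-index-based component identification: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dicimap)
```

## The problem

Spatial independent component analysis (ICA) decomposes a resting-state
fMRI run into spatial maps with associated time courses without requiring a
task or a seed. For presurgical language mapping the open question is not
the decomposition but the *identification*: which of the 20-60 components,
at which model order, is the language network? Visual selection by experts
is subjective and slow; the traditional goodness-of-fit (GOF) comparator is
sensitive to the extreme voxel values that ICA maps routinely contain.

`dicimap` implements a fully automated identification chain:

1. build a binarized network **template** from a healthy cohort via
   seed-based functional connectivity;
2. decompose the individual subject at several **model orders** (the total
   number of components, TNC);
3. score every component of every order against the template with the
   **discriminability index** (d′) under an **adaptive binarization
   threshold**;
4. select the maximum-d′ candidate per order and then across orders;
5. optionally validate the winning map against intra-operative stimulation
   sites and compare the selection with GOF.

## The discriminability index

A binarized component map $C$ is compared with a binary template $T$ inside
a brain mask $B$ by two rates,

$$\mathrm{HR} = \frac{|C \cap T|}{|T|}, \qquad
  \mathrm{FAR} = \frac{|C \cap (B \setminus T)|}{|B \setminus T|},$$

which are mapped through the inverse standard-normal CDF and subtracted:

$$d' = \Phi^{-1}(\mathrm{HR}) - \Phi^{-1}(\mathrm{FAR}).$$

This is the classical signal-detection d′: the separation between the
"signal" and "noise" response distributions in standard-deviation units. It
rewards template coverage and penalizes spillover symmetrically on the
quantile scale, so a component that covers half the template while staying
clean outside can outrank one that covers slightly more but leaks broadly.

Rates of exactly 0 or 1 have infinite quantiles. We apply the standard d′
continuity correction with *rate-specific* epsilons,
$\varepsilon_{\mathrm{HR}} = 1/(2|T|)$ and
$\varepsilon_{\mathrm{FAR}} = 1/(2|B \setminus T|)$, clipping each rate into
$[\varepsilon, 1-\varepsilon]$. This keeps scores finite and preserves the
ordering between components that differ only at the degenerate boundary.

Why not GOF? GOF (mean or sum of in-template z-values minus out-of-template
z-values) operates on raw map values, so a handful of extreme-valued voxels
— common in ICA maps — can dominate the score. Binarization before counting
makes d′ insensitive to value magnitude; the package keeps `gof_score()` as
a comparator and `method_agreement()` for agreement accounting, and the test
suite contains a constructed fixture on which GOF misranks an
extreme-valued distractor while d′ does not.

## The adaptive threshold

Components are binarized at `z > 1.96` (two-sided p < 0.05 under the map's
standard-normal calibration). On noisy individual data this can leave no
overlap with the template at all, making every d′ degenerate. The descent
rule is: if at least one component of at least one order overlaps the
template by at least one voxel, score *all* components of *all* orders at
the current threshold; otherwise drop the threshold by 0.2 and retry, down
to a red line of `z > 0.8` (`1.96, 1.76, ..., 0.96, 0.8`). If even 0.8
produces no overlap anywhere, everything is scored at 0.8 and
`expert_review_flag` is set — the signal that automated identification is
not trustworthy for these data and a human must look.

Two readings of the descent were possible: re-test overlap per order
independently (different orders could end at different thresholds) or
jointly. We implement the joint reading with one shared threshold per run:
the cross-order argmax that follows is only meaningful if all d′ values are
computed under the same binarization.

Ties in the argmax are broken toward the lower model order, then the lower
component index — deterministic, and favoring the more parsimonious
decomposition. The selection also reports the top-k ranked components
across orders (`top_k = 2` exposes the runner-up, useful when the first two
d′ values are close).

## Template construction

For each cohort subject the mean time series of a spherical seed (default
radius 6 mm — the radius is a convention, not a published value; it is a
config knob) is correlated with every in-brain voxel; Pearson r maps are
Fisher-transformed (`atanh`, with |r| clipped to `1 - 1e-7`); a voxelwise
one-sample t-test is run across subjects; p-values are corrected by
Benjamini-Hochberg FDR at `q = 0.001` over in-brain voxels; surviving
voxels are cluster-filtered at 20 voxels (26-connectivity) and binarized.
The default seed is Broca's area at MNI `[-57, 15, 24]`; seeds are inputs,
not estimated.

Two conventions were genuinely open and are exposed as configuration with
these defaults: the t-test is one-sided positive (the template represents
positive connectivity with the seed), and the FDR correction domain is the
brain mask (not the full field of view). Cluster connectivity 26 matches
common SPM-style labeling.

## Preprocessing

The temporal conditioning steps mirror standard resting-state practice:
discard the first 10 frames (steady-state magnetization), per-voxel linear
detrending, band-pass 0.01-0.08 Hz, optional Gaussian smoothing (FWHM
8 mm), and motion screening that excludes subjects exceeding 2 mm
translation or 2 degrees rotation on any axis at any frame (strict
inequality — motion of exactly 2 mm passes). Slice timing, realignment and
spatial normalization are out of scope: inputs are expected in a shared
grid, with templates already warped to the subject's space.

The band-pass is a zero-phase (forward-backward) Butterworth design of
order 2 (effective order 4 after the two passes). The filter family and
order behind the published band were not documented anywhere we could
verify, so the zero-phase Butterworth is this package's documented choice;
it avoids phase-shifting network time courses. Out-of-mask voxels are
zeroed after every temporal operation so the ICA input rank stays
well-defined. Smoothing uses constant-zero padding with a unit-sum discrete
kernel, so interior mass is preserved to numerical precision.

## The ICA engine

Per model order the in-mask voxel-by-time matrix is PCA-whitened to exactly
`order` components and unmixed by symmetric FastICA with the logcosh
contrast (tolerance `1e-4`, up to 1000 iterations, random orthogonal
initialization drawn from the run's seed). Each resulting spatial map is
standardized to mean 0 / sd 1 over the mask — that calibration is what
makes `z > 1.96` meaningful — and sign-oriented so its skewness is
non-negative; the time course is flipped with the map, leaving the
reconstruction unchanged.

One numerical point deserves emphasis. For a whitened direction that is
exactly Gaussian, Stein's identity gives $E[s\,g(s)] = E[g'(s)]$ for the
FastICA update nonlinearity, so the update has no preferred fixed point:
when the requested order exceeds the non-Gaussian signal rank (routine on
phantoms, possible on heavily smoothed clinical data), the excess
directions rotate freely forever and any convergence criterion over the
full unmixing matrix fails, no matter the iteration cap. ICA theory says
those directions are unidentifiable — any rotation of the Gaussian subspace
is an equally valid solution. `run_ica()` therefore declares convergence
over the *identifiable* components only: a direction counts as identifiable
when its logcosh moment gap $|E[s\,g(s)] - E[g'(s)]|$ exceeds
$\max(0.02,\; 5 \cdot 0.9267/\sqrt{n})$, where 0.9267 is the analytic null
standard deviation of the per-sample gap statistic under a standard normal
and $n$ is the number of in-mask voxels. Genuine non-convergence of
identifiable components still raises an error carrying the order and seed.
The test suite cross-checks the engine against an independent FastICA
implementation (`ica::icafast`) at an order where both converge.

The published pipeline aggregated 100 randomized-initialization group-ICA
runs for stability; that scheme is out of scope here and replaced by
deterministic per-order seeding (`rng_seed + order`), which makes every run
bit-reproducible — a property we consider non-negotiable for presurgical
tooling.

## The phantom generator

`make_phantom()` builds a ground-truth-annotated synthetic acquisition:

* grid 24 x 28 x 24 voxels at 3 mm isotropic (an ellipsoidal brain mask
  fills ~60% of it), 150 frames at TR = 2 s — a deliberately reduced-scale
  analogue of a 240-frame clinical acquisition, chosen so that a full
  multi-order identification run completes in seconds;
* sources as unions of Gaussian-profile blobs thresholded at half maximum
  (binary masks with smooth boundaries), mixed with mutually orthogonal
  band-limited time courses: each source owns a disjoint random subset of
  the Fourier bins inside 0.01-0.08 Hz, so 100% of time-course power is in
  band and pairwise correlations vanish by orthogonality of distinct
  frequencies;
* additive noise that is spatially independent Gaussian with AR(1) temporal
  autocorrelation (coefficient 0.3 — resting-state noise is temporally
  autocorrelated); the default amplitude/noise-sd ratio is 2.

`make_language_phantom()` arranges the clinically motivated topology: a
two-cluster "language" source (frontal + temporal sub-networks) among
motor-like, visual-like and broad low-amplitude drift distractors, all
pairwise disjoint within a 5% overlap budget. The matching template is
*deliberately imperfect*: one-voxel dilation shell partially added (30%)
plus random dropout of true voxels (10%), constrained to Dice 0.6-0.9
against the truth — emulating the template-to-subject registration mismatch
a warped group template carries, without implementing registration.

What the phantom does **not** emulate: physiological (cardiac/respiratory)
noise structure, susceptibility artifacts, tumor mass effect, and spatial
noise correlations. Passing the recovery tests therefore demonstrates that
the selection logic is correct and robust to Gaussian noise and template
mismatch, not that clinical sensitivity figures transfer to arbitrary
scanners or lesions.

## Validation against stimulation sites

`classify_site()` maps each stimulation-positive coordinate to its nearest
voxel (rounding, consistent with `mm_to_voxel()`): a site is `inside_map`
if that voxel is suprathreshold, otherwise `within_radius` if any
suprathreshold voxel center lies within the extension radius (default
10 mm) by 3D Euclidean distance, otherwise a `miss`. Exact sensitivity is
`inside / positive`; extended sensitivity adds the within-radius sites.
Distances are measured to voxel centers — exact and grid-independent to
state — and the 1 cm test uses 3D Euclidean distance (a cortical-surface
distance was the other candidate; it needs a surface model we do not have).
Negative (stimulation-silent) sites are classified and counted when
supplied, but no headline specificity is printed by default.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run entirely on synthetic data:
phantom grids of 24 x 28 x 24 (about 9,500 brain voxels), 150 frames,
order grids 5/8/11, 20 seeded replicates for recovery rates; property
checks use 5^3 mask triples (1000 replicates against a triple-loop oracle)
and random p-vectors (200 replicates against a quadratic-time step-up
oracle). Grid equality between images is checked with tolerance `1e-4` on
affine entries, absorbing registration-software float drift. All randomness
in a pipeline run flows from one top-level seed via documented derivations
(per-order: `+ order`; per-subject: `+ 101 * i`).

## Known limitations

* Registration is out of scope; all inputs must share a grid.
* Model orders of 70 and above (where language networks may split into
  sub-networks) are untested and deliberately deferred.
* The expert-review flag is an escalation signal, not a quality metric; a
  flagged run means the data, template or registration needs human
  inspection.
* The GOF comparator implements the mean variant by default (scale-free
  across template sizes); the sum variant is available by configuration.
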