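---
title: "Demixing and fingerprint-based reconstruction: models, parameters, design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demixing and fingerprint-based reconstruction: models, parameters, design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(speckledemix)
```

This vignette documents the science implemented by **speckledemix**: the
measurement model, the algorithms, every tunable parameter that matters
(with units, defaults and rationale), what the simulator does and does not
emulate, and the design choices made where the method leaves genuine
freedom.  It states no empirical numbers beyond what the package's own
test suite computes.

## 1. Measurement model

A hidden fluorescent object behind a static scattering layer is excited by
a sequence of `T` unknown random speckle illuminations.  Each of its `P`
independent emitters contributes a fixed camera-plane speckle pattern — its
*fingerprint* `w_k(r)` — weighted by the excitation `h_k(t)` it happened to
receive in frame `t`:

$$ I(r, t) \;=\; \sum_{k=1}^{P} w_k(r)\, h_k(t), \qquad
   w_k \ge 0,\; h_k \ge 0 . $$

Key physical facts the whole method rests on:

* **Memory effect (ME).** Emitters closer than the ME range produce
  fingerprints that are translated copies of one another, the translation
  equal to their separation.  Beyond the ME range, fingerprints are
  uncorrelated.  The ME range is the radius of the *isoplanatic patch*.
* **Speckle statistics.** A single fingerprint is fully developed speckle:
  exponential intensity marginals, contrast (sd/mean) near 1.  A frame is
  an incoherent sum of many fingerprints and is therefore *low contrast* —
  visually featureless, which is why raw frames cannot be used directly.
* **Illumination weights.** Sampling a random speckle illumination at an
  emitter position gives exponential (unit-mean, fully-developed-speckle)
  weight statistics; emitters within one illumination grain receive
  correlated weights.

## 2. Pipeline

### 2.1 Preprocessing

Frames are optionally cropped (`crop_stack()`, exact sub-array, no
resampling) and background-subtracted by a Fourier-domain Gaussian
high-pass (`highpass_filter()`): the spectrum is multiplied by
`1 − exp(−f²/2σ²)`, `f` in cycles per frame.

* `highpass_sigma` (cycles/frame, default **2**): the smooth fluorescent
  background occupies the lowest one or two spatial frequencies, while the
  informative speckle grains live tens of cycles up (a frame holds a few
  tens of grains per axis direction at typical settings).  The default
  removes only that background.  The DC component of every filtered frame
  is exactly zero before clipping.
* `clip_mode` (default **clip_zero**): filtering creates negatives but the
  factorization needs non-negative input.  Clipping at zero preserves the
  sparse speckle structure; the alternative `shift_min` (subtract the
  frame minimum) re-introduces a DC pedestal that measurably lowers the
  contrast the factorization can exploit, so it is not the default.  Which
  variant the original experimental processing used is not documented
  anywhere we could verify; both are provided.
* Boundary handling is circular (pure FFT).  Frames are much larger than
  the filter scale, so wrap-around bias is negligible; no padding option
  was worth the complexity.

### 2.2 Demixing (NMF)

`flatten_stack()` reshapes the stack into the pixels-by-frames matrix `I`
(row-major pixel order, a documented and round-trippable contract), and
`nmf_factorize()` solves

$$ \min_{W \ge 0, H \ge 0} \; \lVert I - WH \rVert_F^2 $$

from a uniform-random initialization scaled to the data norm.  Two monotone
solvers are provided:

* `method = "mu"` (default): Lee–Seung multiplicative updates.  Guaranteed
  non-increasing objective, cheap per iteration, entirely adequate for
  demixing noisy data.
* `method = "hals"`: HALS coordinate descent, also monotone, with much
  faster tail convergence — the right tool when data are exactly low-rank
  and the residual must be driven to numerical zero.

The objective is evaluated every iteration from Gram matrices the updates
already need, so the trace is essentially free; tests assert its
monotonicity directly on the trace.  Defaults: `max_iter = 500`,
`tol = 1e-5` (relative residual decrease), 3 restarts with the best
objective kept — random initializations occasionally stall in shallow
basins, and restarts are the standard, cheap guard.  Returned `W` columns
are normalized to unit maximum with the scale absorbed into `H` (the
product is gauge-invariant; unit-max makes the deconvolution weight `mu`
meaningful across datasets).  Columns with vanishing maximum are flagged
`dead` and excluded downstream.

### 2.3 Rank estimation

The factorization rank ρ ≈ P must be estimated.  The RMS residual
`‖I − WH‖_F / √(rt)` is monotone non-increasing in ρ, so its literal
minimum is degenerate (always the largest rank scanned); what carries
information is the *shape* of the residual-vs-rank curve: a sharp drop
until ρ reaches P, then a plateau (noiseless) or a shallow overfitting
slope (noisy — each extra component keeps absorbing a few percent of
residual noise).  `estimate_rank()` scans a rank window and offers two
knee rules:

* `criterion = "knee"` (default): geometric elbow — the rank maximizing
  the vertical distance between the residual curve and the chord joining
  its endpoints.  Robust on both noiseless plateaus and noisy overfitting
  slopes, with no tuning constant.
* `criterion = "threshold"`: last rank whose residual improvement exceeds
  `knee_frac` (default 2%) *of the data RMS*.  Normalizing by the data
  scale, not the shrinking residual, is essential: near an exact fit the
  local relative improvement is numerically erratic, and on a noise floor
  it never falls below a fixed percentage.
* Either way, a rank fitting the data to below `1e-9` of its RMS
  short-circuits the scan: the data are exactly low-rank.

The pipeline runs the scan on a frame subset (`rank_frames`, default 300)
with a reduced iteration cap: the scan is a model-order probe, not the
final fit, and this keeps its cost a fraction of the full factorization.

### 2.4 Fingerprint-based reconstruction

For each ordered pair (i, k), `pairwise_deconvolve()` solves

$$ \hat o_{i,k} = \arg\min_{o} \; \frac{\mu}{2}
   \lVert w_i - o \circledast w_k \rVert_2^2 + \lVert o \rVert_{TV} $$

with circular convolution and isotropic TV on forward differences.  Within
one ME patch the solution is a near-flat image with one delta at
`r_i − r_k`; beyond it, low-amplitude noise.

**Solver.** The objective is specified but no algorithm is; we use
split-variable ADMM with FFT-domain quadratic solves (the classical
FTVd construction): shrink the gradient split, solve the coupled quadratic
exactly in Fourier space, update the scaled dual.  This handles the
enormous dynamic range of a speckle OTF (DC huge, high frequencies tiny)
that would paralyse plain proximal-gradient schemes.  Raw ADMM iterates
are not guaranteed objective-monotone, so the exact objective is evaluated
each iteration and the **best iterate is retained and returned**
(MFISTA-style monotonization); the reported trace is the running best and
is non-increasing by construction, which is what the monotonicity tests
assert.  Defaults: `mu = 100` (on unit-max-normalized fingerprints — the
value is meaningless without that normalization), `beta = 10` (ADMM
penalty), `max_iter = 120`, `solver_tol = 1e-5`; on clean pairs the peak
emerges within ten iterations.

**Quality score.** Peak value over the median of `|o|` outside a
grain-sized disk around the peak.  TV shrinkage can drive the clipped
background to exactly zero, so the median is computed on the unclipped
iterate and floored at `1e-9` of the peak; without the floor the score
degenerates to infinity on both good and empty results.

**Quality threshold (default 9).**  Calibrated, as intended by the
design, from the two-population separation measured on simulation: with
10% additive Gaussian noise on the fingerprints, within-ME pairs scored
11–20 and beyond-3×ME pairs 4.7–7.2 (20 pairs each); 9 is the midpoint of
the gap.  The acceptance suite re-measures both populations and asserts
zero misclassification at this default.

**Shift graph.**  An undirected edge (i, k) is accepted when *both*
directed deconvolutions clear the threshold *and* are antisymmetric
(`‖r_ik + r_ki‖ ≤ consistency_tol`, default 2 px) — computing both
directions is cheap and filters most false edges.  Positions relative to
emitter 1 accumulate along a maximum-quality spanning tree
(igraph-backed).  A further **cycle-consistency pruning** pass then
iteratively rejects any accepted edge whose shift disagrees with the tree
positions by more than `consistency_tol`, recomputing the placement each
time.  This last filter matters in practice: when the NMF rank falls one
short of P, a blended component can pass quality and antisymmetry with
edges pointing at *different* constituent emitters; such edges break
triangle closure by tens of pixels and must not constrain the placement.
Nodes with no surviving path to emitter 1 cannot be placed — a physical
limitation, not an implementation one (no chain of ME-overlapping emitters
connects them) — and are reported via a structured warning
(`speckledemix_disconnected`), never silently dropped.

**Partial images and stitching.**  `partial_image()` computes
`O_k = Σ_i o_{i,k}` — by default the literal sum over all ρ terms,
including beyond-ME noise images, whose TV-flattened amplitude is low
enough not to disturb peak extraction; `accepted_only = TRUE` restricts
the sum to accepted neighbours if a cleaner background is wanted.
`compose_global()` sums the partials at their tree offsets on an expanded
canvas.  The result is defined up to one global translation (tests assert
gauge invariance under relabeling of emitter 1).

**Peak convention.** All shifts are signed integer (row, col) lags,
row-down positive, zero lag at the canvas centre `(⌊H/2⌋+1, ⌊W/2⌋+1)`;
peak localization is integer argmax.  Sub-pixel refinement was deliberately
left out: the shift arithmetic (antisymmetry, triangle closure, stitching)
is then exactly testable in integer arithmetic, and a grain is several
pixels wide anyway.

### 2.5 Evaluation

`evaluate_recovery()` extracts local maxima (prominence ≥ 20% of the
canvas maximum, non-maximum suppression at one grain), exhaustively
searches a bounded window of integer translations (the reconstruction's
global-translation gauge), greedily matches peaks to true emitters within
`match_radius` (default 2 grains — about the resolution of
speckle-correlation imaging), and reports matched fraction, localization
errors, and the spatial span of the matched peaks in pixels and ME units.

## 3. The simulator: what it emulates, what it does not

Fingerprints are synthesized as
`w_k = |IFFT[ A(ξ) · exp(i(φ₀(ξ) + σψ(ξ; r_k) − 2πξ·r_k)) ]|²`:

* `A` — circular pupil of cutoff `0.5/grain_size` cycles/px, giving an
  intensity autocorrelation (grain) FWHM of about `grain_size` px.
* `φ₀` — one random phase screen shared by all emitters.
* the linear tilt encodes the emitter position: nearby emitters get
  translated copies of the same speckle (the ME), with sub-pixel positions
  supported exactly.
* `ψ(ξ; r)` — a zero-mean unit-variance Gaussian-process perturbation over
  emitter position with correlation `exp(−d²/2L²)`, realized exactly
  through the eigendecomposition of the P×P position-correlation matrix.
  Fields of two emitters then correlate as `exp(−σ²(1−ρ(d)))` and
  intensities as its square.  We fix `σ² = 2` (far-field intensity
  correlation floor `e⁻⁴ ≈ 0.02`) and solve `L` in closed form so the
  intensity correlation is **0.5 at d = me_range** — the single
  calibration point that defines what `me_range` means here.  An earlier
  sketch of this generator tied the perturbation amplitude to each
  emitter's distance from a patch reference point; that makes correlation
  depend on the reference, not on pairwise separation, so the stationary
  GP formulation replaced it.
* Weights: `iid_exponential` (default — unit-mean exponential, the
  marginal statistics of sampling a fresh speckle per frame) or
  `speckle_field` (a correlated complex-Gaussian field sampled at emitter
  positions: exponential marginals plus the spatial correlation nearby
  emitters would really share).  The default is iid because typical
  emitter separations exceed the illumination grain, and independent
  weights are the identifiability-friendly regime.
* Noise: Poisson at `noise_photons` expected counts at the brightest pixel
  (default 2000 — a moderate exposure for an sCMOS fluorescence
  acquisition), then Gaussian read noise (`read_noise_sigma`, default 2
  counts), then clipping at zero.  Poisson-before-Gaussian matches sCMOS
  physics; clipping keeps the stack NMF-ready.
* Seeding: one master seed; every sub-generator derives a deterministic
  child seed, so fixtures are bit-reproducible.

**Not emulated:** rigorous wave propagation through a volumetric medium,
polarization, chromatic effects, diffuser mechanics, detector fixed-pattern
noise, and any temporal drift of the medium (fingerprints are strictly
static across frames).  The tilt model also makes fingerprints wrap
circularly at the frame edge; this is harmless for within-ME pairs (whose
shifts are small) and irrelevant for beyond-ME pairs (uncorrelated
anyway), but it means a green test establishes correctness of the
*algorithms under the stated speckle statistics*, not performance on any
particular physical diffuser.  The ME range of real media enters only as
the free parameter `me_range`.

## 4. Degenerate inputs and numerical choices

* NMF rejects negative or NaN entries; rank must lie in `[1, min(r, t)]`.
* `pairwise_deconvolve()` rejects all-zero fingerprints;
  `crosscorr_shift()` rejects constant (zero-variance) input.
* Dead NMF columns (max below `1e-12` of the data max) are excluded before
  deconvolution — they would otherwise divide by ~zero in normalization.
* Single-emitter reconstructions skip the graph entirely (one node at the
  origin).
* Tie-breaks: integer argmax takes the first maximum in column-major
  order; the translation search prefers more matches, then smaller summed
  distance.
* All FFT work is double precision; equality assertions in tests use
  `1e-12`-level tolerances for exact identities and physically motivated
  tolerances (±1 px, fractions of a grain) for estimated quantities.

## 5. Known limitations

* Runtime scales as ρ² deconvolutions; for ρ beyond ~50 the all-pairs
  stage dominates and would want batching or early rejection by
  cross-correlation prescreening (not implemented).
* Rank under-estimation by one merges two emitters into one component;
  cycle pruning protects the geometry, but the merged emitters appear as
  one (or a doubled) peak.  More frames sharpen the knee.
* Continuous (non-sparse) objects are handled by the same machinery in
  principle — components become object patches rather than single
  emitters — but the simulator and the recovery metrics are built around
  point emitters; no claims are made beyond sparse scenes.
* No sub-pixel localization, no joint (all-pairs-at-once) deconvolution,
  no spectral or 3-D unmixing, no dynamic media.
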