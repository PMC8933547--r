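# speckledemix

Non-invasive fluorescence imaging through strongly scattering layers, from
nothing but a stack of low-contrast speckle frames recorded under varying
random illumination.

## The problem

A fluorescent object hidden behind a scattering layer (a diffuser, a slab of
tissue) cannot be imaged directly: every point emitter produces a seemingly
random speckle pattern on the camera — its *fingerprint*.  Within the
optical memory-effect (ME) range, the fingerprints of two nearby emitters
are identical up to a translation equal to their separation; beyond the ME
range they are completely uncorrelated, which is why classical
speckle-correlation imaging is confined to a single isoplanatic patch.

If the object is excited by a *changing* random illumination (e.g. a
rotating diffuser in the excitation path), frame `t` on the camera is an
incoherent mixture

    I(r, t) = Σ_k  w_k(r) h_k(t),      k = 1..P emitters,

where `w_k` is emitter k's fingerprint and `h_k(t)` the (unknown,
exponential-distributed) excitation it received in frame `t`.  This is a
non-negative factorization problem: given enough frames, NMF recovers the
individual fingerprints from the low-contrast mixtures.

The object is then reassembled from the fingerprints alone.  For every
ordered pair (i, k) a total-variation-regularized deconvolution

    argmin_o  (μ/2) ‖w_i − o ⊛ w_k‖₂² + ‖o‖_TV

yields a delta-like peak at the emitters' relative displacement
`r_i − r_k` when they share an ME patch, and structureless noise when they
do not.  Summing the deconvolutions per PSF emitter gives a partial image
`O_k = Σ_i o_{i,k}` of the object around emitter k.  Displacements compose
along chains (`r_ik = r_ij + r_jk`), so a spanning tree over the
quality-filtered *shift graph* places every emitter relative to emitter 1
even when the layout spans several ME ranges, and the global image is the
sum of shifted partials, `O(r) = Σ_k O_k(r − r_k1)`.  The package also
ships the classical cross-correlation shift estimator as a baseline, and a
physics-based simulator (tilted, progressively decorrelating random phase
screens) that provides ground truth for every stage.

## Worked example

Simulate a chain of 6 emitters spanning more than two ME ranges on a
64 × 64 px camera, 400 frames at moderate shot noise, then demix and
reconstruct:

```r
library(speckledemix)

cfg <- pipeline_config(
  optical = optical_config(frame_height = 64, frame_width = 64,
                           grain_size = 3, me_range = 14,
                           noise_photons = 2000, read_noise_sigma = 2),
  emitters = list(n = 6, fov_radius = 25, min_separation = 3,
                  layout = "connected_chain", chain_step = 7),
  T_frames = 400, rank_min = 3, rank_max = 10, rank_frames = 250,
  seed = 4)
res <- run_pipeline(cfg)
print(res$rank_scan)
print(res$factors)
print(res$graph)
print(res$global)
print(res$report)
```

prints

```
rank_scan: 8 ranks scanned, chosen rank 6
factorization_result: rank 6 | 115 iterations | residual 19642 (converged)
shift_graph: 6 nodes, 10 accepted edges, 6 placed
global_image: 69 x 95 canvas, 6 partials composed
recovery_report: 6 matched (100%), mean error 0.73 px, span 31.4 px (2.24 ME)
```

Reading the output: the residual-vs-rank knee found all 6 emitters without
being told `P`; 10 of the 15 emitter pairs produced mutually consistent,
high-quality deconvolution peaks (the rest lie too far apart — beyond the
ME range — and were rejected); the spanning tree placed all 6 partial
images; and against the simulator's ground truth every emitter was
localized, to 0.73 px on average, across a reconstruction spanning 2.2
ME ranges — i.e. well beyond what a single isoplanatic patch allows.

Lower-level entry points (`synthesize_fingerprints()`, `nmf_factorize()`,
`pairwise_deconvolve()`, `build_shift_graph()`, `compose_global()`,
`evaluate_recovery()`) expose each stage separately; see the methods
vignette source in `vignettes/` for the model, parameter guidance, and
design notes.

## CLI

```sh
Rscript inst/scripts/speckledemix run --config pipe.json --out-dir out/
Rscript inst/scripts/speckledemix simulate --config pipe.json --out stack.rds
Rscript inst/scripts/speckledemix reconstruct --config pipe.json --in stack.rds --out-dir out/
```

`pipe.json` mirrors the arguments of `pipeline_config()`; see
`?read_pipeline_config`.
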