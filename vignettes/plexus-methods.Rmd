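---
title: "Quantifying enteric nervous system architecture with plexus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying enteric nervous system architecture with plexus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plexus)
```

## The problem

Wholemount preparations of the gut wall stained for a pan-neuronal fibre
marker (such as beta-III tubulin) show the enteric nervous system (ENS) as a
planar meshwork: ganglia — clusters of neuronal somata — joined by
interganglionic fibre bundles, with finer secondary fibres branching off.
Conditions that remodel this network (loss of an enzyme such as neuronal
nitric-oxide synthase, or developmental loss of ganglia as in
endothelin-receptor-B-null colon) can change its density, branching and
junctioning without being obvious to the eye. `plexus` implements an
automated measurement chain for confocal z-stacks of such preparations —
nominally 21 optical sections of 512 x 512 px at a 1 um z-step — and pairs
it with a synthetic-scene generator that produces the same kind of images
*with exact ground truth*, so that every stage of the chain can be validated
and its detection power demonstrated without animal data.

The measurement chain per field is:

1. **Pre-filter** each slice (median radius 2 px, then Gaussian sigma 1 px
   by default) and collapse to a single frame by **maximum-intensity
   z-projection**.
2. **Segment** the network: either a WEKA-style trainable random-forest
   pixel classifier on a multiscale feature bank, or a non-learned Otsu
   threshold.
3. **Network density**: 100 x foreground / total pixels of the binary mask.
4. **Interganglionic areas**: connected components of the mask complement
   (4-connectivity), binned into seven size classes with integer-inclusive
   edges 0–50, 51–200, 201–400, 401–600, 601–800, 801–1000 and >1000 px.
5. **Skeleton topology**: thin the mask to a unit-width centreline, build
   the skeleton graph, and census junctions (triple = degree 3, quadruple =
   degree 4) and branches (count, total and mean length in weighted pixel
   steps: 1, sqrt 2, sqrt 3).
6. **Orientation and coherency** from the structure tensor, including an
   HSB map (hue = orientation over 180 degrees, saturation = coherency,
   brightness = intensity).
7. **Cohort statistics**: per-subject averaging and Welch's t-tests, plus a
   delta-delta-Ct module for companion qPCR expression tables.

A 3D ridge detector (`ridge_detect_3d()`) complements the 2D chain: fibres
crossing at different depths project onto a spurious 2D junction, and the
Hessian-based 3D centreline keeps them separate.

## The synthetic scene model

`network_spec()` describes a scene: ganglia on a jittered `grid_rows` x
`grid_cols` lattice, fibre connectives between lattice neighbours (each
present with `connective_prob`, then minimally augmented so the network is
connected), and Poisson-distributed secondary fibres ("sprouts") branching
off connectives at 55–125 degrees with lengths of 25–45 % of the lattice
spacing. `render_params()` describes the optics: tubes of constant intensity
and width `fibre_width_px` around each centreline and flat ellipsoids at
ganglia, a Gaussian PSF (lateral and axial), Poisson shot noise scaled by
`photon_scale`, additive Gaussian read noise and a constant background.

Three design choices matter for validation:

* **Flat-top rendering.** Tube and soma intensity is uniform over the
  support, so the support *is* the analytic ground-truth mask and the
  noiseless, blur-free limit is exactly two-valued. Realistic intensity
  shading comes entirely from the PSF. (A Gaussian radial profile would
  blur the correspondence between mask and threshold.)
* **Clearance-based sprout placement.** Candidate sprouts are rejected if
  their centreline comes within `fibre_width + 2` px of any unrelated fibre
  or ganglion (and of their own parent beyond the base zone, which would
  otherwise enclose background slivers). Rendered topology therefore equals
  graph topology, which is what makes *exact* recovery a meaningful test.
  The cost is an upper bound on achievable density: crowded variants
  saturate near 35–40 % coverage.
* **Topological ground truth.** A skeleton graph cannot represent a
  pass-through (degree-2) ganglion as a node, so `graph_truth()` reports
  junctions as nodes of degree >= 3 and branches as maximal chains after
  contracting degree-2 nodes. Raw geometric edge counts are kept alongside
  (`n_edges_raw`).

Subject-level variation in cohorts is a log-normal multiplier (SD 0.05) on
`connective_prob`, giving correlated fields within a subject without
changing the topology class; the subject is then the natural statistical
unit. All randomness flows from one seed through a named-substream scheme,
so any single scene is reproducible in isolation.

What the generator does *not* emulate: tissue autofluorescence and staining
gradients, stitching artefacts, fibre-width variation along a bundle,
curved (non-lattice) ganglion arrangements, and touching somata. Passing
tests therefore demonstrate correctness of the measurement chain under a
controlled forward model, not robustness to every property of real
micrographs.

## Calibrated defaults

The source study does not publish fibre-width or ganglion-size
distributions, so the defaults were calibrated once so that synthetic
network density lands inside the 25–45 % range observed for real distal
colon wholemounts, and then frozen:

* `ens_control_spec()` — 7 x 7 lattice, ganglion radius 9 px, fibre width
  10 px, connective probability 0.9, sprout rate 1: true density about 25 %
  at 512 x 512.
* `ens_ko_spec()` — denser, more branched: 8 x 8 lattice, fibre width 11 px,
  full connectivity, sprout rate 1.2: about 32 %. The contrast (about
  1.3-fold) mirrors the direction and approximate magnitude of the reported
  knockout phenotype (39.2 % vs 29.3 %); the clearance rule caps the
  variant short of the exact reported ratio.
* `ens_power_specs()` — a reduced 128 x 128 pair (5 x 5 lattices, 3 optical
  sections) used by the power study: control about 28 % density and 14
  junctions per field, variant about 37 % and 21 junctions (density ratio
  1.33, junction ratio 1.46, close to the reported 835.6/566.9).
* `ens_validation_specs()` — 256 x 256 conditions (9 sections) for the
  recovery and ablation benchmarks. The ablation spec uses a 6 x 6 lattice
  specifically so the intermediate scene of a 1.0/0.5/0.1 retain series
  keeps a non-zero junction count; on sparser lattices the *truth* ties at
  zero junctions between 0.5 and 0.1, and no measurement could order the
  scenes strictly.

## Skeletonization and the junction census

Thinning uses the Guo–Hall two-subiteration parallel algorithm followed by
a sequential simple-point cleanup (Hilditch crossing number). Two facts
drove this choice, both discovered on rendered tubes: the textbook
Zhang–Suen parallel scheme deletes 2-px-wide diagonal strokes *entirely*
(both subiterations remove opposite rails of the band), and any parallel
thinning leaves staircase-corner doublets that masquerade as junction
pixels. Guo–Hall preserves diagonal strokes; the cleanup pass removes the
redundant corners without shortening open curve ends (pixels with fewer
than two neighbours are never deleted).

The raw graph build follows standard skeleton-analysis practice: pixels
with one neighbour are endpoints, two are branch ("slab") pixels, three or
more are junction candidates; touching candidates merge into one junction
node; branches are traced slab-to-slab; isolated cycles become single
self-loop branches. Three cleanups then run, all configurable through
`analysis_options()`:

* `prune_px` (default 2): sub-2-px self-loops and duplicate parallel
  branches between the same junction pair — thinning artefacts at thick
  crossings.
* `spur_px` (default 10, about one fibre width): terminal branches shorter
  than this are pruned. Thinning a wide fibre end or a ganglion disc can
  leave spurs of up to roughly one fibre width; genuine terminal fibres in
  both synthetic and typical real networks are much longer.
* `fuse_px` (default 10, about one ganglion radius): junction nodes joined
  by a skeleton path shorter than this are fused into one node. A ganglion
  with four entering fibre bundles is one anatomical junction, but thinning
  its disc frequently yields two nearby triple points; fusion restores the
  quadruple.

After pruning and fusion, any degree-2 node left behind is contracted so
that one anatomical branch is not counted as two. With all three cleanups
at their defaults, the census of noiseless rendered lattices equals the
generator's ground truth exactly (10/10 seeds in the shipped benchmarks),
and at the default signal-to-noise ratio the median junction and branch
errors are zero. `build_graph()` itself defaults to `fuse_px = 0` and
`spur_px = 0` (the raw touching-pixel rule), which is also how the
equivalence against the brute-force census oracle is asserted. Before
thinning, the pipeline fills background holes of at most `fill_holes_px`
(default 9 px, well below any interganglionic space) so that shot-noise
pinholes do not spawn spurious loops; the interganglionic-area census
always sees the unfilled mask.

## Segmentation

The feature bank reconstructs the commonly enabled WEKA set at sigma in
{1, 2, 4, 8} px: Gaussian smoothing, gradient magnitude, Laplacian, both
Hessian eigenvalues and a difference of Gaussians per scale, plus the raw
intensity (25 features). The classifier is a probability random forest
(ranger; 200 trees, unlimited depth, class-balanced case weights, fixed
seed, single-threaded for determinism), trained once per dataset on sparse
annotations and applied to every field. `annotate_from_mask()` stands in
for interactive scribbles when ground truth is available. The Otsu
fallback (`auto_threshold()`) is used by the soma counter and wherever no
classifier is supplied; at the default SNR both segmenters recover the
true mask with IoU well above 0.95, and IoU is non-decreasing in the
photon budget.

## Orientation conventions

Per-pixel orientation is the structure axis (perpendicular to the dominant
gradient) in (-90, +90] degrees, 0 horizontal, positive counter-clockwise;
gradient scale sigma 1 px, tensor window sigma 4 px. Image-level coherency
is computed from the *summed* tensor, so isotropic images score near zero
(a mean of per-pixel coherencies would not vanish under the null — finite
windows give random textures a floor around 0.16). The image-level
orientation is reported twice, deliberately: the axial circular mean
(doubled-angle vector mean, weighted by tensor energy x coherency), and
the naive arithmetic mean of per-pixel angles. The naive mean reproduces a
known reporting artefact: in a vertically oriented field, pixels register
at +90 or -90 essentially at random, so their arithmetic average collapses
toward zero and is unstable from image to image, while the axial mean
stays pinned at +-90. Both are kept so that the artefact-prone statistic
can be compared against the corrected one. Coherency is reported on the
0–1 scale and as a percentage; the two differ only by the factor 100, and
both are emitted because published coherency values mix the scales.

## Soma counting

`count_somata()` applies Otsu, labels 8-connected components, converts
areas to um^2 via the pixel size and filters with size 10 um^2 to infinity
and circularity 0.00–1.00 (Crofton 4-direction perimeter estimate, clamped
to [0, 1]). Touching somata are *not* split by default — the synthetic
generator enforces a minimum centre distance of 2.5 radii so counts are
exact by construction; a distance-map watershed is available behind
`watershed = TRUE` for real data. Note a packing constraint: at 2.5 radii
spacing, 12-um-diameter somata jam near 100 cells in a 212-um field, so
dense validation scenes (150–200 cells) use 8–9-um somata.

## Statistics

Group comparisons use Welch's unequal-variance t-test (two-sided), with the
statistical unit configurable: `"subject"` (fields averaged per animal
first — the conservative default) or `"field"`. No multiple-testing
correction is applied by default. The qPCR module computes per-sample
dCT = CT_target − CT_reference, baselines against the control-group mean
dCT, and reports fold = 2^−ddCT rescaled so the control-group mean fold is
exactly 1 (the usual presentation convention; `normalize = "none"` gives
the raw quantity). Not-detected targets report fold 0 and are excluded from
the Welch test on dCT values.

## The power and null studies

The shipped detection-power demonstration asks: with 6 subjects x 5 fields
per group — the study layout — does the chain detect a knockout-like
contrast? Each replicate cohort is simulated at 128 x 128 px from
`ens_power_specs()`, analyzed field by field (Gaussian pre-filter, Otsu
segmentation, orientation disabled as it is not a compared metric), and
Welch-tested on subject means for density, total junctions and total branch
length. Across 100 replicate cohorts the three tests are jointly
significant at p < 0.05 in at least 95 % of replicates.

Null calibration uses the same imaging chain: a pool of 60 control-only
subjects (300 rendered and analyzed fields) is resampled into 400 disjoint
6-vs-6 pseudo-cohorts, and the rejection rate at alpha = 0.05 across the
three metrics is checked against the [0.025, 0.075] band. Resampling from
a fixed measured pool keeps the estimate unbiased (each pseudo-cohort is a
valid null cohort) at a fraction of the cost of 400 independent imaging
runs; the mild correlation between replicates only widens the estimate's
variance.

Problem sizes throughout (256 x 256 recovery benchmarks, 128 x 128 power
cohorts, 10-seed ladders) are the package's own choices, balancing
counting statistics against simulation cost; all are centralized in
`ens_validation_specs()` / `ens_power_specs()` and can be scaled up.

## Numerical and degenerate-input choices

* Filters use reflective borders; the feature bank errors on images smaller
  than its largest kernel.
* Otsu requires a non-constant image and logs its threshold as an
  attribute.
* `mean_branch_length_px` is `NA` (not 0) for empty graphs; empty masks
  yield empty skeletons, graphs and censuses rather than errors.
* Branch-length ties in junction fusion resolve shortest-first;
  deterministic scan orders everywhere make every result bit-reproducible
  for a fixed seed (`num.threads = 1` in ranger included).
* The 3D ridge detector treats FFT round-off on flat stacks as no signal
  (response below 1e-6 of the intensity range returns an empty skeleton).
* Branch lengths are reported in weighted pixel steps, matching how such
  results are usually printed ("pxls"); multiply by `pixel_size_um` for
  micrometres.

## Known limitations

* The clearance rule caps synthetic density near 40 %; phenotypes denser
  than that cannot be emulated with exact ground truth by this generator.
* Junction fusion at ganglion scale will merge genuinely distinct
  junctions closer than `fuse_px` along the skeleton; for fields whose
  true junction spacing approaches the ganglion radius, reduce `fuse_px`.
* The 3D ridge census is validated on clean geometric scenarios
  (centreline accuracy, depth-separated crossings); it is a secondary
  mode, not the primary quantitative chain.
* The naive-mean orientation statistic is retained only for comparability;
  it should not be used for inference.
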