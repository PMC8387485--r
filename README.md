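# plexus

Quantitative analysis of enteric nervous system (ENS) network architecture
from confocal z-stacks, with a fully ground-truthed synthetic benchmark.

Wholemount gut preparations stained for a pan-neuronal fibre marker (TuJ1 /
beta-III tubulin) show the ENS as a meshwork of ganglia joined by fibre
bundles. Remodelling of this network — denser coverage, more branching and
junctioning, or graded loss of ganglia — is often invisible to qualitative
inspection. `plexus` measures it: for every z-stack it computes

* **network density** — `100 · |foreground| / |pixels|` of the segmented
  mask on the maximum z-projection;
* **interganglionic areas** — connected components of the mask complement,
  binned at 0–50 / 51–200 / 201–400 / 401–600 / 601–800 / 801–1000 / >1000 px²;
* **junction and branch censuses** — the mask is thinned to a unit-width
  skeleton whose graph has endpoints (degree 1), triple (degree 3) and
  quadruple (degree 4) junctions; branches carry weighted step lengths
  (1, √2, √3 px);
* **orientation and coherency** — from the structure tensor
  `J = G_σ * (∇I ∇Iᵀ)`: fibre axis `θ ∈ (−90°, 90°]` and coherency
  `(λ₁−λ₂)/(λ₁+λ₂)`;
* **soma counts** — Otsu threshold, 8-connected particles, size filter
  10 μm²–∞, circularity `4πA/P²` in 0–1;
* **cohort statistics** — per-subject averaging, Welch's t-tests, and
  ΔΔCT fold changes (`2^−ΔΔCT`, control mean normalized to 1) for companion
  qPCR tables.

Segmentation is a WEKA-style trainable random forest over a multiscale
feature bank (Gaussian, gradient, Laplacian, Hessian eigenvalues,
difference of Gaussians at σ ∈ {1,2,4,8} px), with an Otsu fallback. A 3D
Hessian ridge detector separates fibres that cross at different depths.

Because real stacks ship with no ground truth, the package includes a
synthetic generator: ganglion lattices joined by fibre tubes with secondary
sprouts, rendered with PSF blur, Poisson shot noise and Gaussian read noise
— and with the exact mask, graph, junction/branch counts and density known
by construction. Every stage of the pipeline is validated against it.

## Worked example

```r
library(plexus)

# a control-like synthetic field with known truth
spec  <- ens_validation_specs()$recovery      # 4x4 ganglion lattice, 256 px
shape <- ens_validation_specs()$shape
g     <- generate_network_graph(spec, seed = 3, shape = shape)
scene <- render_stack(g, render_params(shape = shape), seed = 3)

metrics <- analyze_field(scene$stack)
metrics[, c("density_percent", "n_junctions", "n_triple", "n_quadruple",
            "n_branches", "mean_branch_length_px", "coherency")]
#>   density_percent n_junctions n_triple n_quadruple n_branches
#> 1        25.31433          20       17           3         36
#>   mean_branch_length_px  coherency
#> 1              46.98596 0.03495417

str(scene$truth[c("n_junctions", "n_triple", "n_quadruple", "n_branches")])
#> List of 4
#>  $ n_junctions: int 20
#>  $ n_triple   : int 17
#>  $ n_quadruple: int 3
#>  $ n_branches : int 36
```

At the default signal-to-noise ratio the measured junction and branch
counts equal the generator's ground truth, density is recovered to ~2 %,
and the low coherency reflects the network's isotropic ("random") fibre
coverage. A two-group comparison over a simulated cohort:

```r
ps <- ens_power_specs()                       # 128-px control vs KO-like pair
co <- generate_cohort(ps$control, ps$variant, n_subjects = 6,
                      fields_per_subject = 5, render = ps$render, seed = 1,
                      include_truth = FALSE)
pf  <- analyze_cohort(co, opts = ps$options)
compare_groups(pf, metrics = ps$metrics, unit = "subject")[, c("metric", "mean1", "mean2", "p")]
#>                   metric     mean1     mean2            p
#>         density_percent  29.39168  36.47359 1.009657e-07
#>             n_junctions  15.83333  19.96667 7.287795e-05
#>  total_branch_length_px 869.12661 971.18763 1.616823e-04
```

The variant group (denser, more branched — the knockout-like phenotype) is
detected on all three metrics with the subject as the unit of analysis.

See `vignette("plexus-methods")` for the scene model, the skeleton-graph
cleanup rules (spur pruning, ganglion-scale junction fusion), orientation
conventions, and the power/null study design. A thin command-line wrapper
over the same functions lives at `inst/cli/plexus-cli.R`
(`simulate | analyze | compare | qpcr`).

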