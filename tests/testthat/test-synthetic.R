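# Synthetic scene generator: lattice topology, determinism, rendering,
# soma scenes, cohorts and graded ablation.

small_shape <- c(5L, 160L, 160L)
small_spec <- function(...) {
  args <- utils::modifyList(
    list(grid_rows = 4, grid_cols = 4, ganglion_radius_px = 6,
         jitter_px = 2, connective_prob = 0.9, extra_branch_rate = 1,
         fibre_width_px = 7),
    list(...))
  do.call(network_spec, args)
}

test_that("full 2x2 lattice has four degree-2 corners and no junctions", {
  sp <- network_spec(2, 2, ganglion_radius_px = 6, jitter_px = 0,
                     connective_prob = 1, extra_branch_rate = 0,
                     fibre_width_px = 7)
  g <- generate_network_graph(sp, seed = 1, shape = c(3L, 128L, 128L))
  expect_equal(nrow(g$nodes), 4L)
  expect_equal(length(g$edges), 4L)
  deg <- plexus:::node_degrees(g)
  expect_true(all(deg == 2L))
  tr <- graph_truth(g)
  expect_equal(tr$n_junctions, 0L)
  expect_equal(tr$n_triple, 0L)
  expect_equal(tr$n_quadruple, 0L)
})

test_that("full 3x3 lattice has a quadruple centre and four triple sides", {
  sp <- network_spec(3, 3, ganglion_radius_px = 6, jitter_px = 0,
                     connective_prob = 1, extra_branch_rate = 0,
                     fibre_width_px = 7)
  g <- generate_network_graph(sp, seed = 1, shape = c(3L, 192L, 192L))
  tr <- graph_truth(g)
  expect_equal(tr$n_quadruple, 1L)
  expect_equal(tr$n_triple, 4L)
  expect_equal(tr$n_junctions, 5L)
  # 12 lattice edges; 4 degree-2 corners contract away
  expect_equal(tr$n_branches, 8L)
})

test_that("truth branch count equals an independent edge-list census", {
  sp <- small_spec(extra_branch_rate = 2)
  g <- generate_network_graph(sp, seed = 7, shape = small_shape)
  expect_equal(graph_truth(g)$n_edges_raw, length(g$edges))
  # handshake on the raw geometric graph
  deg <- plexus:::node_degrees(g)
  expect_equal(sum(deg), 2L * length(g$edges))
  # degree >= 3 nodes partition as triple/quadruple/higher
  tr <- graph_truth(g)
  expect_equal(tr$n_junctions, sum(deg >= 3L))
  expect_equal(tr$n_triple + tr$n_quadruple + tr$n_higher, tr$n_junctions)
})

test_that("generation and rendering are deterministic in (spec, seed)", {
  sp <- small_spec()
  g1 <- generate_network_graph(sp, seed = 11, shape = small_shape)
  g2 <- generate_network_graph(sp, seed = 11, shape = small_shape)
  expect_identical(g1, g2)
  rp <- render_params(shape = small_shape)
  r1 <- render_stack(g1, rp, seed = 5)
  r2 <- render_stack(g2, rp, seed = 5)
  expect_identical(r1$stack$voxels, r2$stack$voxels)
  # same graph, different noise seed: identical truth, different voxels
  r3 <- render_stack(g1, rp, seed = 6)
  expect_identical(r1$truth$true_mask, r3$truth$true_mask)
  expect_false(identical(r1$stack$voxels, r3$stack$voxels))
})

test_that("noiseless renders are two-valued on/off the true mask", {
  sp <- small_spec()
  g <- generate_network_graph(sp, seed = 2, shape = small_shape)
  rp <- render_params(shape = small_shape, psf_sigma_px = c(0, 0),
                      photon_scale = Inf, gauss_noise_sd = 0,
                      background_level = 0.05)
  r <- render_stack(g, rp, seed = 1)
  expect_true(all(r$stack$voxels[r$truth$true_mask] == 1.05))
  expect_true(all(r$stack$voxels[!r$truth$true_mask] == 0.05))
})

test_that("at default SNR the mask interior is brighter than background", {
  sp <- small_spec()
  g <- generate_network_graph(sp, seed = 2, shape = small_shape)
  r <- render_stack(g, render_params(shape = small_shape), seed = 1)
  expect_gt(mean(r$stack$voxels[r$truth$true_mask]),
            mean(r$stack$voxels[!r$truth$true_mask]))
})

test_that("density truth equals direct counting on the projected mask", {
  sp <- small_spec()
  g <- generate_network_graph(sp, seed = 4, shape = small_shape)
  r <- render_stack(g, render_params(shape = small_shape), seed = 1)
  m2 <- apply(r$truth$true_mask, c(1, 2), any)
  expect_equal(r$truth$true_density_fraction, mean(m2))
})

test_that("oversized lattices are rejected", {
  expect_error(generate_network_graph(network_spec(8, 8, fibre_width_px = 12),
                                      seed = 1, shape = c(3L, 96L, 96L)),
               "too large")
})

test_that("soma scenes have exact counts and sub-threshold debris", {
  sc <- generate_soma_scene(20, radius_um = 6,
                            render = render_params(shape = c(1L, 256L, 256L)),
                            seed = 3, n_debris = 10)
  expect_equal(sc$true_soma_count, 20L)
  expect_true(all(sc$debris_areas_um2 < 10))
  # non-overlap: pairwise centre distance >= 2.5 x radius
  dmin <- min(stats::dist(sc$centers))
  expect_gte(dmin, 2.5 * 6 / 0.415 - 1e-9)
  # empty scene is background only
  sc0 <- generate_soma_scene(0, render = render_params(shape = c(1L, 64L, 64L)),
                             seed = 1)
  expect_equal(sum(sc0$true_mask), 0L)
  # infeasible packing errors out
  expect_error(generate_soma_scene(500, radius_um = 6,
    render = render_params(shape = c(1L, 128L, 128L)), seed = 1),
    "cannot place")
})

test_that("cohorts have the study layout and heritable subject effects", {
  sp <- small_spec()
  co <- generate_cohort(sp, small_spec(connective_prob = 1),
                        n_subjects = 6, fields_per_subject = 5,
                        render = render_params(shape = small_shape),
                        seed = 9, include_truth = FALSE)
  expect_equal(nrow(co$manifest), 60L)
  expect_equal(sum(co$manifest$group == "control"), 30L)
  # one multiplier per subject, shared by its fields
  mu <- unique(co$manifest[, c("group", "subject", "subject_mult")])
  expect_equal(nrow(mu), 12L)
  expect_error(generate_cohort(sp, sp, n_subjects = 1), "n_subjects")
})

test_that("doubling the sprout rate raises mean true branch counts", {
  lo <- generate_cohort(small_spec(extra_branch_rate = 0.5),
                        small_spec(extra_branch_rate = 2),
                        n_subjects = 3, fields_per_subject = 2,
                        render = render_params(shape = small_shape), seed = 21)
  m <- tapply(lo$manifest$true_n_branches, lo$manifest$group, mean)
  expect_gt(m["variant"], m["control"])
})

test_that("graded ablation is nested and monotone in ground truth", {
  sp <- small_spec()
  scenes <- generate_graded_ablation(sp, c(1, 0.5, 0.1), seed = 5)
  full <- generate_network_graph(sp, plexus:::substream_seed(5, 1L),
                                 c(21L, 512L, 512L))
  expect_equal(length(scenes[[1]]$graph$edges), length(full$edges))
  tj <- vapply(scenes, function(s) s$truth$n_junctions, numeric(1))
  expect_true(all(diff(tj) <= 0))
  expect_error(generate_graded_ablation(sp, c(0.5, 1)), "non-increasing")
  none <- generate_graded_ablation(sp, 0, seed = 5)
  expect_equal(length(none[[1]]$graph$edges), 0L)
  expect_equal(none[[1]]$truth$n_branches, 0L)
})

test_that("cohort fields regenerate bit-identically from the manifest", {
  sp <- small_spec()
  co <- generate_cohort(sp, sp, n_subjects = 2, fields_per_subject = 2,
                        render = render_params(shape = small_shape),
                        seed = 13, include_truth = FALSE)
  f1 <- cohort_field(co, 3)
  f2 <- cohort_field(co, 3)
  expect_identical(f1$stack$voxels, f2$stack$voxels)
})
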