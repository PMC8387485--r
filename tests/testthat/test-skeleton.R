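# Erosion, thinning, skeleton-graph construction and censusing, 3D ridges.

plus_mask <- function(arm = 4L) {
  n <- 2L * arm + 3L
  m <- matrix(FALSE, n, n)
  c0 <- arm + 2L
  m[c0, 2:(n - 1L)] <- TRUE
  m[2:(n - 1L), c0] <- TRUE
  m
}

test_that("cross erosion shrinks monotonically and zero iterations is identity", {
  m <- matrix(FALSE, 9, 9); m[3:7, 3:7] <- TRUE
  expect_identical(erode_mask(m, 0L), m)
  e1 <- erode_mask(m, 1L)
  # independent morphology oracle: EBImage erosion with a diamond brush
  oracle <- EBImage::erode(EBImage::Image(m * 1),
                           EBImage::makeBrush(3, "diamond")) > 0.5
  expect_identical(e1, matrix(as.logical(oracle), 9, 9))
  expect_true(all(e1[4:6, 4:6]))
  expect_false(any(e1 & !m))
  expect_equal(sum(e1), 9L)  # square shrinks by one on every side
  line <- matrix(FALSE, 5, 9); line[3, 2:8] <- TRUE
  expect_equal(sum(erode_mask(line, 1L)), 0L)
  # 3D cross erosion of a 3x3x3 cube leaves its centre
  v <- array(FALSE, c(5, 5, 5)); v[2:4, 2:4, 2:4] <- TRUE
  expect_equal(sum(erode_mask(v, 1L)), 1L)
})

test_that("thinning reduces bars to unit-width centrelines, idempotently", {
  bar <- matrix(FALSE, 9, 20); bar[4:6, 3:18] <- TRUE
  sk <- skeletonize_2d(bar)
  # a single 1-px line (the rounded bar ends may retract by a pixel)
  expect_equal(sum(rowSums(sk) > 0), 1L)
  expect_gte(sum(sk), 14L)
  expect_lte(sum(sk), 16L)
  expect_identical(skeletonize_2d(sk), sk)
  expect_equal(sum(skeletonize_2d(matrix(FALSE, 8, 8))), 0L)
  # thick diagonal strokes survive with full extent
  diagm <- matrix(FALSE, 60, 60)
  for (k in -3:3) {
    rr <- 50:10
    cc <- pmin(pmax((5 + k):(45 + k), 1), 60)
    diagm[cbind(rr, cc)] <- TRUE
  }
  skd <- skeletonize_2d(diagm)
  expect_gte(diff(range(which(apply(skd, 1, any)))), 35L)
})

test_that("thinning a solid disc preserves the Euler characteristic", {
  m <- outer(1:41, 1:41, function(i, j) (i - 21)^2 + (j - 21)^2 <= 15^2)
  sk <- skeletonize_2d(m)
  expect_gt(sum(sk), 0)
  # still one 8-connected component, no holes
  expect_equal(max(plexus:::.label2d_cpp(sk, 8L)), 1L)
  holes <- interganglionic_areas(sk, exclude_border = TRUE)
  expect_equal(length(holes), 0L)
})

test_that("hand fixtures census correctly", {
  g <- build_graph(plus_mask(5L), prune_px = 0, fuse_px = 0)
  expect_equal(unname(junction_census(g)), c(1L, 0L, 1L, 0L))
  bs <- branch_stats(g)
  expect_equal(unname(bs["n_branches"]), 4)
  e <- g$edges
  expect_equal(length(unique(round(e$length_px, 6))), 1L)  # symmetric arms

  tee <- matrix(FALSE, 11, 11)
  tee[6, 2:10] <- TRUE; tee[6:10, 6] <- TRUE
  gt <- build_graph(tee, prune_px = 0, fuse_px = 0)
  expect_equal(unname(junction_census(gt)), c(1L, 1L, 0L, 0L))
  expect_equal(unname(branch_stats(gt)["n_branches"]), 3)

  line <- matrix(FALSE, 5, 12); line[3, 2:11] <- TRUE
  gl <- build_graph(line, prune_px = 0, fuse_px = 0)
  expect_equal(unname(junction_census(gl)), c(0L, 0L, 0L, 0L))
  expect_equal(unname(branch_stats(gl)), c(1, 9, 9))

  two_tees <- matrix(FALSE, 11, 24)
  two_tees[6, 2:10] <- TRUE; two_tees[6:10, 6] <- TRUE
  two_tees[6, 14:22] <- TRUE; two_tees[6:10, 18] <- TRUE
  g2 <- build_graph(two_tees, prune_px = 0, fuse_px = 0)
  expect_equal(unname(junction_census(g2)), c(2L, 2L, 0L, 0L))
})

test_that("graphs cover the skeleton and satisfy the handshake lemma", {
  set.seed(5)
  for (i in 1:20) {
    m <- matrix(runif(18 * 18) < 0.45, 18)
    sk <- skeletonize_2d(m)
    g <- build_graph(sk, prune_px = 0, fuse_px = 0)
    # coverage: node pixels + slab pixels = all skeleton pixels
    covered <- sum(g$nodes$n_pixels) + sum(g$edges$n_slab)
    expect_equal(covered, g$n_skeleton_pixels)
    expect_equal(sum(g$nodes$degree), 2L * nrow(g$edges))
  }
})

test_that("non-thinned input is rejected when checking is on", {
  blob <- matrix(TRUE, 6, 6)
  expect_error(build_graph(blob, check_thinned = TRUE), "thinned")
})

test_that("branch stats report missing mean for empty graphs", {
  g <- build_graph(matrix(FALSE, 5, 5))
  expect_equal(unname(branch_stats(g)[1:2]), c(0, 0))
  expect_true(is.na(branch_stats(g)["mean_length_px"]))
  expect_equal(unname(junction_census(g)), rep(0L, 4))
})

test_that("spur pruning and junction fusion clean artefact topology", {
  # T with a 2-px spur at the junction
  m <- matrix(FALSE, 15, 15)
  m[8, 2:14] <- TRUE; m[8:14, 8] <- TRUE; m[7:6, 9] <- TRUE
  g0 <- build_graph(m, prune_px = 0, fuse_px = 0)
  g1 <- build_graph(m, prune_px = 0, spur_px = 4, fuse_px = 0)
  expect_gt(nrow(g0$edges), nrow(g1$edges))
  expect_equal(unname(junction_census(g1)), c(1L, 1L, 0L, 0L))
  # two nearby triples fuse into one quadruple
  h <- matrix(FALSE, 13, 21)
  h[7, 2:20] <- TRUE
  h[2:6, 8] <- TRUE; h[8:12, 12] <- TRUE
  gh0 <- build_graph(h, prune_px = 0, fuse_px = 0)
  expect_equal(unname(junction_census(gh0)["triple"]), 2L)
  gh <- build_graph(h, prune_px = 0, fuse_px = 6)
  expect_equal(unname(junction_census(gh)), c(1L, 0L, 1L, 0L))
  # fusion removes only the short connector between the two triples
  expect_equal(nrow(gh$edges), nrow(gh0$edges) - 1L)
  expect_lte(sum(gh0$edges$length_px) - sum(gh$edges$length_px), 6)
})

test_that("3D ridge detection recovers a straight tube centreline", {
  spec <- network_spec(2, 2, ganglion_radius_px = 5, jitter_px = 0,
                       connective_prob = 1, extra_branch_rate = 0,
                       fibre_width_px = 5)
  shape <- c(9L, 64L, 64L)
  g <- structure(list(
    nodes = data.frame(id = 1:2, row = c(32, 32), col = c(6, 58),
                       z = c(5, 5), kind = "tip", radius_px = 0),
    edges = list(list(from = 1L, to = 2L,
                      path = rbind(c(32, 6, 5), c(32, 58, 5)))),
    spec = spec, shape = shape), class = "ens_graph")
  rp <- render_params(shape = shape, psf_sigma_px = c(0, 0),
                      photon_scale = Inf, gauss_noise_sd = 0,
                      background_level = 0.02)
  r <- render_stack(g, rp, 1)
  sk <- ridge_detect_3d(r$stack, sigma = 2)
  idx <- which(sk, arr.ind = TRUE)
  expect_gt(nrow(idx), 30)
  expect_lte(mean(abs(idx[, 1] - 32)), 1)
  expect_lte(mean(abs(idx[, 3] - 5)), 1)
  # blank stacks yield empty skeletons
  expect_equal(sum(ridge_detect_3d(image_stack(array(0.02, c(64, 64, 9))))), 0L)
  expect_error(ridge_detect_3d(image_stack(array(0.1, c(64, 64, 2)))),
               "3 slices")
})

test_that("z-separated crossings are junctions only in 2D projection", {
  spec <- network_spec(2, 2, ganglion_radius_px = 5, jitter_px = 0,
                       connective_prob = 1, extra_branch_rate = 0,
                       fibre_width_px = 5)
  shape <- c(9L, 64L, 64L)
  g <- structure(list(
    nodes = data.frame(id = 1:4, row = c(32, 32, 6, 58),
                       col = c(6, 58, 32, 32), z = c(3, 3, 7, 7),
                       kind = "tip", radius_px = 0),
    edges = list(
      list(from = 1L, to = 2L, path = rbind(c(32, 6, 3), c(32, 58, 3))),
      list(from = 3L, to = 4L, path = rbind(c(6, 32, 7), c(58, 32, 7)))),
    spec = spec, shape = shape), class = "ens_graph")
  rp <- render_params(shape = shape, psf_sigma_px = c(0, 0),
                      photon_scale = Inf, gauss_noise_sd = 0,
                      background_level = 0.02)
  r <- render_stack(g, rp, 1)
  g3 <- build_graph(ridge_detect_3d(r$stack, sigma = 2),
                    prune_px = 2, spur_px = 4, fuse_px = 0)
  proj <- z_project_max(r$stack)
  g2 <- build_graph(skeletonize_2d(proj > 0.1), prune_px = 2, spur_px = 4,
                    fuse_px = 0)
  expect_equal(unname(junction_census(g3)["total"]), 0L)
  expect_gte(unname(junction_census(g2)["total"]), 1L)
})
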