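# Stack container, TIFF round-trip, pre-filtering, maximum projection.

test_that("stacks round-trip through multi-page TIFF with calibration", {
  vox <- array(runif(32 * 32 * 21), c(32L, 32L, 21L))
  st <- image_stack(vox, pixel_size_um = 0.415, z_step_um = 1)
  f <- withr::local_tempfile(fileext = ".tif")
  save_stack(st, f)
  st2 <- load_stack(f)
  expect_equal(st2$voxels, vox, tolerance = 1e-6)
  expect_equal(st2$pixel_size_um, 0.415)
  expect_equal(st2$z_step_um, 1)
})

test_that("single-page files load as 1-slice stacks; missing calibration warns", {
  f <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(runif(64), 8), f, bits.per.sample = 32L)
  expect_warning(st <- load_stack(f), "calibration")
  expect_equal(dim(st$voxels)[3], 1L)
  expect_equal(st$pixel_size_um, 1)
})

test_that("pages of differing sizes are rejected", {
  f <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(list(matrix(0.1, 8, 8), matrix(0.1, 6, 8)), f,
                  bits.per.sample = 32L)
  expect_error(load_stack(f), "differing")
})

test_that("stack construction validates inputs", {
  expect_error(image_stack(array(-1, c(4, 4, 2))), ">= 0")
  expect_error(image_stack(array(1, c(4, 4, 2)), pixel_size_um = 0), "> 0")
})

test_that("pre-filtering leaves constant images unchanged and kills hot pixels", {
  const <- image_stack(array(0.4, c(24L, 24L, 2L)))
  expect_equal(prefilter(const, "median")$voxels, const$voxels)
  hot <- matrix(0.1, 25, 25)
  hot[13, 13] <- 1
  st <- image_stack(array(hot, c(25L, 25L, 1L)))
  filt <- prefilter(st, "median", median_radius = 1)
  expect_lt(filt$voxels[13, 13, 1], 0.2)
  expect_error(prefilter(st, "gaussian", gauss_sigma = 0), "> 0")
})

test_that("default pre-filter improves foreground/background separation", {
  g <- generate_network_graph(network_spec(4, 4, ganglion_radius_px = 7,
                                           fibre_width_px = 8,
                                           extra_branch_rate = 0.5),
                              seed = 3, shape = c(5L, 192L, 192L))
  r <- render_stack(g, render_params(shape = c(5L, 192L, 192L),
                                     photon_scale = 20), seed = 3)
  sep <- function(stack) {
    proj <- z_project_max(stack)
    fg <- proj[r$truth$true_mask_2d]; bg <- proj[!r$truth$true_mask_2d]
    (mean(fg) - mean(bg)) / sqrt((stats::var(fg) + stats::var(bg)) / 2)
  }
  expect_gt(sep(prefilter(r$stack)), sep(r$stack))
})

test_that("max projection is the pixel-wise maximum and is monotone", {
  vox <- array(runif(16 * 16 * 4), c(16L, 16L, 4L))
  st <- image_stack(vox)
  proj <- z_project_max(st)
  for (k in 1:4) expect_true(all(proj >= vox[, , k]))
  # constant-slice ladder
  lad <- image_stack(array(rep(0:4 / 4, each = 25), c(5L, 5L, 5L)))
  expect_true(all(z_project_max(lad) == 1))
  # idempotent on single-slice stacks
  one <- image_stack(vox[, , 1])
  expect_equal(as.vector(z_project_max(one)), as.vector(vox[, , 1]))
  # adding a slice never decreases any pixel
  bigger <- image_stack(array(c(vox, runif(256)), c(16L, 16L, 5L)))
  expect_true(all(z_project_max(bigger) >= proj))
})

test_that("filters are shift-equivariant away from borders", {
  base <- matrix(0, 40, 40)
  base[18:22, 18:22] <- 1
  shifted <- matrix(0, 40, 40)
  shifted[21:25, 21:25] <- 1
  f1 <- prefilter(image_stack(base), "gaussian")$voxels[, , 1]
  f2 <- prefilter(image_stack(shifted), "gaussian")$voxels[, , 1]
  expect_equal(f1[10:30, 10:30], f2[13:33, 13:33], tolerance = 1e-8)
})
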