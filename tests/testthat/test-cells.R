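# Soma counting and per-subject averaging.

test_that("counts are exact with debris excluded by the area floor", {
  sc <- generate_soma_scene(35, radius_um = 6,
                            render = render_params(shape = c(1L, 320L, 320L)),
                            seed = 5, n_debris = 12)
  res <- count_somata(sc$image)
  expect_equal(res$count, 35L)
  expect_true(all(res$particles$area_um2 >= 10))
  expect_true(all(res$particles$circularity >= 0 &
                    res$particles$circularity <= 1))
})

test_that("auto-threshold covers nearly all true soma pixels at default SNR", {
  sc <- generate_soma_scene(25, radius_um = 6,
                            render = render_params(shape = c(1L, 256L, 256L)),
                            seed = 9)
  mask <- auto_threshold(sc$image)
  expect_gte(sum(mask & sc$true_mask) / sum(sc$true_mask), 0.95)
})

test_that("the raw-component filter returns everything, monotone in min area", {
  sc <- generate_soma_scene(30, radius_um = 5,
                            render = render_params(shape = c(1L, 256L, 256L)),
                            seed = 2, n_debris = 8)
  raw <- count_somata(sc$image, filter = particle_filter(0, Inf, 0, 1))
  flt <- count_somata(sc$image)
  expect_gte(raw$count, flt$count + 8L)
  counts <- vapply(c(0, 10, 40, 90),
                   function(a) count_somata(sc$image,
                     filter = particle_filter(min_area_um2 = a))$count,
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("small-blob arithmetic matches the stated filter", {
  img <- matrix(0.05, 64, 64)
  img[30:32, 30:32] <- 1  # 9 px at 0.5 um/px = 2.25 um^2
  attr(img, "pixel_size_um") <- 0.5
  expect_equal(count_somata(img)$count, 0L)
  expect_equal(count_somata(img,
    filter = particle_filter(min_area_um2 = 2))$count, 1L)
  expect_error(count_somata(matrix(0.3, 8, 8), pixel_size_um = 1), "constant")
  expect_error(particle_filter(min_area_um2 = 5, max_area_um2 = 1))
})

test_that("circularity separates discs from bars", {
  img <- matrix(0.02, 80, 80)
  img[outer(1:80, 1:80, function(i, j) (i - 20)^2 + (j - 20)^2 <= 100)] <- 1
  img[60:62, 10:70] <- 1
  attr(img, "pixel_size_um") <- 1
  res <- count_somata(img, filter = particle_filter(min_area_um2 = 10))
  expect_equal(res$count, 2L)
  expect_gt(max(res$particles$circularity), 0.85)
  round_only <- count_somata(img,
    filter = particle_filter(min_area_um2 = 10, circularity_min = 0.6))
  expect_equal(round_only$count, 1L)
})

test_that("averaging treats the subject as the unit of analysis", {
  one <- data.frame(subject = 1, count = rep(150, 5))
  expect_equal(average_counts(one)$per_subject$mean_count, 150)
  two <- data.frame(subject = rep(1:2, each = 2), count = c(10, 20, 30, 50))
  av <- average_counts(two)
  expect_equal(sort(av$per_subject$mean_count), c(15, 40))
  expect_equal(av$group_summary$mean, 27.5)
  expect_equal(av$group_summary$sem, stats::sd(c(15, 40)) / sqrt(2))
  expect_error(average_counts(data.frame(subject = integer(0),
                                         count = numeric(0))), "empty")
})
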