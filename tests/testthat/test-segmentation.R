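# Multiscale features, random-forest pixel classification, Otsu fallback.

test_that("features of a constant image are flat or zero as appropriate", {
  img <- matrix(0.3, 64, 64)
  fs <- compute_features(img, scales = c(1, 2))
  grad <- grep("gradmag|laplacian|dog", fs$feature_names)
  for (i in grad)
    expect_lt(max(abs(fs$features[, , i])), 1e-10)
  gauss <- grep("^gauss_", fs$feature_names)
  for (i in gauss)
    expect_equal(max(abs(fs$features[, , i] - 0.3)), 0, tolerance = 1e-10)
})

test_that("gradient-magnitude feature recovers a ramp slope", {
  img <- matrix(seq(0, 1, length.out = 64), 64, 64, byrow = TRUE)  # d/dcol
  slope <- 1 / 63
  fs <- compute_features(img, scales = 1)
  gm <- fs$features[, , grep("gradmag", fs$feature_names)]
  expect_equal(mean(gm[20:44, 20:44]), slope, tolerance = 1e-6)
})

test_that("feature computation rejects undersized images", {
  expect_error(compute_features(matrix(0.1, 10, 10), scales = c(1, 8)),
               "smaller")
})

test_that("classifier separates offset classes and is seed-deterministic", {
  set.seed(1)
  img <- matrix(runif(64 * 64, 0, 0.2), 64)
  img[, 33:64] <- img[, 33:64] + 0.6
  truth <- matrix(FALSE, 64, 64); truth[, 33:64] <- TRUE
  ann <- annotate_from_mask(truth, 100, seed = 2)
  clf <- train_classifier(img, ann, scales = c(1, 2), n_trees = 100, seed = 3)
  expect_equal(clf$training_accuracy, 1)
  p1 <- classify(img, clf)
  p2 <- classify(img, train_classifier(img, ann, scales = c(1, 2),
                                       n_trees = 100, seed = 3))
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
  mask <- binarize_prob(p1, 0.5)
  idx <- cbind(ann$row, ann$col)
  expect_equal(mask[idx], truth[idx])
  # threshold bounds
  expect_true(all(binarize_prob(p1, 0)))
  expect_true(!any(binarize_prob(p1, 1.0001)))
})

test_that("single-class annotations and descriptor mismatches error", {
  img <- matrix(runif(64 * 64), 64)
  truth <- matrix(FALSE, 64, 64); truth[1:32, ] <- TRUE
  ann <- annotate_from_mask(truth, 50, seed = 1)
  expect_error(train_classifier(img, ann[ann$class == "network", ],
                                scales = 1), "both classes")
  clf <- train_classifier(img, ann, scales = c(1, 2), n_trees = 50)
  clf$feature_names <- rev(clf$feature_names)
  expect_error(classify(img, clf), "mismatch")
})

test_that("classifier round-trips through disk", {
  img <- matrix(runif(48 * 48), 48)
  truth <- matrix(FALSE, 48, 48); truth[1:20, ] <- TRUE
  img[truth] <- img[truth] + 1
  clf <- train_classifier(img, annotate_from_mask(truth, 50, seed = 1),
                          scales = 1, n_trees = 50)
  f <- withr::local_tempfile(fileext = ".rds")
  save_classifier(clf, f)
  expect_identical(classify(img, load_classifier(f)), classify(img, clf))
})

test_that("otsu splits bimodal images and rejects constants", {
  set.seed(4)
  img <- matrix(0.2 + rnorm(64 * 64, 0, 0.005), 64)
  img[, 33:64] <- img[, 33:64] + 0.5
  m <- auto_threshold(img)
  expect_true(all(m[, 40:64]))
  expect_true(!any(m[, 1:25]))
  thr <- attr(m, "threshold")
  expect_true(thr > 0.25 && thr < 0.65)
  expect_error(auto_threshold(matrix(1, 8, 8)), "constant")
  # inverted image gives the complementary mask up to ties
  m2 <- auto_threshold(max(img) - img)
  expect_gt(mean(m == !m2), 0.999)
})
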