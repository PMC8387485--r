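# Welch's t-test, delta-delta-Ct analysis, pipeline determinism.

test_that("welch matches the closed form and handles degenerate input", {
  wt <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(wt["t"]), 0)
  expect_equal(unname(wt["p"]), 1)
  set.seed(2)
  shifted <- c(1, 2, 3) + 10 + rnorm(3, 0, 1e-3)
  expect_lt(welch_t(c(1, 2, 3), shifted)["p"], 1e-3)
  # equal-variance case approaches the pooled t
  a <- c(4.1, 5.2, 6.0, 5.5); b <- c(6.1, 7.3, 6.8, 7.7)
  wt <- welch_t(a, b)
  pooled <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(unname(wt["t"]), unname(pooled$statistic), tolerance = 0.05)
  expect_error(welch_t(1, c(1, 2)), "n >= 2")
  expect_error(welch_t(c(1, 1), c(2, 2)), "zero variance")
})

test_that("welch t/df/p agree with hand formulas", {
  set.seed(9)
  for (i in 1:5) {
    a <- rnorm(sample(4:9, 1)); b <- rnorm(sample(4:9, 1), 0.5)
    wt <- welch_t(a, b)
    se2a <- stats::var(a) / length(a); se2b <- stats::var(b) / length(b)
    t_hand <- (mean(a) - mean(b)) / sqrt(se2a + se2b)
    df_hand <- (se2a + se2b)^2 /
      (se2a^2 / (length(a) - 1) + se2b^2 / (length(b) - 1))
    expect_equal(unname(wt["t"]), t_hand, tolerance = 1e-12)
    expect_equal(unname(wt["df"]), df_hand, tolerance = 1e-12)
    expect_equal(unname(wt["p"]), 2 * stats::pt(-abs(t_hand), df_hand),
                 tolerance = 1e-12)
  }
})

make_qpcr <- function(shift = 0, noise = 0, nd = FALSE, seed = 1) {
  set.seed(seed)
  samples <- paste0("s", 1:6)
  group <- rep(c("control", "ko"), each = 3)
  ref <- data.frame(sample = samples, group = group, gene = "Gapdh",
                    ct = 18 + rnorm(6, 0, noise))
  tgt_ct <- 24 + rnorm(6, 0, noise) - ifelse(group == "ko", shift, 0)
  if (nd) tgt_ct[group == "ko"] <- NA
  tgt <- data.frame(sample = samples, group = group, gene = "Vip",
                    ct = tgt_ct)
  rbind(ref, tgt)
}

test_that("flat tables give unit folds and the control mean is exactly one", {
  tab <- make_qpcr()
  tab$ct[tab$gene == "Vip"] <- tab$ct[tab$gene == "Gapdh"]
  res <- ddct_fold_change(tab, control_group = "control")
  expect_true(all(abs(res$per_sample$fold - 1) < 1e-12))
  set.seed(3)
  noisy <- make_qpcr(noise = 0.3, seed = 3)
  res2 <- ddct_fold_change(noisy, control_group = "control")
  ctrl <- res2$per_sample$fold[res2$per_sample$group == "control"]
  expect_equal(mean(ctrl), 1, tolerance = 1e-12)
})

test_that("not-detected targets report fold zero", {
  res <- ddct_fold_change(make_qpcr(nd = TRUE), control_group = "control")
  ko <- res$per_sample[res$per_sample$group == "ko", ]
  expect_true(all(ko$fold == 0))
  expect_true(all(!ko$detected))
})

test_that("a known expression shift is recovered", {
  folds <- vapply(1:6, function(s) {
    res <- ddct_fold_change(make_qpcr(shift = log2(1.43), noise = 0.1,
                                      seed = s),
                            control_group = "control")
    res$per_gene$test_mean_fold
  }, numeric(1))
  expect_equal(mean(folds), 1.43, tolerance = 0.05)
})

test_that("missing reference CTs are an error", {
  tab <- make_qpcr()
  tab <- tab[!(tab$gene == "Gapdh" & tab$sample == "s2"), ]
  expect_error(ddct_fold_change(tab, control_group = "control"), "reference")
})

test_that("group comparison works on subject or field units", {
  set.seed(8)
  res <- data.frame(group = rep(c("a", "b"), each = 10),
                    subject = rep(rep(1:2, each = 5), 2),
                    density_percent = c(rnorm(10, 25), rnorm(10, 40)))
  cs <- compare_groups(res, metrics = "density_percent", unit = "subject")
  cf <- compare_groups(res, metrics = "density_percent", unit = "field")
  expect_equal(cs$n1, 2L)
  expect_equal(cf$n1, 10L)
  expect_lt(cf$p, 0.001)
  expect_equal(cf$stars, significance_stars(cf$p))
})

test_that("the pipeline is deterministic end to end", {
  sp <- network_spec(3, 3, ganglion_radius_px = 6, jitter_px = 2,
                     connective_prob = 0.9, extra_branch_rate = 0.8,
                     fibre_width_px = 7)
  cfg <- list(control = unclass(sp), variant = unclass(sp),
              render = list(shape = c(3L, 128L, 128L)),
              n_subjects = 2, fields_per_subject = 2, seed = 5,
              options = list(prefilter_method = "gaussian",
                             do_orientation = FALSE))
  r1 <- run_pipeline(cfg)
  r2 <- run_pipeline(cfg)
  expect_identical(r1$per_field, r2$per_field)
  expect_identical(r1$comparison, r2$comparison)
})
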