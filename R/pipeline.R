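# End-to-end field analysis and cohort comparison.

#' Default analysis options
#'
#' @param prefilter_method pre-filter chain for [prefilter()].
#' @param median_radius,gauss_sigma pre-filter sizes (px).
#' @param segmenter `"classifier"` (requires `classifier`) or `"otsu"`.
#' @param prob_threshold binarization threshold on the network probability.
#' @param fuse_px junction-fusion scale for [build_graph()] (px); default
#'   about one ganglion radius.
#' @param prune_px artefact-pruning threshold (px).
#' @param spur_px terminal-spur pruning threshold (px), below fibre width.
#' @param fill_holes_px fill sub-fibre mask holes up to this area before
#'   skeletonization (the area census still sees the raw mask).
#' @param gradient_sigma,window_sigma structure-tensor scales (px).
#' @param do_orientation compute the orientation/coherency summary (can be
#'   disabled when only mask/skeleton metrics are needed).
#' @return Options list for [analyze_field()].
#' @export
analysis_options <- function(prefilter_method = "median_then_gaussian",
                             median_radius = 2, gauss_sigma = 1,
                             segmenter = c("otsu", "classifier"),
                             prob_threshold = 0.5, fuse_px = 10, prune_px = 2,
                             spur_px = 10, fill_holes_px = 9,
                             gradient_sigma = 1, window_sigma = 4,
                             do_orientation = TRUE) {
  list(prefilter_method = prefilter_method, median_radius = median_radius,
       gauss_sigma = gauss_sigma, segmenter = match.arg(segmenter),
       prob_threshold = prob_threshold, fuse_px = fuse_px,
       prune_px = prune_px, spur_px = spur_px,
       fill_holes_px = fill_holes_px, gradient_sigma = gradient_sigma,
       window_sigma = window_sigma, do_orientation = do_orientation)
}

#' Analyze one field (z-stack) end to end
#'
#' Pre-filter, maximum z-projection, segmentation (trained classifier or
#' Otsu fallback), then the full metric set: network density, binned
#' interganglionic areas, skeleton junction/branch census, orientation and
#' coherency.
#'
#' @param stack an [image_stack()] (or 2D matrix, taken as one slice).
#' @param classifier optional [train_classifier()] model.
#' @param opts an [analysis_options()] list.
#' @return One-row data.frame of field metrics (density_percent, area bin
#'   counts `bin1..bin7`, n_junctions/-triple/-quadruple, n_branches,
#'   total/mean branch length, orientation and coherency summaries).
#' @export
analyze_field <- function(stack, classifier = NULL,
                          opts = analysis_options()) {
  if (is.matrix(stack)) stack <- image_stack(stack)
  stopifnot(inherits(stack, "ImageStack"))
  st <- prefilter(stack, opts$prefilter_method,
                  median_radius = opts$median_radius,
                  gauss_sigma = opts$gauss_sigma)
  proj <- z_project_max(st)
  if (opts$segmenter == "classifier") {
    if (is.null(classifier)) stop("segmenter 'classifier' needs a classifier")
    mask <- binarize_prob(classify(proj, classifier), opts$prob_threshold)
  } else {
    mask <- auto_threshold(proj)
  }
  density <- network_density(mask)
  bins <- bin_areas(interganglionic_areas(mask))
  skel <- skeletonize_2d(fill_holes(mask, opts$fill_holes_px))
  graph <- build_graph(skel, prune_px = opts$prune_px,
                       spur_px = opts$spur_px, fuse_px = opts$fuse_px)
  jc <- junction_census(graph)
  bs <- branch_stats(graph)
  ori <- if (isTRUE(opts$do_orientation))
    orientation_and_coherency(proj, opts$gradient_sigma, opts$window_sigma)
  else list(mean_orientation_deg = NA_real_,
            raw_arithmetic_mean_deg = NA_real_, coherency_mean = NA_real_)
  out <- data.frame(density_percent = density,
                    n_junctions = unname(jc["total"]),
                    n_triple = unname(jc["triple"]),
                    n_quadruple = unname(jc["quadruple"]),
                    n_branches = unname(bs["n_branches"]),
                    total_branch_length_px = unname(bs["total_length_px"]),
                    mean_branch_length_px = unname(bs["mean_length_px"]),
                    orientation_deg = ori$mean_orientation_deg,
                    orientation_naive_deg = ori$raw_arithmetic_mean_deg,
                    coherency = ori$coherency_mean)
  for (i in seq_along(bins)) out[[paste0("bin", i)]] <- unname(bins[i])
  out
}

#' Analyze a synthetic cohort
#'
#' Runs [analyze_field()] over every field of a [generate_cohort()]
#' manifest, regenerating each scene from its seed.
#'
#' @param cohort an `ens_cohort`.
#' @param classifier optional classifier shared across all fields ("trained
#'   once per dataset").
#' @param opts an [analysis_options()] list.
#' @param verbose print progress.
#' @return The manifest with measured metric columns appended.
#' @export
analyze_cohort <- function(cohort, classifier = NULL,
                           opts = analysis_options(), verbose = FALSE) {
  stopifnot(inherits(cohort, "ens_cohort"))
  res <- vector("list", nrow(cohort$manifest))
  for (i in seq_len(nrow(cohort$manifest))) {
    sc <- cohort_field(cohort, i)
    res[[i]] <- analyze_field(sc$stack, classifier, opts)
    if (verbose && i %% 10 == 0)
      message("analyzed ", i, "/", nrow(cohort$manifest), " fields")
  }
  cbind(cohort$manifest, do.call(rbind, res))
}

#' Group comparison over cohort metrics
#'
#' Welch's t-test per metric between the two groups. The statistical unit is
#' configurable: `"subject"` (conservative default; fields are averaged per
#' subject first) or `"field"`.
#'
#' @param results data.frame from [analyze_cohort()] (needs `group`,
#'   `subject`, and the metric columns).
#' @param metrics metric column names to compare.
#' @param unit `"subject"` or `"field"`.
#' @return Data.frame: metric, per-group mean and sem, n, t, df, p, stars.
#' @export
compare_groups <- function(results,
                           metrics = c("density_percent", "n_junctions",
                                       "n_branches",
                                       "total_branch_length_px"),
                           unit = c("subject", "field")) {
  unit <- match.arg(unit)
  groups <- unique(results$group)
  stopifnot(length(groups) == 2L)
  do.call(rbind, lapply(metrics, function(m) {
    vals <- lapply(groups, function(g) {
      r <- results[results$group == g, ]
      if (unit == "subject") as.numeric(tapply(r[[m]], r$subject, mean))
      else r[[m]]
    })
    wt <- welch_t(vals[[1]], vals[[2]])
    data.frame(metric = m, unit = unit,
               group1 = groups[1], mean1 = mean(vals[[1]]),
               sem1 = stats::sd(vals[[1]]) / sqrt(length(vals[[1]])),
               n1 = length(vals[[1]]),
               group2 = groups[2], mean2 = mean(vals[[2]]),
               sem2 = stats::sd(vals[[2]]) / sqrt(length(vals[[2]])),
               n2 = length(vals[[2]]),
               t = unname(wt["t"]), df = unname(wt["df"]),
               p = unname(wt["p"]),
               stars = significance_stars(wt["p"]))
  }))
}

#' Run a full simulate-analyze-compare pipeline from a config
#'
#' Config keys (YAML/JSON file or list): `control` / `variant` (lists of
#' [network_spec()] arguments), `render` ([render_params()] arguments),
#' `n_subjects`, `fields_per_subject`, `seed`, `unit`, `options`
#' ([analysis_options()] arguments), `out_dir` (optional; CSV outputs).
#' Rerunning with the same config and seed reproduces identical tables.
#'
#' @param config list or path to a YAML/JSON config file.
#' @return List: `cohort`, `per_field`, `comparison`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config, simplifyVector = TRUE)
      else yaml::read_yaml(config)
  }
  control <- do.call(network_spec, as.list(config$control %||% list()))
  variant <- do.call(network_spec, as.list(config$variant %||% list()))
  render <- do.call(render_params, as.list(config$render %||% list()))
  opts <- do.call(analysis_options, as.list(config$options %||% list()))
  seed <- config$seed %||% 1L
  cohort <- generate_cohort(control, variant,
                            n_subjects = config$n_subjects %||% 6L,
                            fields_per_subject = config$fields_per_subject %||% 5L,
                            render = render, seed = seed)
  per_field <- analyze_cohort(cohort, opts = opts)
  comparison <- compare_groups(per_field, unit = config$unit %||% "subject")
  if (!is.null(config$out_dir)) {
    if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
    utils::write.csv(per_field, file.path(config$out_dir, "per_field.csv"),
                     row.names = FALSE)
    utils::write.csv(comparison, file.path(config$out_dir, "comparison.csv"),
                     row.names = FALSE)
    jsonlite::write_json(comparison, file.path(config$out_dir, "comparison.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  list(cohort = cohort, per_field = per_field, comparison = comparison)
}
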