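# Two-group synthetic cohorts with subject-level random effects.

#' Generate a two-group synthetic cohort
#'
#' Emulates the study layout: `fields_per_subject` z-stacks ("high-power
#' fields") for each of `n_subjects` subjects per group (default 5 x 6 = 30
#' fields per group). Each subject carries a log-normal multiplier (SD
#' `subject_sd`) on `connective_prob`, so fields within a subject are
#' correlated and the subject is the natural statistical unit.
#'
#' @param control,variant [network_spec()]s for the two groups.
#' @param n_subjects subjects per group (>= 2).
#' @param fields_per_subject fields (stacks) per subject.
#' @param render a [render_params()].
#' @param seed integer seed; all scene seeds derive from it.
#' @param subject_sd SD of the log-normal subject effect.
#' @param include_truth record per-field topological ground truth in the
#'   manifest (requires generating each scene graph at manifest time).
#' @param include_density also rasterize each field's true mask to record its
#'   ground-truth density (slower).
#' @param out_dir when given, each field is rendered and written as a
#'   multi-page TIFF (plus a ground-truth mask TIFF) and the manifest is
#'   saved as CSV and JSON in `out_dir`.
#' @return An `ens_cohort`: list with `manifest` (one row per field: group,
#'   subject, field, scene_seed, optional `path`, and ground-truth columns
#'   `true_*`), the two specs, `render`, `seed`, `subject_sd`.
#' @export
generate_cohort <- function(control, variant, n_subjects = 6L,
                            fields_per_subject = 5L,
                            render = render_params(), seed = 1L,
                            subject_sd = 0.05, include_truth = TRUE,
                            include_density = FALSE, out_dir = NULL) {
  stopifnot(inherits(control, "NetworkSpec"), inherits(variant, "NetworkSpec"))
  if (n_subjects < 2L) stop("n_subjects must be >= 2")
  specs <- list(control = control, variant = variant)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  rows <- list()
  for (gi in 1:2) {
    gname <- names(specs)[gi]
    for (s in seq_len(n_subjects)) {
      mult <- with_seed(substream_seed(seed, gi, s, 0L),
                        exp(stats::rnorm(1, 0, subject_sd)))
      sp <- specs[[gi]]
      sp$connective_prob <- min(1, sp$connective_prob * mult)
      for (f in seq_len(fields_per_subject)) {
        sseed <- substream_seed(seed, gi, s, f)
        row <- data.frame(group = gname, subject = s, field = f,
                          subject_mult = mult, scene_seed = sseed,
                          true_n_triple = NA_integer_,
                          true_n_quadruple = NA_integer_,
                          true_n_junctions = NA_integer_,
                          true_n_branches = NA_integer_,
                          true_total_branch_length_px = NA_real_,
                          true_density_percent = NA_real_,
                          path = NA_character_,
                          stringsAsFactors = FALSE)
        if (include_truth || include_density || !is.null(out_dir)) {
          graph <- generate_network_graph(sp, sseed, render$shape)
          tr <- graph_truth(graph)
          row$true_n_triple <- tr$n_triple
          row$true_n_quadruple <- tr$n_quadruple
          row$true_n_junctions <- tr$n_junctions
          row$true_n_branches <- tr$n_branches
          row$true_total_branch_length_px <- tr$total_branch_length_px
          if (!is.null(out_dir)) {
            r <- render_stack(graph, render, substream_seed(seed, gi, s, f, 9L))
            fn <- file.path(out_dir, sprintf("%s_s%02d_f%02d.tif", gname, s, f))
            save_stack(r$stack, fn)
            mk <- r$truth$true_mask_2d
            tiff::writeTIFF(mk * 1, sub("\\.tif$", "_truemask.tif", fn),
                            bits.per.sample = 8L)
            row$path <- fn
            row$true_density_percent <- 100 * r$truth$true_density_fraction
          } else if (include_density) {
            m <- raster_mask(graph, render)
            m2 <- m[, , 1]
            if (dim(m)[3] > 1L) for (k in 2:dim(m)[3]) m2 <- m2 | m[, , k]
            row$true_density_percent <- 100 * mean(m2)
          }
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  manifest <- do.call(rbind, rows)
  cohort <- structure(list(manifest = manifest, control = control,
                           variant = variant, render = render, seed = seed,
                           subject_sd = subject_sd),
                      class = "ens_cohort")
  if (!is.null(out_dir)) {
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  cohort
}

#' @export
print.ens_cohort <- function(x, ...) {
  cat(sprintf("ens_cohort: %d fields (%s)\n", nrow(x$manifest),
              paste(sprintf("%s: %d", unique(x$manifest$group),
                            table(x$manifest$group)[unique(x$manifest$group)]),
                    collapse = ", ")))
  invisible(x)
}

#' Re-realize one cohort field
#'
#' Deterministically regenerates the graph and rendered stack for row `i` of
#' a cohort manifest (the manifest stores only seeds and truths, so cohorts
#' scale without holding every stack in memory).
#'
#' @param cohort an `ens_cohort`.
#' @param i manifest row index.
#' @return List `stack`, `truth`, `graph` as from [render_stack()].
#' @export
cohort_field <- function(cohort, i) {
  row <- cohort$manifest[i, ]
  sp <- if (row$group == "control") cohort$control else cohort$variant
  sp$connective_prob <- min(1, sp$connective_prob * row$subject_mult)
  graph <- generate_network_graph(sp, row$scene_seed, cohort$render$shape)
  gi <- if (row$group == "control") 1L else 2L
  r <- render_stack(graph, cohort$render,
                    substream_seed(cohort$seed, gi, row$subject, row$field, 9L))
  r$graph <- graph
  r
}
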