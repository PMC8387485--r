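# Cohort statistics: Welch's t-test, delta-delta-Ct expression analysis.

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value; the test used for all group comparisons.
#'
#' @param a,b numeric samples (each n >= 2, finite variance).
#' @return Named numeric vector: `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("each sample needs n >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(c(t = 0, df = length(a) + length(b) - 2, p = 1))
    stop("zero variance in both samples with unequal means")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  c(t = unname(ht$statistic), df = unname(ht$parameter),
    p = unname(ht$p.value))
}

significance_stars <- function(p) {
  ifelse(p <= 1e-4, "****", ifelse(p <= 1e-3, "***",
    ifelse(p <= 1e-2, "**", ifelse(p <= 0.05, "*", "ns"))))
}

#' Relative expression by delta-delta-Ct
#'
#' Per sample, `dCT = CT_target - CT_reference`; `ddCT` subtracts the
#' control-group mean dCT; fold change is `2^-ddCT`. Folds are then rescaled
#' so the control-group mean fold is exactly 1 (the usual presentation
#' convention; `normalize = "none"` reports raw `2^-ddCT`). Targets flagged
#' not-detected report fold 0. Group comparison uses Welch's t-test on dCT
#' values.
#'
#' @param table data.frame with columns `sample`, `group`, `gene`, `ct`;
#'   not-detected reactions carry `NA` ct.
#' @param reference_gene housekeeping gene name present for every sample.
#' @param control_group control group label.
#' @param normalize `"control_mean"` (default) or `"none"`.
#' @return List: `per_sample` (sample, group, gene, dct, ddct, fold,
#'   detected) and `per_gene` (group means +- sem of fold, Welch t/df/p on
#'   dCT, stars).
#' @export
ddct_fold_change <- function(table, reference_gene = "Gapdh",
                             control_group = "control",
                             normalize = c("control_mean", "none")) {
  normalize <- match.arg(normalize)
  stopifnot(all(c("sample", "group", "gene", "ct") %in% names(table)))
  if (!control_group %in% table$group) stop("control group not present")
  refs <- table[table$gene == reference_gene, ]
  if (!nrow(refs)) stop("reference gene absent")
  ref_ct <- stats::setNames(refs$ct, refs$sample)
  targets <- table[table$gene != reference_gene, ]
  if (any(!targets$sample %in% names(ref_ct)) || any(is.na(ref_ct)))
    stop("missing reference CT for some samples")
  targets$dct <- targets$ct - ref_ct[targets$sample]
  targets$detected <- !is.na(targets$ct)
  out <- do.call(rbind, lapply(split(targets, targets$gene), function(g) {
    ctrl_dct <- g$dct[g$group == control_group & g$detected]
    base <- mean(ctrl_dct)
    g$ddct <- g$dct - base
    g$fold <- ifelse(g$detected, 2^(-g$ddct), 0)
    if (normalize == "control_mean") {
      ctrl_fold <- mean(g$fold[g$group == control_group])
      if (is.finite(ctrl_fold) && ctrl_fold > 0) g$fold <- g$fold / ctrl_fold
    }
    g
  }))
  rownames(out) <- NULL
  per_gene <- do.call(rbind, lapply(split(out, out$gene), function(g) {
    grs <- split(g, g$group)
    summ <- lapply(grs, function(x) c(mean = mean(x$fold),
                                      sem = stats::sd(x$fold) / sqrt(nrow(x)),
                                      n = nrow(x)))
    other <- setdiff(names(grs), control_group)
    res <- data.frame(gene = g$gene[1],
                      control_mean_fold = summ[[control_group]]["mean"],
                      control_sem = summ[[control_group]]["sem"])
    if (length(other) == 1L) {
      res$test_group <- other
      res$test_mean_fold <- summ[[other]]["mean"]
      res$test_sem <- summ[[other]]["sem"]
      a <- grs[[other]]$dct[grs[[other]]$detected]
      b <- grs[[control_group]]$dct[grs[[control_group]]$detected]
      if (length(a) >= 2L && length(b) >= 2L) {
        wt <- welch_t(a, b)
        res$t <- wt["t"]; res$df <- wt["df"]; res$p <- wt["p"]
        res$stars <- significance_stars(wt["p"])
      } else {
        res$t <- res$df <- res$p <- NA_real_; res$stars <- NA_character_
      }
    }
    res
  }))
  rownames(per_gene) <- NULL
  list(per_sample = out[, c("sample", "group", "gene", "dct", "ddct",
                            "fold", "detected")],
       per_gene = per_gene)
}
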