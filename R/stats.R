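#' @title Group statistics: Mann-Whitney U, BH-FDR, Cohen's d, Spearman
#' @description The nonparametric battery applied per ROI: two-sided
#'   Mann-Whitney U tests between phenotype subgroups, Benjamini-Hochberg
#'   FDR correction across the 16-ROI family, pooled-SD Cohen's d effect
#'   sizes, and Spearman brain-behavior correlations.
#' @name group_statistics
NULL

#' Mann-Whitney U test (two-sided)
#'
#' U is the pair-count statistic: the number of pairs `(x_i, y_j)` with
#' `x_i > y_j`, ties counted one half. The p value is exact (enumeration)
#' when `n1 * n2 <= 400` and the pooled sample is tie-free, and otherwise
#' uses the normal approximation with tie and continuity corrections.
#'
#' @param x,y numeric samples (both non-empty).
#' @return list with `u`, `p`, `n1`, `n2`, and `method`
#'   (`"exact"` or `"normal_approx"`).
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    abort_painattn("both samples must be non-empty", "empty_input")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    abort_painattn("samples must be finite", "invalid_input")
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- !ties && length(x) * length(y) <= 400L
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE))
  list(u = unname(ht$statistic), p = ht$p.value,
       n1 = length(x), n2 = length(y),
       method = if (use_exact) "exact" else "normal_approx")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjusted p values over one correction family (here: the
#' 16 ROIs for a given metric and contrast). Adjusted values are returned
#' in the input order, are never below the raw values, and preserve the raw
#' ordering.
#'
#' @param p numeric vector of raw p values, all in (0, 1].
#' @return adjusted p values, same length and order as `p`.
#' @examples
#' bh_fdr(c(0.0174, 0.0029, 0.3698))
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L)
    abort_painattn("`p` is empty", "empty_input")
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    abort_painattn("p values must lie in (0, 1]", "invalid_input")
  stats::p.adjust(p, method = "BH")
}

#' Cohen's d (pooled SD, magnitude)
#'
#' \eqn{d = |\bar x - \bar y| / s_p} with
#' \eqn{s_p^2 = [(n_1-1)s_1^2 + (n_2-1)s_2^2] / (n_1+n_2-2)}. The magnitude
#' is reported (effect sizes accompany two-sided tests whose direction is
#' read off the group means).
#'
#' @param x,y numeric samples with at least 2 observations each.
#' @return scalar `d >= 0`.
#' @export
cohens_d <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L)
    abort_painattn("each sample needs >= 2 observations", "invalid_input")
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
    (n1 + n2 - 2)
  if (!is.finite(sp2) || sp2 <= 0)
    abort_painattn("pooled variance is zero: d undefined",
                   "degenerate_samples")
  abs(mean(x) - mean(y)) / sqrt(sp2)
}

#' Spearman rank correlation (two-sided)
#'
#' Pearson correlation of mid-ranks with the two-sided p value from the t
#' approximation.
#'
#' @param a,b paired numeric samples, `n >= 3`.
#' @return list with `rho`, `p`, `n`.
#' @export
spearman_corr <- function(a, b) {
  if (length(a) != length(b))
    abort_painattn("`a` and `b` must be paired (equal length)",
                   "invalid_input")
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3L)
    abort_painattn("need >= 3 complete pairs", "invalid_input")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    abort_painattn("correlation undefined for a constant input",
                   "undefined_correlation")
  ht <- suppressWarnings(
    stats::cor.test(a, b, method = "spearman", exact = FALSE))
  list(rho = unname(ht$estimate), p = ht$p.value, n = length(a))
}

#' Two-sample pooled-variance t statistic from summary statistics
#'
#' Student's t with pooled variance and `n1 + n2 - 2` degrees of freedom,
#' computable directly from printed group summaries (mean, SD, n), as used
#' for behavioral contrasts.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summary statistics.
#' @return list with `t`, `df`, `p` (two-sided).
#' @examples
#' pooled_t(1344, 184, 35, 1216, 162, 12)$t  # ~ 2.1
#' @export
pooled_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  for (v in c("n1", "n2")) {
    n <- get(v)
    if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 2)
      abort_painattn(sprintf("`%s` must be an integer >= 2", v),
                     "invalid_input")
  }
  if (sd1 < 0 || sd2 < 0 || (sd1 == 0 && sd2 == 0))
    abort_painattn("SDs must be >= 0 and not both 0", "invalid_input")
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
  t <- (mean1 - mean2) / (sp * sqrt(1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

.metric_names <- c("total_alpha_power", "total_theta_power",
                   "paf_speed", "paf_power")

#' Per-ROI subgroup comparison with FDR across ROIs
#'
#' For a chosen phenotype contrast (low vs high IAP, or A vs P type) and
#' spectral metric(s), runs a two-sided Mann-Whitney U test per ROI,
#' adjusts p values with Benjamini-Hochberg across the ROI family
#' (separately per metric; families are never merged across metrics), and
#' reports Cohen's d. Subjects with a `boundary` phenotype (score or
#' \eqn{\Delta RT} exactly 0) are excluded with a warning reporting the
#' count.
#'
#' @param metrics long-format metrics table from [compute_cohort_metrics()].
#' @param phenotypes per-subject table with `subject_id` and `iap_group`
#'   and/or `ap_type` (see [phenotype_table()]).
#' @param contrast `"iap"` (low vs high) or `"ap"` (A vs P).
#' @param metric character vector of metric columns to test (default all
#'   four).
#' @param fdr_threshold significance threshold on the adjusted p
#'   (default 0.05).
#' @param atlas ROI atlas used to attach network labels.
#' @return data.frame with one row per ROI x metric: `contrast`, `metric`,
#'   `roi`, `network`, `n_group1`, `n_group2`, `u_statistic`,
#'   `p_uncorrected`, `p_fdr`, `cohen_d`, `significant`. Group 1 is
#'   low-IAP (or A type), group 2 high-IAP (or P type).
#' @export
run_group_comparison <- function(metrics, phenotypes,
                                 contrast = c("iap", "ap"),
                                 metric = .metric_names,
                                 fdr_threshold = 0.05,
                                 atlas = dpc_atlas()) {
  contrast <- match.arg(contrast)
  metric <- match.arg(metric, .metric_names, several.ok = TRUE)
  grp <- phenotype_groups(phenotypes, contrast)
  dat <- merge(metrics, grp, by = "subject_id")
  if (nrow(dat) == 0L)
    abort_painattn("no subjects shared between metrics and phenotypes",
                   "empty_input")
  rois <- unique(metrics$roi)
  out <- list()
  for (m in metric) {
    rows <- lapply(rois, function(r) {
      sub <- dat[dat$roi == r, , drop = FALSE]
      g1 <- sub[[m]][sub$.group == levels(sub$.group)[1L]]
      g2 <- sub[[m]][sub$.group == levels(sub$.group)[2L]]
      if (length(g1) < 2L || length(g2) < 2L)
        abort_painattn(sprintf(
          "contrast '%s', ROI %s: a group has < 2 subjects (n1=%d, n2=%d)",
          contrast, r, length(g1), length(g2)), "insufficient_group")
      mw <- mann_whitney_u(g1, g2)
      data.frame(contrast = contrast, metric = m, roi = r,
                 n_group1 = length(g1), n_group2 = length(g2),
                 u_statistic = mw$u, p_uncorrected = mw$p,
                 cohen_d = cohens_d(g1, g2), stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$p_fdr <- bh_fdr(tab$p_uncorrected)
    tab$significant <- tab$p_fdr < fdr_threshold
    out[[m]] <- tab
  }
  res <- do.call(rbind, out)
  res <- merge(res, atlas[, c("roi", "network")], by = "roi",
               all.x = TRUE, sort = FALSE)
  res <- res[order(res$metric, match(res$roi, rois)),
             c("contrast", "metric", "roi", "network", "n_group1",
               "n_group2", "u_statistic", "p_uncorrected", "p_fdr",
               "cohen_d", "significant")]
  rownames(res) <- NULL
  res
}

# Resolve the grouping factor for a contrast, dropping boundary subjects.
phenotype_groups <- function(phenotypes, contrast) {
  col <- switch(contrast, iap = "iap_group", ap = "ap_type")
  lev <- switch(contrast, iap = c("low", "high"), ap = c("A", "P"))
  if (!col %in% names(phenotypes))
    abort_painattn(sprintf("phenotype table lacks column `%s`", col),
                   "invalid_input")
  keep <- !is.na(phenotypes[[col]])
  ph <- phenotypes[keep, , drop = FALSE]
  n_boundary <- sum(ph[[col]] == "boundary")
  if (n_boundary > 0L)
    warn_painattn(sprintf(
      "excluding %d boundary subject(s) from the %s contrast",
      n_boundary, contrast), "boundary_excluded")
  ph <- ph[ph[[col]] != "boundary", , drop = FALSE]
  data.frame(subject_id = ph$subject_id,
             .group = factor(ph[[col]], levels = lev),
             stringsAsFactors = FALSE)
}

#' Per-ROI Spearman correlations between behavior and spectral metrics
#'
#' Correlates a continuous behavioral predictor (IAP score or
#' \eqn{\Delta RT_{mean}}) with a spectral metric in each ROI, adjusting p
#' values across the ROI family with Benjamini-Hochberg. Boundary subjects
#' are included: the predictor is continuous here.
#'
#' @param metrics long-format metrics table.
#' @param phenotypes per-subject phenotype table containing the predictor.
#' @param predictor `"iap_score"` or `"delta_rt_mean"`.
#' @param metric metric column(s) to correlate (default `paf_speed` and
#'   `paf_power`).
#' @param fdr_threshold significance threshold on adjusted p.
#' @param atlas ROI atlas for network labels.
#' @return data.frame, one row per ROI x metric: `predictor`, `metric`,
#'   `roi`, `network`, `n`, `spearman_rho`, `p_uncorrected`, `p_fdr`,
#'   `significant`.
#' @export
run_correlations <- function(metrics, phenotypes,
                             predictor = c("iap_score", "delta_rt_mean"),
                             metric = c("paf_speed", "paf_power"),
                             fdr_threshold = 0.05, atlas = dpc_atlas()) {
  predictor <- match.arg(predictor)
  metric <- match.arg(metric, .metric_names, several.ok = TRUE)
  if (!predictor %in% names(phenotypes))
    abort_painattn(sprintf("phenotype table lacks column `%s`", predictor),
                   "invalid_input")
  dat <- merge(metrics,
               phenotypes[, c("subject_id", predictor), drop = FALSE],
               by = "subject_id")
  rois <- unique(metrics$roi)
  out <- list()
  for (m in metric) {
    rows <- lapply(rois, function(r) {
      sub <- dat[dat$roi == r, , drop = FALSE]
      sc <- spearman_corr(sub[[predictor]], sub[[m]])
      data.frame(predictor = predictor, metric = m, roi = r, n = sc$n,
                 spearman_rho = sc$rho, p_uncorrected = sc$p,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$p_fdr <- bh_fdr(tab$p_uncorrected)
    tab$significant <- tab$p_fdr < fdr_threshold
    out[[m]] <- tab
  }
  res <- do.call(rbind, out)
  res <- merge(res, atlas[, c("roi", "network")], by = "roi",
               all.x = TRUE, sort = FALSE)
  res <- res[order(res$metric, match(res$roi, rois)),
             c("predictor", "metric", "roi", "network", "n",
               "spearman_rho", "p_uncorrected", "p_fdr", "significant")]
  rownames(res) <- NULL
  res
}
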