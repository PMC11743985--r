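test_that("Mann-Whitney U matches brute-force pair counting", {
  # complete separation and symmetric tie cases
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$u, 0)
  x <- c(1, 2, 2, 5)
  expect_equal(mann_whitney_u(x, x)$u, length(x)^2 / 2)
  set.seed(401)
  for (i in 1:20) {
    a <- sample(1:12, 8, replace = TRUE)  # ties likely
    b <- sample(1:12, 8, replace = TRUE)
    res <- mann_whitney_u(a, b)
    expect_equal(res$u, brute_force_u(a, b))
    # U from both directions sums to n1 * n2
    expect_equal(res$u + mann_whitney_u(b, a)$u, 64)
    expect_true(res$p > 0 && res$p <= 1)
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), class = "empty_input")
})

test_that("exact enumeration is used for small tie-free samples", {
  set.seed(402)
  x <- rnorm(8); y <- rnorm(8)
  expect_equal(mann_whitney_u(x, y)$method, "exact")
  expect_equal(mann_whitney_u(rnorm(30), rnorm(30))$method, "normal_approx")
  expect_equal(mann_whitney_u(c(1, 1, 2), c(3, 4, 5))$method,
               "normal_approx")
})

test_that("BH adjustment reproduces the printed 16-ROI theta family", {
  # uncorrected theta p values for the 16 ROIs, in atlas order
  p_uncor <- c(0.0174, 0.0164, 0.0326, 0.1605, 0.0117, 0.0553, 0.0139,
               0.0216, 0.0971, 0.0253, 0.0360, 0.0504, 0.3698, 0.0029,
               0.2197, 0.0046)
  p_corr <- c(0.0464, 0.0464, 0.0576, 0.1834, 0.0464, 0.0737, 0.0464,
              0.0494, 0.1195, 0.0506, 0.0576, 0.0733, 0.3698, 0.0368,
              0.2343, 0.0368)
  expect_equal(round(bh_fdr(p_uncor), 4), p_corr)
})

test_that("BH adjustment is order-preserving, bounded, and idempotent edges", {
  expect_equal(bh_fdr(0.031), 0.031)          # m = 1: adjusted = raw
  expect_equal(bh_fdr(rep(0.02, 7)), rep(0.02, 7))  # constant family
  set.seed(403)
  for (i in 1:10) {
    p <- runif(16, min = 1e-6)
    adj <- bh_fdr(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
  expect_error(bh_fdr(c(0.5, 0)), class = "invalid_input")
  expect_error(bh_fdr(c(0.5, 1.2)), class = "invalid_input")
})

test_that("Cohen's d is the pooled-SD magnitude and recovers truth", {
  x <- c(1, 2, 3, 4)
  expect_equal(cohens_d(x, x + 0), 0)
  expect_equal(cohens_d(x, x + 1), cohens_d(x + 1, x))  # magnitude
  # hand computation: means 0/1, sds 1.2909944, pooled sd the same
  expect_equal(cohens_d(c(-1, 0, 1), c(0, 1, 2)), 1)
  expect_error(cohens_d(rep(1, 5), rep(1, 5)), class = "degenerate_samples")
  expect_error(cohens_d(1, 1:5), class = "invalid_input")
})

test_that("Spearman correlation matches rank-then-Pearson brute force", {
  expect_equal(spearman_corr(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_corr(1:10, rev(1:10))$rho, -1)
  set.seed(404)
  for (i in 1:15) {
    a <- rnorm(6); b <- rnorm(6)
    expect_equal(spearman_corr(a, b)$rho, brute_force_spearman(a, b),
                 tolerance = 1e-12)
  }
  expect_error(spearman_corr(rep(1, 5), rnorm(5)),
               class = "undefined_correlation")
  expect_error(spearman_corr(1:2, 1:2), class = "invalid_input")
})

test_that("pooled t from summary statistics matches direct computation", {
  set.seed(405)
  x <- rnorm(14, 2); y <- rnorm(9)
  ours <- pooled_t(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  expect_equal(pooled_t(5, 1, 10, 5, 2, 12)$t, 0)
  expect_error(pooled_t(1, 1, 1, 2, 1, 10), class = "invalid_input")
})

test_that("group comparison tests each ROI and corrects within metric", {
  set.seed(406)
  atlas <- dpc_atlas()
  subj <- sprintf("s%02d", 1:20)
  grp <- rep(c("low", "high"), each = 10)
  metrics <- expand.grid(subject_id = subj, roi = atlas$roi,
                         stringsAsFactors = FALSE)
  metrics$total_theta_power <- rnorm(nrow(metrics)) +
    ifelse(metrics$roi == "PCC" & metrics$subject_id %in% subj[1:10], 3, 0)
  phen <- data.frame(subject_id = subj, iap_group = grp,
                     stringsAsFactors = FALSE)
  res <- run_group_comparison(metrics, phen, contrast = "iap",
                              metric = "total_theta_power")
  expect_equal(nrow(res), 16)
  expect_setequal(res$roi, atlas$roi)
  expect_true(all(res$p_fdr >= res$p_uncorrected))
  expect_true(all(res$u_statistic >= 0 &
                    res$u_statistic <= res$n_group1 * res$n_group2))
  # the one ROI with a real effect is the significant one
  expect_true(res$significant[res$roi == "PCC"])
  expect_equal(sum(res$significant), 1)
  expect_equal(unique(res$n_group1), 10)
})

test_that("boundary phenotypes are excluded with a warning", {
  set.seed(407)
  subj <- sprintf("s%02d", 1:11)
  metrics <- expand.grid(subject_id = subj, roi = c("PCC", "mPFC"),
                         stringsAsFactors = FALSE)
  metrics$paf_speed <- rnorm(nrow(metrics), 10)
  phen <- data.frame(subject_id = subj,
                     iap_group = c(rep("low", 5), rep("high", 5), "boundary"),
                     stringsAsFactors = FALSE)
  expect_warning(
    res <- run_group_comparison(metrics, phen, contrast = "iap",
                                metric = "paf_speed"),
    class = "boundary_excluded")
  expect_equal(unique(res$n_group1 + res$n_group2), 10)
})

test_that("a group with fewer than two subjects is refused", {
  metrics <- expand.grid(subject_id = c("a", "b", "c"), roi = "PCC",
                         stringsAsFactors = FALSE)
  metrics$paf_power <- c(1, 2, 3)
  phen <- data.frame(subject_id = c("a", "b", "c"),
                     iap_group = c("low", "low", "high"),
                     stringsAsFactors = FALSE)
  expect_error(run_group_comparison(metrics, phen, "iap", "paf_power"),
               class = "insufficient_group")
  # degenerate: everyone in one group
  phen$iap_group <- "low"
  expect_error(run_group_comparison(metrics, phen, "iap", "paf_power"),
               class = "insufficient_group")
})

test_that("a localized group effect is flagged in the affected ROIs only", {
  set.seed(408)
  atlas <- dpc_atlas()
  subj <- sprintf("s%02d", 1:50)
  phen <- data.frame(subject_id = subj,
                     iap_group = rep(c("low", "high"), c(26, 24)),
                     stringsAsFactors = FALSE)
  hits <- setNames(numeric(16), atlas$roi)
  for (rep_i in 1:40) {
    metrics <- expand.grid(subject_id = subj, roi = atlas$roi,
                           stringsAsFactors = FALSE)
    shift <- ifelse(metrics$roi %in% c("PCC", "precuneus") &
                      metrics$subject_id %in% subj[1:26], 0.9, 0)
    metrics$total_theta_power <- rnorm(nrow(metrics)) + shift
    res <- run_group_comparison(metrics, phen, "iap", "total_theta_power")
    hits[res$roi[res$significant]] <- hits[res$roi[res$significant]] + 1
  }
  top2 <- names(sort(hits, decreasing = TRUE))[1:2]
  expect_setequal(top2, c("PCC", "precuneus"))
})

test_that("per-ROI correlations include boundary subjects and correct FDR", {
  set.seed(409)
  subj <- sprintf("s%02d", 1:20)
  metrics <- expand.grid(subject_id = subj, roi = c("PCC", "mPFC"),
                         stringsAsFactors = FALSE)
  metrics$paf_speed <- rnorm(nrow(metrics), 10, 0.5)
  phen <- data.frame(subject_id = subj, iap_score = rnorm(20),
                     stringsAsFactors = FALSE)
  phen$iap_score[1] <- 0  # boundary on the grouping scale, kept here
  res <- run_correlations(metrics, phen, predictor = "iap_score",
                          metric = "paf_speed")
  expect_equal(nrow(res), 2)
  expect_equal(unique(res$n), 20)
  expect_true(all(abs(res$spearman_rho) <= 1))
  expect_true(all(res$p_fdr >= res$p_uncorrected))
})
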