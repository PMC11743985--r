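#' @title Synthetic cohort generator
#' @description Generates behavioral task tables and ROI resting-state time
#'   series with the statistical structure the analysis pipeline assumes,
#'   together with the ground truth needed for parameter-recovery and
#'   false-discovery tests. The spectral model is a 1/f power-law background
#'   plus a Gaussian alpha bump and a flat theta-band elevation; series are
#'   synthesized by shaping the amplitude spectrum on the FFT grid,
#'   randomizing phases uniformly, and inverting to the time domain.
#' @name synthetic_cohort
NULL

#' Cohort generator configuration
#'
#' Defaults emulate the study conditions: 26 low-IAP and 24 high-IAP
#' subjects, 5-minute resting-state series at 1000 Hz per ROI over the
#' 16-node dynamic pain connectome atlas, a 1/f background, an alpha bump
#' near 10 Hz (slightly slower in the low-IAP group), and a theta-band
#' power elevation in the low-IAP group calibrated so that the Cohen's d of
#' measured total theta power equals `theta_effect_d` (default 0.93, the
#' large default-mode effect size) in the ROIs listed in
#' `theta_effect_rois`.
#'
#' Group-valued arguments are named vectors over `c("low", "high")`. When
#' `theta_power_by_group["low"]` is `NA` (the default), it is derived from
#' `theta_effect_d` by [calibrate_theta_effect()].
#'
#' @param n_subjects_per_group named counts per group (each >= 2).
#' @param seed master integer seed; every behavioral table and series
#'   derives a private substream from it.
#' @param duration_s,fs series duration (s) and sampling rate (Hz).
#' @param aperiodic_exponent power-law slope of the background spectrum.
#' @param aperiodic_offset background power density at 1 Hz
#'   (arbitrary units).
#' @param f_floor Hz below which the background is flat (avoids the 1/f
#'   singularity at DC).
#' @param alpha_center_by_group mean alpha-peak frequency per group, Hz,
#'   within \[8, 13\].
#' @param alpha_center_sd between-subject SD of the alpha center, Hz.
#' @param alpha_bump_power_by_group peak height of the Gaussian alpha bump
#'   (power-density units) per group.
#' @param alpha_bump_width Gaussian SD of the alpha bump, Hz.
#' @param theta_power_by_group flat theta-band (4-8 Hz) power-density
#'   elevation per group.
#' @param theta_effect_d target Cohen's d (>= 0) of measured total theta
#'   power between groups in the affected ROIs.
#' @param theta_effect_rois ROIs carrying the theta group effect; all other
#'   ROIs use the `"high"` theta level for both groups.
#' @param theta_power_cv between-subject lognormal coefficient of variation
#'   of the true theta power.
#' @param noise_sd SD of white measurement noise added in the time domain
#'   (signal units).
#' @param roi_list ROI identifiers (default: the 16 atlas ROIs).
#' @param iap_latent_range_by_group list of `c(lo, hi)` ranges (within
#'   \[0, 1\]) from which each group's latent probability of attending to
#'   pain is drawn uniformly.
#' @param es_n_trials experience-sampling trials per subject (default 20).
#' @param p_type_fraction fraction of subjects assigned P type (default
#'   12/47, the observed prevalence).
#' @param rt_nopain_mean_by_type,rt_nopain_sd_by_type no-pain mean RT
#'   distribution (ms) per A/P type.
#' @param pain_shift_mean_by_type,pain_shift_sd_by_type pain-induced RT
#'   shift distribution (ms) per A/P type (A negative, P positive).
#' @param ni_n_blocks,ni_trials_per_block NI task block structure
#'   (default 6 blocks of 24 trials, alternating no-pain/pain).
#' @param rt_shift_ms shift of the shifted-lognormal trial RT distribution
#'   (ms).
#' @param rt_sdlog log-scale SD of trial RTs (0 gives deterministic RTs).
#' @param outlier_rate probability a trial RT is replaced by an
#'   out-of-range value (< 200 or > 2500 ms) to exercise the filters.
#' @param p_correct probability a trial is answered correctly (carried but
#'   not used in classification).
#' @return object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_subjects_per_group = c(low = 26, high = 24),
                          seed = 1L,
                          duration_s = 300, fs = 1000,
                          aperiodic_exponent = 1,
                          aperiodic_offset = 1,
                          f_floor = 1,
                          alpha_center_by_group = c(low = 10.0, high = 10.25),
                          alpha_center_sd = 0.4,
                          alpha_bump_power_by_group = c(low = 1.5, high = 1.5),
                          alpha_bump_width = 0.8,
                          theta_power_by_group = c(low = NA, high = 0.25),
                          theta_effect_d = 0.93,
                          theta_effect_rois = c("PCC", "precuneus"),
                          theta_power_cv = 0.4,
                          noise_sd = 0.05,
                          roi_list = dpc_atlas()$roi,
                          iap_latent_range_by_group =
                            list(low = c(0.05, 0.35), high = c(0.65, 0.95)),
                          es_n_trials = 20L,
                          p_type_fraction = 12 / 47,
                          rt_nopain_mean_by_type = c(A = 1344, P = 1216),
                          rt_nopain_sd_by_type = c(A = 184, P = 162),
                          pain_shift_mean_by_type = c(A = -75, P = 48),
                          pain_shift_sd_by_type = c(A = 50, P = 33),
                          ni_n_blocks = 6L,
                          ni_trials_per_block = 24L,
                          rt_shift_ms = 300,
                          rt_sdlog = 0.25,
                          outlier_rate = 0.02,
                          p_correct = 0.95) {
  cfg <- as.list(environment())
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  stopifnot_scalar_number(cfg$fs, "fs", positive = TRUE)
  stopifnot_scalar_number(cfg$duration_s, "duration_s", positive = TRUE)
  stopifnot_scalar_number(cfg$seed, "seed")
  for (nm in c("n_subjects_per_group", "alpha_center_by_group",
               "alpha_bump_power_by_group", "theta_power_by_group")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || !identical(sort(names(v)), c("high", "low")))
      abort_painattn(sprintf(
        "`%s` must be a numeric vector named c('low', 'high')", nm),
        "invalid_config")
  }
  if (any(cfg$n_subjects_per_group < 2))
    abort_painattn("need >= 2 subjects per group", "invalid_config")
  ac <- cfg$alpha_center_by_group
  if (any(ac < 8 | ac > 13))
    abort_painattn("alpha centers must lie within [8, 13] Hz",
                   "invalid_config")
  if (!is.finite(cfg$theta_effect_d) || cfg$theta_effect_d < 0)
    abort_painattn("`theta_effect_d` must be >= 0", "invalid_config")
  if (cfg$theta_power_cv <= 0)
    abort_painattn("`theta_power_cv` must be > 0", "invalid_config")
  if (!is.finite(cfg$theta_power_by_group[["high"]]) ||
      cfg$theta_power_by_group[["high"]] < 0)
    abort_painattn("`theta_power_by_group['high']` must be a finite value >= 0",
                   "invalid_config")
  bad_roi <- setdiff(cfg$theta_effect_rois, cfg$roi_list)
  if (length(bad_roi))
    abort_painattn(paste0("theta_effect_rois not in roi_list: ",
                          paste(bad_roi, collapse = ", ")), "invalid_config")
  for (g in c("low", "high")) {
    r <- cfg$iap_latent_range_by_group[[g]]
    if (is.null(r) || any(r < 0 | r > 1) || r[1] > r[2])
      abort_painattn("latent IAP ranges must be ordered and within [0, 1]",
                     "invalid_config")
  }
  invisible(cfg)
}

# One-sided model PSD (without the white measurement-noise floor).
model_psd_core <- function(f, aperiodic_offset, aperiodic_exponent, f_floor,
                           alpha_power, alpha_center, alpha_bump_width,
                           theta_power) {
  aperiodic_offset / pmax(f, f_floor)^aperiodic_exponent +
    alpha_power * exp(-(f - alpha_center)^2 / (2 * alpha_bump_width^2)) +
    theta_power * (f >= 4 & f < 8)
}

# Expected theta-band fraction of total power for a z-normalized series:
# the measured theta AUC converges to this because the normalized series
# has unit variance and the full-band AUC approximates that variance.
expected_theta_fraction <- function(theta_power, config, group) {
  f <- seq(0.05, config$fs / 2, by = 0.05)
  base <- model_psd_core(
    f, config$aperiodic_offset, config$aperiodic_exponent, config$f_floor,
    config$alpha_bump_power_by_group[[group]],
    config$alpha_center_by_group[[group]],
    config$alpha_bump_width, theta_power = 0) +
    2 * config$noise_sd^2 / config$fs
  in_theta <- f >= 4 & f < 8
  vapply(theta_power, function(t) {
    s <- base + t * in_theta
    sum(s[in_theta]) / sum(s)
  }, numeric(1))
}

#' Calibrate the theta group effect to a target Cohen's d
#'
#' Solves for the low-group theta power level such that the expected
#' Cohen's d of the measured total theta power (the theta fraction of a
#' unit-variance spectrum) between the two groups equals
#' `config$theta_effect_d`, given the between-subject lognormal spread
#' `theta_power_cv`. The group distributions are evaluated by deterministic
#' probit-grid quadrature over the lognormal multiplier, so the calibration
#' involves no Monte-Carlo error and no time-series synthesis.
#'
#' @param config a [cohort_config()] whose
#'   `theta_power_by_group["low"]` is `NA`.
#' @return the config with `theta_power_by_group["low"]` filled in.
#' @export
calibrate_theta_effect <- function(config) {
  tp <- config$theta_power_by_group
  if (is.finite(tp[["low"]])) return(config)
  base <- tp[["high"]]
  target <- config$theta_effect_d
  if (target == 0 || base == 0) {
    config$theta_power_by_group[["low"]] <- base
    return(config)
  }
  sigma <- sqrt(log(1 + config$theta_power_cv^2))
  z <- stats::qnorm((seq_len(401L) - 0.5) / 401L)
  mult <- exp(sigma * z - sigma^2 / 2)  # unit-mean lognormal nodes
  frac_high <- expected_theta_fraction(base * mult, config, "high")
  d_of_ratio <- function(r) {
    frac_low <- expected_theta_fraction(base * r * mult, config, "low")
    (mean(frac_low) - mean(frac_high)) /
      sqrt((stats::var(frac_low) + stats::var(frac_high)) / 2)
  }
  sol <- stats::uniroot(function(r) d_of_ratio(r) - target,
                        interval = c(1, 500), tol = 1e-8)
  config$theta_power_by_group[["low"]] <- base * sol$root
  config
}

# Random-phase synthesis: amplitude spectrum shaped on the FFT grid,
# phases uniform, inverse FFT back to the time domain. Caller sets the RNG.
synth_series <- function(n, fs, psd_one_sided_fun, noise_sd) {
  if (n < 4L) abort_painattn("series too short to synthesize",
                             "invalid_config")
  half <- n %/% 2L
  k <- seq_len(if (n %% 2L == 0L) half - 1L else half)
  f <- k * fs / n
  s2 <- psd_one_sided_fun(f) / 2               # two-sided density
  amp <- sqrt(s2 * fs * n)
  phase <- stats::runif(length(k), 0, 2 * pi)
  X <- complex(length.out = n)
  X[k + 1L] <- amp * exp(1i * phase)
  X[n - k + 1L] <- Conj(X[k + 1L])
  if (n %% 2L == 0L) {
    f_nyq <- half * fs / n
    X[half + 1L] <- sqrt(psd_one_sided_fun(f_nyq) * fs * n) *
      sample(c(-1, 1), 1L)
  }
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  if (noise_sd > 0) x <- x + stats::rnorm(n, 0, noise_sd)
  x
}

#' Simulate one ROI resting-state time series
#'
#' Synthesizes a series whose expected power spectrum is the model
#' spectrum: `aperiodic_offset / f^exponent` background, a Gaussian alpha
#' bump at `alpha_center`, a flat 4-8 Hz elevation of height `theta_power`,
#' plus white measurement noise. Amplitudes are shaped on the frequency
#' grid, phases drawn uniformly, and the spectrum inverted to the time
#' domain.
#'
#' @param config a [cohort_config()]; `duration_s`, `fs` and the spectral
#'   shape parameters are read from it.
#' @param seed integer seed for this series' private substream (`NULL` to
#'   use the current RNG state).
#' @param group `"low"` or `"high"`: supplies defaults for the subject-level
#'   parameters below.
#' @param alpha_center,alpha_power,theta_power subject-level overrides of
#'   the group spectral parameters (Hz / power-density units).
#' @param subject_id,roi identifiers attached to the returned series.
#' @return a [roi_timeseries()] of `duration_s * fs` samples.
#' @examples
#' cfg <- cohort_config(duration_s = 4, fs = 500, noise_sd = 0,
#'                      theta_power_by_group = c(low = 0.2, high = 0.2))
#' ts <- simulate_roi_timeseries(cfg, seed = 7, alpha_center = 10)
#' @export
simulate_roi_timeseries <- function(config, seed = NULL, group = "high",
                                    alpha_center = NULL, alpha_power = NULL,
                                    theta_power = NULL,
                                    subject_id = NA_character_,
                                    roi = NA_character_) {
  validate_cohort_config(config)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(alpha_center))
    alpha_center <- config$alpha_center_by_group[[group]]
  if (is.null(alpha_power))
    alpha_power <- config$alpha_bump_power_by_group[[group]]
  if (is.null(theta_power)) {
    theta_power <- config$theta_power_by_group[[group]]
    if (!is.finite(theta_power))
      abort_painattn(
        "theta power for this group is uncalibrated; run calibrate_theta_effect()",
        "invalid_config")
  }
  n <- as.integer(round(config$duration_s * config$fs))
  psd_fun <- function(f) model_psd_core(
    f, config$aperiodic_offset, config$aperiodic_exponent, config$f_floor,
    alpha_power, alpha_center, config$alpha_bump_width, theta_power)
  x <- synth_series(n, config$fs, psd_fun, config$noise_sd)
  roi_timeseries(x, fs = config$fs, subject_id = subject_id, roi = roi)
}

#' Simulate experience-sampling responses for one subject
#'
#' Each trial draws two latent "attend to pain" indicators with probability
#' `latent_p` and thresholds their sum into the four ordinal categories:
#' both attend gives "only pain", neither gives "only something else", and
#' a single attend splits evenly between the two "mostly" categories. The
#' per-trial expected IAP contribution is then `2 * (2 latent_p - 1)`, so a
#' subject with `latent_p = 1` scores exactly +2, `latent_p = 0` scores
#' exactly -2, and `latent_p = 0.5` scores 0 on average.
#'
#' @param latent_p probability in \[0, 1\] of attending to pain.
#' @param n_trials number of probes (default 20).
#' @param subject_id identifier written into the table.
#' @param seed optional integer seed (`NULL` uses the current RNG state).
#' @return data.frame with columns `subject_id`, `trial`, `response`.
#' @export
simulate_experience_sampling <- function(latent_p, n_trials = 20L,
                                         subject_id = "s1", seed = NULL) {
  stopifnot_scalar_number(latent_p, "latent_p")
  if (latent_p < 0 || latent_p > 1)
    abort_painattn("`latent_p` must lie in [0, 1]", "invalid_config")
  stopifnot_scalar_number(n_trials, "n_trials", positive = TRUE)
  if (!is.null(seed)) set.seed(seed)
  k <- stats::rbinom(n_trials, 2L, latent_p)
  response <- character(n_trials)
  response[k == 2L] <- "only_pain"
  response[k == 0L] <- "only_else"
  n_mid <- sum(k == 1L)
  if (n_mid > 0L)
    response[k == 1L] <- sample(c("mostly_pain", "mostly_else"), n_mid,
                                replace = TRUE)
  data.frame(subject_id = subject_id, trial = seq_len(n_trials),
             response = response, stringsAsFactors = FALSE)
}

#' Simulate numeric-interference task trials for one subject
#'
#' Blocks alternate no-pain / pain starting with no-pain. Trial RTs follow
#' a shifted lognormal (a standard right-skewed RT model) whose condition
#' mean is `base_rt_ms` in no-pain blocks and `base_rt_ms + pain_shift_ms`
#' in pain blocks; with `rt_sdlog = 0` the RTs are exactly the condition
#' means. With probability `outlier_rate` a trial RT is replaced by an
#' out-of-range value (< 200 ms or > 2500 ms) so that exclusion filters are
#' exercised.
#'
#' @param base_rt_ms mean no-pain reaction time, ms.
#' @param pain_shift_ms additive shift of the mean in pain blocks, ms.
#' @param n_blocks even number of blocks (default 6).
#' @param trials_per_block trials per block (default 24).
#' @param rt_shift_ms lognormal shift parameter, ms (must leave positive
#'   mass: condition means must exceed it).
#' @param rt_sdlog log-scale SD of the lognormal RT component.
#' @param outlier_rate probability of replacing a trial with an outlier RT.
#' @param p_correct probability of a correct response.
#' @param subject_id identifier written into the table.
#' @param seed optional integer seed.
#' @return data.frame with columns `subject_id`, `block`, `condition`,
#'   `rt_ms`, `correct`.
#' @export
simulate_ni_trials <- function(base_rt_ms, pain_shift_ms = 0,
                               n_blocks = 6L, trials_per_block = 24L,
                               rt_shift_ms = 300, rt_sdlog = 0.25,
                               outlier_rate = 0, p_correct = 0.95,
                               subject_id = "s1", seed = NULL) {
  stopifnot_scalar_number(trials_per_block, "trials_per_block",
                          positive = TRUE)
  stopifnot_scalar_number(n_blocks, "n_blocks", positive = TRUE)
  if (n_blocks %% 2L != 0L)
    abort_painattn("`n_blocks` must be even (alternating conditions)",
                   "invalid_config")
  if (outlier_rate < 0 || outlier_rate > 1)
    abort_painattn("`outlier_rate` must lie in [0, 1]", "invalid_config")
  if (!is.null(seed)) set.seed(seed)
  blocks <- rep(seq_len(n_blocks), each = trials_per_block)
  condition <- ifelse(blocks %% 2L == 1L, "no_pain", "pain")
  target <- base_rt_ms + ifelse(condition == "pain", pain_shift_ms, 0)
  if (any(target <= rt_shift_ms))
    abort_painattn("condition mean RT must exceed `rt_shift_ms`",
                   "invalid_config")
  n <- length(blocks)
  if (rt_sdlog == 0) {
    rt <- target
  } else {
    mu <- log(target - rt_shift_ms) - rt_sdlog^2 / 2
    rt <- rt_shift_ms + stats::rlnorm(n, meanlog = mu, sdlog = rt_sdlog)
  }
  if (outlier_rate > 0) {
    out <- stats::runif(n) < outlier_rate
    if (any(out)) {
      low <- stats::runif(sum(out)) < 0.5
      rt[out][low] <- stats::runif(sum(low), 50, 199)
      rt[out][!low] <- stats::runif(sum(!low), 2501, 4000)
    }
  }
  data.frame(subject_id = subject_id, block = blocks,
             condition = condition, rt_ms = rt,
             correct = stats::runif(n) < p_correct,
             stringsAsFactors = FALSE)
}

# Deterministic substream seeds: one per subject for each behavioral task
# and one per subject x ROI for the series, all drawn once from the master
# seed so any part of the cohort can be regenerated independently.
cohort_seed_table <- function(config, n_subjects) {
  n_roi <- length(config$roi_list)
  set.seed(config$seed)
  draws <- sample.int(.Machine$integer.max, n_subjects * (2L + n_roi))
  m <- matrix(draws, nrow = n_subjects, byrow = TRUE)
  list(es = m[, 1L], ni = m[, 2L],
       series = matrix(m[, -(1:2), drop = FALSE], nrow = n_subjects,
                       dimnames = list(NULL, config$roi_list)))
}

#' Simulate a full synthetic cohort
#'
#' Draws per-subject ground truth (group labels, latent attention
#' propensity, A/P assignment and RT parameters, alpha centers, per-ROI
#' theta powers), then generates the experience-sampling table, the NI
#' trial table, and (optionally) the ROI series matrices. Everything
#' derives from the master seed through per-subject/per-ROI substreams, so
#' a fixed seed reproduces the cohort bit-identically and series can be
#' regenerated lazily with [subject_series_matrix()].
#'
#' @param config a [cohort_config()]; calibrated with
#'   [calibrate_theta_effect()] if needed.
#' @param keep_series keep all series matrices in memory (`TRUE` only for
#'   small cohorts; a full-scale cohort holds 50 x 16 x 300000 doubles).
#' @return object of class `pain_cohort`: list with `config` (calibrated),
#'   `truth` (per-subject data.frame), `theta_power` (subject x ROI matrix
#'   of true theta levels), `seeds`, `experience`, `ni_trials`, and
#'   `series` (named list of samples x ROI matrices, or `NULL`).
#' @export
simulate_cohort <- function(config = cohort_config(), keep_series = FALSE) {
  validate_cohort_config(config)
  config <- calibrate_theta_effect(config)
  n_per <- config$n_subjects_per_group
  n <- sum(n_per)
  groups <- rep(c("low", "high"), times = c(n_per[["low"]], n_per[["high"]]))
  set.seed(config$seed)
  # -- ground truth draws, fixed order --
  latent <- numeric(n)
  for (g in c("low", "high")) {
    r <- config$iap_latent_range_by_group[[g]]
    latent[groups == g] <- stats::runif(sum(groups == g), r[1], r[2])
  }
  alpha_center <- pmin(13, pmax(8, stats::rnorm(
    n, mean = config$alpha_center_by_group[groups],
    sd = config$alpha_center_sd)))
  n_p <- round(config$p_type_fraction * n)
  is_p <- rep(FALSE, n)
  is_p[sample.int(n, n_p)] <- TRUE
  ap <- ifelse(is_p, "P", "A")
  base_rt <- stats::rnorm(n, config$rt_nopain_mean_by_type[ap],
                          config$rt_nopain_sd_by_type[ap])
  pain_shift <- stats::rnorm(n, config$pain_shift_mean_by_type[ap],
                             config$pain_shift_sd_by_type[ap])
  sigma <- sqrt(log(1 + config$theta_power_cv^2))
  n_roi <- length(config$roi_list)
  mult <- matrix(exp(stats::rnorm(n * n_roi, -sigma^2 / 2, sigma)),
                 nrow = n, dimnames = list(NULL, config$roi_list))
  base_theta <- matrix(config$theta_power_by_group[["high"]],
                       nrow = n, ncol = n_roi,
                       dimnames = list(NULL, config$roi_list))
  base_theta[groups == "low", config$theta_effect_rois] <-
    config$theta_power_by_group[["low"]]
  theta_power <- base_theta * mult
  truth <- data.frame(
    subject_id = sprintf("sub-%03d", seq_len(n)),
    group = groups, latent_p = latent, alpha_center = alpha_center,
    ap_type_true = ap, base_rt_ms = base_rt, pain_shift_ms = pain_shift,
    stringsAsFactors = FALSE)
  rownames(theta_power) <- truth$subject_id
  seeds <- cohort_seed_table(config, n)
  experience <- do.call(rbind, lapply(seq_len(n), function(i)
    simulate_experience_sampling(latent[i], config$es_n_trials,
                                 truth$subject_id[i], seed = seeds$es[i])))
  ni <- do.call(rbind, lapply(seq_len(n), function(i)
    simulate_ni_trials(base_rt[i], pain_shift[i],
                       n_blocks = config$ni_n_blocks,
                       trials_per_block = config$ni_trials_per_block,
                       rt_shift_ms = config$rt_shift_ms,
                       rt_sdlog = config$rt_sdlog,
                       outlier_rate = config$outlier_rate,
                       p_correct = config$p_correct,
                       subject_id = truth$subject_id[i],
                       seed = seeds$ni[i])))
  cohort <- structure(list(config = config, truth = truth,
                           theta_power = theta_power, seeds = seeds,
                           experience = experience, ni_trials = ni,
                           series = NULL),
                      class = "pain_cohort")
  if (keep_series) {
    cohort$series <- lapply(seq_len(n), function(i)
      subject_series_matrix(cohort, truth$subject_id[i]))
    names(cohort$series) <- truth$subject_id
  }
  cohort
}

#' @export
print.pain_cohort <- function(x, ...) {
  cat(sprintf(
    "<pain_cohort> %d subjects (%d low / %d high IAP), %d ROIs, %g s @ %g Hz\n",
    nrow(x$truth), sum(x$truth$group == "low"),
    sum(x$truth$group == "high"), length(x$config$roi_list),
    x$config$duration_s, x$config$fs))
  invisible(x)
}

#' Regenerate one subject's multi-ROI series matrix
#'
#' Uses the cohort's per-subject x ROI seed substreams, so the result is
#' identical whether series were kept at simulation time or regenerated
#' later.
#'
#' @param cohort a `pain_cohort`.
#' @param subject_id one of the cohort's subject ids.
#' @return numeric matrix, samples x ROIs (columns named by ROI).
#' @export
subject_series_matrix <- function(cohort, subject_id) {
  i <- match(subject_id, cohort$truth$subject_id)
  if (is.na(i))
    abort_painattn(sprintf("unknown subject '%s'", subject_id),
                   "invalid_input")
  if (!is.null(cohort$series) && subject_id %in% names(cohort$series))
    return(cohort$series[[subject_id]])
  cfg <- cohort$config
  n <- as.integer(round(cfg$duration_s * cfg$fs))
  out <- matrix(NA_real_, nrow = n, ncol = length(cfg$roi_list),
                dimnames = list(NULL, cfg$roi_list))
  for (r in cfg$roi_list) {
    ts <- simulate_roi_timeseries(
      cfg, seed = cohort$seeds$series[i, r], group = cohort$truth$group[i],
      alpha_center = cohort$truth$alpha_center[i],
      theta_power = cohort$theta_power[i, r],
      subject_id = subject_id, roi = r)
    out[, r] <- ts$samples
  }
  out
}
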