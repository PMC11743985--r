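#' @title Behavioral phenotyping: IAP score and A/P type
#' @description Functions that turn raw behavioral task tables into
#'   per-subject phenotypes: the intrinsic attention to pain (IAP) score
#'   from experience-sampling thought probes, and the A/P classification
#'   from numeric-interference (NI) task reaction times.
#' @name behavioral_phenotyping
NULL

# canonical response labels, ordered from "attending to pain" downwards
.iap_responses <- c("only_pain", "mostly_pain", "mostly_else", "only_else")
.iap_weights   <- c(only_pain = 2, mostly_pain = 1,
                    mostly_else = -1, only_else = -2)

#' Compute IAP scores from experience-sampling records
#'
#' The IAP score summarises, per subject, how often thought-probe responses
#' reported attention toward the painful stimulus versus away from it:
#'
#' \deqn{IAP = (2 n_{only\_pain} + n_{mostly\_pain} - 2 n_{only\_else} -
#'   n_{mostly\_else}) / n_{total}}
#'
#' so a subject answering "only pain" on every trial scores +2 and one
#' answering "only something else" on every trial scores -2. Subjects with a
#' negative score form the low-IAP group (mind-wander away from pain),
#' positive scores the high-IAP group; a score of exactly 0 is labelled
#' `boundary` and excluded from two-group contrasts downstream (with a
#' warning there), since neither group definition covers it.
#'
#' @param records data.frame with columns `subject_id`, `trial`, `response`;
#'   `response` must be one of `"only_pain"`, `"mostly_pain"`,
#'   `"mostly_else"`, `"only_else"`.
#' @return data.frame with one row per subject: `subject_id`, `iap_score`
#'   (in \[-2, 2\]), `iap_group` (`"low"`, `"high"`, or `"boundary"`),
#'   `n_trials`.
#' @examples
#' rec <- data.frame(subject_id = "s1", trial = 1:20, response = "only_pain")
#' compute_iap_score(rec)  # iap_score == 2
#' @export
compute_iap_score <- function(records) {
  records <- validate_experience_records(records)
  split_idx <- split(seq_len(nrow(records)), records$subject_id)
  rows <- lapply(names(split_idx), function(sid) {
    resp <- records$response[split_idx[[sid]]]
    n <- length(resp)
    counts <- table(factor(resp, levels = .iap_responses))
    score <- (2 * counts[["only_pain"]] + counts[["mostly_pain"]]
              - 2 * counts[["only_else"]] - counts[["mostly_else"]]) / n
    data.frame(subject_id = sid, iap_score = score,
               iap_group = iap_group_label(score), n_trials = n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

iap_group_label <- function(score) {
  ifelse(score < 0, "low", ifelse(score > 0, "high", "boundary"))
}

validate_experience_records <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    abort_painattn("experience-sampling records are empty", "empty_input")
  need <- c("subject_id", "trial", "response")
  miss <- setdiff(need, names(records))
  if (length(miss))
    abort_painattn(paste0("missing column(s): ", paste(miss, collapse = ", ")),
                   "parse_error")
  bad <- setdiff(unique(records$response), .iap_responses)
  if (length(bad))
    abort_painattn(paste0("unknown response label(s): ",
                          paste(bad, collapse = ", ")), "parse_error")
  dup <- stats::aggregate(trial ~ subject_id, records,
                          function(t) anyDuplicated(t) > 0L)
  if (any(dup$trial))
    abort_painattn("duplicated trial indices within a subject", "parse_error")
  records
}

#' Filter numeric-interference trials before RT averaging
#'
#' Applies the two exclusion rules used before computing condition means:
#' the first two blocks (one no-pain, one pain) are dropped to reduce
#' learning effects, and trials with reaction times below 200 ms or
#' exceeding 2500 ms are dropped. Both bounds are inclusive: a 200 ms or
#' 2500 ms trial is retained.
#'
#' @param records data.frame with columns `subject_id`, `block`, `condition`
#'   (`"pain"`/`"no_pain"`), `rt_ms`, and optionally `correct`.
#' @param rt_min,rt_max retention bounds in ms (defaults 200 and 2500).
#' @param drop_blocks block indices excluded as practice (default `1:2`).
#' @return The subset of `records` passing all filters (possibly 0 rows).
#' @export
filter_ni_trials <- function(records, rt_min = 200, rt_max = 2500,
                             drop_blocks = 1:2) {
  records <- validate_ni_records(records)
  keep <- !(records$block %in% drop_blocks) &
    records$rt_ms >= rt_min & records$rt_ms <= rt_max
  records[keep, , drop = FALSE]
}

validate_ni_records <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    abort_painattn("NI trial records are empty", "empty_input")
  need <- c("subject_id", "block", "condition", "rt_ms")
  miss <- setdiff(need, names(records))
  if (length(miss))
    abort_painattn(paste0("missing column(s): ", paste(miss, collapse = ", ")),
                   "parse_error")
  bad <- setdiff(unique(records$condition), c("pain", "no_pain"))
  if (length(bad))
    abort_painattn(paste0("unknown condition label(s): ",
                          paste(bad, collapse = ", ")), "parse_error")
  if (any(!is.finite(records$rt_ms) | records$rt_ms <= 0))
    abort_painattn("rt_ms must be finite and > 0", "parse_error")
  records
}

#' Classify subjects as A or P type from filtered NI trials
#'
#' Computes the mean reaction time per condition over the surviving trials
#' and the pain interference effect
#' \deqn{\Delta RT_{mean} = RT_{mean,pain} - RT_{mean,no\mbox{-}pain}.}
#' A negative difference (faster under pain: attention to task dominates)
#' gives A type; a positive difference (pain-induced slowing) gives P type;
#' exactly zero is labelled `boundary`.
#'
#' Records are expected to be pre-filtered with [filter_ni_trials()]; if a
#' condition has no surviving trials for a subject the function fails with
#' an `empty_after_filter` error naming that condition.
#'
#' @param records filtered NI trial data.frame (see [filter_ni_trials()]).
#' @return data.frame with one row per subject: `subject_id`,
#'   `rt_mean_pain`, `rt_mean_nopain`, `delta_rt_mean`, `ap_type`
#'   (`"A"`, `"P"`, or `"boundary"`), `n_trials_used_pain`,
#'   `n_trials_used_nopain`.
#' @export
compute_ap_type <- function(records) {
  if (is.data.frame(records) && nrow(records) == 0L)
    abort_painattn("no trials remain after filtering", "empty_after_filter")
  records <- validate_ni_records(records)
  split_idx <- split(seq_len(nrow(records)), records$subject_id)
  rows <- lapply(names(split_idx), function(sid) {
    sub <- records[split_idx[[sid]], , drop = FALSE]
    pain <- sub$rt_ms[sub$condition == "pain"]
    nop  <- sub$rt_ms[sub$condition == "no_pain"]
    for (cond in c(pain = "pain", no_pain = "no_pain")) {
      n_cond <- if (cond == "pain") length(pain) else length(nop)
      if (n_cond == 0L)
        abort_painattn(sprintf(
          "subject %s: no trials left in condition '%s' after filtering",
          sid, cond), "empty_after_filter")
    }
    delta <- mean(pain) - mean(nop)
    data.frame(subject_id = sid,
               rt_mean_pain = mean(pain), rt_mean_nopain = mean(nop),
               delta_rt_mean = delta,
               ap_type = ifelse(delta < 0, "A",
                                ifelse(delta > 0, "P", "boundary")),
               n_trials_used_pain = length(pain),
               n_trials_used_nopain = length(nop),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build a combined per-subject phenotype table
#'
#' Convenience wrapper: computes IAP results from experience-sampling
#' records and A/P results from (unfiltered) NI trials, applies
#' [filter_ni_trials()], and merges the two by subject. Subjects present in
#' only one table get `NA` in the other phenotype's columns.
#'
#' @param experience experience-sampling data.frame
#'   (see [compute_iap_score()]).
#' @param ni_trials raw NI trial data.frame (see [filter_ni_trials()]).
#' @return merged data.frame with columns `subject_id`, `iap_score`,
#'   `iap_group`, `delta_rt_mean`, `ap_type` (plus supporting counts/means).
#' @export
phenotype_table <- function(experience, ni_trials) {
  iap <- compute_iap_score(experience)
  ap <- compute_ap_type(filter_ni_trials(ni_trials))
  merge(iap, ap, by = "subject_id", all = TRUE, sort = TRUE)
}
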