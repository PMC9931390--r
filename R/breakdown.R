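#' Area under a growth curve after blank subtraction
#'
#' Trapezoidal integral of `max(od - blank, 0)` over time, with time
#' converted from minutes to hours.
#'
#' @param time_min measurement times (minutes), strictly increasing,
#'   at least two.
#' @param od OD readings (same length).
#' @param blank blank OD to subtract (default 0).
#' @return AUC in OD h.
#' @export
growth_auc <- function(time_min, od, blank = 0) {
  gs_assert(length(time_min) >= 2, "need at least two timepoints")
  gs_assert(length(od) == length(time_min), "length mismatch")
  gs_assert(all(diff(time_min) > 0), "times must be strictly increasing")
  y <- pmax(od - blank, 0)
  th <- time_min / 60
  sum(diff(th) * (y[-1] + y[-length(y)]) / 2)
}

#' One-tailed t-test between knockout and wild-type AUCs
#'
#' Tests whether conditioned buffer from a knockout changed the reporter
#' strain's growth relative to wild-type-conditioned buffer.
#' `side = "greater"` tests knockout > wild type (the fast-degrader
#' direction on 15-min buffer); `side = "less"` tests knockout < wild
#' type (slow-degrader direction on 45-min buffer). The default is the
#' pooled-variance Student t: with 3 knockout versus 18 wild-type
#' replicates the Welch statistic is left with about 2.4 effective
#' degrees of freedom and little power, while the assay replicates come
#' from a common protocol with comparable variances. Set
#' `var_equal = FALSE` for the Welch form.
#'
#' @param ko_aucs knockout replicate AUCs (>= 2).
#' @param wt_aucs wild-type replicate AUCs (>= 2).
#' @param side `"greater"` or `"less"`.
#' @param var_equal pooled-variance t (default) or Welch.
#' @return one-tailed p-value.
#' @export
degrader_test <- function(ko_aucs, wt_aucs, side = c("greater", "less"),
                          var_equal = TRUE) {
  side <- match.arg(side)
  gs_assert(length(ko_aucs) >= 2 && length(wt_aucs) >= 2,
            "each group needs >= 2 values")
  gs_assert(stats::var(ko_aucs) > 0 || stats::var(wt_aucs) > 0,
            "zero variance in both groups: t statistic undefined",
            "gemscreen_statistical_error")
  stats::t.test(ko_aucs, wt_aucs, alternative = side,
                var.equal = var_equal)$p.value
}

#' Classify knockouts as fast or slow drug degraders
#'
#' For each knockout, the 15-min conditioned-buffer AUCs are tested
#' against wild type in the `greater` direction (fast degrader: drug
#' depleted early, reporter grows more) and the 45-min AUCs in the `less`
#' direction (slow degrader: drug still present late, reporter grows
#' less). P-values are BH-adjusted separately per direction across
#' strains; a strain is called where its q-value is below `q_cutoff`.
#' Strains significant in both directions are set to `"none"` with a
#' warning; strains missing a timepoint are skipped with a warning.
#'
#' @param summaries data.frame with columns `strain`, `timepoint`
#'   (`"15"`/`"45"`), `replicate`, `auc` (as from
#'   [simulate_breakdown_cohort()]).
#' @param wt_strain strain id of the wild-type control (default "WT").
#' @param q_cutoff FDR threshold (default 0.1).
#' @return data.frame of class `degrader_calls`: strain, class, p_fast,
#'   q_fast, p_slow, q_slow, mean_auc_15, mean_auc_45.
#' @export
classify_degraders <- function(summaries, wt_strain = "WT", q_cutoff = 0.1) {
  gs_assert(all(c("strain", "timepoint", "replicate", "auc")
                %in% names(summaries)),
            "`summaries` needs strain, timepoint, replicate, auc")
  summaries$timepoint <- sub("\\s*min$", "", as.character(summaries$timepoint))
  gs_assert(all(summaries$timepoint %in% c("15", "45")),
            "timepoints must be 15 or 45 (min)")
  gs_assert(wt_strain %in% summaries$strain,
            "wild-type strain not present in `summaries`")
  wt15 <- summaries$auc[summaries$strain == wt_strain &
                          summaries$timepoint == "15"]
  wt45 <- summaries$auc[summaries$strain == wt_strain &
                          summaries$timepoint == "45"]
  strains <- setdiff(unique(summaries$strain), wt_strain)
  rows <- lapply(strains, function(s) {
    a15 <- summaries$auc[summaries$strain == s & summaries$timepoint == "15"]
    a45 <- summaries$auc[summaries$strain == s & summaries$timepoint == "45"]
    if (length(a15) < 2 || length(a45) < 2) {
      gs_warn(sprintf("strain '%s' skipped: missing timepoint replicates", s))
      return(NULL)
    }
    data.frame(strain = s,
               p_fast = degrader_test(a15, wt15, "greater"),
               p_slow = degrader_test(a45, wt45, "less"),
               mean_auc_15 = mean(a15), mean_auc_45 = mean(a45))
  })
  out <- do.call(rbind, rows)
  gs_assert(!is.null(out), "no testable strains")
  out$q_fast <- stats::p.adjust(out$p_fast, "BH")
  out$q_slow <- stats::p.adjust(out$p_slow, "BH")
  fast <- out$q_fast < q_cutoff
  slow <- out$q_slow < q_cutoff
  both <- fast & slow
  if (any(both)) {
    gs_warn(sprintf(
      "%d strain(s) significant in both directions set to 'none'",
      sum(both)))
  }
  out$class <- ifelse(both, "none",
                      ifelse(fast, "fast", ifelse(slow, "slow", "none")))
  out <- out[, c("strain", "class", "p_fast", "q_fast", "p_slow", "q_slow",
                 "mean_auc_15", "mean_auc_45")]
  class(out) <- c("degrader_calls", "data.frame")
  out
}
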