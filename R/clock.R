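#' Fit the gestational clock and test for acceleration in the PTB group
#'
#' Predicts GA at sampling from the omics matrix with the repeated
#' cross-validation harness, computes each participant's clock discrepancy
#' (predicted minus ultrasound GA, in weeks, so an "accelerated" clock is a
#' positive discrepancy), and compares discrepancies between PTB and term
#' participants with the two-sided rank-sum test. A sensitivity variant
#' restricted to GA-matched case-control pairs (when pair labels are
#' supplied) is reported alongside.
#'
#' Under unbiased cross-validated prediction the discrepancy averages to
#' about zero over all participants; the group contrast isolates the planted
#' or biological forward shift.
#'
#' @param omics \linkS4class{OmicsMatrix} (or matrix) of predictors.
#' @param cohort \linkS4class{CohortTable} providing ultrasound GA at
#'   sampling and PTB status for the same participants.
#' @param cfg a regression \code{\link{harnessConfig}}.
#' @param pairs optional named vector of matched-pair labels for the
#'   sensitivity test.
#' @return a \linkS4class{ClockResult}.
#' @export
fitClock <- function(omics, cohort, cfg = harnessConfig("regression"),
                     pairs = NULL) {
  if (is(omics, "OmicsMatrix")) omics <- featureMatrix(omics)
  d <- cohortData(cohort)
  stopifnot(all(rownames(omics) %in% d$participant_id))
  d <- d[match(rownames(omics), d$participant_id), ]
  if (anyNA(d$ga_sampling_weeks)) stop("GA at sampling must be available for all participants")
  if (diff(range(d$ga_sampling_weeks)) < 2) {
    warning("GA at sampling spans under 2 weeks; clock fit is weakly identified")
  }
  stopifnot(cfg$task == "regression")
  cv <- repeatedCV(omics, d$ga_sampling_weeks, cfg, sites = d$site)
  p <- cvPredictions(cv)
  disc <- data.frame(
    participant_id = p$participant_id,
    predicted_ga = p$predicted,
    ultrasound_ga = p$observed,
    discrepancy = p$predicted - p$observed,
    ptb = d$ptb,
    stringsAsFactors = FALSE
  )
  ok <- !is.na(disc$discrepancy)
  test <- wilcoxonRankSum(disc$discrepancy[ok & disc$ptb],
                          disc$discrepancy[ok & !disc$ptb])
  test$median_shift <- stats::median(disc$discrepancy[ok & disc$ptb]) -
    stats::median(disc$discrepancy[ok & !disc$ptb])
  if (!is.null(pairs)) {
    pr <- pairs[disc$participant_id]
    paired <- !is.na(pr) & ok
    test$matched_p <- wilcoxonRankSum(disc$discrepancy[paired & disc$ptb],
                                      disc$discrepancy[paired & !disc$ptb])$p
  }
  new("ClockResult", discrepancies = disc, test = test, cv = cv)
}

#' Convert time-to-delivery predictions into predicted GA at birth
#'
#' Predicted GA at birth = GA at sampling (known at prediction time) +
#' predicted time-to-delivery; the addition is exact. PTB discrimination is
#' assessed by the two-sided rank-sum comparison of predicted GA at birth
#' between PTB and term groups. Negative predicted times-to-delivery are
#' permitted but reported.
#'
#' @param predicted_ttd numeric predicted time-to-delivery in weeks.
#' @param ga_sampling numeric GA at sampling in weeks, aligned with
#'   \code{predicted_ttd}.
#' @param ptb logical PTB status, aligned.
#' @return list with \code{predicted_ga_birth}, \code{test} (rank-sum
#'   statistic and p), and \code{n_negative_ttd}.
#' @export
ttdToBirthGA <- function(predicted_ttd, ga_sampling, ptb) {
  stopifnot(length(predicted_ttd) == length(ga_sampling),
            length(ptb) == length(ga_sampling))
  neg <- sum(predicted_ttd < 0, na.rm = TRUE)
  if (neg > 0) message(neg, " negative predicted time(s)-to-delivery")
  pred_birth <- ga_sampling + predicted_ttd
  ok <- !is.na(pred_birth)
  list(
    predicted_ga_birth = pred_birth,
    test = wilcoxonRankSum(pred_birth[ok & ptb], pred_birth[ok & !ptb]),
    n_negative_ttd = neg
  )
}

#' Residual-versus-truth error profile of a regression result
#'
#' Bins residuals (predicted - observed) by deciles of the observed target
#' and reports per-decile mean residuals plus the slope of the residual on
#' the truth. A shrinking predictor (prediction = s x truth + const, s < 1)
#' has slope s - 1 < 0: it underestimates large targets and overestimates
#' small ones, the regression-to-the-mean signature.
#'
#' @param result a regression \linkS4class{CVResult} (or data.frame with
#'   \code{predicted} and \code{observed} columns).
#' @param n_bins number of truth-quantile bins (default 10).
#' @return list with \code{bins} (data.frame: bin, mid, mean_residual, n)
#'   and \code{slope}.
#' @export
errorProfile <- function(result, n_bins = 10L) {
  p <- if (is(result, "CVResult")) result@predictions else as.data.frame(result)
  p <- p[!is.na(p$predicted), ]
  resid <- p$predicted - p$observed
  br <- unique(stats::quantile(p$observed, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(p$observed, breaks = br, include.lowest = TRUE)
  bins <- data.frame(
    bin = levels(bin),
    mid = as.numeric(tapply(p$observed, bin, mean)),
    mean_residual = as.numeric(tapply(resid, bin, mean)),
    n = as.integer(table(bin)),
    stringsAsFactors = FALSE
  )
  slope <- unname(stats::coef(stats::lm(resid ~ p$observed))[2])
  list(bins = bins, slope = slope)
}
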