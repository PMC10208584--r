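#' Area under the ROC curve (rank-based)
#'
#' Normalized Mann-Whitney U with midrank tie handling: the probability that
#' a random positive outranks a random negative, counting ties as 1/2.
#'
#' @param pred numeric scores (higher = more positive).
#' @param labels logical or 0/1 outcome.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(pred, labels) {
  labels <- as.logical(labels)
  ok <- !is.na(pred) & !is.na(labels)
  pred <- pred[ok]; labels <- labels[ok]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(pred) # midranks
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (interpolation-free)
#'
#' Step-curve summation over recall increments: walking down the ranking,
#' each block of tied scores contributes (recall gained in the block) times
#' (precision at the block's end). Without ties this is the standard average
#' precision; with all scores tied it collapses to the prevalence, the
#' chance-level baseline.
#'
#' @param pred numeric scores (higher = more positive).
#' @param labels logical or 0/1 outcome.
#' @return AUPRC in (0, 1].
#' @export
auprc <- function(pred, labels) {
  labels <- as.logical(labels)
  ok <- !is.na(pred) & !is.na(labels)
  pred <- pred[ok]; labels <- labels[ok]
  n_pos <- sum(labels)
  if (n_pos == 0 || n_pos == length(labels)) stop("both classes must be present")
  o <- order(pred, decreasing = TRUE)
  lab <- labels[o]; sc <- pred[o]
  block <- cumsum(!duplicated(sc)) # tied scores share a block
  tp_block <- tapply(lab, block, sum)
  n_block <- tapply(lab, block, length)
  tp_cum <- cumsum(tp_block)
  n_cum <- cumsum(n_block)
  precision_end <- tp_cum / n_cum
  delta_recall <- tp_block / n_pos
  sum(delta_recall * precision_end)
}

#' Lift: AUPRC relative to the chance-level baseline
#'
#' A random ranker's AUPRC equals the outcome prevalence, so Lift = 1 means
#' chance-level ranking and Lift = 2.4 a 2.4-fold improvement over baseline.
#'
#' @param auprc_value AUPRC of the model.
#' @param prevalence positive-class prevalence in the evaluated population.
#' @export
lift <- function(auprc_value, prevalence) {
  stopifnot(prevalence > 0, prevalence <= 1)
  auprc_value / prevalence
}

#' Regression evaluation: Pearson r with CI, p, RMSE, MAE
#'
#' Product-moment correlation with Fisher-z 95\% confidence interval and
#' two-sided p (via \code{stats::cor.test}), root mean square error and mean
#' absolute error. Zero variance in either vector leaves r undefined
#' (flagged \code{NA} with a warning); the error metrics are still returned.
#'
#' @param pred predicted values.
#' @param truth observed values.
#' @return list with r, r_ci, p, rmse, mae, n.
#' @export
regressionMetrics <- function(pred, truth) {
  ok <- !is.na(pred) & !is.na(truth)
  pred <- pred[ok]; truth <- truth[ok]
  if (length(pred) < 3) stop("need at least 3 paired observations")
  out <- list(
    rmse = sqrt(mean((pred - truth)^2)),
    mae = mean(abs(pred - truth)),
    n = length(pred)
  )
  if (stats::sd(pred) == 0 || stats::sd(truth) == 0) {
    warning("zero variance; Pearson r undefined")
    out$r <- NA_real_; out$r_ci <- c(NA_real_, NA_real_); out$p <- NA_real_
  } else {
    ct <- stats::cor.test(pred, truth, method = "pearson")
    out$r <- unname(ct$estimate)
    out$r_ci <- as.numeric(ct$conf.int)
    out$p <- ct$p.value
  }
  out[c("r", "r_ci", "p", "rmse", "mae", "n")]
}

#' Two-sided Wilcoxon rank-sum test (normal approximation)
#'
#' Mann-Whitney U computed on midranks with the tie-corrected normal
#' approximation (no continuity correction). When the tie-corrected variance
#' is zero (all values identical) the p-value is 1.
#'
#' @param a,b numeric samples.
#' @return list with \code{statistic} (U for the first sample) and \code{p}.
#' @export
wilcoxonRankSum <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 == 0 || n2 == 0) stop("both samples must be non-empty")
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  nn <- n1 + n2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
  if (sigma2 <= 0) return(list(statistic = u, p = 1))
  z <- (u - n1 * n2 / 2) / sqrt(sigma2)
  list(statistic = u, p = 2 * stats::pnorm(-abs(z)))
}

#' Risk ratio from a 2x2 table with log-scale Wald confidence interval
#'
#' Rows are exposure (exposed first), columns outcome (event first).
#'
#' @param tab 2x2 matrix of counts, or a length-4 vector (a, b, c, d) =
#'   (exposed events, exposed non-events, unexposed events, unexposed
#'   non-events).
#' @param conf_level confidence level (default 0.95).
#' @return list with rr, ci, p.
#' @export
riskRatio <- function(tab, conf_level = 0.95) {
  if (is.matrix(tab)) tab <- c(t(tab))
  stopifnot(length(tab) == 4, all(tab >= 0))
  a <- tab[1]; b <- tab[2]; c_ <- tab[3]; d <- tab[4]
  risk1 <- a / (a + b)
  risk0 <- c_ / (c_ + d)
  rr <- risk1 / risk0
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c_ - 1 / (c_ + d))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  z <- log(rr) / se
  list(
    rr = rr,
    ci = exp(log(rr) + c(-1, 1) * zq * se),
    p = 2 * stats::pnorm(-abs(z))
  )
}
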