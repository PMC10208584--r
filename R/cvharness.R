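#' Configuration of the repeated cross-validation harness
#'
#' @param task "classification" or "regression".
#' @param n_reps number of repeated random splits (default 50).
#' @param train_fraction fraction of participants in each training half
#'   (default 0.5, the even split the harness is designed around).
#' @param seed base seed; repetition r uses seed + r so results are
#'   independent of execution order.
#' @param params gradient-boosted-tree hyperparameters handed to the learner
#'   (conservative defaults: shallow trees, small learning rate).
#' @param nrounds boosting rounds.
#' @param weighted for classification, weight the loss by inverse class
#'   frequency (positive-class weight = n_neg/n_pos of the training split).
#' @param bootstrap_ci_reps participant-level bootstrap resamples for
#'   AUROC/AUPRC confidence intervals (default 1000).
#' @return list of class settings used by \code{\link{repeatedCV}}.
#' @export
harnessConfig <- function(task = c("classification", "regression"),
                          n_reps = 50L, train_fraction = 0.5, seed = 1L,
                          params = list(max_depth = 3, eta = 0.1,
                                        subsample = 0.8,
                                        colsample_bytree = 0.8),
                          nrounds = 150L, weighted = TRUE,
                          bootstrap_ci_reps = 1000L) {
  task <- match.arg(task)
  stopifnot(n_reps >= 1, train_fraction > 0, train_fraction < 1)
  list(task = task, n_reps = as.integer(n_reps),
       train_fraction = train_fraction, seed = as.integer(seed),
       params = params, nrounds = as.integer(nrounds), weighted = weighted,
       bootstrap_ci_reps = as.integer(bootstrap_ci_reps))
}

## single gradient-boosted tree fit + prediction, the learner behind every
## multivariate model in the package
fitBoost <- function(x_train, y_train, x_test, cfg) {
  params <- cfg$params
  params$nthread <- 1
  if (cfg$task == "classification") {
    params$objective <- "binary:logistic"
    if (isTRUE(cfg$weighted)) {
      params$scale_pos_weight <- sum(y_train == 0) / sum(y_train == 1)
    }
  } else {
    params$objective <- "reg:squarederror"
  }
  dtrain <- xgboost::xgb.DMatrix(x_train, label = y_train, nthread = 1)
  bst <- xgboost::xgb.train(params = params, data = dtrain,
                            nrounds = cfg$nrounds, verbose = 0)
  pred <- if (is.null(x_test)) NULL else {
    stats::predict(bst, xgboost::xgb.DMatrix(x_test, nthread = 1))
  }
  list(model = bst, pred = pred)
}

## stratified (classification) or simple random train indices
drawSplit <- function(y, task, train_fraction, seed) {
  set.seed(seed)
  n <- length(y)
  if (task == "classification") {
    idx_pos <- which(y == 1); idx_neg <- which(y == 0)
    train <- c(sample(idx_pos, round(length(idx_pos) * train_fraction)),
               sample(idx_neg, round(length(idx_neg) * train_fraction)))
  } else {
    train <- sample(n, round(n * train_fraction))
  }
  sort(train)
}

#' Repeated split-half cross-validation with per-participant averaging
#'
#' The estimation scheme used for every multivariate model in the package:
#' participants are randomly split into an even training and test half
#' (stratified by outcome for classification), a gradient-boosted tree
#' ensemble is fitted on the training half and predicts the test half; this
#' is repeated \code{n_reps} times, and each participant's final prediction
#' is the average of their predictions over the repetitions in which they
#' fell in the test half. Because contributing models never saw the
#' participant during training, the averaged prediction is out-of-fold; the
#' train-membership ledger kept in the result makes this property checkable.
#'
#' Classification uses an imbalance-weighted loss (positive-class weight =
#' n_neg/n_pos of each training half). Metrics: AUROC and AUPRC with
#' participant-level percentile-bootstrap 95\% CIs, Lift over the observed
#' prevalence and the rank-sum p comparing predicted scores between classes;
#' or Pearson r (Fisher-z CI), RMSE and MAE for regression. If a training
#' half loses a class (possible only without stratification), the repetition
#' is redrawn with an incremented seed and a message is logged. Participants
#' never appearing in a test half are excluded from metrics with a message.
#'
#' @param features participants-by-features numeric matrix (rownames =
#'   participant ids) or an \linkS4class{OmicsMatrix}. Missing values are
#'   left to the tree learner's native missing handling.
#' @param target outcome vector aligned with the rows of \code{features}
#'   (logical/0-1 for classification, numeric for regression).
#' @param cfg a \code{\link{harnessConfig}}.
#' @param sites optional site labels aligned with participants; triggers the
#'   per-site metric table.
#' @return a \linkS4class{CVResult}.
#' @export
repeatedCV <- function(features, target, cfg, sites = NULL) {
  if (is(features, "OmicsMatrix")) features <- featureMatrix(features)
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 20) stop("need at least 20 participants")
  ids <- rownames(features)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  y <- if (cfg$task == "classification") as.numeric(as.logical(target)) else as.numeric(target)
  stopifnot(length(y) == n, !anyNA(y))
  if (cfg$task == "classification" && length(unique(y)) < 2) {
    stop("both classes must be present")
  }

  pred_sum <- numeric(n); pred_n <- integer(n)
  membership <- matrix(FALSE, nrow = cfg$n_reps, ncol = n,
                       dimnames = list(NULL, ids))
  for (r in seq_len(cfg$n_reps)) {
    seed_r <- cfg$seed + r
    repeat {
      train <- drawSplit(y, cfg$task, cfg$train_fraction, seed_r)
      if (cfg$task != "classification" ||
          length(unique(y[train])) == 2) break
      message("repetition ", r, ": class lost in training split; redrawing")
      seed_r <- seed_r + cfg$n_reps
    }
    test <- setdiff(seq_len(n), train)
    fit <- fitBoost(features[train, , drop = FALSE], y[train],
                    features[test, , drop = FALSE], cfg)
    pred_sum[test] <- pred_sum[test] + fit$pred
    pred_n[test] <- pred_n[test] + 1L
    membership[r, train] <- TRUE
  }

  never <- pred_n == 0L
  if (any(never)) {
    message("excluded from metrics (never in a test half): ",
            paste(ids[never], collapse = ", "))
  }
  predictions <- data.frame(
    participant_id = ids,
    observed = y,
    predicted = ifelse(never, NA_real_, pred_sum / pmax(pred_n, 1L)),
    n_test = pred_n,
    stringsAsFactors = FALSE
  )
  if (!is.null(sites)) predictions$site <- as.character(sites)

  keep <- !never
  metrics <- computeTaskMetrics(predictions$predicted[keep], y[keep],
                                cfg$task, cfg$bootstrap_ci_reps, cfg$seed)
  res <- new("CVResult",
    task = cfg$task, predictions = predictions, metrics = metrics,
    per_site = data.frame(), train_membership = membership,
    config = cfg
  )
  if (!is.null(sites)) res@per_site <- perSiteMetrics(res)
  res
}

computeTaskMetrics <- function(pred, y, task, ci_reps, seed) {
  if (task == "classification") {
    prevalence <- mean(y)
    m <- list(
      auroc = auroc(pred, y),
      auprc = auprc(pred, y),
      prevalence = prevalence
    )
    m$lift <- lift(m$auprc, prevalence)
    m$rank_sum_p <- wilcoxonRankSum(pred[y == 1], pred[y == 0])$p
    if (ci_reps > 0) {
      ci <- bootstrapMetricCI(pred, y,
                              list(auroc = auroc, auprc = auprc),
                              ci_reps, seed)
      m$auroc_ci <- ci$auroc; m$auprc_ci <- ci$auprc
    } else {
      m$auroc_ci <- c(NA_real_, NA_real_); m$auprc_ci <- c(NA_real_, NA_real_)
    }
    m
  } else {
    regressionMetrics(pred, y)
  }
}

## participant-level percentile bootstrap on the averaged predictions
bootstrapMetricCI <- function(pred, y, metric_fns, n_boot, seed) {
  set.seed(seed)
  draws <- vapply(seq_len(n_boot), function(b) {
    idx <- sample(length(pred), replace = TRUE)
    while (length(unique(y[idx])) < 2) idx <- sample(length(pred), replace = TRUE)
    vapply(metric_fns, function(f) f(pred[idx], y[idx]), numeric(1))
  }, numeric(length(metric_fns)))
  draws <- matrix(draws, nrow = length(metric_fns))
  out <- lapply(seq_along(metric_fns), function(i) {
    unname(stats::quantile(draws[i, ], c(0.025, 0.975)))
  })
  names(out) <- names(metric_fns)
  out
}

#' @rdname perSiteMetrics
#' @export
setGeneric("perSiteMetrics", function(result, sites = NULL)
  standardGeneric("perSiteMetrics"))

#' Per-site metric table from shared averaged predictions
#'
#' Recomputes the task metrics for each site's participants from the same
#' averaged out-of-fold predictions; the combined row equals the
#' whole-cohort metrics. Sites with fewer than 3 evaluable participants (or
#' a single outcome class, for classification) are skipped with a warning.
#'
#' @param result a \linkS4class{CVResult}.
#' @param sites site labels aligned with the result's participants; omitted
#'   if the predictions already carry a \code{site} column.
#' @return data.frame with one row per site plus a "combined" row.
#' @export
setMethod("perSiteMetrics", "CVResult", function(result, sites = NULL) {
  p <- result@predictions
  if (!is.null(sites)) p$site <- as.character(sites)
  if (is.null(p$site)) stop("no site labels available")
  p <- p[!is.na(p$predicted), ]
  rows <- lapply(c(sort(unique(p$site)), "combined"), function(s) {
    sub <- if (s == "combined") p else p[p$site == s, ]
    if (nrow(sub) < 3) {
      warning("site ", s, " has fewer than 3 participants; skipped")
      return(NULL)
    }
    if (result@task == "classification" && length(unique(sub$observed)) < 2) {
      warning("site ", s, " has a single outcome class; skipped")
      return(NULL)
    }
    m <- computeTaskMetrics(sub$predicted, sub$observed, result@task,
                            ci_reps = 0, seed = 0)
    if (result@task == "classification") {
      data.frame(site = s, n = nrow(sub), auroc = m$auroc, auprc = m$auprc,
                 lift = m$lift, stringsAsFactors = FALSE)
    } else {
      data.frame(site = s, n = nrow(sub), r = m$r, p = m$p, rmse = m$rmse,
                 mae = m$mae, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
})

#' Site-specific versus integrated-model comparison
#'
#' For each site, runs the repeated-CV harness on that site's participants
#' alone and compares the site-specific performance with the integrated
#' model's performance evaluated on the same site (from a single harness run
#' over all participants). The reported delta = integrated - site-specific,
#' positive when pooled training helps the site.
#'
#' @param features participants-by-features matrix or
#'   \linkS4class{OmicsMatrix}.
#' @param target outcome vector aligned with participants.
#' @param cfg a \code{\link{harnessConfig}}.
#' @param sites site labels aligned with participants (at least two sites).
#' @return data.frame: site, n, site_specific, integrated, delta (metric is
#'   Pearson r for regression, AUROC for classification).
#' @export
siteTransferComparison <- function(features, target, cfg, sites) {
  if (is(features, "OmicsMatrix")) features <- featureMatrix(features)
  sites <- as.character(sites)
  lv <- sort(unique(sites))
  if (length(lv) < 2) stop("site transfer comparison needs at least 2 sites")
  integrated <- repeatedCV(features, target, cfg, sites = sites)
  int_tab <- integrated@per_site
  metric <- if (cfg$task == "classification") "auroc" else "r"
  rows <- lapply(lv, function(s) {
    idx <- sites == s
    site_res <- repeatedCV(features[idx, , drop = FALSE], target[idx], cfg)
    int_val <- int_tab[[metric]][int_tab$site == s]
    if (length(int_val) == 0) int_val <- NA_real_
    data.frame(site = s, n = sum(idx),
               site_specific = cvMetrics(site_res)[[metric]],
               integrated = int_val,
               delta = int_val - cvMetrics(site_res)[[metric]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Evaluate model performance in resampled cohorts with a target prevalence
#'
#' Repeatedly samples cohorts at a target outcome prevalence from the
#' evaluated participants: the full control complement is kept fixed and the
#' number of cases achieving the target rate is drawn without replacement
#' (ties broken by the seeded RNG). Task metrics are recomputed per draw
#' from the same averaged predictions, estimating how the model would score
#' in a population with a realistic prevalence.
#'
#' @param result a \linkS4class{CVResult}.
#' @param labels named logical case indicator for the evaluated participants
#'   (for classification results, defaults to the observed outcome).
#' @param target_prevalence desired case fraction of the sampled cohorts.
#' @param n_draws number of sampled cohorts.
#' @param seed RNG seed.
#' @return data.frame of per-draw metrics.
#' @export
prevalenceMatchedEval <- function(result, labels = NULL, target_prevalence,
                                  n_draws = 100L, seed = 1L) {
  p <- result@predictions[!is.na(result@predictions$predicted), ]
  if (is.null(labels)) {
    if (result@task != "classification") {
      stop("labels must be supplied for regression results")
    }
    labels <- stats::setNames(p$observed == 1, p$participant_id)
  }
  lab <- as.logical(labels[p$participant_id])
  stopifnot(!anyNA(lab))
  n_ctrl <- sum(!lab)
  n_case_needed <- round(n_ctrl * target_prevalence / (1 - target_prevalence))
  if (n_case_needed < 1 || n_case_needed > sum(lab)) {
    stop("target prevalence ", target_prevalence,
         " not achievable with ", sum(lab), " cases and ", n_ctrl, " controls")
  }
  set.seed(seed)
  case_idx <- which(lab)
  rows <- lapply(seq_len(n_draws), function(dr) {
    keep <- c(which(!lab), sample(case_idx, n_case_needed))
    sub <- p[keep, ]
    sublab <- lab[keep]
    if (result@task == "classification") {
      a <- auroc(sub$predicted, sublab); pr <- auprc(sub$predicted, sublab)
      data.frame(draw = dr, n = length(keep), prevalence = mean(sublab),
                 auroc = a, auprc = pr, lift = lift(pr, mean(sublab)))
    } else {
      m <- regressionMetrics(sub$predicted, sub$observed)
      data.frame(draw = dr, n = length(keep), prevalence = mean(sublab),
                 r = m$r, rmse = m$rmse, mae = m$mae)
    }
  })
  do.call(rbind, rows)
}
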