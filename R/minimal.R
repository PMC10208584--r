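#' Configuration of stability-based minimal-model selection
#'
#' @param train_fraction fraction of participants in the single selection
#'   split (default 0.7; the remainder is the untouched test set).
#' @param n_iter subsampling iterations (default 100).
#' @param top_k features tallied per iteration by importance (default 10).
#' @param n_final size of the minimal panel (default 3).
#' @param subsample_fraction fraction of the training split refit per
#'   iteration, drawn without replacement (default 0.8).
#' @param replace draw iteration subsamples with replacement (default FALSE).
#' @param n_null permutation-null iterations used to calibrate the
#'   stability flag (default equal to \code{n_iter}; 0 disables the flag).
#' @param seed RNG seed.
#' @export
stabilityConfig <- function(train_fraction = 0.7, n_iter = 100L, top_k = 10L,
                            n_final = 3L, subsample_fraction = 0.8,
                            replace = FALSE, n_null = n_iter, seed = 1L) {
  stopifnot(n_final <= top_k, train_fraction > 0, train_fraction <= 1,
            subsample_fraction > 0, subsample_fraction <= 1, n_null >= 0)
  list(train_fraction = train_fraction, n_iter = as.integer(n_iter),
       top_k = as.integer(top_k), n_final = as.integer(n_final),
       subsample_fraction = subsample_fraction, replace = replace,
       n_null = as.integer(n_null), seed = as.integer(seed))
}

#' Stability-based minimal-panel selection
#'
#' Participants are split once into a training split (70\% by default, used
#' for all selection work) and a test split that is never touched before the
#' final evaluation. In each of \code{n_iter} iterations a seeded subsample
#' of the training split is drawn, a gradient-boosted tree model is fitted on
#' the full feature set, and the \code{top_k} features by total-gain
#' importance are tallied. The \code{n_final} most frequently selected
#' features (ties broken by frequency, then lexicographic feature id) form
#' the minimal panel, which is then (a) evaluated by repeated cross-validation
#' within the training split and (b) fitted once on the whole training split
#' and scored once on the held-out test split.
#'
#' The stability flag is calibrated by a permutation null: the same
#' subsampling schedule is re-run with the target permuted, which preserves
#' the tally concentration that tree models produce on overlapping
#' subsamples even without signal. The selection is called stable when the
#' panel-sized (n_final-th highest) real tally significantly exceeds its
#' null counterpart (one-sided Fisher test at the 1\% level); all-noise
#' inputs are flagged unstable with a warning.
#'
#' @param features participants-by-features matrix or
#'   \linkS4class{OmicsMatrix}.
#' @param target numeric outcome aligned with participants.
#' @param cfg a \code{\link{stabilityConfig}}.
#' @param harness_cfg \code{\link{harnessConfig}} for the cross-validated
#'   training-split evaluation of the minimal panel.
#' @return a \linkS4class{MinimalModelResult}.
#' @export
stabilitySelect <- function(features, target, cfg = stabilityConfig(),
                            harness_cfg = harnessConfig("regression",
                                                        seed = cfg$seed)) {
  if (is(features, "OmicsMatrix")) features <- featureMatrix(features)
  features <- as.matrix(features)
  n <- nrow(features)
  ids <- rownames(features)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  y <- as.numeric(target)
  stopifnot(length(y) == n)

  set.seed(cfg$seed)
  train <- sort(sample(n, round(n * cfg$train_fraction)))
  test <- setdiff(seq_len(n), train)
  if (length(train) < 30) stop("need at least 30 participants in the training split")

  boost_cfg <- harness_cfg
  boost_cfg$task <- "regression"
  runTally <- function(n_runs, target, seed_offset) {
    tally <- integer(ncol(features))
    names(tally) <- colnames(features)
    m_sub <- max(2L, round(length(train) * cfg$subsample_fraction))
    for (it in seq_len(n_runs)) {
      set.seed(cfg$seed + seed_offset + it)
      idx <- train[sample(length(train), m_sub, replace = cfg$replace)]
      fit <- fitBoost(features[idx, , drop = FALSE], target[idx], NULL,
                      boost_cfg)
      imp <- xgboost::xgb.importance(model = fit$model)
      top <- utils::head(imp$Feature[order(-imp$Gain)], cfg$top_k)
      tally[top] <- tally[top] + 1L
      rm(fit); if (it %% 20L == 0L) gc(verbose = FALSE)
    }
    tally
  }
  tally <- runTally(cfg$n_iter, y, 0L)

  freq <- data.frame(feature_id = names(tally), freq = as.integer(tally),
                     stringsAsFactors = FALSE)
  freq <- freq[order(-freq$freq, freq$feature_id), ]
  rownames(freq) <- NULL
  if (sum(freq$freq > 0) < cfg$n_final) {
    stop("fewer than ", cfg$n_final, " features were ever selected")
  }
  selected <- freq$feature_id[seq_len(cfg$n_final)]

  ## permutation-calibrated stability flag: the null run keeps the
  ## subsample-overlap tally concentration but carries no signal
  stable <- NA
  if (cfg$n_null > 0 && cfg$top_k < ncol(features)) {
    set.seed(cfg$seed - 1L)
    y_perm <- y[sample(n)]
    null_tally <- runTally(cfg$n_null, y_perm, 10000L)
    ## compare the n_final-th highest tallies: a single spurious feature can
    ## stay persistently favoured under a fixed permutation, but a whole
    ## panel of them is what instability actually looks like
    f1 <- sort(freq$freq, decreasing = TRUE)[cfg$n_final]
    f0 <- sort(null_tally, decreasing = TRUE)[cfg$n_final]
    cmp <- stats::fisher.test(
      matrix(c(f1, cfg$n_iter - f1, f0, cfg$n_null - f0), nrow = 2),
      alternative = "greater"
    )
    stable <- cmp$p.value < 0.01
    if (!stable) {
      warning("no selection stability: rank-", cfg$n_final, " frequency ",
              f1, "/", cfg$n_iter, " does not exceed the permutation-null ",
              f0, "/", cfg$n_null)
    }
  }

  ## cross-validated evaluation within the training split
  cv <- repeatedCV(features[train, selected, drop = FALSE], y[train],
                   harness_cfg)

  ## single final fit on the full training split, scored once on the test split
  fit <- fitBoost(features[train, selected, drop = FALSE], y[train],
                  features[test, selected, drop = FALSE], boost_cfg)
  test_metrics <- regressionMetrics(fit$pred, y[test])

  new("MinimalModelResult",
    frequency = freq, selected = selected,
    train_metrics = c(cvMetrics(cv), list(stable = stable)),
    test_metrics = test_metrics,
    split = list(train = ids[train], test = ids[test])
  )
}
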