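#' Construct a CohortTable
#'
#' @param data data.frame with the required identifier/site/GA/PTB columns and
#'   one column per covariate.
#' @param covariates data.frame declaring each covariate's \code{type}
#'   (binary/ordinal/continuous) and clinical \code{category}.
#' @return A validated \linkS4class{CohortTable}.
#' @export
CohortTable <- function(data, covariates) {
  data <- as.data.frame(data)
  covariates <- as.data.frame(covariates)
  data$participant_id <- as.character(data$participant_id)
  data$site <- as.character(data$site)
  new("CohortTable", data = data, covariates = covariates)
}

#' Construct an OmicsMatrix from a participants-by-features matrix
#'
#' @param values numeric matrix, participants as rows (rownames = participant
#'   ids), features as columns (colnames = feature ids). Stored internally
#'   features-by-participants, the SummarizedExperiment convention.
#' @param omic either a single omic label recycled across features or a
#'   vector with one label per feature.
#' @return A validated \linkS4class{OmicsMatrix}.
#' @export
OmicsMatrix <- function(values, omic) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values needs participant rownames and feature colnames")
  }
  omic <- rep(omic, length.out = ncol(values))
  se <- SummarizedExperiment(
    assays = list(exprs = t(values)),
    rowData = DataFrame(feature_id = colnames(values), omic = omic,
                        row.names = colnames(values))
  )
  new("OmicsMatrix", se)
}

#' @rdname participantIds
#' @export
setGeneric("participantIds", function(x) standardGeneric("participantIds"))

#' Participant identifiers
#'
#' @param x a \linkS4class{CohortTable} or \linkS4class{OmicsMatrix}.
#' @return character vector of participant ids.
#' @export
setMethod("participantIds", "CohortTable", function(x) x@data$participant_id)

#' @rdname participantIds
#' @export
setMethod("participantIds", "OmicsMatrix", function(x) colnames(x))

#' @rdname featureIds
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' Feature identifiers of an omics matrix
#' @param x an \linkS4class{OmicsMatrix}.
#' @export
setMethod("featureIds", "OmicsMatrix", function(x) rowData(x)$feature_id)

#' @rdname omicOf
#' @export
setGeneric("omicOf", function(x) standardGeneric("omicOf"))

#' Per-feature omic labels
#' @param x an \linkS4class{OmicsMatrix}.
#' @return character vector, one of proteome/metabolome/lipidome per feature.
#' @export
setMethod("omicOf", "OmicsMatrix", function(x) as.character(rowData(x)$omic))

#' @rdname featureMatrix
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' Participants-by-features value matrix
#'
#' The transpose of the stored assay, i.e. the orientation model fitting and
#' file IO use (participants as rows).
#' @param x an \linkS4class{OmicsMatrix}.
#' @export
setMethod("featureMatrix", "OmicsMatrix", function(x) t(assay(x, "exprs")))

#' @rdname cohortData
#' @export
setGeneric("cohortData", function(x) standardGeneric("cohortData"))

#' Cohort data and covariate declarations
#' @param x a \linkS4class{CohortTable}.
#' @return \code{cohortData}: the full per-participant data.frame;
#'   \code{covariateInfo}: the covariate declaration table.
#' @export
setMethod("cohortData", "CohortTable", function(x) x@data)

#' @rdname cohortData
#' @export
setGeneric("covariateInfo", function(x) standardGeneric("covariateInfo"))

#' @rdname cohortData
#' @export
setMethod("covariateInfo", "CohortTable", function(x) x@covariates)

#' @rdname ptbStatus
#' @export
setGeneric("ptbStatus", function(x) standardGeneric("ptbStatus"))

#' Preterm-birth indicator per participant
#' @param x a \linkS4class{CohortTable}.
#' @export
setMethod("ptbStatus", "CohortTable", function(x) {
  stats::setNames(x@data$ptb, x@data$participant_id)
})

setMethod("show", "CohortTable", function(object) {
  d <- object@data
  cat("CohortTable:", nrow(d), "participants,",
      nrow(object@covariates), "covariates,",
      length(unique(d$site)), "sites\n")
  cat(sprintf("  PTB: %d (%.1f%%); GA at sampling median %.1f wk\n",
              sum(d$ptb), 100 * mean(d$ptb),
              stats::median(d$ga_sampling_weeks, na.rm = TRUE)))
})

setMethod("show", "OmicsMatrix", function(object) {
  tab <- table(omicOf(object))
  cat("OmicsMatrix:", nrow(object), "features x", ncol(object),
      "participants\n  ")
  cat(paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  nmiss <- sum(is.na(assay(object)))
  if (nmiss > 0) cat("  missing cells:", nmiss, "\n")
})

setMethod("show", "CorrelationSet", function(object) {
  p <- object@pairs
  nsig <- sum(p$significant, na.rm = TRUE)
  cat("CorrelationSet:", nrow(p), "feature pairs,",
      object@n_participants, "participants\n")
  cat(sprintf("  |rho| threshold %.4f (alpha %.3g over %s tests); %d significant (%.2f%%)\n",
              object@rho_threshold, object@alpha,
              format(object@n_tests, big.mark = ","), nsig,
              100 * nsig / nrow(p)))
})

setMethod("show", "CVResult", function(object) {
  cat("CVResult (", object@task, "): ", nrow(object@predictions),
      " participants, ", nrow(object@train_membership), " repetitions\n",
      sep = "")
  m <- object@metrics
  if (object@task == "classification") {
    cat(sprintf("  AUROC %.3f [%.3f, %.3f]; AUPRC %.3f [%.3f, %.3f]; Lift %.2f\n",
                m$auroc, m$auroc_ci[1], m$auroc_ci[2],
                m$auprc, m$auprc_ci[1], m$auprc_ci[2], m$lift))
  } else {
    cat(sprintf("  Pearson r %.3f [%.3f, %.3f] (p %.3g); RMSE %.2f; MAE %.2f\n",
                m$r, m$r_ci[1], m$r_ci[2], m$p, m$rmse, m$mae))
  }
})

setMethod("show", "MinimalModelResult", function(object) {
  cat("MinimalModelResult: selected", paste(object@selected, collapse = ", "), "\n")
  cat(sprintf("  train r %.3f; held-out test r %.3f\n",
              object@train_metrics$r, object@test_metrics$r))
})

setMethod("show", "ClockResult", function(object) {
  d <- object@discrepancies
  cat("ClockResult:", nrow(d), "participants\n")
  cat(sprintf("  median discrepancy PTB %.2f wk vs term %.2f wk (rank-sum p %.3g)\n",
              stats::median(d$discrepancy[d$ptb]),
              stats::median(d$discrepancy[!d$ptb]), object@test$p))
})

setMethod("show", "CovariateNetwork", function(object) {
  cat("CovariateNetwork:", nrow(object@nodes), "covariates,",
      nrow(object@edges), "edges (",
      sum(object@edges$mst_flag), "MST )\n")
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", nrow(object@signals), "planted signal features over",
      length(unique(object@signals$target)), "targets; clock shift",
      object@clock_shift_weeks, "wk\n")
})

#' @rdname truthSignals
#' @export
setGeneric("truthSignals", function(x) standardGeneric("truthSignals"))

#' Planted-signal ledger accessors
#' @param x a \linkS4class{SyntheticTruth}.
#' @return \code{truthSignals}: data.frame of planted features;
#'   \code{minimalPanel}: the 3 designated panel feature ids.
#' @export
setMethod("truthSignals", "SyntheticTruth", function(x) x@signals)

#' @rdname truthSignals
#' @export
setGeneric("minimalPanel", function(x) standardGeneric("minimalPanel"))

#' @rdname truthSignals
#' @export
setMethod("minimalPanel", "SyntheticTruth", function(x) x@minimal_panel)

#' @rdname correlationPairs
#' @export
setGeneric("correlationPairs", function(x) standardGeneric("correlationPairs"))

#' Per-pair correlation table
#' @param x a \linkS4class{CorrelationSet}.
#' @export
setMethod("correlationPairs", "CorrelationSet", function(x) x@pairs)

#' @rdname cvPredictions
#' @export
setGeneric("cvPredictions", function(x) standardGeneric("cvPredictions"))

#' Averaged out-of-fold predictions
#' @param x a \linkS4class{CVResult}.
#' @export
setMethod("cvPredictions", "CVResult", function(x) x@predictions)

#' @rdname cvMetrics
#' @export
setGeneric("cvMetrics", function(x) standardGeneric("cvMetrics"))

#' Cross-validated performance metrics
#' @param x a \linkS4class{CVResult}.
#' @export
setMethod("cvMetrics", "CVResult", function(x) x@metrics)
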