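#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

OMIC_LEVELS <- c("proteome", "metabolome", "lipidome")

CLINICAL_CATEGORIES <- c(
  "maternal anthropometry", "maternal bloodwork", "medical history",
  "obstetric history", "socioeconomic determinants", "ultrasound measurements"
)

COVARIATE_TYPES <- c("binary", "ordinal", "continuous")

#' CohortTable: participant covariates with clinical-category tags
#'
#' Holds one row per participant with identifier, study site, gestational age
#' (GA) at sampling and at birth in weeks, the preterm-birth (PTB) indicator,
#' and an arbitrary set of clinical covariates. Each covariate is declared in
#' the \code{covariates} slot with a measurement type
#' (binary/ordinal/continuous) and exactly one clinical category.
#'
#' Validity enforces: unique participant identifiers; \code{ptb} equivalent to
#' GA at birth < 37 weeks (the clinical definition of preterm birth); every
#' covariate column declared with a known type and category.
#'
#' @slot data data.frame with columns \code{participant_id}, \code{site},
#'   \code{ga_sampling_weeks}, \code{ga_birth_weeks}, \code{ptb}, plus one
#'   column per declared covariate.
#' @slot covariates data.frame with columns \code{covariate}, \code{type},
#'   \code{category} describing each covariate column.
#' @exportClass CohortTable
setClass("CohortTable",
  representation(data = "data.frame", covariates = "data.frame")
)

setValidity("CohortTable", function(object) {
  d <- object@data
  cv <- object@covariates
  req <- c("participant_id", "site", "ga_sampling_weeks", "ga_birth_weeks", "ptb")
  msgs <- character()
  miss <- setdiff(req, names(d))
  if (length(miss)) {
    return(paste("missing required columns:", paste(miss, collapse = ", ")))
  }
  dup <- d$participant_id[duplicated(d$participant_id)]
  if (length(dup)) {
    msgs <- c(msgs, paste("duplicate participant_id:", paste(unique(dup), collapse = ", ")))
  }
  if (!is.logical(d$ptb)) msgs <- c(msgs, "ptb must be logical")
  bad <- which(d$ptb != (d$ga_birth_weeks < 37))
  if (length(bad)) {
    msgs <- c(msgs, paste0(
      "ptb flag inconsistent with ga_birth_weeks < 37 at rows: ",
      paste(utils::head(bad, 5L), collapse = ", ")
    ))
  }
  if (any(d$ga_sampling_weeks <= 0, na.rm = TRUE) ||
      any(d$ga_birth_weeks <= 0, na.rm = TRUE)) {
    msgs <- c(msgs, "gestational ages must be positive")
  }
  if (!all(c("covariate", "type", "category") %in% names(cv))) {
    msgs <- c(msgs, "covariates slot needs columns covariate, type, category")
  } else {
    if (anyDuplicated(cv$covariate)) {
      msgs <- c(msgs, "each covariate must be declared exactly once")
    }
    if (!all(cv$type %in% COVARIATE_TYPES)) {
      msgs <- c(msgs, paste("covariate type outside",
                            paste(COVARIATE_TYPES, collapse = "/")))
    }
    if (!all(cv$category %in% CLINICAL_CATEGORIES)) {
      msgs <- c(msgs, paste(
        "unknown clinical category:",
        paste(setdiff(cv$category, CLINICAL_CATEGORIES), collapse = ", ")
      ))
    }
    absent <- setdiff(cv$covariate, names(d))
    if (length(absent)) {
      msgs <- c(msgs, paste("declared covariates absent from data:",
                            paste(absent, collapse = ", ")))
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' OmicsMatrix: a tagged participants-by-features measurement block
#'
#' A \linkS4class{SummarizedExperiment} with features as rows and participants
#' as columns. \code{rowData} carries \code{feature_id} and \code{omic}
#' (proteome, metabolome or lipidome). Missing values are allowed before
#' imputation. Feature identifiers must be unique (also across omics, which
#' \code{\link{combineOmics}} enforces when concatenating).
#'
#' @exportClass OmicsMatrix
setClass("OmicsMatrix", contains = "SummarizedExperiment")

setValidity("OmicsMatrix", function(object) {
  msgs <- character()
  rd <- rowData(object)
  if (!all(c("feature_id", "omic") %in% colnames(rd))) {
    return("rowData must contain feature_id and omic")
  }
  if (!all(rd$omic %in% OMIC_LEVELS)) {
    msgs <- c(msgs, paste(
      "omic label outside {proteome, metabolome, lipidome}:",
      paste(unique(setdiff(rd$omic, OMIC_LEVELS)), collapse = ", ")
    ))
  }
  if (anyDuplicated(rd$feature_id)) msgs <- c(msgs, "feature_id not unique")
  if (is.null(colnames(object))) msgs <- c(msgs, "participant ids (colnames) required")
  if (!is.numeric(assay(object))) msgs <- c(msgs, "assay must be numeric")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' SyntheticTruth: ledger of planted structure in a synthetic cohort
#'
#' Records everything the generator planted so downstream recovery can be
#' scored: per-target signal features with their latent loadings, the
#' designated minimal-panel features, the forward clock shift applied to the
#' PTB group's gestational-age features, and per-participant latent values.
#'
#' @slot signals data.frame: target, feature_id, omic, loading.
#' @slot minimal_panel character vector of 3 feature ids.
#' @slot clock_shift_weeks numeric scalar.
#' @slot participants data.frame of per-participant latent targets/outcome.
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
  representation(
    signals = "data.frame",
    minimal_panel = "character",
    clock_shift_weeks = "numeric",
    participants = "data.frame"
  )
)

#' GeneratorConfig: all knobs of the synthetic cohort generator
#'
#' See \code{\link{generatorConfig}} for field semantics and defaults.
#'
#' @exportClass GeneratorConfig
setClass("GeneratorConfig",
  representation(
    seed = "integer",
    n_full = "integer",
    n_sub = "integer",
    sites = "character",
    omic_sizes = "integer",
    ptb_prevalence_target = "numeric",
    clock_shift_weeks = "numeric",
    signal_spec = "list",
    minimal_panel = "character",
    missing_rate = "numeric",
    risk_scale = "numeric",
    block_spec = "list",
    interomic_coupling = "list"
  )
)

setValidity("GeneratorConfig", function(object) {
  msgs <- character()
  if (object@ptb_prevalence_target <= 0 || object@ptb_prevalence_target >= 1) {
    msgs <- c(msgs, "ptb_prevalence_target must be in (0,1)")
  }
  if (object@missing_rate < 0 || object@missing_rate >= 1) {
    msgs <- c(msgs, "missing_rate must be in [0,1)")
  }
  if (object@clock_shift_weeks < 0) msgs <- c(msgs, "clock_shift_weeks must be >= 0")
  if (!identical(sort(names(object@omic_sizes)), sort(OMIC_LEVELS))) {
    msgs <- c(msgs, "omic_sizes must be named proteome/metabolome/lipidome")
  }
  if (length(object@minimal_panel) != 3L) {
    msgs <- c(msgs, "minimal_panel must name 3 features")
  }
  for (tgt in names(object@signal_spec)) {
    sp <- object@signal_spec[[tgt]]
    if (!all(c("omic", "index", "weight") %in% names(sp))) {
      msgs <- c(msgs, paste0("signal_spec[", tgt, "] needs omic/index/weight"))
      next
    }
    over <- sp$index > object@omic_sizes[sp$omic]
    if (any(over)) {
      msgs <- c(msgs, paste0(
        "signal_spec[", tgt, "]: feature index exceeds omic size for ",
        paste(sp$omic[over], collapse = ", ")
      ))
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' CorrelationSet: all-pairs Spearman results with significance classification
#'
#' Stores one row per unordered feature pair: Spearman rho, raw and
#' Bonferroni-adjusted two-sided p (t approximation on n-2 degrees of
#' freedom), intra-/inter-omic class, the omic-pair label, and the strength
#' bin (none / weak / moderate / strong). Pairs involving a constant feature
#' carry \code{NA} rho and are excluded from significance counts.
#'
#' @slot pairs data.frame of per-pair statistics.
#' @slot n_participants number of participants correlations were computed on.
#' @slot n_tests number of unordered pairs (the Bonferroni family).
#' @slot alpha family-wise significance level.
#' @slot rho_threshold the analytic |rho| significance threshold.
#' @slot omic_sizes named integer vector of feature counts per omic.
#' @exportClass CorrelationSet
setClass("CorrelationSet",
  representation(
    pairs = "data.frame",
    n_participants = "integer",
    n_tests = "numeric",
    alpha = "numeric",
    rho_threshold = "numeric",
    omic_sizes = "integer"
  )
)

#' CVResult: repeated cross-validation predictions and metrics
#'
#' Per participant the averaged out-of-fold prediction (mean over the
#' repetitions in which the participant fell in the test half) plus the count
#' of test appearances; overall metrics with bootstrap confidence intervals;
#' a per-site metric table; and the train-membership ledger (reps x
#' participants logical matrix) supporting the structural no-leakage check.
#'
#' @exportClass CVResult
setClass("CVResult",
  representation(
    task = "character",
    predictions = "data.frame",
    metrics = "list",
    per_site = "data.frame",
    train_membership = "matrix",
    config = "list"
  )
)

#' MinimalModelResult: stability-selection output
#'
#' @slot frequency data.frame: feature_id, freq (times in the per-iteration
#'   top-k importance list).
#' @slot selected character vector of the chosen panel features.
#' @slot train_metrics cross-validated metrics on the 70\% training split.
#' @slot test_metrics single-shot metrics on the untouched 30\% test split.
#' @slot split list with train/test participant ids.
#' @exportClass MinimalModelResult
setClass("MinimalModelResult",
  representation(
    frequency = "data.frame",
    selected = "character",
    train_metrics = "list",
    test_metrics = "list",
    split = "list"
  )
)

#' ClockResult: gestational-clock discrepancy analysis
#'
#' @slot discrepancies data.frame: participant_id, predicted GA, ultrasound
#'   GA, discrepancy (predicted - ultrasound, weeks), ptb.
#' @slot test list: rank-sum statistic and p comparing PTB vs term
#'   discrepancies.
#' @slot cv the underlying \linkS4class{CVResult}.
#' @exportClass ClockResult
setClass("ClockResult",
  representation(
    discrepancies = "data.frame",
    test = "list",
    cv = "CVResult"
  )
)

#' CovariateNetwork: MST-reduced covariate correlation network
#'
#' @slot nodes data.frame: covariate, category, assoc_score, predictability_score.
#' @slot edges data.frame: from, to, rho, weight, mst_flag, significant_flag.
#' @slot layout matrix of 2-D coordinates, one row per node.
#' @slot graph the underlying igraph object.
#' @exportClass CovariateNetwork
setClass("CovariateNetwork",
  representation(
    nodes = "data.frame",
    edges = "data.frame",
    layout = "matrix",
    graph = "ANY"
  )
)
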