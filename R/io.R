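#' Write and read a cohort table
#'
#' The cohort is stored as two delimited UTF-8 text files: the per-participant
#' CSV (one header row, \code{participant_id} key, empty cell = missing) and a
#' covariate-declaration CSV (\code{covariate}, \code{type},
#' \code{category}).
#'
#' @param cohort a \linkS4class{CohortTable}.
#' @param path path of the participant CSV.
#' @param meta_path path of the covariate-declaration CSV.
#' @return \code{readCohort} returns a validated \linkS4class{CohortTable};
#'   violations are rejected with the offending row/column named.
#' @export
writeCohort <- function(cohort, path, meta_path) {
  utils::write.csv(cohortData(cohort), path, row.names = FALSE, na = "")
  utils::write.csv(covariateInfo(cohort), meta_path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path, meta_path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = "", check.names = FALSE)
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  if (!"ptb" %in% names(d)) stop("cohort file lacks a ptb column")
  d$ptb <- as.logical(d$ptb)
  CohortTable(d, meta)
}

#' Write and read an omics matrix
#'
#' The matrix is stored as TSV with participants as rows (first column
#' \code{participant_id}) and a feature-metadata sidecar TSV
#' (\code{feature_id}, \code{omic}). Empty cells are missing values.
#'
#' @param m an \linkS4class{OmicsMatrix}.
#' @param matrix_path path of the value TSV.
#' @param metadata_path path of the feature-metadata TSV.
#' @param cohort optional \linkS4class{CohortTable}; when supplied,
#'   \code{readOmics} rejects matrices containing participants absent from
#'   the cohort, naming the offending ids.
#' @return \code{readOmics} returns a validated \linkS4class{OmicsMatrix}.
#' @export
writeOmics <- function(m, matrix_path, metadata_path) {
  vals <- featureMatrix(m)
  out <- data.frame(participant_id = rownames(vals), vals,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, matrix_path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  utils::write.table(
    data.frame(feature_id = featureIds(m), omic = omicOf(m)),
    metadata_path, sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(matrix_path)
}

#' @rdname writeOmics
#' @export
readOmics <- function(matrix_path, metadata_path, cohort = NULL) {
  d <- utils::read.delim(matrix_path, stringsAsFactors = FALSE,
                         na.strings = "", check.names = FALSE)
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  if (names(d)[1] != "participant_id") {
    stop("first column of the omics matrix must be participant_id")
  }
  ids <- as.character(d$participant_id)
  if (anyDuplicated(ids)) {
    stop("duplicate participant ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  vals <- as.matrix(d[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- colnames(vals)[!apply(vals, 2, function(x) {
      all(is.na(x) | !is.na(suppressWarnings(as.numeric(x))))
    })]
    stop("non-numeric cells in feature column(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  rownames(vals) <- ids
  if (!identical(colnames(vals), as.character(meta$feature_id))) {
    stop("feature metadata does not match matrix columns")
  }
  if (!is.null(cohort)) {
    extra <- setdiff(ids, participantIds(cohort))
    if (length(extra)) {
      stop("participants absent from cohort: ",
           paste(extra, collapse = ", "))
    }
  }
  OmicsMatrix(vals, as.character(meta$omic))
}

#' Write and read the synthetic-truth ledger
#'
#' Lossless JSON round-trip of the planted-structure ledger.
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param path JSON file path.
#' @export
writeTruth <- function(truth, path) {
  jsonlite::write_json(
    list(
      signals = truth@signals,
      minimal_panel = truth@minimal_panel,
      clock_shift_weeks = truth@clock_shift_weeks,
      participants = truth@participants
    ),
    path, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("SyntheticTruth",
    signals = as.data.frame(x$signals),
    minimal_panel = as.character(x$minimal_panel),
    clock_shift_weeks = as.numeric(x$clock_shift_weeks),
    participants = as.data.frame(x$participants)
  )
}

#' @rdname meanImpute
#' @export
setGeneric("meanImpute", function(m) standardGeneric("meanImpute"))

#' Mean imputation of missing omics values
#'
#' Replaces every missing cell by the arithmetic mean of the feature's
#' observed values; observed cells are untouched, so per-feature observed
#' means are preserved exactly. A feature with no observed value is an error.
#'
#' @param m an \linkS4class{OmicsMatrix}.
#' @return the imputed \linkS4class{OmicsMatrix}.
#' @export
setMethod("meanImpute", "OmicsMatrix", function(m) {
  a <- assay(m, "exprs") # features x participants
  allmiss <- rowSums(!is.na(a)) == 0L
  if (any(allmiss)) {
    stop("feature(s) with no observed value: ",
         paste(featureIds(m)[allmiss], collapse = ", "))
  }
  idx <- which(is.na(a), arr.ind = TRUE)
  if (nrow(idx)) {
    a[idx] <- rowMeans(a, na.rm = TRUE)[idx[, 1]]
    SummarizedExperiment::assay(m, "exprs") <- a
  }
  m
})

#' Column-concatenate omics matrices over a shared participant set
#'
#' Inputs must cover identical participant sets; features keep their omic
#' tags and the feature count of the result is the sum of the inputs'.
#' Feature order follows the declared input order (by convention proteome,
#' metabolome, lipidome).
#'
#' @param ... \linkS4class{OmicsMatrix} objects, or a single list of them.
#' @return the combined \linkS4class{OmicsMatrix}.
#' @export
combineOmics <- function(...) {
  mats <- list(...)
  if (length(mats) == 1L && is.list(mats[[1]]) && !is(mats[[1]], "OmicsMatrix")) {
    mats <- mats[[1]]
  }
  stopifnot(length(mats) >= 1L, all(vapply(mats, is, logical(1), "OmicsMatrix")))
  if (length(mats) == 1L) return(mats[[1]])
  ref <- participantIds(mats[[1]])
  for (i in seq_along(mats)[-1]) {
    ids <- participantIds(mats[[i]])
    if (!setequal(ids, ref)) {
      stop("participant sets differ; symmetric difference: ",
           paste(c(setdiff(ref, ids), setdiff(ids, ref)), collapse = ", "))
    }
  }
  vals <- do.call(cbind, lapply(mats, function(m) featureMatrix(m)[ref, , drop = FALSE]))
  omic <- unlist(lapply(mats, omicOf))
  if (anyDuplicated(colnames(vals))) {
    stop("feature ids collide across inputs: ",
         paste(unique(colnames(vals)[duplicated(colnames(vals))]), collapse = ", "))
  }
  OmicsMatrix(vals, omic)
}
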