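#' Construct a SurvivalDataset
#'
#' @param features numeric matrix, patients in rows and features in columns
#'   (the transpose of the internal assay layout). \code{NA} entries are
#'   allowed before imputation. A zero-column matrix is accepted when all
#'   features are still categorical.
#' @param times numeric vector of non-negative survival / follow-up times.
#' @param events event indicators, 1 = event observed, 0 = right-censored.
#' @param patientIds unique patient identifiers; defaults to the rownames of
#'   \code{features} or \code{P1..Pn}.
#' @param featureKinds optional per-feature tag, one of \code{"numeric"},
#'   \code{"binary-expanded"}, \code{"clinical-binary"}.
#' @param categorical optional data.frame of unexpanded categorical columns
#'   (patients in rows), stored in the metadata until
#'   \code{\link{expandCategorical}}.
#' @return a \linkS4class{SurvivalDataset}.
#' @examples
#' x <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("f1", "f2")))
#' ds <- SurvivalDataset(x, times = rexp(10), events = rbinom(10, 1, 0.5))
#' ds
#' @export
SurvivalDataset <- function(features, times, events, patientIds = NULL,
                            featureKinds = NULL, categorical = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (is.null(patientIds)) {
    patientIds <- rownames(features) %||% paste0("P", seq_len(n))
  }
  patientIds <- as.character(patientIds)
  if (length(times) != n || length(events) != n || length(patientIds) != n)
    stop2("features, times, events and patientIds must agree in length")
  if (is.null(featureKinds)) featureKinds <- rep("numeric", ncol(features))
  if (!all(featureKinds %in% c("numeric", "binary-expanded", "clinical-binary")))
    stop2("unknown feature kind")
  storage.mode(features) <- "double"
  rownames(features) <- NULL
  se <- SummarizedExperiment(
    assays = list(features = t(features)),
    rowData = DataFrame(kind = featureKinds, row.names = colnames(features)),
    colData = DataFrame(time = as.numeric(times), event = as.numeric(events),
                        row.names = patientIds))
  if (!is.null(categorical) && ncol(as.data.frame(categorical)) > 0) {
    categorical <- as.data.frame(categorical, stringsAsFactors = FALSE)
    rownames(categorical) <- patientIds
    metadata(se)$categorical <- categorical
  }
  ds <- new("SurvivalDataset", se)
  validObject(ds)
  ds
}

#' Accessors for SurvivalDataset
#'
#' \code{featureMatrix} returns the numeric feature matrix with patients in
#' rows (transposing the internal assay); \code{survTimes} and
#' \code{survEvents} return the outcome vectors; \code{patientIds} and
#' \code{featureKinds} the identifiers and per-feature kind tags.
#'
#' @param x a \linkS4class{SurvivalDataset}.
#' @return \code{featureMatrix}: patients x features numeric matrix; the
#'   others: vectors of length n (patients) or N (features).
#' @name featureMatrix
#' @aliases featureMatrix,SurvivalDataset-method
NULL

#' @rdname featureMatrix
#' @export
setMethod("featureMatrix", "SurvivalDataset", function(x) {
  m <- t(assay(x, "features"))
  rownames(m) <- colnames(x)
  m
})

#' @rdname featureMatrix
#' @export
setMethod("survTimes", "SurvivalDataset", function(x) {
  stats::setNames(colData(x)$time, colnames(x))
})

#' @rdname featureMatrix
#' @export
setMethod("survEvents", "SurvivalDataset", function(x) {
  stats::setNames(colData(x)$event, colnames(x))
})

#' @rdname featureMatrix
#' @export
setMethod("patientIds", "SurvivalDataset", function(x) colnames(x))

#' @rdname featureMatrix
#' @export
setMethod("featureKinds", "SurvivalDataset", function(x) {
  stats::setNames(as.character(rowData(x)$kind), rownames(x))
})

setMethod("show", "SurvivalDataset", function(object) {
  ev <- colData(object)$event
  cat("SurvivalDataset:", ncol(object), "patients x", nrow(object),
      "features\n")
  cat(sprintf("  events: %d observed, %d censored (%.1f%% censored)\n",
              sum(ev == 1), sum(ev == 0), 100 * mean(ev == 0)))
  ncat <- ncol(metadata(object)$categorical %||% data.frame())
  if (ncat > 0)
    cat("  unexpanded categorical columns:", ncat, "\n")
  if (anyNA(assay(object, "features")))
    cat(sprintf("  missing feature cells: %d\n",
                sum(is.na(assay(object, "features")))))
  invisible(NULL)
})

## internal: rebuild a SurvivalDataset from a patients x features matrix,
## reusing outcomes and carrying selected metadata forward
.replaceFeatures <- function(ds, newX, kinds, keepCategorical = TRUE) {
  out <- SurvivalDataset(newX, survTimes(ds), survEvents(ds), patientIds(ds),
                         featureKinds = kinds,
                         categorical = if (keepCategorical)
                           metadata(ds)$categorical else NULL)
  keep <- setdiff(names(metadata(ds)), "categorical")
  for (nm in keep) metadata(out)[[nm]] <- metadata(ds)[[nm]]
  out
}
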