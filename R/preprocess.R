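#' Expand categorical columns to binary indicators
#'
#' Each categorical column with k distinct observed levels is replaced by k
#' 0/1 indicator columns named \code{<column>=<level>} (levels in sorted
#' order), tagged \code{"binary-expanded"}. A column with a single observed
#' level carries no information and is dropped with a warning. A missing
#' categorical value propagates \code{NA} to all of its indicators so that
#' downstream imputation can fill them.
#'
#' @param ds a \linkS4class{SurvivalDataset} with categorical columns flagged
#'   at load time (see \code{\link{readSurvivalTable}}).
#' @return a \linkS4class{SurvivalDataset} with no pending categorical
#'   columns.
#' @export
expandCategorical <- function(ds) {
  cats <- metadata(ds)$categorical
  if (is.null(cats) || ncol(cats) == 0) return(ds)
  blocks <- list()
  kinds <- character()
  for (nm in names(cats)) {
    v <- as.character(cats[[nm]])
    levs <- sort(unique(v[!is.na(v)]))
    if (length(levs) < 2) {
      warning("categorical column '", nm,
              "' has a single observed level and was dropped")
      next
    }
    ind <- vapply(levs, function(l) as.numeric(v == l),
                  numeric(length(v)))
    colnames(ind) <- paste0(nm, "=", levs)
    blocks[[nm]] <- ind
    kinds <- c(kinds, rep("binary-expanded", length(levs)))
  }
  newX <- cbind(featureMatrix(ds), do.call(cbind, blocks))
  out <- .replaceFeatures(ds, newX, c(featureKinds(ds), kinds),
                          keepCategorical = FALSE)
  out
}

#' Mean-impute designated columns
#'
#' Replaces missing entries in the named feature columns by the column mean
#' over observed entries. For a binary column (e.g. radiation treatment
#' status) this is the observed prevalence, so the imputed value reflects
#' the prior likelihood of the positive class.
#'
#' @param ds a \linkS4class{SurvivalDataset}.
#' @param cols character vector of feature names to impute.
#' @return the dataset with those columns complete.
#' @export
imputeMean <- function(ds, cols) {
  X <- featureMatrix(ds)
  miss <- setdiff(cols, colnames(X))
  if (length(miss)) stop2("unknown feature(s): ", paste(miss, collapse = ", "))
  for (nm in cols) {
    v <- X[, nm]
    if (all(is.na(v))) stop2("feature '", nm, "' is entirely missing")
    v[is.na(v)] <- mean(v, na.rm = TRUE)
    X[, nm] <- v
  }
  .replaceFeatures(ds, X, featureKinds(ds))
}

#' 1-nearest-neighbour imputation with a missingness cutoff
#'
#' Features missing in at least \code{maxMissingFrac} of patients are
#' discarded (the boundary itself is dropped: only features with a strictly
#' smaller missing fraction are imputed). Each remaining missing cell is
#' filled with that feature's value in the single nearest patient, where
#' distance is the Euclidean distance over the features observed in both
#' patients and candidates are restricted to patients with the feature
#' observed. Ties and a missing candidate pool fall back deterministically
#' (lowest patient index; column mean, with a message).
#'
#' @param ds a \linkS4class{SurvivalDataset}.
#' @param maxMissingFrac drop threshold on the per-feature missing fraction
#'   (default 0.20).
#' @return a dataset whose retained features have no missing values.
#' @export
imputeKNN <- function(ds, maxMissingFrac = 0.20) {
  X <- featureMatrix(ds)
  if (ncol(X) == 0) return(ds)
  frac <- colMeans(is.na(X))
  if (!any(frac == 0))
    stop2("1-NN imputation needs at least one fully observed feature")
  drop <- frac >= maxMissingFrac
  if (any(drop)) {
    warning("dropping ", sum(drop), " feature(s) with >= ",
            format(100 * maxMissingFrac), "% missing: ",
            paste(colnames(X)[drop], collapse = ", "))
    X <- X[, !drop, drop = FALSE]
  }
  kinds <- featureKinds(ds)[colnames(X)]
  n <- nrow(X)
  for (f in which(colSums(is.na(X)) > 0)) {
    holes <- which(is.na(X[, f]))
    donors <- which(!is.na(X[, f]))
    for (i in holes) {
      obs_i <- !is.na(X[i, ])
      d <- vapply(donors, function(j) {
        shared <- obs_i & !is.na(X[j, ])
        shared[f] <- FALSE
        if (!any(shared)) return(Inf)
        sqrt(sum((X[i, shared] - X[j, shared])^2))
      }, numeric(1))
      if (!length(donors) || all(!is.finite(d))) {
        message("no usable neighbour for patient ", i, ", feature '",
                colnames(X)[f], "'; falling back to the column mean")
        X[i, f] <- mean(X[donors, f])
      } else {
        X[i, f] <- X[donors[which.min(d)], f]
      }
    }
  }
  .replaceFeatures(ds, X, kinds)
}

#' Standardize features to zero mean, unit variance
#'
#' Centers and scales every feature using the population standard deviation
#' (divisor n). Zero-variance features are dropped with a warning. The
#' per-feature center/scale record is stored in
#' \code{metadata(ds)$standardization} so that validation or test patients
#' can be transformed with training statistics via
#' \code{\link{applyStandardization}}. By default the statistics are
#' computed on the full dataset before splitting; compute them on the
#' training rows and reuse them if strict train-only preprocessing is
#' wanted.
#'
#' @param ds a \linkS4class{SurvivalDataset} with no missing feature values.
#' @return the standardized dataset; retrieve the record with
#'   \code{standardizationRecord}.
#' @export
standardizeFeatures <- function(ds) {
  X <- featureMatrix(ds)
  if (anyNA(X)) stop2("impute missing values before standardizing")
  n <- nrow(X)
  ctr <- colMeans(X)
  sc <- sqrt(colMeans(sweep(X, 2, ctr)^2))
  keep <- sc > 0
  if (!all(keep))
    warning("dropping ", sum(!keep), " zero-variance feature(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, ctr[keep]), 2, sc[keep], "/")
  out <- .replaceFeatures(ds, Xs, featureKinds(ds)[keep])
  metadata(out)$standardization <- list(center = ctr[keep], scale = sc[keep])
  out
}

#' @rdname standardizeFeatures
#' @export
standardizationRecord <- function(ds) metadata(ds)$standardization

#' Apply a stored standardization to new data
#'
#' @param ds a \linkS4class{SurvivalDataset} containing (at least) the
#'   features named in the record.
#' @param record a list with \code{center} and \code{scale}, as produced by
#'   \code{\link{standardizeFeatures}}.
#' @rdname standardizeFeatures
#' @export
applyStandardization <- function(ds, record) {
  X <- featureMatrix(ds)
  nm <- names(record$center)
  miss <- setdiff(nm, colnames(X))
  if (length(miss))
    stop2("features missing from dataset: ", paste(miss, collapse = ", "))
  Xs <- sweep(sweep(X[, nm, drop = FALSE], 2, record$center), 2,
              record$scale, "/")
  out <- .replaceFeatures(ds, Xs, featureKinds(ds)[nm])
  metadata(out)$standardization <- record
  out
}

#' Split patients into training, validation and test sets
#'
#' Draws a uniformly random permutation (deterministic for a fixed seed) and
#' assigns the first round(0.6 n) patients to training, the next
#' round(0.2 n) to validation, and the remainder to testing.
#'
#' @param ds a \linkS4class{SurvivalDataset} with at least 5 patients.
#' @param seed integer seed.
#' @return a \linkS4class{SplitAssignment}.
#' @export
splitTrainValTest <- function(ds, seed) {
  n <- if (is(ds, "SurvivalDataset")) ncol(ds) else as.integer(ds)
  if (n < 5) stop2("need at least 5 patients to form a 60/20/20 split")
  perm <- withSeed(seed, sample.int(n))
  ntr <- round(0.6 * n)
  nva <- round(0.2 * n)
  new("SplitAssignment",
      train = sort(perm[seq_len(ntr)]),
      val = sort(perm[ntr + seq_len(nva)]),
      test = sort(perm[(ntr + nva + 1):n]),
      seed = as.integer(seed), n = as.integer(n))
}

setMethod("show", "SplitAssignment", function(object) {
  cat(sprintf("SplitAssignment (seed %d): %d train / %d val / %d test\n",
              object@seed, length(object@train), length(object@val),
              length(object@test)))
  invisible(NULL)
})

#' Default feature-name aliases for multi-cohort merging
#'
#' Cohorts record tumour stage under different clinical variables;
#' pathologic and clinical stage are unified as a single \code{stage}
#' feature before intersecting feature names.
#'
#' @return named character vector mapping original to unified names.
#' @export
stageAliases <- function() {
  c(pathologic_stage = "stage", clinical_stage = "stage")
}

#' Merge cohorts on their shared features
#'
#' Row-concatenates two or more datasets restricted to the intersection of
#' their feature names, after applying an optional alias map (see
#' \code{\link{stageAliases}}). Each patient's cohort of origin is kept as a
#' provenance column (\code{colData(x)$origin}) outside the feature matrix.
#' No re-normalization is applied to the merged features.
#'
#' @param dsList list of two or more \linkS4class{SurvivalDataset}s,
#'   optionally named (names become the origin labels).
#' @param aliases named character vector renaming features before the
#'   intersection, e.g. \code{stageAliases()}.
#' @return the merged \linkS4class{SurvivalDataset}.
#' @export
mergeDatasets <- function(dsList, aliases = NULL) {
  if (length(dsList) < 2) stop2("need at least two datasets to merge")
  labels <- names(dsList) %||% paste0("dataset", seq_along(dsList))
  labels[labels == ""] <- paste0("dataset", which(labels == ""))
  Xs <- lapply(dsList, function(d) {
    if (!is.null(metadata(d)$categorical))
      stop2("expand categorical columns before merging")
    X <- featureMatrix(d)
    if (!is.null(aliases)) {
      hit <- colnames(X) %in% names(aliases)
      colnames(X)[hit] <- aliases[colnames(X)[hit]]
      if (anyDuplicated(colnames(X)))
        stop2("alias map creates duplicate feature names")
    }
    X
  })
  shared <- Reduce(intersect, lapply(Xs, colnames))
  if (length(shared) == 0) stop2("datasets share no features")
  ids <- unlist(lapply(dsList, patientIds))
  if (anyDuplicated(ids))
    stop2("duplicate patient ids across datasets: ",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  X <- do.call(rbind, lapply(Xs, function(m) m[, shared, drop = FALSE]))
  ## aliasing may have renamed features; key kinds by the post-alias names
  k1 <- stats::setNames(featureKinds(dsList[[1]]), colnames(Xs[[1]]))
  out <- SurvivalDataset(X,
                         unlist(lapply(dsList, survTimes)),
                         unlist(lapply(dsList, survEvents)),
                         ids, featureKinds = unname(k1[shared]))
  colData(out)$origin <- rep(labels, vapply(dsList, ncol, integer(1)))
  out
}
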