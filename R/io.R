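## Accepted encodings for the event-indicator column. Anything outside this
## table is a validation error.
.EVENT_MAP <- c("0" = 0, "1" = 1, "true" = 1, "false" = 0,
                "dead" = 1, "alive" = 0)

.parseEvents <- function(x) {
  if (is.logical(x)) return(as.numeric(x))
  if (is.numeric(x)) {
    if (anyNA(x) || !all(x %in% c(0, 1)))
      stop2("event column must contain only 0/1 (or TRUE/FALSE, dead/alive); ",
            "found: ", paste(unique(x[!x %in% c(0, 1)]), collapse = ", "))
    return(as.numeric(x))
  }
  key <- tolower(trimws(as.character(x)))
  bad <- unique(key[!key %in% names(.EVENT_MAP)])
  if (length(bad))
    stop2("unrecognized event values: ", paste(bad, collapse = ", "),
          " (accepted: 0/1, TRUE/FALSE, dead/alive)")
  unname(.EVENT_MAP[key])
}

#' Read a delimited survival table
#'
#' Reads a header-ed TSV (default) or CSV feature table with one row per
#' patient. All columns other than the time, event and optional id columns
#' become features: numeric columns enter the feature matrix directly, while
#' non-numeric (categorical) columns are flagged for later one-hot expansion
#' by \code{\link{expandCategorical}}. Empty cells, \code{NA} and \code{NaN}
#' are read as missing.
#'
#' Event indicators may be coded 0/1, TRUE/FALSE or dead/alive
#' (case-insensitive); any other coding is rejected, as are negative times.
#'
#' @param path file to read.
#' @param timeCol,eventCol,idCol column names; \code{idCol = NULL} generates
#'   \code{P1..Pn}.
#' @param delimiter field separator, \code{"\t"} (default) or \code{","}.
#' @return a \linkS4class{SurvivalDataset}.
#' @seealso \code{\link{writeSurvivalTable}}
#' @export
readSurvivalTable <- function(path, timeCol = "time", eventCol = "event",
                              idCol = NULL, delimiter = "\t") {
  if (!file.exists(path)) stop2("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          na.strings = c("", "NA", "NaN"),
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "\"", comment.char = "")
  need <- c(timeCol, eventCol, idCol)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop2("missing required column(s): ", paste(miss, collapse = ", "))
  times <- suppressWarnings(as.numeric(df[[timeCol]]))
  if (anyNA(times)) stop2("time column contains missing or non-numeric values")
  if (any(times < 0)) stop2("negative survival times are not allowed")
  events <- .parseEvents(df[[eventCol]])
  ids <- if (is.null(idCol)) paste0("P", seq_len(nrow(df)))
         else as.character(df[[idCol]])
  feat <- df[setdiff(names(df), need)]
  isNum <- vapply(feat, function(v) is.numeric(v) || is.logical(v) ||
                    all(is.na(v)), logical(1))
  num <- feat[isNum]
  X <- if (ncol(num)) {
    m <- do.call(cbind, lapply(num, as.numeric))
    colnames(m) <- names(num)
    m
  } else matrix(numeric(0), nrow(df), 0)
  SurvivalDataset(X, times, events, ids,
                  categorical = if (any(!isNum)) feat[!isNum] else NULL)
}

#' Write a SurvivalDataset as a delimited table
#'
#' Inverse of \code{\link{readSurvivalTable}}: writes id, time and event
#' columns followed by the numeric features and any unexpanded categorical
#' columns. Missing values are written as \code{NA}.
#'
#' @param ds a \linkS4class{SurvivalDataset}.
#' @param path output file.
#' @param delimiter field separator.
#' @export
writeSurvivalTable <- function(ds, path, delimiter = "\t") {
  df <- data.frame(id = patientIds(ds), time = survTimes(ds),
                   event = survEvents(ds), check.names = FALSE,
                   stringsAsFactors = FALSE)
  X <- featureMatrix(ds)
  if (ncol(X)) df <- cbind(df, as.data.frame(X, check.names = FALSE))
  cats <- metadata(ds)$categorical
  if (!is.null(cats)) df <- cbind(df, cats)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Serialize a split assignment
#'
#' Writes a two-column tab-separated table mapping patient id to its split
#' (\code{train}, \code{val} or \code{test}).
#'
#' @param split a \linkS4class{SplitAssignment}.
#' @param ds the \linkS4class{SurvivalDataset} the split indexes into.
#' @param path output file.
#' @export
writeSplitAssignment <- function(split, ds, path) {
  lab <- character(split@n)
  lab[split@train] <- "train"
  lab[split@val] <- "val"
  lab[split@test] <- "test"
  utils::write.table(data.frame(id = patientIds(ds), split = lab),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
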