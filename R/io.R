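# Plain-text serialization: responses and labels as CSV, truth and
# configurations as JSON.

#' Write a response matrix (and labels) to CSV
#'
#' Responses go to one CSV with a `person_id` column followed by one column
#' per indicator (missing responses as empty cells); feature labels go to a
#' second CSV (`person_id`, `feature1`..`feature4`).
#'
#' @param x A `response_matrix`.
#' @param dir Output directory (created if needed).
#' @param responses,labels File names within `dir`.
#' @return Invisibly, the paths written.
#' @export
write_response_matrix <- function(x, dir, responses = "responses.csv",
                                  labels = "labels.csv") {
  stopifnot(inherits(x, "response_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rpath <- file.path(dir, responses)
  df <- data.frame(person_id = x$person_ids, x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, rpath, row.names = FALSE, na = "")
  paths <- rpath
  if (!is.null(x$feature_labels)) {
    lpath <- file.path(dir, labels)
    ldf <- data.frame(person_id = x$person_ids, x$feature_labels,
                      check.names = FALSE, stringsAsFactors = FALSE)
    write.csv(ldf, lpath, row.names = FALSE)
    paths <- c(paths, lpath)
  }
  invisible(paths)
}

#' Read a response matrix (and labels) from CSV
#'
#' @param responses Path to the responses CSV (`person_id` + indicator
#'   columns, empty cells for missing).
#' @param labels Optional path to the labels CSV.
#' @return A `response_matrix`.
#' @export
read_response_matrix <- function(responses, labels = NULL) {
  df <- read.csv(responses, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot("person_id" %in% names(df))
  y <- as.matrix(df[, setdiff(names(df), "person_id"), drop = FALSE])
  storage.mode(y) <- "integer"
  rownames(y) <- df$person_id
  fl <- NULL
  if (!is.null(labels)) {
    ldf <- read.csv(labels, check.names = FALSE, stringsAsFactors = FALSE)
    stopifnot(identical(ldf$person_id, df$person_id))
    fl <- as.matrix(ldf[, setdiff(names(ldf), "person_id"), drop = FALSE])
  }
  new_response_matrix(y, feature_labels = fl)
}

#' Serialize a synthetic truth to JSON
#' @param truth A `synthetic_truth`.
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  out <- truth
  out$factor_correlations <- unname(out$factor_correlations)
  class(out) <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' Read a synthetic truth from JSON
#' @param path Path written by [write_truth()].
#' @return A `synthetic_truth`.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$items <- as.data.frame(x$items, stringsAsFactors = FALSE)
  x$dims <- as.data.frame(x$dims, stringsAsFactors = FALSE)
  S <- as.matrix(x$factor_correlations)
  dimnames(S) <- list(x$dims$dimension, x$dims$dimension)
  x$factor_correlations <- S
  if (!is.null(x$dependency_pairs)) {
    x$dependency_pairs <- as.data.frame(x$dependency_pairs,
                                        stringsAsFactors = FALSE)
  }
  structure(x, class = "synthetic_truth")
}

#' Write fitted item parameters
#'
#' CSV (`indicator_id`, `a`, `b`) for a `.csv` path; JSON with link and
#' convergence metadata otherwise.
#'
#' @param params An `irt_2pl` fit.
#' @param path Output path ending in `.csv` or `.json`.
#' @export
write_item_params <- function(params, path) {
  stopifnot(inherits(params, "irt_2pl"))
  tab <- params$coefficients
  if (grepl("\\.csv$", path)) {
    write.csv(data.frame(indicator_id = tab$indicator, a = tab$a, b = tab$b),
              path, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(link = params$link, D = params$D,
           convergence = params$convergence,
           items = data.frame(indicator_id = tab$indicator,
                              a = tab$a, b = tab$b)),
      path, auto_unbox = TRUE, digits = NA, dataframe = "columns",
      pretty = TRUE)
  }
  invisible(path)
}

#' Read item parameters written by [write_item_params()]
#' @param path `.csv` or `.json` path.
#' @param D Scaling constant assumed for CSV input (default 1.7).
#' @return A parameter table usable by [test_information()],
#'   [eap_scores()] and the selection functions.
#' @export
read_item_params <- function(path, D = 1.7) {
  if (grepl("\\.csv$", path)) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    out <- data.frame(indicator = df$indicator_id, a = df$a, b = df$b,
                      D = D, stringsAsFactors = FALSE)
  } else {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    out <- data.frame(indicator = x$items$indicator_id,
                      a = x$items$a, b = x$items$b, D = x$D,
                      stringsAsFactors = FALSE)
  }
  out
}

#' Indicator-set configuration
#'
#' The indicator configuration maps each analytic indicator to a CAM
#' feature (1-4) and a collection mode, with a forced-retention flag
#' honoured by the screening stage and an optional source-item reference.
#' `read_indicator_config()`/`write_indicator_config()` use a JSON array of
#' objects with fields `indicator_id`, `feature`, `mode`, `forced_retain`,
#' `source_item`.
#'
#' @param path JSON path.
#' @return A data frame with those columns.
#' @export
read_indicator_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  df <- as.data.frame(x, stringsAsFactors = FALSE)
  stopifnot(all(c("indicator_id", "feature", "mode") %in% names(df)))
  if (is.null(df$forced_retain)) df$forced_retain <- FALSE
  if (is.null(df$source_item)) df$source_item <- df$indicator_id
  df$feature <- as.integer(df$feature)
  df
}

#' @rdname read_indicator_config
#' @param config Indicator configuration data frame.
#' @export
write_indicator_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Derive an indicator configuration from a synthetic truth
#'
#' @param truth A `synthetic_truth`.
#' @param forced_retain Indicator ids to flag for forced retention.
#' @return An indicator configuration data frame.
#' @export
indicator_config_from_truth <- function(truth, forced_retain = character()) {
  stopifnot(inherits(truth, "synthetic_truth"))
  data.frame(indicator_id = truth$items$indicator,
             feature = truth$items$feature,
             mode = truth$items$mode,
             forced_retain = truth$items$indicator %in% forced_retain,
             source_item = truth$items$indicator,
             stringsAsFactors = FALSE)
}
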