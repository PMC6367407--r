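# Plain-text interchange: CSV/TSV matrices with a sample_id column, and the
# dose-grid-as-header convention for response matrices.

read_delim_auto <- function(path) {
  first <- readLines(path, n = 1)
  delim <- if (grepl("\t", first)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

#' Read a feature matrix
#'
#' Expects a CSV or TSV file with a header row of feature names and a first
#' column of sample identifiers. All remaining cells must be numeric.
#'
#' @param path file path.
#' @return tibble with `sample_id` and numeric feature columns.
#' @export
read_feature_matrix <- function(path) {
  df <- read_delim_auto(path)
  names(df)[1] <- "sample_id"
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) abort("duplicate sample ids")
  for (j in seq(2, ncol(df))) {
    v <- df[[j]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) | is.na(v))[1]
      abort(sprintf("non-numeric at row %d, col %d", bad, j))
    }
    if (anyNA(v)) {
      abort(sprintf("non-numeric at row %d, col %d", which(is.na(v))[1], j))
    }
  }
  tibble::as_tibble(df)
}

#' Read a response matrix with a dose-grid header
#'
#' The header row after the sample-id column holds the dose values in uM
#' and must parse as strictly increasing positive numbers.
#'
#' @param path file path.
#' @param features optional feature tibble (from [read_feature_matrix()]);
#'   when given, the responses are inner-joined to its samples in its row
#'   order, with a warning for samples dropped on either side.
#' @return list with `responses` (wide tibble), `doses` (a [dose_grid()]).
#' @export
read_response_matrix <- function(path, features = NULL) {
  df <- read_delim_auto(path)
  names(df)[1] <- "sample_id"
  df$sample_id <- as.character(df$sample_id)
  doses <- suppressWarnings(as.numeric(names(df)[-1]))
  if (anyNA(doses)) abort("response header must contain numeric dose values")
  doses <- tryCatch(dose_grid(doses),
                    error = function(e) abort(paste("bad dose header:",
                                                    conditionMessage(e))))
  if (!is.null(features)) {
    keep <- intersect(features$sample_id, df$sample_id)
    n_drop <- (nrow(features) - length(keep)) + (nrow(df) - length(keep))
    if (n_drop > 0) {
      warn(sprintf("sample mismatch at join: %d sample(s) dropped, %d kept",
                   n_drop, length(keep)))
    }
    df <- df[match(keep, df$sample_id), , drop = FALSE]
  }
  list(responses = tibble::as_tibble(df), doses = doses)
}

#' Write predictions to CSV
#'
#' Curve predictions (long tibbles from [predict_curve()]) are written as
#' `sample_id, dose, predicted, sd`; metric predictions as
#' `sample_id, metric, value, not_reached` with an empty value cell and a
#' raised flag for metrics not reached in-span. A write-then-read round
#' trip reproduces the numeric values exactly.
#'
#' @param predictions a prediction tibble.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  if (all(c("dose", ".pred") %in% names(predictions))) {
    out <- tibble::tibble(sample_id = predictions$sample_id,
                          dose = predictions$dose,
                          predicted = predictions$.pred,
                          sd = predictions$.pred_sd %||% NA_real_)
  } else if (".pred" %in% names(predictions)) {
    out <- tibble::tibble(sample_id = predictions$sample_id,
                          metric = ".pred", value = predictions$.pred,
                          not_reached = FALSE)
  } else {
    long <- tidyr::pivot_longer(predictions, -"sample_id",
                                names_to = "metric", values_to = "value")
    out <- dplyr::mutate(long, not_reached = is.na(.data$value))
  }
  readr::write_csv(out, path)
  invisible(path)
}
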