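# Input coercion shared across the package: tibble-first interfaces with a
# sample_id column are converted to plain matrices internally.

# Feature table -> list(x = numeric matrix, ids = character)
as_feature_matrix <- function(x, arg = "x") {
  if (is.matrix(x)) {
    ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
    storage.mode(x) <- "double"
    return(list(x = unname(x), ids = ids, features = colnames(x) %||%
                  paste0("f", seq_len(ncol(x)))))
  }
  if (!is.data.frame(x)) abort(sprintf("`%s` must be a data frame or matrix", arg))
  x <- as.data.frame(x)
  id_col <- which(names(x) == "sample_id")
  if (length(id_col) == 0 && !is.numeric(x[[1]])) id_col <- 1L
  if (length(id_col) > 0) {
    ids <- as.character(x[[id_col[1]]])
    x <- x[, -id_col[1], drop = FALSE]
  } else {
    ids <- as.character(seq_len(nrow(x)))
  }
  bad <- !vapply(x, is.numeric, logical(1))
  if (any(bad)) {
    abort(sprintf("non-numeric feature column(s): %s",
                  paste(names(x)[bad], collapse = ", ")))
  }
  list(x = as.matrix(x), ids = ids, features = names(x))
}

# Response table (wide: sample_id + one column per dose) -> list(y, doses, ids)
as_response_matrix <- function(y, doses = NULL, arg = "y") {
  if (is.numeric(y) && is.null(dim(y))) y <- matrix(y, ncol = 1)
  if (is.matrix(y)) {
    ids <- rownames(y) %||% as.character(seq_len(nrow(y)))
    if (is.null(doses)) doses <- suppressWarnings(as.numeric(colnames(y)))
    storage.mode(y) <- "double"
    y <- unname(y)
  } else if (is.data.frame(y)) {
    y <- as.data.frame(y)
    id_col <- which(names(y) == "sample_id")
    if (length(id_col) == 0 && !is.numeric(y[[1]])) id_col <- 1L
    if (length(id_col) > 0) {
      ids <- as.character(y[[id_col[1]]])
      y <- y[, -id_col[1], drop = FALSE]
    } else {
      ids <- as.character(seq_len(nrow(y)))
    }
    if (is.null(doses)) doses <- suppressWarnings(as.numeric(names(y)))
    y <- as.matrix(y)
  } else {
    abort(sprintf("`%s` must be a data frame, matrix or numeric vector", arg))
  }
  if (!is.null(doses) && length(doses) > 0 && !anyNA(doses)) {
    doses <- dose_grid(doses)
    if (length(doses) != ncol(y)) {
      abort("number of response columns does not match the dose grid")
    }
  } else {
    doses <- NULL
  }
  list(y = y, doses = doses, ids = ids)
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

new_seed <- function(seed, offset) {
  if (is.null(seed)) NULL else (seed + 7919L * offset) %% .Machine$integer.max
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) set.seed(seed)
  code
}
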