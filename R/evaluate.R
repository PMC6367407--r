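#' Normalized mean absolute error
#'
#' Mean absolute difference pooled over all entries, divided by the range
#' of the true responses. Translation- and scale-invariant.
#'
#' @param y_true,y_pred matrices or vectors of matching shape.
#' @return nonnegative scalar.
#' @export
nmae <- function(y_true, y_pred) {
  y_true <- as.matrix(y_true); y_pred <- as.matrix(y_pred)
  if (!all(dim(y_true) == dim(y_pred))) abort("shape mismatch")
  rng <- diff(range(y_true))
  if (rng <= 0) abort("zero range")
  mean(abs(y_true - y_pred)) / rng
}

make_folds <- function(n, k) {
  if (k < 2) abort("at least 2 folds are required")
  if (k > n) abort("more folds than samples")
  sample(rep_len(seq_len(k), n))
}

fit_predict <- function(model, xtr, ytr, doses, xte, trees, mtry, min_node,
                        cost = NULL, metric = "auc", sds = NULL) {
  if (model == "rf_per_dose") {
    out <- vapply(seq_len(ncol(ytr)), function(j) {
      fit <- frf(xtr, ytr[, j], mode = "rf", trees = trees, mtry = mtry,
                 min_node = min_node)
      predict_matrix(fit, xte)[, 1]
    }, numeric(nrow(xte)))
    return(matrix(out, nrow = nrow(xte)))
  }
  mode <- switch(model, frf = "frf", mrf = "mrf", frfl = "frfl",
                 abort(sprintf("unknown model '%s'", model)))
  fit <- frf(xtr, ytr, doses = doses, mode = mode, cost = cost,
             trees = trees, mtry = mtry, min_node = min_node,
             metric = metric, sds = sds)
  predict_matrix(fit, xte)
}

#' Seeded k-fold cross-validation of a forest model
#'
#' Shuffled sample-level k-fold split; the configured model is fitted on
#' the training folds and scored on the held-out fold. Out-of-fold
#' predictions are concatenated and summarized as pooled NMAE/MAE and
#' per-dose MAE and Pearson correlation.
#'
#' @param x feature table.
#' @param y wide response table / matrix.
#' @param doses dose grid (from response column names if `NULL`).
#' @param model `"frf"`, `"mrf"`, `"frfl"`, or `"rf_per_dose"` (one
#'   univariate forest per dose column, the dose-wise baseline).
#' @param folds number of folds (k >= 2).
#' @param seed integer seed controlling the fold split and every fit.
#' @param truth optional evaluation targets of the same shape as `y`
#'   (e.g. noiseless simulated curves); defaults to `y`.
#' @param trees,mtry,min_node forest hyperparameters.
#' @param cost node cost passed to [frf()].
#' @param metric leaf metric for `model = "frfl"`.
#' @param sds per-dose replicate SDs (divergence costs).
#' @return an `frf_cv` object: list with `nmae`, `mae`, `per_dose`
#'   (tibble of per-dose MAE and correlation), `predictions` (wide tibble
#'   of out-of-fold predictions), `folds` (tibble `sample_id`, `fold`).
#' @export
cross_validate <- function(x, y, doses = NULL, model = "frf", folds = 5L,
                           seed = NULL, truth = NULL, trees = 150L,
                           mtry = 10L, min_node = 10L, cost = NULL,
                           metric = "auc", sds = NULL) {
  fx <- as_feature_matrix(x)
  ry <- as_response_matrix(y, doses)
  al <- align_samples(fx, ry)
  fx <- al$fx; ry <- al$ry
  n <- nrow(fx$x)
  y_eval <- if (is.null(truth)) ry$y else {
    rt <- as_response_matrix(truth, doses)
    rt$y[match(fx$ids, rt$ids), , drop = FALSE]
  }
  if (!is.null(seed)) set.seed(seed)
  fold <- make_folds(n, folds)
  pred <- matrix(NA_real_, n, if (model == "frfl") 1 else ncol(ry$y))
  for (k in seq_len(folds)) {
    tr <- fold != k; te <- !tr
    pred[te, ] <- fit_predict(model, fx$x[tr, , drop = FALSE],
                              ry$y[tr, , drop = FALSE], ry$doses,
                              fx$x[te, , drop = FALSE], trees, mtry,
                              min_node, cost = cost, metric = metric,
                              sds = if (is.null(sds)) NULL else
                                sds[tr, , drop = FALSE])
  }
  if (model == "frfl") {
    y_eval <- matrix(frfl_metric(y_eval, ry$doses, metric), ncol = 1)
  }
  per_dose <- tibble::tibble(
    dose = as.numeric(ry$doses %||% seq_len(ncol(pred)))[seq_len(ncol(pred))],
    mae = colMeans(abs(y_eval - pred)),
    pearson = vapply(seq_len(ncol(pred)), function(j) {
      if (sd(y_eval[, j]) == 0 || sd(pred[, j]) == 0) NA_real_
      else stats::cor(y_eval[, j], pred[, j])
    }, numeric(1)))
  structure(list(
    nmae = nmae(y_eval, pred), mae = mean(abs(y_eval - pred)),
    per_dose = per_dose,
    predictions = dplyr::bind_cols(
      tibble::tibble(sample_id = fx$ids),
      tibble::as_tibble(as.data.frame(pred, col.names = colnames(pred)))),
    folds = tibble::tibble(sample_id = fx$ids, fold = fold),
    config = list(model = model, folds = folds, trees = trees, mtry = mtry,
                  min_node = min_node, seed = seed)),
    class = "frf_cv")
}

#' @export
print.frf_cv <- function(x, ...) {
  cat(sprintf("<%s %d-fold CV: NMAE %.4f, MAE %.4f>\n",
              x$config$model, x$config$folds, x$nmae, x$mae))
  invisible(x)
}

#' @export
glance.frf_cv <- function(x, ...) {
  tibble::tibble(model = x$config$model, folds = x$config$folds,
                 trees = x$config$trees, nmae = x$nmae, mae = x$mae)
}

#' Noise-level benchmark grid: functional forest vs dose-wise baseline
#'
#' For every combination of noise level, tree count, fold count and repeat,
#' simulates a fresh cohort ([simulate_drc_cohort()] defaults), trains the
#' functional random forest and the per-dose univariate forest baseline
#' under k-fold cross-validation on the noisy targets, and scores both
#' against the noiseless ground-truth curves. The baseline fits one forest
#' per dose column, since a univariate forest cannot predict a curve
#' directly.
#'
#' @param noise_levels additive noise fractions.
#' @param tree_counts forest sizes to sweep.
#' @param fold_counts CV fold counts to sweep.
#' @param repeats simulated cohorts per cell.
#' @param base_seed integer; every cohort and fit seed derives from it.
#' @param mtry,min_node forest hyperparameters.
#' @param ... passed to [simulate_drc_cohort()] (e.g. `n_doses`).
#' @return tibble (class `frf_benchmark`) with one row per cell x repeat x
#'   model: `noise_level`, `trees`, `folds`, `repeat_id`, `model`, `nmae`.
#' @export
run_noise_benchmark <- function(noise_levels = c(0, 0.05, 0.10, 0.20),
                                tree_counts = c(50L, 150L),
                                fold_counts = 5L, repeats = 5L,
                                base_seed = 1L, mtry = 10L, min_node = 10L,
                                ...) {
  rows <- list(); k <- 1
  for (r in seq_len(repeats)) {
    for (ni in seq_along(noise_levels)) {
      cohort_seed <- new_seed(base_seed, 131L * r + ni)
      cohort <- simulate_drc_cohort(noise_level = noise_levels[ni],
                                    seed = cohort_seed, ...)
      for (trees in tree_counts) {
        for (folds in fold_counts) {
          for (model in c("rf_per_dose", "frf")) {
            cv <- cross_validate(cohort$features, cohort$responses,
                                 model = model, folds = folds,
                                 seed = new_seed(base_seed,
                                                 10000L * r + 100L * ni +
                                                   trees + folds),
                                 truth = cohort$clean, trees = trees,
                                 mtry = mtry, min_node = min_node)
            rows[[k]] <- tibble::tibble(
              noise_level = noise_levels[ni], trees = trees, folds = folds,
              repeat_id = r, model = model, nmae = cv$nmae)
            k <- k + 1
          }
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("frf_benchmark", class(out))
  out
}

#' Summarize a benchmark grid
#'
#' Per noise level: the repeat-averaged NMAE of both models in each
#' (trees, folds) setting, and the relative improvement
#' `100 (NMAE_baseline - NMAE_functional) / NMAE_baseline` averaged over
#' the settings.
#'
#' @param grid output of [run_noise_benchmark()].
#' @return tibble with `noise_level`, `rf_nmae`, `frf_nmae`,
#'   `improvement_pct`.
#' @export
summarize_benchmark <- function(grid) {
  cell <- grid |>
    dplyr::group_by(.data$noise_level, .data$trees, .data$folds,
                    .data$model) |>
    dplyr::summarise(nmae = mean(.data$nmae), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "model", values_from = "nmae")
  cell |>
    dplyr::group_by(.data$noise_level) |>
    dplyr::summarise(
      rf_nmae = mean(.data$rf_per_dose),
      frf_nmae = mean(.data$frf),
      improvement_pct = mean(100 * (.data$rf_per_dose - .data$frf) /
                               .data$rf_per_dose),
      .groups = "drop")
}

#' Bootstrap model comparison
#'
#' Draws bootstrap resamples of the cohort, fits both configured models on
#' each resample, evaluates their MAE on the out-of-resample samples, and
#' returns the distribution of MAE differences (model A minus model B);
#' predominantly negative differences mean model A is the more accurate.
#'
#' @param x,y,doses cohort, as in [cross_validate()].
#' @param model_a,model_b model names, as in [cross_validate()].
#' @param n_boot bootstrap replicates.
#' @param trees,mtry,min_node forest hyperparameters (shared).
#' @param truth optional evaluation targets (defaults to `y`).
#' @param seed integer seed.
#' @return tibble (class `frf_boot`) with `replicate`, `mae_a`, `mae_b`,
#'   `diff`.
#' @export
bootstrap_compare <- function(x, y, doses = NULL, model_a = "frf",
                              model_b = "rf_per_dose", n_boot = 50L,
                              trees = 50L, mtry = 10L, min_node = 10L,
                              truth = NULL, seed = NULL) {
  if (n_boot < 2) abort("n_boot must be at least 2")
  fx <- as_feature_matrix(x)
  ry <- as_response_matrix(y, doses)
  al <- align_samples(fx, ry)
  fx <- al$fx; ry <- al$ry
  n <- nrow(fx$x)
  y_eval <- if (is.null(truth)) ry$y else {
    rt <- as_response_matrix(truth, doses)
    rt$y[match(fx$ids, rt$ids), , drop = FALSE]
  }
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), unique(idx))
      if (length(oob) > 0) break
      message("bootstrap replicate with empty out-of-resample set; redrawing")
    }
    xo <- fx$x[oob, , drop = FALSE]
    # both models consume an identical RNG stream within a replicate, so
    # the comparison is paired and identical configurations tie exactly
    rep_seed <- new_seed(seed %||% 0L, b)
    mae <- vapply(c(model_a, model_b), function(m) {
      set.seed(rep_seed)
      p <- fit_predict(m, fx$x[idx, , drop = FALSE],
                       ry$y[idx, , drop = FALSE], ry$doses, xo,
                       trees, mtry, min_node)
      mean(abs(y_eval[oob, , drop = FALSE] - p))
    }, numeric(1))
    mae <- unname(mae)
    set.seed(new_seed(rep_seed, 1L))
    rows[[b]] <- tibble::tibble(replicate = b, mae_a = mae[1], mae_b = mae[2],
                                diff = mae[1] - mae[2])
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("frf_boot", class(out))
  out
}
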