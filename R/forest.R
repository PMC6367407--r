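#' Fit a (functional) random forest
#'
#' Grows a bootstrap ensemble of regression trees over dose-response
#' targets. Four modes are available:
#'
#' * `"frf"` — functional random forest: node deviances are computed
#'   region-wise over the whole curve (or over per-dose response
#'   distributions for the divergence costs) and leaves store entire
#'   curves, so the model predicts a full dose-response profile.
#' * `"frfl"` — functional node costs, but leaves store a scalar summary
#'   metric of each training curve and the prediction is the conventional
#'   weighted average of that metric.
#' * `"mrf"` — multivariate random forest: Mahalanobis node deviance on the
#'   response vectors, curve-valued leaves.
#' * `"rf"` — univariate random forest on a scalar target (SSD cost).
#'
#' @param x feature table: a data frame with a `sample_id` column (or
#'   non-numeric first column) and numeric feature columns, or a matrix.
#' @param y targets: a wide response table / matrix (samples x doses) for
#'   the curve modes, or a numeric vector for `mode = "rf"`.
#' @param doses dose grid; taken from the response column names if `NULL`.
#' @param mode see above.
#' @param cost node cost: a [node_cost_spec()] or kind string; defaults to
#'   `"region_ssd"` for `frf`/`frfl`, `"mahalanobis"` for `mrf`, `"ssd"`
#'   for `rf`.
#' @param trees number of trees.
#' @param mtry features drawn (without replacement) at each node.
#' @param min_node a node with at most this many samples becomes a leaf.
#' @param max_depth depth limit (`Inf` = none).
#' @param bootstrap draw n-with-replacement bootstrap samples per tree
#'   (`TRUE`, default) or train every tree on the full data.
#' @param metric leaf summary metric for `mode = "frfl"` (`"auc"` or any
#'   column of [curve_summary()]).
#' @param sds optional per-dose replicate SDs (samples x doses), used by
#'   the divergence costs.
#' @param seed integer seed; the fit is fully reproducible from it.
#' @return an object of class `frf`.
#' @export
frf <- function(x, y, doses = NULL, mode = c("frf", "rf", "frfl", "mrf"),
                cost = NULL, trees = 150L, mtry = 10L, min_node = 10L,
                max_depth = Inf, bootstrap = TRUE, metric = "auc",
                sds = NULL, seed = NULL) {
  mode <- match.arg(mode)
  fx <- as_feature_matrix(x)
  if (mode == "rf" && is.numeric(y) && is.null(dim(y))) {
    if (length(y) != nrow(fx$x)) abort("x and y differ in sample count")
    ry <- list(y = matrix(y, ncol = 1), doses = NULL, ids = fx$ids)
  } else {
    ry <- as_response_matrix(y, doses)
  }
  al <- align_samples(fx, ry)
  fx <- al$fx; ry <- al$ry
  n <- nrow(fx$x); M <- ncol(fx$x)
  if (n < 2) abort("at least 2 samples are required")
  if (mode == "rf" && ncol(ry$y) != 1) {
    abort("mode 'rf' needs a scalar target; use mode 'frf' for curves")
  }
  if (mode %in% c("frf", "mrf", "frfl") && is.null(ry$doses) &&
      ncol(ry$y) > 1) {
    abort("curve modes need a dose grid (numeric response column names or `doses`)")
  }
  cost <- as_cost_spec(cost %||% switch(mode, rf = "ssd", mrf = "mahalanobis",
                                        "region_ssd"))
  if (mode == "rf" && !cost$kind %in% c("ssd", "region_ssd")) {
    abort("mode 'rf' uses the scalar SSD cost")
  }
  mtry <- as.integer(min(mtry, M))
  md <- if (is.finite(max_depth)) as.integer(max_depth) else -1L

  # leaf payload: curves (frf/mrf), the scalar target (rf), or a summary
  # metric of each training curve (frfl)
  ypay <- switch(mode,
    frf = , mrf = ry$y,
    rf = ry$y,
    frfl = {
      m <- frfl_metric(ry$y, ry$doses, metric)
      matrix(m, ncol = 1)
    })

  if (!is.null(seed)) set.seed(seed)
  boot <- if (bootstrap) {
    vapply(seq_len(trees), function(t) sample.int(n, n, replace = TRUE),
           integer(n))
  } else {
    matrix(rep(seq_len(n), trees), nrow = n)
  }

  plan <- prepare_cost(cost, ry$y, doses = ry$doses, sds = sds)
  picked <- integer(M); selected <- integer(M)
  if (plan$family == "ssd" && !isTRUE(plan$per_tree_cov)) {
    fr <- cpp_grow_forest(fx$x, plan$yt, ypay, boot, mtry,
                          as.integer(min_node), md)
    tree_list <- fr$trees
    picked <- fr$picked; selected <- fr$selected
  } else if (plan$family == "ssd") {
    # Mahalanobis with covariance re-estimated from each tree's bootstrap
    tree_list <- vector("list", trees)
    for (t in seq_len(trees)) {
      yb <- ry$y[boot[, t], , drop = FALSE]
      yt <- whiten(ry$y, stats::cov(yb), cost$ridge)
      fr <- cpp_grow_forest(fx$x, yt, ypay, boot[, t, drop = FALSE], mtry,
                            as.integer(min_node), md)
      tree_list[[t]] <- fr$trees[[1]]
      picked <- picked + fr$picked; selected <- selected + fr$selected
    }
  } else {
    # divergence costs: densities discretized per tree on a support grid
    # spanning that tree's pooled bootstrap responses
    sds_m <- plan$sds
    tree_list <- vector("list", trees)
    for (t in seq_len(trees)) {
      bt <- boot[, t]
      omega <- omega_grid(plan$means[bt, , drop = FALSE],
                          sds_m[bt, , drop = FALSE], cost$omega_points)
      dens <- density_array(plan$means[bt, , drop = FALSE],
                            sds_m[bt, , drop = FALSE], omega, cost$eps_sd)
      gt <- grow_tree_divergence(fx$x, ypay, dens, cost, mtry,
                                 as.integer(min_node), md, boot = bt)
      tree_list[[t]] <- gt$tree
      picked <- picked + gt$picked; selected <- selected + gt$selected
    }
  }

  structure(list(
    trees = tree_list, mode = mode, cost = cost,
    doses = ry$doses, feature_names = fx$features, sample_ids = fx$ids,
    y = ry$y, y_payload = ypay, boot = boot,
    params = list(trees = as.integer(trees), mtry = mtry,
                  min_node = as.integer(min_node), max_depth = max_depth,
                  bootstrap = bootstrap, metric = metric, seed = seed),
    vim_picked = as.integer(picked), vim_selected = as.integer(selected)),
    class = "frf")
}

frfl_metric <- function(y, doses, metric) {
  if (is.null(doses)) abort("mode 'frfl' needs a dose grid")
  if (metric == "auc") {
    vapply(seq_len(nrow(y)), function(i) curve_auc(doses, y[i, ]), numeric(1))
  } else {
    s <- summarize_curves(y, doses)
    v <- s[[metric]]
    if (anyNA(v)) abort(sprintf("metric '%s' not reached for some training curves", metric))
    v
  }
}

align_samples <- function(fx, ry) {
  if (identical(fx$ids, ry$ids)) return(list(fx = fx, ry = ry))
  common <- intersect(fx$ids, ry$ids)
  if (length(common) == 0) abort("no common sample_ids between x and y")
  dropped <- length(fx$ids) - length(common) + length(ry$ids) - length(common)
  if (dropped > 0) {
    warn(sprintf("dropping %d sample(s) absent from one of the inputs", dropped))
  }
  keep_x <- fx$ids %in% common
  fx$x <- fx$x[keep_x, , drop = FALSE]; fx$ids <- fx$ids[keep_x]
  m <- match(fx$ids, ry$ids)
  ry$y <- ry$y[m, , drop = FALSE]; ry$ids <- ry$ids[m]
  list(fx = fx, ry = ry)
}

new_data_matrix <- function(object, new_data) {
  fx <- as_feature_matrix(new_data, arg = "new_data")
  if (!is.null(colnames(fx$x)) || length(fx$features) > 0) {
    if (setequal(fx$features, object$feature_names) &&
        !identical(fx$features, object$feature_names)) {
      fx$x <- fx$x[, match(object$feature_names, fx$features), drop = FALSE]
      fx$features <- object$feature_names
    }
  }
  if (ncol(fx$x) != length(object$feature_names)) {
    abort("new_data does not match the training features")
  }
  fx
}

#' Predict from a fitted forest
#'
#' Curve modes predict dose-wise: at each dose the forest-weighted training
#' responses define a Gaussian whose mode (= mean) is the predicted
#' response, and whose SD is reported for uncertainty bands. Scalar modes
#' return the weighted average of the training targets.
#'
#' @param object a fitted [frf()] model.
#' @param new_data feature table of samples to predict.
#' @param type `"curve"` (long tibble: `sample_id`, `dose`, `.pred`,
#'   `.pred_sd`), `"metric"` (summary metrics of each predicted curve), or
#'   `"scalar"` (rf/frfl modes). Defaults to the mode's natural type.
#' @param metrics metric columns to keep for `type = "metric"`.
#' @param ... unused.
#' @return a tibble; its class carries `frf_prediction` for `autoplot()`.
#' @export
predict.frf <- function(object, new_data, type = NULL,
                        metrics = c("auc", "ic50", "ec50", "amax"), ...) {
  type <- type %||% if (object$mode %in% c("rf", "frfl")) "scalar" else "curve"
  fx <- new_data_matrix(object, new_data)
  if (type == "scalar") {
    if (!object$mode %in% c("rf", "frfl")) {
      abort("use type = 'curve' (or 'metric') for curve-mode models")
    }
    mu <- cpp_predict_mean(object$trees, fx$x)
    return(tibble::tibble(sample_id = fx$ids, .pred = mu[, 1]))
  }
  if (object$mode %in% c("rf", "frfl")) {
    abort("scalar-mode models do not predict curves; use predict_scalar")
  }
  W <- forest_weights(object, new_data)
  mu <- W %*% object$y
  sdv <- sqrt(pmax(W %*% object$y^2 - mu^2, 0))
  if (type == "metric") {
    out <- purrr::map_dfr(seq_len(nrow(mu)), function(i) {
      curve_summary(object$doses, mu[i, ])
    })
    out <- dplyr::bind_cols(tibble::tibble(sample_id = fx$ids), out)
    return(out[, c("sample_id", intersect(metrics, names(out)))])
  }
  out <- tibble::tibble(
    sample_id = rep(fx$ids, each = ncol(mu)),
    dose = rep(as.numeric(object$doses %||% seq_len(ncol(mu))), nrow(mu)),
    .pred = as.vector(t(mu)),
    .pred_sd = as.vector(t(sdv)))
  class(out) <- c("frf_prediction", class(out))
  out
}

#' Fast matrix prediction
#'
#' Mean predictions as a plain matrix (samples x response points): the
#' average over trees of the leaf payload mean, identical to the
#' normalized-weight prediction but without per-dose SDs. This is the path
#' the evaluation drivers use.
#'
#' @param object a fitted [frf()] model.
#' @param x feature matrix or table.
#' @return numeric matrix of predictions.
#' @export
predict_matrix <- function(object, x) {
  if (is.data.frame(x)) x <- new_data_matrix(object, x)$x
  cpp_predict_mean(object$trees, as.matrix(x))
}

#' Single-tree prediction weights
#'
#' Weights of one tree for a query: `1/leaf size` mass on every
#' bootstrap-multiplicity-counted training sample in the query's leaf,
#' zero elsewhere; sums to one.
#'
#' @param tree one element of a fitted model's `$trees`, or a
#'   [grow_tree()] result.
#' @param x a feature vector or matrix of query rows.
#' @param n_train number of training samples the weights index into.
#' @return matrix (query rows x training samples).
#' @export
tree_weights <- function(tree, x, n_train) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  leaf <- cpp_route(tree, as.matrix(x))
  t(vapply(leaf, function(l) {
    mem <- tree$leaf_members[[l]]
    tabulate(mem, nbins = n_train) / length(mem)
  }, numeric(n_train)))
}

#' Forest weights of a query point over the training samples
#'
#' For each query row, the per-tree weights put mass `1/leaf size` on every
#' (bootstrap-multiplicity-counted) training sample sharing the query's
#' leaf; the forest weight is their average over trees and sums to one.
#'
#' @param object a fitted [frf()] model.
#' @param new_data feature table of query samples.
#' @return matrix (query samples x training samples) of weights.
#' @export
forest_weights <- function(object, new_data) {
  fx <- new_data_matrix(object, new_data)
  n <- nrow(object$y)
  nt <- nrow(fx$x)
  W <- matrix(0, nt, n)
  for (tree in object$trees) {
    leaf <- cpp_route(tree, fx$x)
    for (i in seq_len(nt)) {
      mem <- tree$leaf_members[[leaf[i]]]
      tab <- tabulate(mem, nbins = n)
      W[i, ] <- W[i, ] + tab / length(mem)
    }
  }
  W / length(object$trees)
}

#' Scalar forest prediction
#'
#' Weighted sum of the training scalar targets with the forest weights
#' (rf and frfl modes).
#'
#' @inheritParams forest_weights
#' @return tibble with `sample_id` and `.pred`.
#' @export
predict_scalar <- function(object, new_data) {
  if (!object$mode %in% c("rf", "frfl")) {
    abort("use predict_curve for curve-mode models")
  }
  predict(object, new_data, type = "scalar")
}

#' Curve forest prediction
#'
#' @inheritParams forest_weights
#' @return long tibble with per-dose predictions and SDs.
#' @export
predict_curve <- function(object, new_data) {
  if (object$mode %in% c("rf", "frfl")) {
    abort("use predict_scalar for scalar-mode models")
  }
  predict(object, new_data, type = "curve")
}

#' Summary metric of a predicted curve
#'
#' Applies [curve_summary()] to the predicted dose-response curves.
#'
#' @inheritParams forest_weights
#' @param metric one of `"auc"`, `"ic50"`, `"ec50"`, `"amax"`.
#' @return tibble with `sample_id` and the requested metric (`NA` = not
#'   reached).
#' @export
predict_summary_from_curve <- function(object, new_data, metric = "auc") {
  out <- predict(object, new_data, type = "metric", metrics = metric)
  out
}

#' Frequency-based variable importance
#'
#' The importance of a feature is the fraction of node-level candidacies in
#' which it was chosen for the split: `selected / picked`, accumulated over
#' all splittable nodes of all trees. Features never drawn into a candidate
#' subset get an importance of 0 and are flagged by `picked = 0`.
#'
#' @param object a fitted [frf()] model.
#' @return tibble with `feature`, `picked`, `selected`, `vim`.
#' @export
variable_importance <- function(object) {
  stopifnot(inherits(object, "frf"))
  picked <- object$vim_picked
  vim <- ifelse(picked > 0, object$vim_selected / pmax(picked, 1), 0)
  tibble::tibble(feature = object$feature_names,
                 picked = picked, selected = object$vim_selected,
                 vim = vim)
}

#' @export
tidy.frf <- function(x, ...) variable_importance(x)

#' @export
glance.frf <- function(x, ...) {
  tibble::tibble(mode = x$mode, cost = x$cost$kind,
                 trees = x$params$trees, mtry = x$params$mtry,
                 min_node = x$params$min_node,
                 n = nrow(x$y), n_doses = ncol(x$y),
                 mean_leaves = mean(vapply(x$trees, function(t)
                   nrow(t$leaf_means), numeric(1))))
}

#' @export
print.frf <- function(x, ...) {
  cat(sprintf("<funrf %s forest: %d trees, cost = %s, n = %d, %d response point(s)>\n",
              x$mode, x$params$trees, x$cost$kind, nrow(x$y), ncol(x$y)))
  invisible(x)
}
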