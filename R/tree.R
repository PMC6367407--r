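# Single functional regression trees. The quadratic ("SSD-family") costs go
# through the compiled prefix-sum split scan; divergence costs use an R
# search over the discretized per-dose densities (intended for the modest
# node sizes where replicate distributions are available).

# Reduce a cost spec + training responses to the internal growth plan.
prepare_cost <- function(spec, y, doses = NULL, sds = NULL) {
  spec <- as_cost_spec(spec)
  y <- as.matrix(y)
  switch(spec$kind,
    ssd = ,
    region_ssd = list(family = "ssd", yt = y, spec = spec),
    pca = {
      if (spec$pc_count > ncol(y)) abort("pc_count exceeds the response dimension")
      rot <- prcomp(y, center = TRUE, scale. = FALSE)$rotation
      list(family = "ssd",
           yt = y %*% rot[, seq_len(spec$pc_count), drop = FALSE],
           rotation = rot, spec = spec)
    },
    basis = {
      if (is.null(doses)) abort("the basis cost requires a dose grid")
      nb <- spec$n_basis %||% min(length(doses), 8L)
      x <- dose_axis(dose_grid(doses))
      knots <- bspline_knots(range(x), spec$order, nb)
      B <- splines::splineDesign(knots, x, ord = spec$order)
      C <- t(qr.coef(qr(B), t(y)))
      C[is.na(C)] <- 0
      gram <- bspline_gram(knots, spec$order)
      U <- chol(gram + diag(1e-10 * mean(diag(gram)), nrow(gram)))
      list(family = "ssd", yt = C %*% t(U), coefficients = C, gram = gram,
           spec = spec)
    },
    mahalanobis = {
      if (is.null(spec$covariance)) {
        list(family = "ssd", yt = y, per_tree_cov = TRUE, spec = spec)
      } else {
        list(family = "ssd", yt = whiten(y, spec$covariance, spec$ridge),
             spec = spec)
      }
    },
    kl = ,
    hellinger = {
      if (is.null(sds)) sds <- matrix(0, nrow(y), ncol(y))
      sds <- as.matrix(sds)
      if (!all(dim(sds) == dim(y))) abort("sds / responses dimension mismatch")
      list(family = "divergence", means = y, sds = sds, spec = spec)
    })
}

whiten <- function(y, covariance, ridge) {
  m <- ncol(y)
  sigma <- covariance + diag(ridge * sum(diag(covariance)) / m, m)
  R <- chol(sigma)
  t(backsolve(R, t(y), transpose = TRUE))
}

#' Exhaustive best-split search at one node
#'
#' Evaluates every candidate threshold (midpoints between consecutive
#' distinct values) of every candidate feature and returns the split
#' maximizing the cost reduction `D(parent) - D(left) - D(right)`. Ties are
#' broken toward the lowest feature index and lowest threshold; splits whose
#' reward is not strictly positive are rejected.
#'
#' @param x feature matrix of the node samples (samples x M).
#' @param targets node responses: a vector (scalar costs), a curve matrix,
#'   or per-dose means when `sds` is given.
#' @param cost a [node_cost_spec()] or cost-kind string.
#' @param feature_subset candidate feature indices (default: all).
#' @param doses dose grid (needed by the `basis` cost).
#' @param sds per-dose replicate SDs (divergence costs).
#' @return `NULL` when no admissible split exists, else a list with
#'   `feature`, `threshold`, `reward`.
#' @export
best_split <- function(x, targets, cost = "ssd", feature_subset = NULL,
                       doses = NULL, sds = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) abort("a node needs at least 2 samples to split")
  feature_subset <- feature_subset %||% seq_len(ncol(x))
  plan <- prepare_cost(cost, targets, doses = doses, sds = sds)
  if (plan$family == "ssd") {
    yt <- plan$yt
    if (isTRUE(plan$per_tree_cov)) {
      yt <- whiten(yt, stats::cov(yt), plan$spec$ridge)
    }
    res <- cpp_best_split(x, yt, seq_len(n), seq_len(n),
                          as.integer(feature_subset))
    if (is.null(res$feature)) return(NULL)
    return(res)
  }
  spec <- plan$spec
  omega <- omega_grid(plan$means, plan$sds, spec$omega_points)
  dens <- density_array(plan$means, plan$sds, omega, spec$eps_sd)
  divergence_best_split(x, dens, feature_subset, spec)
}

div_cost_members <- function(dens, members, kind, eps) {
  total <- 0
  d <- dim(dens)[2]
  for (j in seq_len(d)) {
    slab <- matrix(dens[members, j, ], nrow = length(members))
    mix <- colMeans(slab)
    for (k in seq_len(nrow(slab))) {
      total <- total + f_divergence(slab[k, ], mix, kind, eps)
    }
  }
  total
}

divergence_best_split <- function(x, dens, feature_subset, spec,
                                  members = seq_len(nrow(x))) {
  kind <- spec$kind
  eps <- spec$eps_prob
  d_parent <- div_cost_members(dens, members, kind, eps)
  tol <- max(d_parent, 1) * 1e-12
  best <- NULL
  for (f in sort(feature_subset)) {
    xv <- x[members, f]
    ux <- sort(unique(xv))
    if (length(ux) < 2) next
    thr <- (head(ux, -1) + tail(ux, -1)) / 2
    for (z in thr) {
      lm_ <- members[xv <= z]
      rm_ <- members[xv > z]
      reward <- d_parent - div_cost_members(dens, lm_, kind, eps) -
        div_cost_members(dens, rm_, kind, eps)
      if (reward > tol && (is.null(best) || reward > best$reward + tol)) {
        best <- list(feature = f, threshold = z, reward = reward)
      }
    }
  }
  best
}

#' Grow a single functional regression tree
#'
#' Recursively splits the data with reward-maximizing threshold splits. At
#' every splittable node a fresh random subset of `mtry` features is drawn;
#' growth stops when a node has at most `min_node` samples, the depth limit
#' is reached, or no positive-reward split exists. Leaves store the member
#' sample indices and the mean of the leaf payload (whole curves for
#' functional trees, scalars for univariate ones).
#'
#' @param x feature matrix or tibble.
#' @param targets responses: vector or curve matrix / wide table.
#' @param cost a [node_cost_spec()] or cost-kind string.
#' @param mtry features drawn per node (default: all).
#' @param min_node a node with at most this many samples is not split.
#' @param max_depth depth limit (`Inf` = none).
#' @param doses dose grid (curve targets).
#' @param sds per-dose replicate SDs (divergence costs).
#' @return a `funrf_tree`: node table vectors (`feature`, `threshold`,
#'   `left`, `right`, `n`, `leaf_id`), `leaf_members`, `leaf_means`.
#' @export
grow_tree <- function(x, targets, cost = "ssd", mtry = NULL, min_node = 1L,
                      max_depth = Inf, doses = NULL, sds = NULL) {
  fx <- as_feature_matrix(x)
  if (nrow(fx$x) == 0) abort("empty training set")
  ry <- as_response_matrix(targets, doses)
  plan <- prepare_cost(cost, ry$y, doses = ry$doses, sds = sds)
  mtry <- as.integer(mtry %||% ncol(fx$x))
  md <- if (is.finite(max_depth)) as.integer(max_depth) else -1L
  n <- nrow(fx$x)
  if (plan$family == "ssd") {
    yt <- plan$yt
    if (isTRUE(plan$per_tree_cov)) {
      yt <- whiten(yt, stats::cov(yt), plan$spec$ridge)
    }
    fr <- cpp_grow_forest(fx$x, yt, ry$y, matrix(seq_len(n), ncol = 1),
                          mtry, as.integer(min_node), md)
    tree <- fr$trees[[1]]
  } else {
    spec <- plan$spec
    omega <- omega_grid(plan$means, plan$sds, spec$omega_points)
    dens <- density_array(plan$means, plan$sds, omega, spec$eps_sd)
    tree <- grow_tree_divergence(fx$x, ry$y, dens, spec, mtry,
                                 as.integer(min_node), md,
                                 boot = seq_len(n))$tree
  }
  structure(tree, class = "funrf_tree")
}

# R grower for divergence costs; emits the same node-table structure as the
# compiled grower, plus picked/selected counters.
grow_tree_divergence <- function(x, ypay, dens, spec, mtry, n_size,
                                 max_depth, boot) {
  M <- ncol(x)
  env <- new.env()
  env$feature <- integer(); env$threshold <- numeric()
  env$left <- integer(); env$right <- integer()
  env$n <- integer(); env$leaf_id <- integer()
  env$leaf_members <- list(); env$leaf_means <- list()
  env$picked <- integer(M); env$selected <- integer(M)

  new_node <- function(nn) {
    i <- length(env$feature) + 1L
    env$feature[i] <- NA_integer_; env$threshold[i] <- NA_real_
    env$left[i] <- NA_integer_; env$right[i] <- NA_integer_
    env$n[i] <- nn; env$leaf_id[i] <- NA_integer_
    i
  }
  build <- function(idx, members, depth) {
    nn <- length(members)
    split <- NULL
    if (nn > n_size && nn >= 2 && (max_depth < 0 || depth < max_depth)) {
      subset <- sample.int(M, min(mtry, M))
      env$picked[subset] <- env$picked[subset] + 1L
      split <- divergence_best_split(x[boot, , drop = FALSE], dens, subset,
                                     spec, members = members)
    }
    if (is.null(split)) {
      lid <- length(env$leaf_members) + 1L
      env$leaf_id[idx] <- lid
      env$leaf_members[[lid]] <- boot[members]
      rows <- ypay[boot[members], , drop = FALSE]
      env$leaf_means[[lid]] <- colMeans(rows)
      return(invisible())
    }
    env$selected[split$feature] <- env$selected[split$feature] + 1L
    env$feature[idx] <- split$feature
    env$threshold[idx] <- split$threshold
    xv <- x[boot[members], split$feature]
    lm_ <- members[xv <= split$threshold]
    rm_ <- members[xv > split$threshold]
    li <- new_node(length(lm_)); ri <- new_node(length(rm_))
    env$left[idx] <- li; env$right[idx] <- ri
    build(li, lm_, depth + 1L)
    build(ri, rm_, depth + 1L)
  }
  root <- new_node(length(boot))
  build(root, seq_along(boot), 0L)
  tree <- list(feature = env$feature, threshold = env$threshold,
               left = env$left, right = env$right, n = env$n,
               leaf_id = env$leaf_id, leaf_members = env$leaf_members,
               leaf_means = do.call(rbind, env$leaf_means), boot = boot)
  list(tree = tree, picked = env$picked, selected = env$selected)
}

#' Route a feature vector to its leaf
#'
#' Follows the trained split rules (`x[feature] <= threshold` goes left)
#' until a leaf is reached; every feature vector reaches exactly one leaf.
#'
#' @param tree a `funrf_tree` (or one tree of a fitted forest).
#' @param x a feature vector (length M) or matrix of rows to route.
#' @return a list per routed sample with `leaf_id`, `members` (training
#'   sample indices, bootstrap multiplicity preserved) and `mean` (leaf
#'   payload mean); a single list when `x` is one vector.
#' @export
traverse <- function(tree, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  leaf <- cpp_route(tree, as.matrix(x))
  out <- lapply(leaf, function(l) {
    list(leaf_id = l, members = tree$leaf_members[[l]],
         mean = tree$leaf_means[l, ])
  })
  if (length(out) == 1) out[[1]] else out
}
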