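#' Node cost specification
#'
#' Selects the deviance used when growing trees. All quadratic kinds
#' (`ssd`, `region_ssd`, `pca`, `basis`, `mahalanobis`) are internally
#' reduced to a sum of squared deviances of a linearly transformed response
#' matrix, which makes the exhaustive split search an O(n d) prefix-sum scan
#' per feature. The divergence kinds (`kl`, `hellinger`) measure, per dose
#' region, the f-divergence of each sample's per-dose Gaussian from the
#' node's equal-weight mixture distribution.
#'
#' @param kind one of `"region_ssd"` (default for curve targets; per-dose
#'   sum of squared deviances summed over regions), `"ssd"` (scalar
#'   targets), `"pca"` (deviance of principal-component scores, basis fixed
#'   at the forest root), `"basis"` (B-spline coefficient deviance weighted
#'   by the basis Gram matrix), `"mahalanobis"` (multivariate deviance with
#'   inverse-covariance weighting), `"kl"` or `"hellinger"` (f-divergence of
#'   per-dose response distributions).
#' @param pc_count number of principal components retained (`pca`).
#' @param n_basis,order B-spline resolution for the `basis` kind.
#' @param covariance fixed covariance matrix for `mahalanobis`; `NULL`
#'   (default) estimates it once per tree from that tree's bootstrap
#'   responses, with a ridge of `ridge * trace/m` on the diagonal.
#' @param ridge relative ridge for covariance regularization.
#' @param omega_points number of discretization points of the response
#'   support grid used by the divergence kinds (spanning the pooled means
#'   plus/minus 4 max SD, fixed per tree).
#' @param eps_prob probability floor applied before logs and ratios.
#' @param eps_sd floor on per-dose SDs to avoid point masses.
#' @param regions number of dose regions; defaults to one region per dose.
#' @return a `node_cost_spec` object.
#' @export
node_cost_spec <- function(kind = c("region_ssd", "ssd", "pca", "basis",
                                    "mahalanobis", "kl", "hellinger"),
                           pc_count = 3L, n_basis = NULL, order = 4L,
                           covariance = NULL, ridge = 1e-6,
                           omega_points = 256L, eps_prob = 1e-12,
                           eps_sd = 1e-6, regions = NULL) {
  kind <- match.arg(kind)
  if (omega_points < 32) abort("omega_points must be at least 32")
  if (eps_prob <= 0 || eps_sd <= 0) abort("floors must be positive")
  structure(list(kind = kind, pc_count = as.integer(pc_count),
                 n_basis = n_basis, order = as.integer(order),
                 covariance = covariance, ridge = ridge,
                 omega_points = as.integer(omega_points),
                 eps_prob = eps_prob, eps_sd = eps_sd, regions = regions),
            class = "node_cost_spec")
}

as_cost_spec <- function(cost) {
  if (inherits(cost, "node_cost_spec")) cost
  else node_cost_spec(kind = cost)
}

#' Sum of squared deviances
#'
#' The classical regression-tree node cost: squared deviations of scalar
#' responses from the node mean.
#'
#' @param values numeric vector of node responses.
#' @return nonnegative scalar.
#' @export
ssd_cost <- function(values) {
  if (length(values) == 0) abort("empty node")
  sum((values - mean(values))^2)
}

#' Region-wise sum of squared deviances for curve responses
#'
#' The functional node cost on observed dose-response points: the response
#' curves are discretized into dose regions (by default one region per
#' dose), the SSD around the per-dose node mean is computed in each region,
#' and the regional deviances are summed.
#'
#' @param responses matrix of node curves (samples x doses) or a wide
#'   response table.
#' @param regions optional list of dose-index vectors partitioning the dose
#'   columns (validated; the total is invariant to the grouping).
#' @return nonnegative scalar.
#' @export
region_ssd_cost <- function(responses, regions = NULL) {
  y <- if (is.matrix(responses)) responses else as_response_matrix(responses)$y
  if (nrow(y) == 0) abort("empty node")
  if (!is.null(regions)) {
    idx <- sort(unlist(regions))
    if (!identical(idx, seq_len(ncol(y)))) {
      abort("regions must partition the dose indices")
    }
  }
  sum(sweep(y, 2, colMeans(y))^2)
}

#' Mahalanobis node cost for multivariate responses
#'
#' Sum over node samples of the squared Mahalanobis distance to the node
#' mean vector, the multivariate random forest deviance.
#'
#' @param responses matrix of node response vectors (samples x m).
#' @param covariance m x m symmetric covariance matrix.
#' @param ridge nonnegative relative ridge added as `ridge * trace/m` on the
#'   diagonal before inversion; with `ridge = 0` a singular covariance is an
#'   error.
#' @return nonnegative scalar.
#' @export
mahalanobis_cost <- function(responses, covariance, ridge = 0) {
  y <- as.matrix(responses)
  if (nrow(y) == 0) abort("empty node")
  m <- ncol(y)
  if (!isTRUE(all.equal(covariance, t(covariance)))) {
    abort("covariance must be symmetric")
  }
  sigma <- covariance + diag(ridge * sum(diag(covariance)) / m, m)
  ch <- tryCatch(chol(sigma), error = function(e) {
    abort("singular covariance; supply a positive ridge")
  })
  centered <- sweep(y, 2, colMeans(y))
  w <- t(backsolve(ch, t(centered), transpose = TRUE))
  sum(w^2)
}

#' Principal-component node cost
#'
#' Projects the node responses onto the top principal components of a
#' reference response matrix (the root training responses when growing a
#' forest) and returns the SSD of the scores around their node mean.
#'
#' @param responses matrix of node curves (samples x m).
#' @param pc_count number of components retained (at least 1).
#' @param rotation optional m x k rotation matrix fixing the PC basis; when
#'   `NULL` the basis is computed from `responses` itself.
#' @return nonnegative scalar.
#' @export
pca_cost <- function(responses, pc_count, rotation = NULL) {
  y <- as.matrix(responses)
  if (pc_count < 1) abort("pc_count must be at least 1")
  if (pc_count > ncol(y)) abort("pc_count exceeds the response dimension")
  if (is.null(rotation)) {
    rotation <- prcomp(y, center = TRUE, scale. = FALSE)$rotation
  }
  scores <- y %*% rotation[, seq_len(pc_count), drop = FALSE]
  sum(sweep(scores, 2, colMeans(scores))^2)
}

#' Basis-coefficient node cost
#'
#' Deviance of B-spline (or other basis) coefficient vectors around their
#' node mean, weighted by the Gram matrix of basis inner products, i.e.
#' the L2 deviance of the represented functions.
#'
#' @param coefficients matrix of coefficient vectors (samples x k).
#' @param gram k x k symmetric positive semidefinite Gram matrix.
#' @return nonnegative scalar.
#' @export
basis_cost <- function(coefficients, gram) {
  cmat <- as.matrix(coefficients)
  if (ncol(cmat) != nrow(gram) || nrow(gram) != ncol(gram)) {
    abort("coefficient / Gram dimension mismatch")
  }
  centered <- sweep(cmat, 2, colMeans(cmat))
  sum((centered %*% gram) * centered)
}

#' Discretize a Gaussian on a support grid
#'
#' Evaluates the normal density on the grid and renormalizes to unit mass,
#' yielding the discretized per-dose response distribution used by the
#' divergence node costs.
#'
#' @param mean,sd Gaussian parameters; `sd` is floored at `eps_sd`.
#' @param omega strictly increasing support grid.
#' @param eps_sd floor on the SD.
#' @return a `discretized_density`: the mass vector with the support as an
#'   attribute.
#' @export
discretize_gaussian <- function(mean, sd, omega, eps_sd = 1e-6) {
  masses <- dnorm(omega, mean, max(sd, eps_sd))
  tot <- sum(masses)
  if (tot <= 0) masses <- rep(1 / length(omega), length(omega))
  else masses <- masses / tot
  structure(masses, support = omega, class = "discretized_density")
}

#' Equal-weight Gaussian mixture distribution of a node
#'
#' The node-level "mean distribution": an equal-weight mixture of the member
#' samples' per-dose Gaussians, discretized on the support grid.
#'
#' @param means,sds per-sample Gaussian parameters at one dose.
#' @param omega support grid.
#' @param eps_sd floor on the SDs.
#' @return a `discretized_density`.
#' @export
mixture_density <- function(means, sds, omega, eps_sd = 1e-6) {
  if (length(means) == 0) abort("empty node")
  comp <- vapply(seq_along(means), function(i) {
    as.numeric(discretize_gaussian(means[i], sds[i], omega, eps_sd))
  }, numeric(length(omega)))
  structure(rowMeans(comp), support = omega, class = "discretized_density")
}

#' f-divergence between two discretized densities
#'
#' Kullback-Leibler divergence `sum p log(p/q)` or squared Hellinger
#' distance `sum (sqrt(p) - sqrt(q))^2` between mass vectors sharing one
#' support. Masses are floored at `eps` before logs and ratios. The KL
#' orientation follows the node-cost convention: the first argument is the
#' sample distribution, the second the node mixture.
#'
#' @param p,q `discretized_density` objects or bare mass vectors on a
#'   shared support.
#' @param kind `"kl"` or `"hellinger"`.
#' @param eps probability floor.
#' @return nonnegative scalar; the Hellinger kind lies in \[0, 2\].
#' @export
f_divergence <- function(p, q, kind = c("kl", "hellinger"), eps = 1e-12) {
  kind <- match.arg(kind)
  sp <- attr(p, "support"); sq <- attr(q, "support")
  if (!is.null(sp) && !is.null(sq) && !isTRUE(all.equal(sp, sq))) {
    abort("densities have different supports")
  }
  p <- as.numeric(p); q <- as.numeric(q)
  if (length(p) != length(q)) abort("densities have different supports")
  if (kind == "kl") {
    pf <- pmax(p, eps); qf <- pmax(q, eps)
    sum(pf * log(pf / qf))
  } else {
    sum((sqrt(p) - sqrt(q))^2)
  }
}

#' Divergence node cost over per-dose response distributions
#'
#' For each dose region, forms the node mixture distribution and sums the
#' chosen f-divergence of every sample's distribution from it; regional
#' costs are summed into the total node deviance.
#'
#' @param means,sds matrices (samples x doses) of per-dose Gaussian
#'   parameters.
#' @param kind `"kl"` or `"hellinger"`.
#' @param omega support grid; when `NULL`,
#'   `omega_points` equally spaced points spanning the pooled means
#'   plus/minus 4 times the largest SD.
#' @param omega_points grid resolution when `omega` is `NULL`.
#' @param eps_prob,eps_sd floors, as in [node_cost_spec()].
#' @return nonnegative scalar.
#' @export
divergence_cost <- function(means, sds, kind = c("kl", "hellinger"),
                            omega = NULL, omega_points = 256L,
                            eps_prob = 1e-12, eps_sd = 1e-6) {
  kind <- match.arg(kind)
  means <- as.matrix(means); sds <- as.matrix(sds)
  if (!all(dim(means) == dim(sds))) abort("means / sds dimension mismatch")
  if (any(sds < 0)) abort("sds must be nonnegative")
  if (nrow(means) == 0) abort("empty node")
  if (any(sds == 0) && eps_sd <= 0) abort("zero-SD distribution with no floor")
  if (is.null(omega)) omega <- omega_grid(means, sds, omega_points)
  dens <- density_array(means, sds, omega, eps_sd)
  total <- 0
  for (j in seq_len(ncol(means))) {
    slab <- matrix(dens[, j, ], nrow = nrow(means))
    mix <- colMeans(slab)
    for (i in seq_len(nrow(means))) {
      total <- total + f_divergence(dens[i, j, ], mix, kind, eps_prob)
    }
  }
  total
}

omega_grid <- function(means, sds, omega_points) {
  span <- range(means)
  pad <- 4 * max(sds, 1e-6)
  seq(span[1] - pad, span[2] + pad, length.out = omega_points)
}

# n x d x G array of discretized per-dose Gaussians
density_array <- function(means, sds, omega, eps_sd) {
  n <- nrow(means); d <- ncol(means); G <- length(omega)
  out <- array(0, c(n, d, G))
  for (i in seq_len(n)) {
    for (j in seq_len(d)) {
      out[i, j, ] <- as.numeric(
        discretize_gaussian(means[i, j], sds[i, j], omega, eps_sd))
    }
  }
  out
}
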