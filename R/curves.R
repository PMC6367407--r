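#' Validate a dose grid
#'
#' A dose grid is a strictly increasing vector of positive concentrations
#' (micromolar). All curve fitting and area integration in this package is
#' carried out on the log10-dose axis, the scale on which dose-response
#' experiments are designed and plotted.
#'
#' @param doses numeric vector of doses, strictly increasing, all positive,
#'   length at least 2.
#' @param scale axis used for integration and plotting, `"log10"` (default)
#'   or `"linear"`.
#' @return the dose vector with class `dose_grid` and a `scale` attribute.
#' @export
dose_grid <- function(doses, scale = c("log10", "linear")) {
  scale <- match.arg(scale)
  doses <- as.numeric(doses)
  if (length(doses) < 2) abort("a dose grid needs at least 2 doses")
  if (anyNA(doses) || any(!is.finite(doses))) abort("doses must be finite")
  if (any(doses <= 0)) abort("doses must be positive")
  if (any(diff(doses) <= 0)) abort("doses must be strictly increasing")
  structure(doses, class = "dose_grid", scale = scale)
}

dose_axis <- function(doses) {
  if (identical(attr(doses, "scale"), "linear")) as.numeric(doses)
  else log10(as.numeric(doses))
}

#' Least-squares B-spline representation of a dose-response curve
#'
#' Fits a B-spline of the given order on the log10-dose axis by ordinary
#' least squares. With `n_basis` equal to the number of dose points the fit
#' interpolates the observations. The returned object carries the Gram
#' matrix of basis inner products, the weight matrix of the
#' basis-coefficient node deviance.
#'
#' @param doses dose grid (positive, strictly increasing).
#' @param values observed responses, one per dose.
#' @param order spline order (degree + 1), at least 2; 4 = cubic.
#' @param n_basis number of basis functions, between `order` and the number
#'   of dose points.
#' @return an object of class `funrf_bspline` with elements `knots`,
#'   `coefficients`, `order`, `gram` and the log10-dose span.
#' @export
fit_bspline <- function(doses, values, order = 4L, n_basis = length(doses)) {
  doses <- dose_grid(doses)
  if (anyDuplicated(as.numeric(doses))) abort("duplicate doses")
  n <- length(doses)
  if (length(values) != n) abort("values and doses differ in length")
  if (any(!is.finite(values))) abort("non-finite response values")
  if (order < 2) abort("order must be at least 2")
  if (n < order) abort("insufficient points")
  if (n_basis < order || n_basis > n) {
    abort("n_basis must lie between the spline order and the number of doses")
  }
  x <- dose_axis(doses)
  knots <- bspline_knots(range(x), order, n_basis)
  B <- splines::splineDesign(knots, x, ord = order)
  cf <- qr.coef(qr(B), values)
  cf[is.na(cf)] <- 0
  structure(
    list(knots = knots, coefficients = unname(cf), order = as.integer(order),
         gram = bspline_gram(knots, order), span = range(x)),
    class = "funrf_bspline")
}

bspline_knots <- function(span, order, n_basis) {
  inner <- n_basis - order
  interior <- if (inner > 0) {
    seq(span[1], span[2], length.out = inner + 2)[-c(1, inner + 2)]
  } else numeric()
  c(rep(span[1], order), interior, rep(span[2], order))
}

# Gram matrix of basis inner products over the knot span (trapezoidal
# quadrature on a fine grid; symmetric PSD by construction).
bspline_gram <- function(knots, order, n_grid = 401L) {
  span <- range(knots)
  g <- seq(span[1], span[2], length.out = n_grid)
  B <- splines::splineDesign(knots, g, ord = order)
  w <- diff(g)
  w <- c(w / 2, 0) + c(0, w / 2)
  G <- crossprod(B * sqrt(w))
  (G + t(G)) / 2
}

#' Evaluate a fitted B-spline
#'
#' @param spline a `funrf_bspline` object.
#' @param doses doses at which to evaluate; must lie within the fitted span
#'   unless `extrapolate = TRUE`, in which case the boundary value is
#'   carried outward (constant extrapolation).
#' @param extrapolate allow doses outside the fitted span.
#' @return numeric vector of spline values.
#' @export
evaluate_spline <- function(spline, doses, extrapolate = FALSE) {
  stopifnot(inherits(spline, "funrf_bspline"))
  x <- log10(as.numeric(doses))
  lo <- spline$span[1]; hi <- spline$span[2]
  out <- any(x < lo - 1e-10 | x > hi + 1e-10)
  if (out && !extrapolate) abort("dose outside the fitted span")
  xc <- pmin(pmax(x, lo), hi)
  B <- splines::splineDesign(spline$knots, xc, ord = spline$order)
  drop(B %*% spline$coefficients)
}

#' Normalized area between a reference level and a response curve
#'
#' Trapezoidal area of (reference - response) over the log10-dose axis,
#' divided by the axis width so the result is in response units and
#' comparable across dose grids. With `clamp = TRUE` (the vehicle-control
#' convention), portions of the curve above the reference contribute zero.
#'
#' @param doses dose grid.
#' @param values response values at the doses.
#' @param reference reference level, scalar or one value per dose (e.g. a
#'   DMSO control level).
#' @param clamp clamp the curve at the reference before integrating.
#' @return scalar normalized area (response units).
#' @export
curve_auc <- function(doses, values, reference = 1, clamp = TRUE) {
  doses <- dose_grid(doses)
  if (length(values) != length(doses)) abort("values and doses differ in length")
  if (any(!is.finite(values)) || any(!is.finite(reference))) {
    abort("non-finite values")
  }
  reference <- rep_len(reference, length(values))
  effect <- reference - values
  if (clamp) effect <- pmax(effect, 0)
  x <- dose_axis(doses)
  trapz(x, effect) / diff(range(x))
}

#' IC percentiles from a cubic polynomial fit
#'
#' Fits a 3rd-degree polynomial in log10-dose to the observed values and,
#' for each percentile p, locates the smallest in-span dose where the fitted
#' curve has traversed p percent of its total fitted change. The traversal
#' is counted from the fitted curve's starting extremum: for a decreasing
#' trend the target level is `max - (p/100) (max - min)`, for an increasing
#' trend `min + (p/100) (max - min)`, so IC25 <= IC50 <= IC75 in dose order
#' for any monotone trend. Percentiles with no in-span crossing (including
#' flat curves) are reported as `NA` ("not reached"); no extrapolation is
#' attempted.
#'
#' @param doses dose grid with at least 4 points.
#' @param values observed values (e.g. protein expression).
#' @param percentiles percentiles in (0, 100).
#' @return a tibble with columns `percentile`, `dose` (`NA` = not reached).
#' @export
ic_from_polynomial <- function(doses, values, percentiles = c(25, 50, 75)) {
  doses <- dose_grid(doses)
  if (length(doses) < 4) abort("at least 4 dose points are required")
  if (length(values) != length(doses)) abort("values and doses differ in length")
  if (any(percentiles <= 0 | percentiles >= 100)) {
    abort("percentiles must lie in (0, 100)")
  }
  x <- dose_axis(doses)
  fit <- lm(values ~ poly(x, 3, raw = TRUE))
  cf <- coef(fit)
  f <- function(z) cf[1] + cf[2] * z + cf[3] * z^2 + cf[4] * z^3
  grid <- seq(min(x), max(x), length.out = 512)
  fg <- f(grid)
  fmin <- min(fg); fmax <- max(fg)
  rng <- fmax - fmin
  out <- tibble::tibble(percentile = as.numeric(percentiles), dose = NA_real_)
  if (rng < 1e-12 * max(1, abs(fmax))) return(out)
  decreasing <- fg[1] > fg[length(fg)]
  for (i in seq_along(percentiles)) {
    p <- percentiles[i] / 100
    level <- if (decreasing) fmax - p * rng else fmin + p * rng
    out$dose[i] <- first_crossing(grid, fg, f, level)
  }
  out
}

# First (lowest-dose) crossing of the continuous function f with `level`,
# bracketed on the evaluation grid and refined by root finding.
first_crossing <- function(grid, fg, f, level) {
  s <- fg - level
  hit <- which(abs(s) < 1e-12)
  cross <- which(s[-length(s)] * s[-1] < 0)
  idx <- suppressWarnings(min(c(hit, cross)))
  if (!is.finite(idx)) return(NA_real_)
  if (idx %in% hit && abs(s[idx]) < 1e-12) return(10^grid[idx])
  root <- uniroot(function(z) f(z) - level, lower = grid[idx],
                  upper = grid[idx + 1], tol = 1e-12)$root
  10^root
}

#' Four-parameter logistic (sigmoid) dose-response fit
#'
#' Bounded least-squares fit of
#' `y(d) = A0 + (Amax - A0) / (1 + (IC50/d)^theta)`,
#' the standard four-parameter model for viability curves, with multistart
#' over the slope parameter. `A0` and `Amax` are constrained to the data
#' mean plus/minus 1.5 times the data range, `theta` to (0, 10] and `IC50`
#' to one decade beyond the dose range on either side.
#'
#' @param doses dose grid.
#' @param values observed responses.
#' @return a list with elements `a0`, `amax`, `ic50`, `theta`, `fitted`,
#'   `converged`; or `NULL` when no start converges.
#' @export
fit_sigmoid <- function(doses, values) {
  doses <- dose_grid(doses)
  d <- as.numeric(doses)
  rng <- diff(range(values))
  if (rng <= 0) return(NULL)
  mid <- mean(range(values))
  lower <- c(a0 = mid - 1.5 * rng, amax = mid - 1.5 * rng,
             ic50 = min(d) / 10, theta = 1e-3)
  upper <- c(a0 = mid + 1.5 * rng, amax = mid + 1.5 * rng,
             ic50 = max(d) * 10, theta = 10)
  ic50_0 <- exp(mean(log(range(d))))
  model <- function(p) p[1] + (p[2] - p[1]) / (1 + (p[3] / d)^p[4])
  best <- NULL
  for (theta0 in c(0.5, 2, 5)) {
    start <- c(a0 = values[1], amax = values[length(values)],
               ic50 = ic50_0, theta = theta0)
    out <- tryCatch(
      minpack.lm::nls.lm(par = pmin(pmax(start, lower), upper),
                         fn = function(p) values - model(p),
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(out) || out$info < 1 || out$info > 4) next
    if (is.null(best) || out$deviance < best$deviance) best <- out
  }
  if (is.null(best)) return(NULL)
  p <- unname(best$par)
  list(a0 = p[1], amax = p[2], ic50 = p[3], theta = p[4],
       fitted = model(p), converged = TRUE)
}

#' Drug-sensitivity summary metrics of one curve
#'
#' Computes the standard scalar summaries of a viability curve: normalized
#' AUC against the reference level, IC50 (smallest in-span dose where the
#' fitted curve crosses half the reference), and EC50 / Amax from the
#' four-parameter logistic fit (EC50 = fitted inflection concentration,
#' Amax = fitted far-dose asymptote). Metrics undefined within the dose span
#' are reported as `NA` ("not reached"); doses are never extrapolated.
#'
#' @param doses dose grid.
#' @param values responses (viability convention: 1 = untreated level).
#' @param reference reference response level for AUC and the IC50 threshold.
#' @param sigmoid_fallback if the logistic fit fails, fall back to a
#'   spline-based AUC/IC50 with EC50 and Amax not reached (`TRUE`, default)
#'   or raise an error (`FALSE`).
#' @return one-row tibble with columns `auc`, `ic50`, `ec50`, `amax`.
#' @export
curve_summary <- function(doses, values, reference = 1,
                          sigmoid_fallback = TRUE) {
  doses <- dose_grid(doses)
  d <- as.numeric(doses)
  auc <- curve_auc(doses, values, reference = reference, clamp = TRUE)
  sig <- fit_sigmoid(doses, values)
  if (is.null(sig) && !sigmoid_fallback) abort("fit failed")
  half <- 0.5 * mean(reference)
  if (!is.null(sig)) {
    ic50 <- sigmoid_crossing(sig, half, range(d))
    ec50 <- if (sig$ic50 >= min(d) && sig$ic50 <= max(d)) sig$ic50 else NA_real_
    amax <- sig$amax
  } else {
    ic50 <- spline_crossing(doses, values, half)
    ec50 <- NA_real_
    amax <- NA_real_
  }
  tibble::tibble(auc = auc, ic50 = ic50, ec50 = ec50, amax = amax)
}

# Smallest in-span dose where the fitted logistic crosses `level`.
sigmoid_crossing <- function(sig, level, span) {
  a0 <- sig$a0; amax <- sig$amax
  if (abs(amax - a0) < 1e-12) return(NA_real_)
  u <- (level - a0) / (amax - a0)
  if (u <= 0 || u >= 1) return(NA_real_)
  # level = a0 + (amax-a0)/(1+(ic50/d)^theta)  =>  d = ic50 * (u/(1-u))^(1/theta)
  d <- sig$ic50 * (u / (1 - u))^(1 / sig$theta)
  if (d < span[1] - 1e-12 || d > span[2] + 1e-12) return(NA_real_)
  min(max(d, span[1]), span[2])
}

spline_crossing <- function(doses, values, level) {
  n <- length(doses)
  ord <- min(4L, n)
  sp <- fit_bspline(doses, values, order = ord, n_basis = n)
  x <- dose_axis(doses)
  grid <- seq(min(x), max(x), length.out = 512)
  fg <- drop(splines::splineDesign(sp$knots, grid, ord = sp$order) %*%
               sp$coefficients)
  first_crossing(grid, fg, function(z) {
    drop(splines::splineDesign(sp$knots, z, ord = sp$order) %*% sp$coefficients)
  }, level)
}

#' Summary metrics for a set of curves
#'
#' Applies [curve_summary()] to every row of a wide response table.
#'
#' @param responses wide table or matrix (one row per sample, one column per
#'   dose; a `sample_id` column is recognized).
#' @param doses dose grid; taken from the column names if `NULL`.
#' @inheritParams curve_summary
#' @return tibble with one row per sample: `sample_id`, `auc`, `ic50`,
#'   `ec50`, `amax`.
#' @export
summarize_curves <- function(responses, doses = NULL, reference = 1,
                             sigmoid_fallback = TRUE) {
  r <- as_response_matrix(responses, doses)
  if (is.null(r$doses)) abort("a dose grid is required")
  out <- purrr::map_dfr(seq_len(nrow(r$y)), function(i) {
    curve_summary(r$doses, r$y[i, ], reference = reference,
                  sigmoid_fallback = sigmoid_fallback)
  })
  dplyr::bind_cols(tibble::tibble(sample_id = r$ids), out)
}

#' Rank curves by slope
#'
#' Ranks a set of curves sharing one dose grid by their least-squares slope
#' against log10-dose: rank 1 is the steepest-declining curve (most negative
#' slope). Ties are broken stably by input order.
#'
#' @param responses wide response table or matrix.
#' @param doses dose grid; taken from column names if `NULL`.
#' @return integer vector of ranks, a permutation of `1:n`.
#' @export
rank_curves_by_slope <- function(responses, doses = NULL) {
  r <- as_response_matrix(responses, doses)
  if (is.null(r$doses)) abort("a dose grid is required")
  x <- dose_axis(r$doses)
  xc <- x - mean(x)
  slopes <- drop(r$y %*% xc) / sum(xc^2)
  as.integer(rank(slopes, ties.method = "first"))
}

#' Rank curves by pairwise dominance
#'
#' Curve A beats curve B when strictly more than half of A's dose points
#' exceed B's. Curves are ordered by the number of curves beating them
#' (fewest first, i.e. the topmost curve ranks 1), with ties broken by mean
#' value (higher first) and then input order.
#'
#' @inheritParams rank_curves_by_slope
#' @return integer vector of ranks, a permutation of `1:n`.
#' @export
rank_curves_by_dominance <- function(responses, doses = NULL) {
  r <- as_response_matrix(responses, doses)
  y <- r$y
  n <- nrow(y); m <- ncol(y)
  beaten <- integer(n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a != b && sum(y[b, ] > y[a, ]) > m / 2) beaten[a] <- beaten[a] + 1L
    }
  }
  ord <- order(beaten, -rowMeans(y), seq_len(n))
  ranks <- integer(n)
  ranks[ord] <- seq_len(n)
  ranks
}

#' Extract function-to-function predictor features from expression curves
#'
#' Converts per-sample, per-protein dose-expression curves into the scalar
#' feature set used for function-to-function regression: the normalized AUC
#' against a control reference level and the IC25/IC50/IC75 doses from a
#' cubic polynomial fit.
#'
#' @param expression long tibble with columns `sample_id`, `protein`,
#'   `dose`, `value`.
#' @param reference control (e.g. DMSO) expression level, scalar or a tibble
#'   with columns `protein`, `reference`.
#' @param percentiles IC percentiles to extract.
#' @return tibble with one row per sample x protein: `auc` and one `ic<p>`
#'   column per percentile (`NA` = not reached).
#' @export
extract_curve_features <- function(expression, reference = 1,
                                   percentiles = c(25, 50, 75)) {
  stopifnot(all(c("sample_id", "protein", "dose", "value") %in%
                  names(expression)))
  ref_tbl <- if (is.data.frame(reference)) reference else NULL
  expression |>
    dplyr::group_by(.data$sample_id, .data$protein) |>
    dplyr::group_modify(function(df, key) {
      ref <- if (is.null(ref_tbl)) reference else {
        ref_tbl$reference[match(key$protein, ref_tbl$protein)]
      }
      ics <- ic_from_polynomial(df$dose, df$value, percentiles)
      row <- tibble::tibble(auc = curve_auc(df$dose, df$value,
                                            reference = ref, clamp = TRUE))
      for (i in seq_len(nrow(ics))) {
        row[[paste0("ic", ics$percentile[i])]] <- ics$dose[i]
      }
      row
    }) |>
    dplyr::ungroup()
}
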