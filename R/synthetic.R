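#' Four-parameter logistic dose-response
#'
#' `y(d) = A0 + (Amax - A0) / (1 + (IC50/d)^theta)`: the response moves from
#' the untreated level `A0` at low dose to the asymptote `Amax` at high
#' dose, with inflection at `IC50` and slope `theta`.
#'
#' @param dose positive dose(s).
#' @param a0 response at zero dose.
#' @param amax far-dose asymptote.
#' @param ic50 inflection concentration (> 0).
#' @param theta slope parameter (> 0).
#' @return numeric vector of responses.
#' @export
sigmoid_response <- function(dose, a0 = 1, amax = 0, ic50, theta = 2) {
  if (any(dose <= 0) || any(ic50 <= 0) || theta <= 0) {
    abort("dose, ic50 and theta must be positive")
  }
  a0 + (amax - a0) / (1 + (ic50 / dose)^theta)
}

#' Simulate the clustered sigmoid dose-response benchmark
#'
#' Generates a cohort with known structure: samples fall into clusters with
#' limited-overlap Gaussian feature distributions, and each sample's
#' dose-response curve is a four-parameter logistic whose IC50 is the
#' cluster center jittered multiplicatively. Half of the features carry the
#' cluster signal; the rest are standard-Gaussian noise. Optional additive
#' Gaussian noise (SD = `noise_level` times the clean response range) is
#' applied to the returned responses; the noiseless curves are kept in
#' `$clean` for evaluation.
#'
#' The defaults produce a 75 x 20 design matrix (15 samples from each of 5
#' clusters, 10 relevant + 10 noise features) and a 75 x 101 target matrix
#' on a log-spaced dose grid from 0.0025 to 8 uM. Relevant feature k of a
#' cluster-c sample is drawn from N(c * delta, delta/4), so adjacent
#' clusters overlap by ~4.6% of their mass; feature columns are shuffled
#' and the relevant/noise mask recorded.
#'
#' @param n_clusters,samples_per_cluster cohort structure.
#' @param n_relevant,n_noise informative / spurious feature counts.
#' @param n_doses number of log-spaced dose levels.
#' @param a0,amax,theta fixed logistic parameters shared by all curves.
#' @param ic50_centers per-cluster IC50 centers (uM), strictly increasing;
#'   default: log-spaced from 0.01 to 4.
#' @param ic50_jitter multiplicative jitter half-width: sample IC50 =
#'   center * (1 + U(-jitter, jitter)).
#' @param noise_level additive noise SD as a fraction of the clean response
#'   range (e.g. 0.05 for 5% additive noise).
#' @param dose_range (min, max) dose in uM.
#' @param cluster_sep spacing delta between adjacent cluster feature means.
#' @param seed integer seed.
#' @return a `drc_cohort`: list with tibbles `features`, `responses`
#'   (noisy), `clean`, plus `doses`, `truth` (`sample_id`, `cluster`,
#'   `ic50`), `feature_info` (`feature`, `relevant`) and `config`.
#' @export
simulate_drc_cohort <- function(n_clusters = 5L, samples_per_cluster = 15L,
                                n_relevant = 10L, n_noise = 10L,
                                n_doses = 101L, a0 = 1, amax = 0, theta = 2,
                                ic50_centers = NULL, ic50_jitter = 0.1,
                                noise_level = 0, dose_range = c(0.0025, 8),
                                cluster_sep = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ic50_centers <- ic50_centers %||%
    10^seq(log10(0.01), log10(4), length.out = n_clusters)
  if (length(ic50_centers) != n_clusters || any(diff(ic50_centers) <= 0)) {
    abort("ic50_centers must be strictly increasing, one per cluster")
  }
  n <- n_clusters * samples_per_cluster
  cluster <- rep(seq_len(n_clusters), each = samples_per_cluster)
  ids <- sprintf("s%03d", seq_len(n))
  doses <- dose_grid(10^seq(log10(dose_range[1]), log10(dose_range[2]),
                            length.out = n_doses))

  rel <- vapply(seq_len(n_relevant), function(j) {
    rnorm(n, mean = cluster * cluster_sep, sd = cluster_sep / 4)
  }, numeric(n))
  noise <- matrix(rnorm(n * n_noise), n, n_noise)
  X <- cbind(rel, noise)
  relevant <- c(rep(TRUE, n_relevant), rep(FALSE, n_noise))
  shuffle <- sample.int(ncol(X))
  X <- X[, shuffle, drop = FALSE]
  relevant <- relevant[shuffle]
  colnames(X) <- sprintf("f%02d", seq_len(ncol(X)))

  ic50 <- ic50_centers[cluster] *
    (1 + runif(n, -ic50_jitter, ic50_jitter))
  clean <- t(vapply(ic50, function(v) {
    sigmoid_response(as.numeric(doses), a0, amax, v, theta)
  }, numeric(n_doses)))
  responses <- clean
  if (noise_level > 0) {
    responses <- clean + rnorm(length(clean),
                               sd = noise_level * diff(range(clean)))
    dim(responses) <- dim(clean)
  }

  wide <- function(m) {
    colnames(m) <- format(as.numeric(doses), trim = TRUE)
    dplyr::bind_cols(tibble::tibble(sample_id = ids),
                     tibble::as_tibble(as.data.frame(m)))
  }
  structure(list(
    features = dplyr::bind_cols(tibble::tibble(sample_id = ids),
                                tibble::as_tibble(as.data.frame(X))),
    responses = wide(responses),
    clean = wide(clean),
    doses = doses,
    truth = tibble::tibble(sample_id = ids, cluster = cluster, ic50 = ic50),
    feature_info = tibble::tibble(feature = colnames(X), relevant = relevant),
    config = list(n_clusters = n_clusters,
                  samples_per_cluster = samples_per_cluster,
                  n_relevant = n_relevant, n_noise = n_noise,
                  n_doses = n_doses, a0 = a0, amax = amax, theta = theta,
                  ic50_centers = ic50_centers, ic50_jitter = ic50_jitter,
                  noise_level = noise_level, dose_range = dose_range,
                  cluster_sep = cluster_sep, seed = seed)),
    class = "drc_cohort")
}

#' @export
print.drc_cohort <- function(x, ...) {
  cat(sprintf("<drc_cohort: %d samples, %d features, %d doses, noise %.0f%%>\n",
              nrow(x$features), ncol(x$features) - 1, length(x$doses),
              100 * x$config$noise_level))
  invisible(x)
}

#' Simulate functional predictors (dose-expression curves)
#'
#' A small cohort in the shape of post-treatment proteomic profiling:
#' per-sample dose-expression curves for a panel of proteins with mixed
#' trends (decreasing, flat, increasing) around a vehicle-control reference
#' level of 1, and viability curves functionally linked to the mean
#' area-under-curve of the first few (causal) proteins.
#'
#' @param n_samples,n_proteins,n_doses cohort shape (defaults 10 x 21 x 7).
#' @param dose_range (min, max) dose in uM.
#' @param n_causal number of proteins whose curves drive viability.
#' @param noise_sd additive measurement noise SD on expression values.
#' @param seed integer seed.
#' @return list with `expression` (long tibble: `sample_id`, `protein`,
#'   `dose`, `value`), `reference` (tibble `protein`, `reference`),
#'   `viability` (wide tibble), `doses`, `trends`.
#' @export
simulate_functional_predictors <- function(n_samples = 10L, n_proteins = 21L,
                                           n_doses = 7L,
                                           dose_range = c(0.0032, 3.2),
                                           n_causal = 5L, noise_sd = 0.02,
                                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  doses <- dose_grid(10^seq(log10(dose_range[1]), log10(dose_range[2]),
                            length.out = n_doses))
  d <- as.numeric(doses)
  trends <- rep(c("decreasing", "flat", "increasing"),
                c(ceiling(n_proteins * 0.6), ceiling(n_proteins * 0.2), 0))
  trends <- c(trends, rep("increasing", n_proteins - length(trends)))
  proteins <- sprintf("p%02d", seq_len(n_proteins))
  ids <- sprintf("s%02d", seq_len(n_samples))

  expr <- list(); k <- 1
  auc_causal <- matrix(0, n_samples, n_causal)
  for (i in seq_len(n_samples)) {
    for (p in seq_len(n_proteins)) {
      ic <- exp(runif(1, log(d[2]), log(d[n_doses - 1])))
      depth <- runif(1, 0.4, 0.9)
      base <- switch(trends[p],
        decreasing = sigmoid_response(d, a0 = 1, amax = 1 - depth, ic, 2),
        flat = rep(1, n_doses) + runif(1, -0.03, 0.03),
        increasing = sigmoid_response(d, a0 = 1, amax = 1 + depth, ic, 2))
      v <- base + rnorm(n_doses, sd = noise_sd)
      if (p <= n_causal) {
        auc_causal[i, p] <- curve_auc(doses, v, reference = 1, clamp = TRUE)
      }
      expr[[k]] <- tibble::tibble(sample_id = ids[i], protein = proteins[p],
                                  dose = d, value = v)
      k <- k + 1
    }
  }
  # viability: samples whose causal proteins are strongly suppressed
  # (high AUC) are more sensitive (lower viability IC50)
  drive <- rowMeans(auc_causal)
  ic50_v <- 10^(log10(max(d)) - 1.5 * (drive - min(drive)) /
                  max(diff(range(drive)), 1e-9))
  viability <- t(vapply(ic50_v, function(v) {
    sigmoid_response(d, 1, 0.05, v, 2)
  }, numeric(n_doses)))
  colnames(viability) <- format(d, trim = TRUE)
  list(expression = dplyr::bind_rows(expr),
       reference = tibble::tibble(protein = proteins, reference = 1),
       viability = dplyr::bind_cols(
         tibble::tibble(sample_id = ids),
         tibble::as_tibble(as.data.frame(viability))),
       doses = doses,
       trends = tibble::tibble(protein = proteins, trend = trends,
                               causal = seq_len(n_proteins) <= n_causal))
}
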