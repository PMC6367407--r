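# Independent oracles used across the suite. These deliberately avoid the
# package's split-search code path: costs are evaluated through the exported
# cost functions on explicit index sets, and the best split is found by a
# plain double loop over features and midpoint thresholds.

brute_force_split <- function(x, cost_fn) {
  n <- nrow(x)
  d_parent <- cost_fn(seq_len(n))
  tol <- max(d_parent, 1) * 1e-9
  best <- NULL
  for (f in seq_len(ncol(x))) {
    ux <- sort(unique(x[, f]))
    if (length(ux) < 2) next
    for (z in (head(ux, -1) + tail(ux, -1)) / 2) {
      l <- which(x[, f] <= z)
      r <- which(x[, f] > z)
      reward <- d_parent - cost_fn(l) - cost_fn(r)
      if (reward > tol && (is.null(best) || reward > best$reward + tol)) {
        best <- list(feature = f, threshold = z, reward = reward)
      }
    }
  }
  best
}

# the documented support grid of the divergence costs: 256 points spanning
# the pooled means +/- 4 max SD
oracle_omega <- function(means, sds, points = 256) {
  pad <- 4 * max(sds)
  seq(min(means) - pad, max(means) + pad, length.out = points)
}

# small deterministic curve cohort for tree/forest tests
toy_cohort <- function(n = 12, d = 5, seed = 99) {
  set.seed(seed)
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  doses <- 10^seq(-2, 1, length.out = d)
  ic50 <- ifelse(x[, 1] > 0, 2, 0.05)
  y <- t(vapply(ic50, function(v) sigmoid_response(doses, 1, 0, v, 2),
                numeric(d)))
  list(x = x, y = y, doses = doses)
}
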