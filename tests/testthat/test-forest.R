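test_that("a single full-data pure tree reproduces its training targets", {
  set.seed(41)
  x <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rnorm(10)
  fit <- frf(x, y, mode = "rf", trees = 1, mtry = 3, min_node = 1,
             bootstrap = FALSE, seed = 1)
  pred <- predict(fit, x)
  expect_equal(pred$.pred, y, tolerance = 1e-12)
})

test_that("bootstrap draws differ across seeds and fits are seed-reproducible", {
  tc <- toy_cohort()
  f1 <- frf(tc$x, tc$y, doses = tc$doses, trees = 5, mtry = 2, min_node = 2,
            seed = 1)
  f2 <- frf(tc$x, tc$y, doses = tc$doses, trees = 5, mtry = 2, min_node = 2,
            seed = 2)
  expect_false(identical(f1$boot, f2$boot))
  f1b <- frf(tc$x, tc$y, doses = tc$doses, trees = 5, mtry = 2, min_node = 2,
             seed = 1)
  expect_identical(f1$boot, f1b$boot)
  expect_equal(predict_matrix(f1, tc$x), predict_matrix(f1b, tc$x))
})

test_that("forest weights: normalization, uniform single leaf, bootstrap multiplicity", {
  tc <- toy_cohort()
  n <- nrow(tc$x)
  # single-leaf forest without bootstrap: uniform 1/n weights
  f0 <- frf(tc$x, tc$y, doses = tc$doses, trees = 3, min_node = n,
            bootstrap = FALSE, seed = 1)
  W0 <- forest_weights(f0, tc$x)
  expect_equal(unname(W0), matrix(1 / n, n, n), tolerance = 1e-12)

  # bootstrapped forest: weights match the leaf multiplicity definition
  f1 <- frf(tc$x, tc$y, doses = tc$doses, trees = 7, min_node = 3, seed = 3)
  W1 <- forest_weights(f1, tc$x)
  expect_equal(rowSums(W1), rep(1, n), tolerance = 1e-9)
  manual <- matrix(0, n, n)
  for (tree in f1$trees) {
    for (i in seq_len(n)) {
      lf <- traverse(tree, tc$x[i, ])
      tab <- tabulate(lf$members, nbins = n)
      manual[i, ] <- manual[i, ] + tab / length(lf$members)
    }
  }
  expect_equal(W1, manual / length(f1$trees), tolerance = 1e-12)
})

test_that("curve prediction equals the dose-wise weighted mean of training curves", {
  tc <- toy_cohort(n = 15)
  fit <- frf(tc$x, tc$y, doses = tc$doses, trees = 20, min_node = 3, seed = 7)
  W <- forest_weights(fit, tc$x[1:4, ])
  expect_equal(unname(W %*% tc$y), unname(predict_matrix(fit, tc$x[1:4, ])),
               tolerance = 1e-12)
  # the long-form prediction carries the same means plus per-dose SDs
  p <- predict(fit, tc$x[1:2, ])
  expect_equal(matrix(p$.pred, nrow = 2, byrow = TRUE),
               unname(predict_matrix(fit, tc$x[1:2, ])), tolerance = 1e-12)
  expect_true(all(p$.pred_sd >= 0))
})

test_that("scalar prediction identities: constant targets and 50/50 weights", {
  x <- matrix(c(0, 0, 10, 10), ncol = 1)
  fit <- frf(x, c(5, 5, 5, 5), mode = "rf", trees = 3, min_node = 1, seed = 1)
  expect_equal(predict(fit, x)$.pred, rep(5, 4))
  # two one-hot leaves averaged half-and-half
  fit2 <- frf(x, c(0, 0, 1, 1), mode = "rf", trees = 10, min_node = 1,
              bootstrap = FALSE, seed = 1)
  expect_equal(predict(fit2, matrix(7, 1, 1))$.pred, 1)
  expect_equal(predict(fit2, matrix(0, 1, 1))$.pred, 0)
  # a query at the threshold routes left by convention
  expect_equal(predict(fit2, matrix(5, 1, 1))$.pred, 0)
})

test_that("frfl keeps scalar leaves behind functional node costs", {
  tc <- toy_cohort()
  fit <- frf(tc$x, tc$y, doses = tc$doses, mode = "frfl", trees = 5,
             min_node = 2, metric = "auc", seed = 2)
  expect_equal(fit$cost$kind, "region_ssd")
  expect_true(all(vapply(fit$trees, function(t) ncol(t$leaf_means) == 1,
                         logical(1))))
  p <- predict_scalar(fit, tc$x)
  expect_equal(nrow(p), nrow(tc$x))
  expect_error(predict_curve(fit, tc$x), "scalar-mode")
  expect_error(predict_scalar(
    frf(tc$x, tc$y, doses = tc$doses, trees = 2, seed = 1), tc$x),
    "curve-mode")
})

test_that("mode/target mismatches are rejected", {
  tc <- toy_cohort()
  expect_error(frf(tc$x, tc$y, doses = tc$doses, mode = "rf"), "scalar")
  expect_error(frf(tc$x, matrix(rnorm(12), 12, 1), mode = "frfl"), "dose")
})

test_that("divergence-cost forests fit, predict and stay deterministic", {
  tc <- toy_cohort(n = 10, d = 3)
  sds <- matrix(0.2, 10, 3)
  f1 <- frf(tc$x, tc$y, doses = tc$doses, cost = "kl", sds = sds, trees = 3,
            mtry = 2, min_node = 3, seed = 9)
  f2 <- frf(tc$x, tc$y, doses = tc$doses, cost = "kl", sds = sds, trees = 3,
            mtry = 2, min_node = 3, seed = 9)
  expect_equal(predict_matrix(f1, tc$x), predict_matrix(f2, tc$x))
  expect_equal(rowSums(forest_weights(f1, tc$x)), rep(1, 10),
               tolerance = 1e-9)
  fh <- frf(tc$x, tc$y, doses = tc$doses, cost = "hellinger", sds = sds,
            trees = 3, mtry = 2, min_node = 3, seed = 9)
  expect_equal(dim(predict_matrix(fh, tc$x)), c(10L, 3L))
})

test_that("variable importance counts candidacies and selections", {
  tc <- toy_cohort(n = 20)
  fit <- frf(tc$x, tc$y, doses = tc$doses, trees = 30, mtry = 2,
             min_node = 3, seed = 4)
  v <- variable_importance(fit)
  expect_true(all(v$selected <= v$picked))
  expect_true(all(v$vim >= 0 & v$vim <= 1))
  expect_equal(v$vim[v$picked > 0],
               (v$selected / v$picked)[v$picked > 0])
  expect_true(all(v$vim[v$picked == 0] == 0))
  # mtry = 1 with a single fully informative feature: always selected when
  # drawn at a splittable node
  x1 <- matrix(c(rep(0, 6), rep(1, 6)), ncol = 1,
               dimnames = list(NULL, "only"))
  y1 <- rep(c(0, 5), each = 6)
  f1 <- frf(x1, y1, mode = "rf", trees = 20, mtry = 1, min_node = 6,
            bootstrap = FALSE, seed = 1)
  v1 <- variable_importance(f1)
  expect_equal(v1$vim, 1)
})

test_that("summary metrics of predicted curves behave at the extremes", {
  doses <- 10^seq(-2, 1, length.out = 8)
  # constant-viability cohort: predicted curve is flat at 1
  x <- matrix(rnorm(16), 8, 2, dimnames = list(NULL, c("a", "b")))
  yflat <- matrix(1, 8, 8)
  fit <- frf(x, yflat, doses = doses, trees = 5, min_node = 2, seed = 1)
  m <- predict_summary_from_curve(fit, x[1:2, ], metric = "auc")
  expect_equal(m$auc, c(0, 0))
  m2 <- predict_summary_from_curve(fit, x[1:2, ], metric = "ec50")
  expect_true(all(is.na(m2$ec50)))
  # a sharp in-span logistic cohort recovers its IC50 from the prediction
  y <- matrix(rep(sigmoid_response(doses, 1, 0, 0.5, 2), each = 8), 8,
              byrow = FALSE)
  y <- t(vapply(1:8, function(i) sigmoid_response(doses, 1, 0, 0.5, 2),
                numeric(8)))
  fit2 <- frf(x, y, doses = doses, trees = 5, min_node = 2, seed = 1)
  m3 <- predict_summary_from_curve(fit2, x[1:2, ], metric = "ic50")
  expect_equal(m3$ic50, c(0.5, 0.5), tolerance = 0.01)
})

test_that("tidy and glance expose importance and fit summaries", {
  tc <- toy_cohort()
  fit <- frf(tc$x, tc$y, doses = tc$doses, trees = 4, min_node = 3, seed = 2)
  td <- tidy(fit)
  expect_named(td, c("feature", "picked", "selected", "vim"))
  g <- glance(fit)
  expect_equal(g$trees, 4L)
  expect_equal(g$mode, "frf")
})

test_that("the univariate mode tracks an independent forest implementation", {
  skip_if_not_installed("randomForest")
  set.seed(61)
  n <- 120
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- sin(x[, 1]) + 0.5 * x[, 2] + rnorm(n, sd = 0.1)
  tr <- 1:80; te <- 81:n
  ours <- frf(x[tr, ], y[tr], mode = "rf", trees = 200, mtry = 2,
              min_node = 5, seed = 1)
  p_ours <- predict(ours, x[te, ])$.pred
  rf <- randomForest::randomForest(x[tr, ], y[tr], ntree = 200, mtry = 2,
                                   nodesize = 5)
  p_rf <- predict(rf, x[te, ])
  expect_gt(cor(p_ours, p_rf), 0.95)
  mse <- function(p) mean((p - y[te])^2)
  expect_lt(mse(p_ours), 2 * mse(p_rf))
})

test_that("single-tree weights carry leaf multiplicity and normalize", {
  tc <- toy_cohort()
  n <- nrow(tc$x)
  fit <- frf(tc$x, tc$y, doses = tc$doses, trees = 4, min_node = 3, seed = 8)
  W <- tree_weights(fit$trees[[2]], tc$x, n)
  expect_equal(rowSums(W), rep(1, n), tolerance = 1e-12)
  # forest weights are the average of per-tree weights
  avg <- Reduce(`+`, lapply(fit$trees, tree_weights, x = tc$x,
                            n_train = n)) / 4
  expect_equal(forest_weights(fit, tc$x), avg, tolerance = 1e-12)
})
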