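test_that("NMAE: exactness, constant error, translation and scale invariance", {
  y <- matrix(c(0, 1, 0, 1), 2)
  expect_equal(nmae(y, y), 0)
  expect_equal(nmae(y, y + 0.1), 0.1)
  expect_equal(nmae(y, y + 0.1), nmae(y + 5, y + 5.1))
  set.seed(2)
  p <- y + matrix(rnorm(4), 2)
  expect_equal(nmae(y, p), nmae(3 * y, 3 * p), tolerance = 1e-12)
  expect_error(nmae(matrix(1, 2, 2), matrix(1, 2, 2)), "zero range")
  expect_error(nmae(y, y[, 1, drop = FALSE]), "shape")
})

test_that("cross-validation: seeded folds partition the cohort and repeat exactly", {
  co <- simulate_drc_cohort(samples_per_cluster = 4, n_doses = 9,
                            noise_level = 0.05, seed = 6)
  cv1 <- cross_validate(co$features, co$responses, model = "frf", folds = 4,
                        seed = 11, trees = 10, min_node = 3)
  cv2 <- cross_validate(co$features, co$responses, model = "frf", folds = 4,
                        seed = 11, trees = 10, min_node = 3)
  expect_identical(cv1$folds, cv2$folds)
  expect_equal(cv1$nmae, cv2$nmae)
  expect_true(all(table(cv1$folds$fold) >= 1))
  expect_equal(sort(unique(cv1$folds$fold)), 1:4)
  expect_equal(nrow(cv1$predictions), 20)
  expect_error(cross_validate(co$features, co$responses, folds = 1), "folds")
})

test_that("leave-one-out predictions match manually fitted per-fold models", {
  tc <- toy_cohort(n = 6, d = 4)
  colnames(tc$x) <- c("a", "b", "c")
  cv <- cross_validate(tc$x, tc$y, doses = tc$doses, model = "frf",
                       folds = 6, seed = 21, trees = 5, mtry = 2,
                       min_node = 2)
  # replay the documented contract: seeded shuffled folds, then one fit per
  # fold in fold order on the shared RNG stream
  set.seed(21)
  fold <- sample(rep_len(1:6, 6))
  pred <- matrix(NA_real_, 6, 4)
  for (k in 1:6) {
    tr <- fold != k
    fit <- frf(tc$x[tr, , drop = FALSE], tc$y[tr, , drop = FALSE],
               doses = tc$doses, trees = 5, mtry = 2, min_node = 2)
    pred[!tr, ] <- predict_matrix(fit, tc$x[!tr, , drop = FALSE])
  }
  expect_equal(unname(as.matrix(cv$predictions[, -1])), pred,
               tolerance = 1e-12)
})

test_that("an oracle-recoverable cohort drives CV error to zero", {
  co <- simulate_drc_cohort(noise_level = 0, ic50_jitter = 0, n_doses = 21,
                            seed = 9)
  cv <- cross_validate(co$features, co$responses, model = "frf", folds = 5,
                       seed = 2, trees = 50, min_node = 1)
  expect_lt(cv$nmae, 0.01)
})

test_that("bootstrap comparison: paired design, exact ties, replicate count", {
  co <- simulate_drc_cohort(samples_per_cluster = 4, n_doses = 7,
                            noise_level = 0.1, seed = 14)
  b2 <- bootstrap_compare(co$features, co$responses, n_boot = 2,
                          trees = 5, min_node = 3, seed = 5)
  expect_equal(nrow(b2), 2)
  # identical model configurations under the shared per-replicate stream
  # tie exactly
  bb <- bootstrap_compare(co$features, co$responses, model_a = "frf",
                          model_b = "frf", n_boot = 3, trees = 5,
                          min_node = 3, seed = 5)
  expect_equal(bb$diff, rep(0, 3))
  expect_error(bootstrap_compare(co$features, co$responses, n_boot = 1),
               "n_boot")
})

test_that("benchmark summaries aggregate cells into per-noise improvements", {
  grid <- tibble::tibble(
    noise_level = rep(0, 8),
    trees = rep(c(50, 150), each = 4),
    folds = 5,
    repeat_id = rep(1:2, 4),
    model = rep(rep(c("rf_per_dose", "frf"), each = 2), 2),
    nmae = c(0.04, 0.04, 0.03, 0.03, 0.05, 0.05, 0.04, 0.04))
  class(grid) <- c("frf_benchmark", class(grid))
  s <- summarize_benchmark(grid)
  expect_equal(s$rf_nmae, 0.045)
  expect_equal(s$frf_nmae, 0.035)
  expect_equal(s$improvement_pct, mean(c(100 * 0.01 / 0.04, 100 * 0.01 / 0.05)))
})
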