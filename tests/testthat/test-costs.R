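test_that("scalar and region-wise SSD match direct arithmetic", {
  expect_equal(ssd_cost(c(1, 1, 1)), 0)
  expect_equal(ssd_cost(c(0, 2)), 2)
  expect_equal(ssd_cost(c(1, 2, 3, 4)), 5)
  expect_error(ssd_cost(numeric()), "empty")

  expect_equal(region_ssd_cost(matrix(0.3, 4, 6)), 0)
  # single dose reduces to the scalar SSD
  expect_equal(region_ssd_cost(matrix(c(1, 2, 3, 4), ncol = 1)),
               ssd_cost(c(1, 2, 3, 4)))
  # per-dose SSDs 2 and 8
  expect_equal(region_ssd_cost(rbind(c(0, 0), c(2, 4))), 10)
  expect_error(region_ssd_cost(rbind(c(0, 0), c(2, 4)), regions = list(1)),
               "partition")
})

test_that("Mahalanobis cost: identity reduction, scalar scaling, explicit toy", {
  set.seed(7)
  y <- matrix(rnorm(18), 6, 3)
  expect_equal(mahalanobis_cost(y, diag(3)), region_ssd_cost(y))
  expect_equal(mahalanobis_cost(y[, 1, drop = FALSE], matrix(4)),
               ssd_cost(y[, 1]) / 4)
  # 2-dose toy against explicit matrix arithmetic
  y2 <- rbind(c(0, 0), c(1, 2), c(2, 1))
  S <- rbind(c(2, 1), c(1, 3))
  centered <- sweep(y2, 2, colMeans(y2))
  manual <- sum(diag(centered %*% solve(S) %*% t(centered)))
  expect_equal(mahalanobis_cost(y2, S), manual, tolerance = 1e-12)
  expect_error(mahalanobis_cost(y2, matrix(c(1, 0, 0, 0), 2)), "singular")
  expect_error(mahalanobis_cost(y2, rbind(c(1, 2), c(0, 1))), "symmetric")
})

test_that("PCA and basis-coefficient costs match their linear-algebra oracles", {
  set.seed(8)
  y <- matrix(rnorm(24), 6, 4)
  # full basis: rotation invariance of SSD
  expect_equal(pca_cost(y, 4), region_ssd_cost(y), tolerance = 1e-10)
  expect_equal(pca_cost(matrix(1, 5, 3), 2), 0)
  # rank-1 responses: one component carries the whole deviance
  u <- rnorm(6); v <- rnorm(4)
  y1 <- outer(u, v)
  expect_equal(pca_cost(y1, 1), region_ssd_cost(y1), tolerance = 1e-8)
  expect_error(pca_cost(y, 0), "at least 1")

  C <- rbind(c(1, 0), c(0, 1), c(2, 2))
  G <- rbind(c(2, 1), c(1, 2))
  centered <- sweep(C, 2, colMeans(C))
  expect_equal(basis_cost(C, G),
               sum(diag(centered %*% G %*% t(centered))), tolerance = 1e-12)
  expect_equal(basis_cost(C, diag(2)), region_ssd_cost(C))
  expect_equal(basis_cost(matrix(1, 4, 2), G), 0)
  expect_error(basis_cost(C, diag(3)), "mismatch")
})

test_that("mixture distributions and f-divergences recover closed forms", {
  om <- seq(-8, 12, length.out = 4096)
  one <- discretize_gaussian(0, 1, om)
  expect_equal(sum(one), 1, tolerance = 1e-9)
  # mixture of one equals the component; two identical components collapse
  expect_equal(as.numeric(mixture_density(0, 1, om)), as.numeric(one),
               tolerance = 1e-12)
  expect_equal(as.numeric(mixture_density(c(2, 2), c(1, 1), om)),
               as.numeric(discretize_gaussian(2, 1, om)), tolerance = 1e-12)
  # N(0,1) + N(4,1): symmetry puts half the mass below 2
  mix <- mixture_density(c(0, 4), c(1, 1), om)
  expect_equal(sum(as.numeric(mix)[om < 2]), 0.5, tolerance = 1e-3)

  p <- discretize_gaussian(0, 1, om)
  q <- discretize_gaussian(1, 1, om)
  expect_equal(f_divergence(p, p, "kl"), 0)
  expect_equal(f_divergence(p, p, "hellinger"), 0)
  # Gaussian closed forms: KL = (mu1-mu2)^2 / 2, H^2 = 2 - 2 exp(-1/8)
  expect_equal(f_divergence(p, q, "kl"), 0.5, tolerance = 1e-3)
  expect_equal(f_divergence(p, q, "hellinger"), 2 - 2 * exp(-1 / 8),
               tolerance = 1e-3)
  # disjoint supports: squared Hellinger attains its maximum of 2
  pd <- c(0.5, 0.5, 0, 0); qd <- c(0, 0, 0.5, 0.5)
  expect_equal(f_divergence(pd, qd, "hellinger"), 2, tolerance = 1e-9)
  # symmetry of Hellinger, asymmetry of KL
  a <- discretize_gaussian(0, 1, om); b <- discretize_gaussian(2, 0.5, om)
  expect_equal(f_divergence(a, b, "hellinger"), f_divergence(b, a, "hellinger"))
  expect_gt(abs(f_divergence(a, b, "kl") - f_divergence(b, a, "kl")), 0.1)
  expect_error(f_divergence(discretize_gaussian(0, 1, om[1:100]), p), "support")
})

test_that("discretized KL converges to the Gaussian closed form as the grid refines", {
  # coarse regime where discretization error dominates floating point
  errs <- vapply(c(8, 16, 32), function(G) {
    om <- seq(-8, 9, length.out = G)
    abs(f_divergence(discretize_gaussian(0, 1, om),
                     discretize_gaussian(1, 1, om), "kl") - 0.5)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_true(all(errs[-1] <= errs[-length(errs)] / 2))
  # and the fine grid is essentially exact
  om <- seq(-8, 9, length.out = 1024)
  expect_equal(f_divergence(discretize_gaussian(0, 1, om),
                            discretize_gaussian(1, 1, om), "kl"), 0.5,
               tolerance = 1e-6)
})

test_that("divergence node cost: degenerate nodes and a quadrature oracle", {
  m <- matrix(c(0.5, 0.5, 0.5), 3, 1)
  s <- matrix(0.1, 3, 1)
  expect_equal(divergence_cost(m, s, "kl"), 0, tolerance = 1e-12)
  expect_equal(divergence_cost(matrix(0.3), matrix(0.2), "hellinger"), 0,
               tolerance = 1e-12)
  # two samples N(0,1), N(2,1): cost = 2 * KL(N(0,1) || mixture) by symmetry;
  # oracle via continuous quadrature
  mix_d <- function(z) 0.5 * dnorm(z, 0, 1) + 0.5 * dnorm(z, 2, 1)
  oracle <- 2 * integrate(function(z) dnorm(z) * log(dnorm(z) / mix_d(z)),
                          -10, 12, rel.tol = 1e-10)$value
  got <- divergence_cost(matrix(c(0, 2), 2, 1), matrix(1, 2, 1), "kl",
                         omega_points = 2048)
  expect_equal(got, oracle, tolerance = 5e-3)
  expect_error(divergence_cost(matrix(0, 0, 1), matrix(0, 0, 1)), "empty")
})

test_that("every quadratic cost is nonnegative and never increased by splitting", {
  set.seed(21)
  for (rep in 1:5) {
    y <- matrix(rnorm(10 * 4), 10, 4)
    split <- sample(c(TRUE, FALSE), 10, replace = TRUE)
    if (all(split) || !any(split)) next
    rot <- prcomp(y)$rotation
    G <- crossprod(matrix(rnorm(16), 4)) + diag(4)
    S <- crossprod(matrix(rnorm(16), 4)) + diag(4)
    costs <- list(
      function(idx) region_ssd_cost(y[idx, , drop = FALSE]),
      function(idx) ssd_cost(y[idx, 1]),
      function(idx) pca_cost(y[idx, , drop = FALSE], 2, rotation = rot),
      function(idx) basis_cost(y[idx, , drop = FALSE], G),
      function(idx) mahalanobis_cost(y[idx, , drop = FALSE], S))
    for (cf in costs) {
      dp <- cf(1:10); dl <- cf(which(split)); dr <- cf(which(!split))
      expect_gte(dp + 1e-9, dl + dr)
      expect_gte(dp, 0)
    }
  }
})
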