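test_that("precision-matrix partial correlations equal the residual oracle", {
  set.seed(61)
  for (i in 1:20) {
    p <- sample(4:6, 1)
    n <- 120
    x <- matrix(rnorm(n * p), n, p) %*% matrix(rnorm(p * p, sd = 0.4) + diag(p), p)
    pc <- partial_correlations(x)
    expect_equal(diag(pc$estimate), rep(1, p))
    expect_equal(pc$estimate, t(pc$estimate))
    for (pair in list(c(1, 2), c(2, p), c(1, p))) {
      expect_equal(pc$estimate[pair[1], pair[2]],
                   pcor_residual_oracle(x, pair[1], pair[2]),
                   tolerance = 1e-8)
    }
  }
})

test_that("partial correlations separate direct from induced association", {
  set.seed(62)
  n <- 5000
  z <- rnorm(n)
  x <- z + rnorm(n)
  y <- z + rnorm(n)          # x and y related only through z
  w <- rnorm(n)
  pc <- partial_correlations(cbind(x = x, y = y, z = z, w = w))
  expect_lt(abs(pc$estimate["x", "y"]), 0.05)
  expect_gt(pc$estimate["x", "z"], 0.5)
  near <- cbind(a = x, b = x + rnorm(n, sd = 0.01), w = w, z = z)
  expect_gt(partial_correlations(near)$estimate["a", "b"], 0.99)

  sing <- cbind(x, y, total = x + y)
  expect_error(partial_correlations(sing), "singular")
  expect_error(partial_correlations(matrix(rnorm(12), 3, 4)), "more observations")
})

test_that("parallel analysis is deterministic and conservative on noise", {
  set.seed(63)
  noise <- matrix(rnorm(200 * 11), 200, 11)
  a <- parallel_analysis(noise, n_iter = 150, seed = 9)
  b <- parallel_analysis(noise, n_iter = 150, seed = 9)
  expect_identical(a$n_factors, b$n_factors)
  expect_identical(a$eigen_reference, b$eigen_reference)
  expect_error(parallel_analysis(noise, n_iter = 50), "at least 100")

  # under the mean criterion observed and random eigenvalues share a
  # distribution, so noise legitimately suggests a factor about half the
  # time; the upper-quantile criterion is the conservative null check
  suggested <- vapply(1:20, function(s) {
    x <- matrix(rnorm(150 * 8), 150, 8)
    parallel_analysis(x, n_iter = 100, seed = s, quantile = 0.95)$n_factors
  }, integer(1))
  expect_gte(mean(suggested <= 1), 0.95)
  suggested_mean <- vapply(1:20, function(s) {
    x <- matrix(rnorm(150 * 8), 150, 8)
    parallel_analysis(x, n_iter = 100, seed = s)$n_factors
  }, integer(1))
  expect_lt(mean(suggested_mean), 2)  # no systematic structure is invented
})

test_that("oblimin rotation preserves the common covariance and reduces the criterion", {
  set.seed(64)
  pd <- generate_probe_data(250, planted_loadings(), seed = 64)
  A <- stats::factanal(scale(as.matrix(pd$items)), 4, rotation = "none")$loadings
  A <- matrix(A, nrow(A), 4)
  rot <- oblimin_rotate(A)
  expect_true(rot$converged)
  # oblique rotation is a reparameterization: L Phi L' == A A'
  expect_equal(rot$loadings %*% rot$Phi %*% t(rot$loadings), A %*% t(A),
               tolerance = 1e-10)
  expect_lte(rot$criterion, dreamcue:::vgq_quartimin(A)$f + 1e-12)
  expect_equal(diag(rot$Phi), rep(1, 4))
})

test_that("EFA recovers a planted one-factor structure in closed form", {
  set.seed(65)
  lambda <- 0.8
  n <- 2000; p <- 8
  f <- rnorm(n)
  x <- outer(f, rep(lambda, p)) + matrix(rnorm(n * p, sd = sqrt(1 - lambda^2)), n, p)
  fit <- efa(x, 1)
  expect_equal(unname(fit$loadings[, 1]), rep(lambda, p), tolerance = 0.05)
  expect_equal(unname(fit$h2), rep(lambda^2, p), tolerance = 0.08)
  expect_equal(fit$variance["SS loadings", 1], p * lambda^2, tolerance = 0.5)
})

test_that("obliquely rotated planted orthogonal factors stay near-orthogonal", {
  set.seed(66)
  L <- planted_loadings(n_items = 12, n_factors = 2, loading = 0.75)
  n <- 800
  f <- matrix(rnorm(n * 2), n, 2)
  x <- f %*% t(L) + matrix(rnorm(n * 12, sd = sqrt(1 - 0.75^2)), n, 12)
  fit <- efa(x, 2)
  expect_lt(abs(fit$Phi[1, 2]), 0.15)
  al <- align_loadings(fit$loadings, L)
  expect_lt(mean(abs(al - L)), 0.05)
})

test_that("flipping an item's sign negates its loadings, h2 unchanged", {
  set.seed(67)
  pd <- generate_probe_data(400, planted_loadings(), seed = 67)
  x <- as.matrix(pd$items)
  fit1 <- suppressWarnings(efa(x, 4))
  x2 <- x
  x2[, "topical_shifts"] <- 6 - x2[, "topical_shifts"]  # reverse-keyed item
  fit2 <- suppressWarnings(efa(x2, 4))
  a1 <- align_loadings(fit2$loadings, fit1$loadings)
  flip <- rep(1, 11); names(flip) <- rownames(fit1$loadings)
  flip["topical_shifts"] <- -1
  expect_equal(unname(a1), unname(fit1$loadings * flip), tolerance = 0.05)
  expect_equal(fit2$h2, fit1$h2, tolerance = 0.05)
})

test_that("variance decomposition is internally consistent", {
  set.seed(68)
  pd <- generate_probe_data(300, planted_loadings(), seed = 68)
  fit <- suppressWarnings(efa(pd$items, 4))
  v <- fit$variance
  # total common variance: sum of communalities equals total SS loadings
  expect_equal(sum(fit$h2), sum(v["SS loadings", ]), tolerance = 1e-8)
  expect_true(all(v["Proportion variance", ] >= 0 &
                    v["Proportion variance", ] <= 1))
  expect_true(all(diff(v["Cumulative variance", ]) >= 0))
  expect_equal(unname(v["Cumulative proportion", fit$n_factors]), 1)
  expect_true(all(diff(v["SS loadings", ]) <= 1e-10))  # descending order
  expect_true(all(fit$h2 <= 1 + 1e-6))
  expect_error(efa(pd$items, 9), "inadmissible")
})

test_that("substantial loadings use an inclusive 0.40 magnitude threshold", {
  fake <- structure(list(loadings = matrix(
    c(0.40, -0.75, 0.39, 0.10,
      0.39, 0.39, 0.39, 0.45),
    nrow = 4, dimnames = list(paste0("item", 1:4), c("F1", "F2")))),
    class = "dc_efa")
  s <- substantial_loadings(fake)
  expect_true(s$mask["item1", "F1"])   # exactly 0.40 counts
  expect_true(s$mask["item2", "F1"])   # negative loadings count by magnitude
  expect_false(s$mask["item3", "F1"])
  expect_identical(unname(s$cross_loading), c(FALSE, FALSE, FALSE, FALSE))
  fake$loadings["item4", "F1"] <- 0.5
  expect_true(substantial_loadings(fake)$cross_loading["item4"])
  all_small <- structure(list(loadings = matrix(0.39, 3, 2)), class = "dc_efa")
  expect_equal(sum(substantial_loadings(all_small)$mask), 0)
})
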