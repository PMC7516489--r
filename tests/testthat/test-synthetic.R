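test_that("degenerate truth reproduces the trend exactly", {
  truth <- truth_params(list(
    list(beta = c(0.5, -0.25, 0.1), sigma = 1e-10, alpha = 2),
    list(beta = 0.2, sigma = 1e-10, alpha = 2, rho = 0)))
  x1 <- seq(-1, 1, length.out = 12)
  ds <- simulate_mufi(truth, list(x1, x1[c(2, 6, 10)]), seed = 1)
  H <- legendre_design_matrix(x1, mean_basis(3, -1, 1))
  expect_equal(ds$z[[1]], drop(H %*% truth$levels[[1]]$beta),
               tolerance = 1e-6)
})

test_that("identical seeds give identical datasets; streams are per level", {
  sc <- mock_scenario()
  d1 <- simulate_mufi(sc$truth, sc$pivots, seed = 9, domain = sc$domain)
  d2 <- simulate_mufi(sc$truth, sc$pivots, seed = 9, domain = sc$domain)
  expect_identical(d1$z, d2$z)
  d3 <- simulate_mufi(sc$truth, sc$pivots, seed = 10, domain = sc$domain)
  expect_false(identical(d1$z[[1]], d3$z[[1]]))
  # changing only the level-2 truth leaves the level-1 draw untouched
  truth2 <- sc$truth
  truth2$levels[[2]]$rho <- -1
  d4 <- simulate_mufi(truth2, sc$pivots, seed = 9, domain = sc$domain)
  expect_identical(d4$z[[1]], d1$z[[1]])
})

test_that("non-nested pivots are rejected by the generator", {
  sc <- mock_scenario()
  expect_error(
    simulate_mufi(sc$truth, list(sc$pivots[[1]], c(-0.5, 0.123456, 0.5)),
                  seed = 1, domain = sc$domain),
    "not nested")
})

test_that("draws match the stated mean and covariance in Monte Carlo", {
  truth <- truth_params(list(list(beta = c(0.3, -0.2), sigma = 0.5,
                                  alpha = 3)))
  x <- c(-0.6, 0.4)
  n <- 4000
  D <- vapply(seq_len(n), function(r)
    simulate_mufi(truth, list(x), seed = 50000 + r)$z[[1]], numeric(2))
  H <- legendre_design_matrix(x, mean_basis(2, -0.6, 0.4))
  mu <- drop(H %*% truth$levels[[1]]$beta)
  # mean within 3 standard errors
  se_mean <- 0.5 / sqrt(n)
  expect_lt(abs(mean(D[1, ]) - mu[1]), 3 * se_mean)
  # covariance within 3 standard errors (domain-rescaled distance = 2)
  theo <- 0.25 * exp(-3 * 2^2)
  emp <- stats::cov(D[1, ], D[2, ])
  se_cov <- 0.25 * sqrt((1 + exp(-3 * 2^2)^2) / n)
  expect_lt(abs(emp - theo), 3 * se_cov)
  expect_lt(abs(stats::var(D[1, ]) - 0.25), 3 * 0.25 * sqrt(2 / n))
})

test_that("level-2 variance decomposes through the recursion in Monte Carlo", {
  truth <- truth_params(list(
    list(beta = 0.1, sigma = 0.4, alpha = 2),
    list(beta = 0.05, sigma = 0.2, alpha = 5, rho = 1.5)))
  x <- c(-0.5, 0.5)
  n <- 3000
  Z <- vapply(seq_len(n), function(r) {
    ds <- simulate_mufi(truth, list(x, x), seed = 90000 + r)
    c(ds$z[[1]][1], ds$z[[2]][1])
  }, numeric(2))
  v2 <- stats::var(Z[2, ])
  theo <- 1.5^2 * 0.4^2 + 0.2^2
  expect_lt(abs(v2 - theo), 3 * theo * sqrt(2 / n))
})

test_that("the mock scenario encodes its stated truth and shapes", {
  sc <- mock_scenario()
  expect_equal(sc$truth$levels[[2]]$rho, 3)
  expect_equal(sc$truth$levels[[1]]$sigma, 0.1)
  expect_equal(sc$truth$levels[[2]]$sigma, 0.01)
  expect_equal(sc$truth$levels[[1]]$alpha, 10.1)
  expect_equal(sc$truth$levels[[2]]$alpha, 20.1)
  expect_length(sc$truth$levels[[1]]$beta, 10)
  expect_length(sc$truth$levels[[2]]$beta, 4)
  expect_length(sc$pivots[[2]], 11)
  expect_length(sc$pivots[[1]], 41)
  expect_true(all(sc$pivots[[2]] %in% sc$pivots[[1]]))
})

test_that("the ICG-shaped fixture has the documented shapes", {
  ds <- icg_fixture(5)
  expect_equal(nrow(ds$x[[1]]), 24 * 21)
  expect_equal(nrow(ds$x[[2]]), 3 * 11)
  expect_true(all(c(5, 11, 18) %in% unique(ds$x[[1]][, 2])))
  expect_setequal(unique(ds$x[[2]][, 2]), c(5, 11, 18))
  # byte-identical CSV for the same seed
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_mufi_csv(ds, p1)
  write_mufi_csv(icg_fixture(5), p2)
  expect_identical(readLines(p1), readLines(p2))
})
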