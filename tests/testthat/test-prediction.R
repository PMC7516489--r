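test_that("difference-process posterior interpolates and decays correctly", {
  ts <- tiny_single_level(n = 6)
  spec0 <- level_spec(2, alpha_bounds = c(0.5, 20), jitter = 0)
  # at a pivot, the Schur complement vanishes and the mean hits the datum
  cd <- conditional_delta(1, 8, ts$dataset, spec0, ts$x[3])
  expect_equal(cd$cov[1, 1], 0, tolerance = 1e-10)
  expect_equal(cd$mean[1], ts$dataset$z[[1]][3], tolerance = 1e-8)
  # far from all pivots with a fast-decaying kernel: prior trend and variance
  spec <- level_spec(2, alpha_bounds = c(0.5, 20))
  cd2 <- conditional_delta(1, 2000, ts$dataset, spec, 0.09)
  st <- sufficient_stats(1, 2000, ts$dataset, spec)
  mom <- conditional_moments(st)
  hq <- legendre_design_matrix(0.09, st$basis)
  expect_equal(cd2$mean[1], drop(hq %*% mom$beta_mean), tolerance = 1e-6)
  expect_equal(cd2$cov[1, 1], 1, tolerance = 1e-6)
})

test_that("conditioning identity matches a textbook GP posterior", {
  ts <- tiny_single_level(n = 8, n_beta = 2)
  alpha <- 4
  cd <- conditional_delta(1, alpha, ts$dataset,
                          level_spec(2, alpha_bounds = c(0.5, 20)),
                          c(-0.45, 0.2, 0.77))
  ref <- uk_reference(ts$x, ts$dataset$z[[1]], c(-0.45, 0.2, 0.77),
                      n_beta = 2, alpha = alpha)
  expect_equal(cd$mean, ref, tolerance = 1e-10)
})

test_that("single-level prediction at fixed alpha is universal kriging", {
  ts <- tiny_single_level(n = 9, n_beta = 2)
  alpha <- 3.7
  xq <- seq(-0.9, 0.9, length.out = 11)
  pred <- predict_moments(ts$dataset, list(level_spec(2, alpha_bounds = c(0.5, 20))),
                          fixed_alpha_post(alpha), xq)
  ref <- uk_reference(ts$x, ts$dataset$z[[1]], xq, n_beta = 2, alpha = alpha)
  expect_equal(pred$mean, ref, tolerance = 1e-10)
})

test_that("multi-fidelity mean interpolates the top-level data at zero jitter", {
  tt <- tiny_two_level(seed = 13)
  specs0 <- lapply(tt$specs, function(s) { s$jitter <- 0; s })
  post <- grid_posterior(tt$dataset, specs0, resolution = 40)
  pred <- predict_moments(tt$dataset, specs0, post, tt$dataset$x[[2]])
  expect_equal(pred$mean, tt$dataset$z[[2]], tolerance = 1e-8)
})

test_that("explicit two-level mixture equals the general recursion", {
  tt <- tiny_two_level(seed = 21)
  xq <- c(-0.7, -0.1, 0.33, 0.9)
  post <- suppressWarnings(
    grid_posterior(tt$dataset, tt$specs, resolution = 25))
  pred <- predict_moments(tt$dataset, tt$specs, post, xq)
  # hand-rolled two-level formulas: mean = <rho1><delta1> + <delta2>,
  # cov = <rho1^2>(<s1^2 S1 + d1 d1'>) - <rho1>^2 <d1><d1>'
  #       + <s2^2 S2 + d2 d2'> - <d2><d2>'
  mix <- function(t) {
    lev <- post$levels[[t]]
    d <- 0; S <- 0; r1 <- 0; r2 <- 0
    for (i in seq_along(lev$alpha)) {
      cd <- conditional_delta(t, lev$alpha[i], tt$dataset, tt$specs[[t]], xq)
      w <- lev$weights[i]
      d <- d + w * cd$mean
      S <- S + w * (cd$moments$sigma_sq_mean * cd$cov + tcrossprod(cd$mean))
      r1 <- r1 + w * cd$moments$rho_mean
      r2 <- r2 + w * cd$moments$rho_sq_mean
    }
    list(d = d, S = S, r1 = r1, r2 = r2)
  }
  m1 <- mix(1); m2 <- mix(2)
  # level-1 contribution is carried up through the coupling chain
  mean2 <- m2$r1 * m1$d + m2$d
  cov2 <- (m2$r2 * m1$S - m2$r1^2 * tcrossprod(m1$d)) +
    (m2$S - tcrossprod(m2$d))
  expect_equal(pred$mean, mean2, tolerance = 1e-12)
  expect_equal(pred$covariance_raw, (cov2 + t(cov2)) / 2, tolerance = 1e-12)
})

test_that("reported covariances are symmetric PSD across random configs", {
  set.seed(71)
  for (rep in 1:100) {
    tt <- tiny_two_level(seed = 1000 + rep)
    post <- suppressWarnings(
      grid_posterior(tt$dataset, tt$specs, resolution = 8))
    xq <- sort(stats::runif(4, -1, 1))
    pred <- predict_moments(tt$dataset, tt$specs, post, xq)
    expect_equal(pred$covariance, t(pred$covariance))
    ev <- eigen(pred$covariance, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * max(sum(diag(pred$covariance)), 1e-300))
    expect_true(all(pred$sd >= 0) && all(is.finite(pred$mean)))
  }
})

test_that("adding a pivot never inflates the conditional variance", {
  # Schur-complement monotonicity at fixed hyperparameters
  x1 <- seq(-1, 1, length.out = 9)
  z1 <- sin(2 * x1) + 0.3 * x1
  sub <- c(1, 3, 5, 7, 9)
  ext <- c(1, 2, 3, 5, 7, 9)
  xq <- c(-0.55, 0.1, 0.62)
  for (alpha in c(2, 8)) {
    v <- function(idx) {
      ds <- mufi_dataset(list(list(x = x1, z = z1),
                              list(x = x1[idx], z = 0.5 * z1[idx])),
                         domain = list(lower = -1, upper = 1))
      diag(conditional_delta(2, alpha, ds,
                             level_spec(1, alpha_bounds = c(1, 20)), xq)$cov)
    }
    expect_true(all(v(ext) <= v(sub) + 1e-12))
  }
})

test_that("credible bands collapse to the mean when k or sd vanish", {
  ts <- tiny_single_level()
  pred <- predict_moments(ts$dataset,
                          list(level_spec(2, alpha_bounds = c(0.5, 20))),
                          fixed_alpha_post(3), c(-0.2, 0.4))
  b0 <- credible_band(pred, k = 0)
  expect_equal(b0$lower, pred$mean)
  expect_equal(b0$upper, pred$mean)
  pred$sd <- rep(0, 2)
  b1 <- credible_band(pred, k = 3)
  expect_equal(b1$lower, b1$upper)
})

test_that("one-sd bands do not under-cover the true top-level curve", {
  # correctly specified recovery study; the factorized posterior neglects
  # the rho/delta cross-level correlation, so bands are conservative --
  # coverage must not fall below the nominal-ish floor
  sc <- mock_scenario()
  xq <- seq(-0.98, 0.98, length.out = 40)
  cov1 <- vapply(1:15, function(s) {
    ds <- simulate_mufi(sc$truth, sc$pivots, seed = 2100 + s,
                        domain = sc$domain, x_eval = xq)
    tc <- attr(ds, "truth_curves")
    fit <- mufi_fit(ds, sc$specs)
    pr <- predict(fit, xq, k = 1)
    mean(tc[, 2] >= pr$band$lower & tc[, 2] <= pr$band$upper)
  }, numeric(1))
  expect_gte(mean(cov1), 0.58)
  expect_true(all(is.finite(cov1)))
})

test_that("empty query sets yield empty, well-formed results", {
  ts <- tiny_single_level()
  pred <- predict_moments(ts$dataset,
                          list(level_spec(2, alpha_bounds = c(0.5, 20))),
                          fixed_alpha_post(3), matrix(0, 0, 1))
  expect_length(pred$mean, 0)
  expect_equal(dim(pred$covariance), c(0L, 0L))
})
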