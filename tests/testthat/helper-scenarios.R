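# small fixtures, built in code

# two-level instance on [-1, 1]: 8 level-1 pivots, 6 nested level-2 pivots,
# trend orders 2 and 1 -- small enough for the quadrature oracle
tiny_two_level <- function(seed = 11, sigma1 = 0.3, sigma2 = 0.1, rho = 2) {
  truth <- truth_params(list(
    list(beta = c(0.4, -0.2), sigma = sigma1, alpha = 4),
    list(beta = 0.15, sigma = sigma2, alpha = 6, rho = rho)))
  x1 <- seq(-1, 1, length.out = 8)
  ds <- simulate_mufi(truth, list(x1, x1[c(1, 2, 3, 5, 7, 8)]), seed = seed)
  specs <- list(level_spec(2, alpha_bounds = c(0.5, 20)),
                level_spec(1, alpha_bounds = c(0.5, 20)))
  list(dataset = ds, specs = specs, truth = truth)
}

# single-level instance for universal-kriging reductions
tiny_single_level <- function(seed = 4, n = 9, n_beta = 2) {
  truth <- truth_params(list(list(beta = seq(0.5, by = -0.3,
                                             length.out = n_beta),
                                  sigma = 0.25, alpha = 3)))
  x <- seq(-1, 1, length.out = n)
  ds <- simulate_mufi(truth, list(x), seed = seed)
  specs <- list(level_spec(n_beta, alpha_bounds = c(0.5, 20)))
  list(dataset = ds, specs = specs, x = x)
}

# independent universal-kriging implementation (plain solve(), no shared
# code with the package internals) used as the reduction oracle
uk_reference <- function(x, z, xq, n_beta, alpha, jitter = 1e-8) {
  b <- mean_basis(n_beta, -1, 1)
  H <- legendre_design_matrix(x, b)
  Hq <- legendre_design_matrix(xq, b)
  K <- exp(-alpha * outer(x, x, "-")^2) + jitter * diag(length(x))
  kq <- exp(-alpha * outer(xq, x, "-")^2)
  Ki <- solve(K)
  beta_hat <- solve(t(H) %*% Ki %*% H, t(H) %*% Ki %*% z)
  drop(Hq %*% beta_hat + kq %*% Ki %*% (z - H %*% beta_hat))
}

# alpha posterior concentrated on a single node (fixed-alpha predictions)
fixed_alpha_post <- function(alphas) {
  structure(list(
    levels = lapply(seq_along(alphas), function(t)
      list(level = t, alpha = alphas[t], log_density = 0, weights = 1,
           log_evidence = 0)),
    log_evidence = 0, resolution = 1L, rule = "midpoint"),
    class = "alpha_posterior")
}
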