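# rough, closed-form-free parameter ranges for the oracle quadrature,
# from an ordinary least-squares pre-fit (the boundary-mass check below
# guards against under-bracketing)
oracle_auto_ranges <- function(t, dataset, spec) {
  basis <- level_basis(dataset, spec)
  H <- legendre_design_matrix(dataset$x[[t]], basis)
  z <- dataset$z[[t]]
  X <- if (t == 1L) H else cbind(H, dataset$z_prev[[t]])
  fit <- stats::lm.fit(X, z)
  s <- sqrt(sum(fit$residuals^2) / max(1, length(z) - ncol(X)))
  se <- sqrt(diag(chol2inv(chol(crossprod(X))))) * s
  est <- fit$coefficients
  nb <- spec$mean_order
  w <- 12 * se[seq_len(nb)] + 2 * s + 1e-3
  ranges <- list(beta = rbind(est[seq_len(nb)] - w, est[seq_len(nb)] + w),
                 log_sigma = log(max(s, 1e-8)) + c(-4, 3))
  if (t > 1L) {
    wr <- 12 * se[nb + 1L] + abs(est[nb + 1L]) + 0.5
    ranges$rho <- c(est[nb + 1L] - wr, est[nb + 1L] + wr)
  }
  ranges
}

#' Brute-force posterior moments of one level by tensor quadrature
#'
#' Reference implementation that certifies the analytic marginalizations:
#' integrates the exact per-level posterior — the Gaussian likelihood of
#' the difference process given (beta, rho, sigma, alpha), times flat
#' priors on beta and rho and the Jeffreys prior 1/sigma — on an iterated
#' Gauss-Legendre tensor grid (sigma on a log grid), and returns the
#' posterior expectations of beta, rho, rho^2 and sigma^2 together with
#' the normalization (the level's marginal likelihood at this alpha). It
#' shares no closed form with [conditional_moments()] or
#' [log_alpha_density()].
#'
#' @inheritParams sufficient_stats
#' @param ranges optional list with elements `beta` (2 x N_beta matrix of
#'   lower/upper rows), `rho` (length 2) and `log_sigma` (length 2);
#'   defaults to generous ranges from an ordinary-least-squares pre-fit.
#' @param nodes Gauss-Legendre nodes per dimension (default 64).
#' @param refine number of adaptive re-centering passes before the final,
#'   boundary-checked pass.
#' @return list with `beta_mean`, `rho_mean`, `rho_sq_mean`,
#'   `sigma_sq_mean`, `log_norm` and the quadrature `settings`.
#' @export
brute_force_level_moments <- function(t, alpha, dataset, spec, ranges = NULL,
                                      nodes = 64L, refine = 2L) {
  stopifnot(inherits(dataset, "mufi_data"))
  if (spec$mean_order > 2L) {
    stop("oracle quadrature is capped at N_beta <= 2", call. = FALSE)
  }
  adaptive <- is.null(ranges)
  if (adaptive) ranges <- oracle_auto_ranges(t, dataset, spec)
  basis <- level_basis(dataset, spec)
  H <- legendre_design_matrix(dataset$x[[t]], basis)
  z <- dataset$z[[t]]
  n <- length(z)
  nb <- spec$mean_order
  has_rho <- t > 1L
  jit <- resolve_jitter(spec, z)
  K <- kernel_matrix(dataset$u[[t]], alpha = alpha,
                     spec = kernel_spec(spec$kernel, jitter = jit))
  R <- chol(K)
  const <- -sum(log(diag(R))) - n / 2 * log(2 * pi)

  zp <- if (has_rho) dataset$z_prev[[t]] else NULL
  nd <- nb + has_rho            # location-parameter dimensions
  iu <- nd + 1L                 # slot of u = log sigma in the moment vectors

  # quadrature in sigma-scaled coordinates: beta_k = c_k + sigma * s_k * v_k,
  # rho = c_rho + sigma * s_rho * v (a plain change of variables with
  # Jacobian sigma^nd * prod(s); the conditional integrand then has
  # sigma-independent width in v, and the heavy sigma tail is covered by two
  # wide log-sigma panels). Still direct quadrature of the exact likelihood.
  one_pass <- function(centers, scales, u_center, check_boundary) {
    glv <- pracma::gaussLegendre(nodes, -9, 9)
    V <- as.matrix(do.call(expand.grid,
                           replicate(nd, list(glv$x))))
    logwV <- rowSums(log(as.matrix(do.call(expand.grid,
                                           replicate(nd, list(glv$w))))))
    u1 <- pracma::gaussLegendre(nodes, u_center - 6, u_center + 2)
    u2 <- pracma::gaussLegendre(nodes, u_center + 2, u_center + 16)
    ug <- c(u1$x, u2$x)
    uw <- c(u1$w, u2$w)
    # residual = E0 - sigma * T v  with E0 the residual at the centers
    E0 <- z - drop(H %*% centers[seq_len(nb)])
    if (has_rho) E0 <- E0 - centers[nb + 1L] * zp
    Tm <- H %*% (t(V[, seq_len(nb), drop = FALSE]) * scales[seq_len(nb)])
    if (has_rho) Tm <- Tm + outer(zp, V[, nb + 1L] * scales[nb + 1L])
    W0 <- backsolve(R, E0, transpose = TRUE)
    W1 <- backsolve(R, Tm, transpose = TRUE)
    q0 <- sum(W0^2)
    q1 <- drop(crossprod(W1, W0))
    q2 <- colSums(W1^2)
    ljac <- sum(log(scales))
    shift <- max(vapply(ug, function(u) {
      s <- exp(u)
      max(const - n * u + nd * u + ljac -
            (q0 - 2 * s * q1 + s^2 * q2) / (2 * s^2))
    }, numeric(1L)))
    Z <- 0
    m1 <- numeric(nd + 2L)
    m2 <- numeric(nd + 2L)
    bmax_v <- -Inf
    bmax_u <- -Inf
    gmax <- -Inf
    edge_v <- apply(V, 1L, function(r) any(r %in% c(glv$x[1L], glv$x[nodes])))
    for (j in seq_along(ug)) {
      u <- ug[j]
      s <- exp(u)
      ssq <- q0 - 2 * s * q1 + s^2 * q2
      logI <- const - n * u + nd * u + ljac - ssq / (2 * s^2)
      gmax <- max(gmax, max(logI))
      bmax_v <- max(bmax_v, max(logI[edge_v]))
      if (j %in% c(1L, length(ug))) bmax_u <- max(bmax_u, max(logI))
      w <- exp(logI + logwV - shift) * uw[j]
      sw <- sum(w)
      Z <- Z + sw
      for (k in seq_len(nd)) {
        val <- centers[k] + s * scales[k] * V[, k]
        m1[k] <- m1[k] + sum(w * val)
        m2[k] <- m2[k] + sum(w * val^2)
      }
      m1[iu] <- m1[iu] + sw * u
      m2[iu] <- m2[iu] + sw * u^2
      m1[iu + 1L] <- m1[iu + 1L] + sw * s^2
    }
    if (check_boundary && max(bmax_v, bmax_u) - gmax > log(1e-4)) {
      stop(paste0("oracle ranges too narrow: boundary density ratio ",
                  sprintf("%.2g", exp(max(bmax_v, bmax_u) - gmax)),
                  " exceeds 1e-4; widen the ranges"), call. = FALSE)
    }
    list(Z = Z, shift = shift, m1 = m1 / Z, m2 = m2 / Z)
  }

  # seed centers/scales from the supplied or OLS ranges, then re-center on
  # the computed posterior mass; the final pass enforces the boundary check
  centers <- c(colMeans(ranges$beta), if (has_rho) mean(ranges$rho))
  u_center <- mean(ranges$log_sigma)
  scales <- c((ranges$beta[2L, ] - ranges$beta[1L, ]) / 18,
              if (has_rho) diff(ranges$rho) / 18) / exp(u_center)
  scales <- pmax(scales, 1e-10)
  for (pass in seq_len(refine)) {
    p <- one_pass(centers, scales, u_center, check_boundary = FALSE)
    sdv <- sqrt(pmax(p$m2 - p$m1^2, 0))
    centers <- p$m1[seq_len(nd)]
    u_center <- p$m1[iu]
    scales <- pmax(sdv[seq_len(nd)], 1e-10) / sqrt(max(p$m1[iu + 1L], 1e-300))
  }
  p <- one_pass(centers, scales, u_center, check_boundary = TRUE)
  list(beta_mean = p$m1[seq_len(nb)],
       rho_mean = if (has_rho) p$m1[nb + 1L] else 0,
       rho_sq_mean = if (has_rho) p$m2[nb + 1L] else 0,
       sigma_sq_mean = p$m1[iu + 1L],
       log_norm = log(p$Z) + p$shift,
       settings = list(centers = centers, scales = scales,
                       u_center = u_center, nodes = nodes))
}

#' Brute-force total log evidence by nested quadrature
#'
#' Adds an outer Gauss-Legendre quadrature over the kernel hyperparameter
#' (with its truncated prior) on top of the per-level
#' [brute_force_level_moments()] normalizations, per level, and sums the
#' per-level log evidences.
#'
#' @inheritParams grid_posterior
#' @param nodes_alpha Gauss-Legendre nodes on alpha per level.
#' @param nodes inner nodes per parameter dimension.
#' @param ranges optional list of per-level oracle ranges.
#' @return list with `log_evidence` (total) and `per_level` vector.
#' @export
brute_force_evidence <- function(dataset, specs, nodes_alpha = 24L,
                                 nodes = 96L, ranges = NULL) {
  validate_design(dataset, specs)
  per <- vapply(seq_len(dataset$n_levels), function(t) {
    spec <- specs[[t]]
    ga <- pracma::gaussLegendre(nodes_alpha, spec$alpha_bounds[1L],
                                spec$alpha_bounds[2L])
    lvals <- vapply(seq_along(ga$x), function(i) {
      bf <- brute_force_level_moments(
        t, ga$x[i], dataset, spec, nodes = nodes,
        ranges = if (is.null(ranges)) NULL else ranges[[t]])
      bf$log_norm + log_alpha_prior(ga$x[i], spec) + log(ga$w[i])
    }, numeric(1L))
    logsumexp(lvals)
  }, numeric(1L))
  list(log_evidence = sum(per), per_level = per)
}

#' Certify the analytic marginalizations against the oracle
#'
#' Runs the brute-force oracle on every level of a (small) dataset at a
#' set of hyperparameter values and tabulates the relative error of each
#' analytic closed form: the conditional moments of beta, rho and sigma^2,
#' the hyperparameter log-density differences across alpha, and the total
#' log evidence.
#'
#' @inheritParams grid_posterior
#' @param alphas hyperparameter values probed per level (default: 5
#'   equispaced inside each level's bounds).
#' @param nodes inner quadrature nodes per dimension.
#' @param tol relative tolerance defining the pass flag (absolute, in log
#'   units, for evidence/density rows).
#' @return data frame (one row per certified quantity) of class
#'   `oracle_report`.
#' @export
certify <- function(dataset, specs, alphas = NULL, nodes = 96L, tol = 1e-3) {
  validate_design(dataset, specs)
  rows <- list()
  add <- function(level, quantity, analytic, oracle, err, tol_used) {
    rows[[length(rows) + 1L]] <<- data.frame(
      level = level, quantity = quantity, analytic = analytic,
      oracle = oracle, rel_error = err, tol = tol_used,
      pass = err < tol_used)
  }
  for (t in seq_len(dataset$n_levels)) {
    spec <- specs[[t]]
    av <- if (is.null(alphas)) {
      seq(spec$alpha_bounds[1L], spec$alpha_bounds[2L], length.out = 7L)[2:6]
    } else alphas
    lnorm <- numeric(length(av))
    ldens <- numeric(length(av))
    for (i in seq_along(av)) {
      bf <- brute_force_level_moments(t, av[i], dataset, spec, nodes = nodes)
      st <- sufficient_stats(t, av[i], dataset, spec)
      mom <- conditional_moments(st)
      lnorm[i] <- bf$log_norm
      ldens[i] <- log_alpha_density(t, av[i], dataset, spec) -
        log_alpha_prior(av[i], spec)
      scale_b <- max(abs(bf$beta_mean), 1e-8)
      add(t, sprintf("beta_mean[alpha=%.3g]", av[i]),
          mom$beta_mean[1L], bf$beta_mean[1L],
          max(abs(mom$beta_mean - bf$beta_mean)) / scale_b, tol)
      if (t > 1L) {
        add(t, sprintf("rho_mean[alpha=%.3g]", av[i]),
            mom$rho_mean, bf$rho_mean,
            abs(mom$rho_mean - bf$rho_mean) / max(abs(bf$rho_mean), 1e-8), tol)
        add(t, sprintf("rho_sq_mean[alpha=%.3g]", av[i]),
            mom$rho_sq_mean, bf$rho_sq_mean,
            abs(mom$rho_sq_mean - bf$rho_sq_mean) / abs(bf$rho_sq_mean), tol)
      }
      add(t, sprintf("sigma_sq_mean[alpha=%.3g]", av[i]),
          mom$sigma_sq_mean, bf$sigma_sq_mean,
          abs(mom$sigma_sq_mean - bf$sigma_sq_mean) / bf$sigma_sq_mean, tol)
    }
    # density *shape*: log-density differences across alpha values
    d_an <- ldens - ldens[1L]
    d_or <- lnorm - lnorm[1L]
    add(t, "log_density_shape", max(abs(d_an)), max(abs(d_or)),
        max(abs(d_an - d_or)), 0.01)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("oracle_report", class(out))
  out
}

#' @export
print.oracle_report <- function(x, ...) {
  cat(sprintf("Oracle certification: %d/%d quantities pass\n",
              sum(x$pass), nrow(x)))
  NextMethod()
}
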