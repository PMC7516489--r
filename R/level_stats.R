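# jitter default: on the unit-diagonal correlation matrix, so the effective
# nugget is 1e-8 * sigma_t^2 in covariance units -- several orders of
# magnitude below the conditional process variance
resolve_jitter <- function(spec, z) {
  if (!is.null(spec$jitter)) return(as.numeric(spec$jitter))
  1e-8
}

level_basis <- function(dataset, spec) {
  mean_basis(spec$mean_order,
             domain_low = dataset$domain$lower,
             domain_high = dataset$domain$upper)
}

#' Per-level sufficient statistics at fixed kernel hyperparameters
#'
#' Computes, for level `t` at a fixed kernel hyperparameter `alpha`, the
#' Gram matrix \eqn{K_t}, the trend design \eqn{H_t}, and the quantities
#' from which every conditional moment and the hyperparameter posterior
#' follow:
#' \eqn{A_t = (H_t' K_t^{-1} H_t)^{-1}}, \eqn{B_t = H_t' K_t^{-1}},
#' \eqn{C_t = K_t^{-1} - B_t' A_t B_t},
#' \eqn{c_t = z_t' C_t z_t}, \eqn{b_t = z_t' C_t z_{t-1}},
#' \eqn{a_t = z_{t-1}' C_t z_{t-1}},
#' \eqn{\gamma_t = (N_{xt} - N_{\beta t})/2} and
#' \eqn{\Phi_t = c_t - b_t^2 / a_t}. Level 1 has no coupling to a previous
#' level, so by convention \eqn{a_1 = 1}, \eqn{b_1 = 0} and
#' \eqn{\Phi_1 = c_1}. All inverses go through triangular (Cholesky)
#' factorizations; a failed factorization is retried once at 10x jitter.
#'
#' @param t level index (1 = lowest fidelity).
#' @param alpha positive kernel hyperparameter.
#' @param dataset a validated [mufi_dataset()].
#' @param spec the [level_spec()] of level `t`.
#' @return an object of class `suff_stats`.
#' @export
sufficient_stats <- function(t, alpha, dataset, spec) {
  stopifnot(inherits(dataset, "mufi_data"))
  u <- dataset$u[[t]]
  z <- dataset$z[[t]]
  n_x <- length(z)
  jit <- resolve_jitter(spec, z)
  kspec <- kernel_spec(spec$kernel, jitter = jit)
  basis <- level_basis(dataset, spec)
  H <- legendre_design_matrix(dataset$x[[t]], basis)
  K <- kernel_matrix(u, alpha = alpha, spec = kspec)
  ch <- chol_with_retry(K, jit)
  R <- ch$R                                   # K = R'R
  Hs <- backsolve(R, H, transpose = TRUE)     # R^{-T} H
  zs <- backsolve(R, z, transpose = TRUE)
  M <- crossprod(Hs)                          # H'K^{-1}H
  RM <- tryCatch(chol(M), error = function(e)
    stop("trend normal matrix H'K^{-1}H is singular; reduce mean_order",
         call. = FALSE))
  Kinv <- chol2inv(R)
  A <- chol2inv(RM)
  B <- crossprod(H, Kinv)
  C <- Kinv - crossprod(B, A %*% B)
  C <- (C + t(C)) / 2
  qf <- function(v, w) {                      # v' C w, via stable solves
    vs <- backsolve(R, v, transpose = TRUE)
    ws <- backsolve(R, w, transpose = TRUE)
    gv <- crossprod(Hs, vs)
    gw <- crossprod(Hs, ws)
    drop(crossprod(vs, ws)) -
      drop(crossprod(backsolve(RM, gv, transpose = TRUE),
                     backsolve(RM, gw, transpose = TRUE)))
  }
  c_t <- qf(z, z)
  if (t == 1L) {
    a_t <- 1
    b_t <- 0
  } else {
    zp <- dataset$z_prev[[t]]
    a_t <- qf(zp, zp)
    b_t <- qf(z, zp)
    if (a_t <= 0) {
      stop(sprintf("level %d: degenerate data, z_{t-1}' C z_{t-1} <= 0", t),
           call. = FALSE)
    }
  }
  gamma_t <- (n_x - spec$mean_order) / 2
  phi_t <- c_t - b_t^2 / a_t
  if (phi_t < 0 && phi_t > -1e-10 * max(c_t, 1)) phi_t <- 0
  structure(list(
    t = t, alpha = alpha, n_x = n_x, n_beta = spec$mean_order,
    K = K, R = R, H = H, Hs = Hs, RM = RM, A = A, B = B, C = C,
    a = a_t, b = b_t, c = c_t, gamma = gamma_t, phi = phi_t,
    log_det_K = 2 * sum(log(diag(R))),
    log_det_A = -2 * sum(log(diag(RM))),
    z = z, z_prev = if (t == 1L) numeric(0) else dataset$z_prev[[t]],
    jitter = ch$jitter, jitter_escalated = ch$escalated,
    basis = basis), class = "suff_stats")
}

#' Analytic conditional moments of beta, rho and sigma^2 at fixed alpha
#'
#' Closed-form posterior expectations of the analytically marginalized
#' parameters of one level, conditioned on the kernel hyperparameter:
#' \eqn{\bar\rho_{t-1} = b_t / a_t},
#' \eqn{\bar{\sigma}_t^2 = \Phi_t / (2\gamma_t - 3 + \delta_{t1})},
#' \eqn{E[\rho_{t-1}^2] = \bar\sigma_t^2 / a_t + (b_t/a_t)^2}, and
#' \eqn{\bar\beta_t = A_t B_t (z_t - \bar\rho_{t-1} z_{t-1})}. The
#' denominator of \eqn{\bar\sigma_t^2} follows from marginalizing the flat
#' trend/coupling priors and the Jeffreys scale prior exactly (certified
#' against [brute_force_level_moments()]); its positivity is precisely the
#' admissibility constraint enforced by [validate_design()]. Also returned:
#' the posterior mean of \eqn{\sigma_t} itself and the posterior covariance
#' of \eqn{\beta_t}, used for reporting.
#'
#' @param stats a [sufficient_stats()] result.
#' @return an object of class `cond_moments`.
#' @export
conditional_moments <- function(stats) {
  stopifnot(inherits(stats, "suff_stats"))
  d1 <- as.numeric(stats$t == 1L)
  denom <- 2 * stats$gamma - 3 + d1
  if (denom <= 0) {
    stop("second moments of sigma_t are not defined for this design",
         call. = FALSE)
  }
  rho_mean <- stats$b / stats$a
  sigma_sq_mean <- stats$phi / denom
  rho_sq_mean <- sigma_sq_mean / stats$a + rho_mean^2
  # posterior of sigma is proportional to sigma^-(m+1) exp(-Phi/(2 sigma^2))
  m <- 2 * stats$gamma - 1 + d1
  sigma_mean <- if (stats$phi > 0)
    sqrt(stats$phi / 2) * exp(lgamma((m - 1) / 2) - lgamma(m / 2)) else 0
  resid <- if (stats$t == 1L) stats$z else stats$z - rho_mean * stats$z_prev
  gb <- crossprod(stats$Hs, backsolve(stats$R, resid, transpose = TRUE))
  beta_mean <- drop(stats$A %*% gb)
  beta_cov <- sigma_sq_mean * stats$A
  if (stats$t > 1L) {
    gp <- drop(stats$A %*% crossprod(
      stats$Hs, backsolve(stats$R, stats$z_prev, transpose = TRUE)))
    beta_cov <- beta_cov + (sigma_sq_mean / stats$a) * tcrossprod(gp)
  }
  structure(list(beta_mean = beta_mean, beta_cov = beta_cov,
                 rho_mean = rho_mean, rho_sq_mean = rho_sq_mean,
                 sigma_sq_mean = sigma_sq_mean, sigma_mean = sigma_mean),
            class = "cond_moments")
}
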