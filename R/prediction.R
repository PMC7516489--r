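#' Conditional difference-process posterior at fixed hyperparameters
#'
#' Posterior mean and covariance of one level's difference process
#' \eqn{\delta_t} at query points, conditioned on the kernel hyperparameter:
#' the textbook GP conditioning identity with the plug-in conditional means
#' of the trend coefficients and of the coupling factor,
#' \deqn{\bar\delta_t(x^*) = h_t(x^*)\bar\beta_t
#'   + K_t(x^*, x_t) K_t(x_t, x_t)^{-1} (\delta_t(x_t) - h_t(x_t)\bar\beta_t),}
#' \deqn{\Sigma_t = K_t(x^*, x^*)
#'   - K_t(x^*, x_t) K_t(x_t, x_t)^{-1} K_t(x_t, x^*),}
#' with \eqn{\delta_t(x_t) = z_t(x_t) - \bar\rho_{t-1} z_{t-1}(x_t)}.
#' Queries more than 10% outside the mapped basis domain raise a warning,
#' not an error.
#'
#' @inheritParams sufficient_stats
#' @param x_query query points (vector or matrix, points in rows, original
#'   coordinates).
#' @return list with `mean` (length `n_query`), `cov` (`n_query` square),
#'   and the level's `cond_moments`.
#' @export
conditional_delta <- function(t, alpha, dataset, spec, x_query) {
  st <- sufficient_stats(t, alpha, dataset, spec)
  mom <- conditional_moments(st)
  uq <- rescale_points(x_query, dataset$domain)
  over <- max(abs(uq)) - 1
  if (over > 0.1) {
    warning(sprintf(
      "query point(s) extrapolate %.1f%% beyond the basis domain", 100 * over))
  }
  Hq <- legendre_design_matrix(x_query, st$basis, extrapolation_tol = Inf)
  Kq <- kernel_matrix(uq, dataset$u[[t]], alpha = alpha)
  Kqq <- kernel_matrix(uq, uq, alpha = alpha)     # no jitter on query block
  Wq <- backsolve(st$R, t(Kq), transpose = TRUE)  # R^{-T} K(x_t, x*)
  delta_data <- if (t == 1L) st$z else st$z - mom$rho_mean * st$z_prev
  resid <- delta_data - drop(st$H %*% mom$beta_mean)
  rs <- backsolve(st$R, resid, transpose = TRUE)
  mean_q <- drop(Hq %*% mom$beta_mean) + drop(crossprod(Wq, rs))
  cov_q <- Kqq - crossprod(Wq)
  cov_q <- (cov_q + t(cov_q)) / 2
  list(mean = mean_q, cov = cov_q, moments = mom, stats = st)
}

#' Posterior predictive moments of the highest-fidelity process
#'
#' Mixes the per-level conditional predictions over the discretized
#' hyperparameter posterior and composes them through the autoregressive
#' recursion. The predictive mean is
#' \deqn{\bar z_{N_t}(x^*) = \sum_t \langle\bar\delta_t(x^*)\rangle_{\alpha_t}
#'   \prod_{l=t}^{N_t-1} \bar\rho_l,}
#' and, because the per-level posteriors are independent, the predictive
#' covariance is the sum of per-level covariances,
#' \deqn{\sum_t \Big[ \langle \bar\sigma_t^2 \Sigma_t + \bar\delta_t
#'   \bar\delta_t'\rangle_{\alpha_t} \prod_l E[\rho_l^2]
#'   - \langle\bar\delta_t\rangle \langle\bar\delta_t\rangle'
#'   \prod_l \bar\rho_l^2 \Big],}
#' with no cross-level covariance terms. The reported covariance is
#' symmetrized and, for the standard deviations, eigenvalue-clipped at
#' zero; the unclipped matrix is retained in `covariance_raw`.
#'
#' @param dataset a validated [mufi_dataset()].
#' @param specs list of [level_spec()].
#' @param alpha_post an [grid_posterior()] result on the same dataset.
#' @param x_query query points (vector or matrix, original coordinates).
#' @param weight_floor grid nodes with posterior weight below this are
#'   skipped in the mixture (renormalized); 0 disables.
#' @return an object of class `mufi_prediction` with fields `query_points`,
#'   `mean`, `sd`, `covariance`, `covariance_raw` and `per_level`.
#' @export
predict_moments <- function(dataset, specs, alpha_post, x_query,
                            weight_floor = 1e-12) {
  stopifnot(inherits(alpha_post, "alpha_posterior"))
  validate_design(dataset, specs)
  xq <- as_points(x_query)
  nq <- nrow(xq)
  nt <- dataset$n_levels
  if (nq == 0L) {
    return(structure(list(query_points = xq, mean = numeric(0),
                          sd = numeric(0),
                          covariance = matrix(0, 0, 0),
                          covariance_raw = matrix(0, 0, 0),
                          per_level = list()),
                     class = "mufi_prediction"))
  }
  dbar <- vector("list", nt)     # alpha-averaged per-level predictive mean
  Smix <- vector("list", nt)     # alpha-averaged sigma^2 Sigma + dbar dbar'
  rho1 <- rep(NA_real_, nt)      # E[rho_{t-1}] stored at level t
  rho2 <- rep(NA_real_, nt)
  for (t in seq_len(nt)) {
    lev <- alpha_post$levels[[t]]
    keep <- which(lev$weights > weight_floor & is.finite(lev$log_density))
    w <- lev$weights[keep] / sum(lev$weights[keep])
    d_acc <- numeric(nq)
    S_acc <- matrix(0, nq, nq)
    r1_acc <- 0
    r2_acc <- 0
    for (i in seq_along(keep)) {
      cd <- conditional_delta(t, lev$alpha[keep[i]], dataset, specs[[t]], xq)
      d_acc <- d_acc + w[i] * cd$mean
      S_acc <- S_acc + w[i] * (cd$moments$sigma_sq_mean * cd$cov +
                                 tcrossprod(cd$mean))
      r1_acc <- r1_acc + w[i] * cd$moments$rho_mean
      r2_acc <- r2_acc + w[i] * cd$moments$rho_sq_mean
    }
    dbar[[t]] <- d_acc
    Smix[[t]] <- S_acc
    rho1[t] <- r1_acc
    rho2[t] <- r2_acc
  }
  mean_q <- numeric(nq)
  cov_raw <- matrix(0, nq, nq)
  per_level <- vector("list", nt)
  for (t in seq_len(nt)) {
    upper <- if (t < nt) (t + 1L):nt else integer(0)
    R1 <- prod(rho1[upper])      # prod over couplings above level t
    R2 <- prod(rho2[upper])
    mean_q <- mean_q + R1 * dbar[[t]]
    contrib <- R2 * Smix[[t]] - R1^2 * tcrossprod(dbar[[t]])
    cov_raw <- cov_raw + contrib
    per_level[[t]] <- list(level = t, delta_mean = dbar[[t]],
                           rho_chain_mean = R1, rho_chain_sq = R2,
                           var_contrib = pmax(diag(contrib), 0))
  }
  cov_raw <- (cov_raw + t(cov_raw)) / 2
  ev <- eigen(cov_raw, symmetric = TRUE)
  cov_psd <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
  cov_psd <- (cov_psd + t(cov_psd)) / 2
  structure(list(query_points = xq, mean = mean_q,
                 sd = sqrt(pmax(diag(cov_raw), 0)),
                 covariance = cov_psd, covariance_raw = cov_raw,
                 per_level = per_level),
            class = "mufi_prediction")
}

#' Central credible band around the predictive mean
#'
#' @param result a [predict_moments()] result.
#' @param k band half-width in posterior standard deviations (default 1).
#' @return data frame with `mean`, `sd`, `lower`, `upper` per query point.
#' @export
credible_band <- function(result, k = 1) {
  stopifnot(inherits(result, "mufi_prediction"), k >= 0)
  data.frame(mean = result$mean, sd = result$sd,
             lower = result$mean - k * result$sd,
             upper = result$mean + k * result$sd)
}

#' @export
print.mufi_prediction <- function(x, ...) {
  cat(sprintf("Multi-fidelity prediction at %d query point(s)\n",
              length(x$mean)))
  if (length(x$mean)) {
    cat(sprintf("  mean in [%.4g, %.4g], sd in [%.4g, %.4g]\n",
                min(x$mean), max(x$mean), min(x$sd), max(x$sd)))
  }
  invisible(x)
}
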