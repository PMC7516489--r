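#' Fit the fully Bayesian multi-fidelity Gaussian process model
#'
#' Validates the nested design, computes the per-level grid posterior of
#' the kernel hyperparameters, and mixes the analytic conditional moments
#' over it to produce parameter summaries (posterior means and standard
#' deviations of every trend coefficient, scale, coupling factor and
#' hyperparameter) and per-level and total log evidence. No parameters are
#' tuned: the only inputs are the data, the trend bases, the kernels and
#' the hyperparameter-prior bounds.
#'
#' @inheritParams grid_posterior
#' @return an object of class `mufi_fit` with elements `dataset`, `specs`,
#'   `post` (the [grid_posterior()]), `summary` (data frame of parameter
#'   estimates) and `log_evidence`.
#' @export
mufi_fit <- function(dataset, specs, resolution = 100L,
                     rule = c("midpoint", "trapezoid"), parallel = FALSE) {
  rule <- match.arg(rule)
  validate_design(dataset, specs)
  post <- grid_posterior(dataset, specs, resolution = resolution, rule = rule,
                         parallel = parallel)
  rows <- list()
  for (t in seq_len(dataset$n_levels)) {
    lev <- post$levels[[t]]
    keep <- which(is.finite(lev$log_density) & lev$weights > 1e-14)
    w <- lev$weights[keep] / sum(lev$weights[keep])
    nb <- specs[[t]]$mean_order
    b1 <- numeric(nb); b2 <- matrix(0, nb, nb)
    s1 <- 0; s2 <- 0; r1 <- 0; r2 <- 0
    for (i in seq_along(keep)) {
      mom <- conditional_moments(
        sufficient_stats(t, lev$alpha[keep[i]], dataset, specs[[t]]))
      b1 <- b1 + w[i] * mom$beta_mean
      b2 <- b2 + w[i] * (mom$beta_cov + tcrossprod(mom$beta_mean))
      s1 <- s1 + w[i] * mom$sigma_mean
      s2 <- s2 + w[i] * mom$sigma_sq_mean
      r1 <- r1 + w[i] * mom$rho_mean
      r2 <- r2 + w[i] * mom$rho_sq_mean
    }
    beta_sd <- sqrt(pmax(diag(b2) - b1^2, 0))
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = sprintf("beta%d(%d)", t, seq_len(nb)),
      level = t, mean = b1, sd = beta_sd)
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = sprintf("sigma%d", t), level = t, mean = s1,
      sd = sqrt(max(s2 - s1^2, 0)))
    if (t > 1L) {
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = sprintf("rho%d", t - 1L), level = t, mean = r1,
        sd = sqrt(max(r2 - r1^2, 0)))
    }
    asum <- posterior_summary(post)
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = sprintf("alpha%d", t), level = t,
      mean = asum$mean[t], sd = asum$sd[t])
  }
  structure(list(dataset = dataset, specs = specs, post = post,
                 summary = do.call(rbind, rows),
                 log_evidence = post$log_evidence),
            class = "mufi_fit")
}

#' @export
print.mufi_fit <- function(x, ...) {
  cat(sprintf("Bayesian multi-fidelity GP fit: %d level(s)\n",
              x$dataset$n_levels))
  scalars <- x$summary[!grepl("^beta", x$summary$parameter), ]
  print(scalars, row.names = FALSE, digits = 4)
  cat(sprintf("total log evidence: %.4f\n", x$log_evidence))
  invisible(x)
}

#' Predict from a fitted multi-fidelity model
#'
#' @param object a [mufi_fit()].
#' @param x_query query points (vector or matrix, original coordinates).
#' @param k credible-band half-width in standard deviations.
#' @param ... unused.
#' @return a `mufi_prediction` (see [predict_moments()]) whose
#'   `band` element holds the `k`-sd [credible_band()].
#' @export
predict.mufi_fit <- function(object, x_query, k = 1, ...) {
  pred <- predict_moments(object$dataset, object$specs, object$post, x_query)
  pred$band <- credible_band(pred, k = k)
  pred
}
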