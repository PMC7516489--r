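#' Truth parameters of the generative multi-fidelity model
#'
#' @param levels list with one entry per level, each a list with `beta`
#'   (trend coefficients), `sigma` (positive process scale), `alpha`
#'   (positive kernel hyperparameter) and, for levels above the first,
#'   `rho` (coupling to the previous level).
#' @return object of class `truth_params`.
#' @export
truth_params <- function(levels) {
  for (t in seq_along(levels)) {
    l <- levels[[t]]
    if (l$sigma <= 0 || l$alpha <= 0) {
      stop("sigma and alpha truth values must be positive", call. = FALSE)
    }
    if (t > 1L && is.null(l$rho)) {
      stop(sprintf("level %d needs a rho truth value", t), call. = FALSE)
    }
  }
  structure(list(levels = levels), class = "truth_params")
}

#' Simulate a nested multi-fidelity dataset from known truth
#'
#' Draws each difference process jointly at the union of all pivot sets
#' (plus optional evaluation points) from its multivariate normal law with
#' Legendre trend mean and squared-exponential covariance, then composes
#' the fidelity levels through the autoregressive recursion
#' \eqn{z_1 = \delta_1}, \eqn{z_t = \rho_{t-1} z_{t-1} + \delta_t}. All
#' randomness flows from the single `seed` through per-level derived
#' streams, so identical seeds give identical datasets and each level's
#' draw is reproducible independently.
#'
#' @param truth a [truth_params()].
#' @param pivots list of per-level pivot matrices/vectors (nested).
#' @param seed integer seed; required, there is no unseeded path.
#' @param domain modelling domain (default: bounding box of level-1
#'   pivots).
#' @param x_eval optional extra points at which the true (noise-free in the
#'   observation sense, but random) level curves are recorded.
#' @param sim_jitter diagonal nugget of the generative correlation matrix;
#'   the default equals the analysis-side default of [kernel_spec()], so the
#'   generative model and the fitted model are the same model and recovery
#'   studies are internally consistent.
#' @return a [mufi_dataset()]; when `x_eval` is given, attribute
#'   `truth_curves` holds a matrix of the simulated \eqn{z_t} at `x_eval`
#'   (one column per level) and attribute `truth` the generating
#'   parameters.
#' @export
simulate_mufi <- function(truth, pivots, seed, domain = NULL, x_eval = NULL,
                          sim_jitter = 1e-8) {
  stopifnot(inherits(truth, "truth_params"))
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  pivots <- lapply(pivots, as_points)
  nt <- length(pivots)
  if (nt != length(truth$levels)) {
    stop("pivots and truth must have the same number of levels", call. = FALSE)
  }
  if (is.null(domain)) {
    domain <- make_domain(apply(pivots[[1L]], 2L, min),
                          apply(pivots[[1L]], 2L, max))
  } else {
    domain <- make_domain(domain$lower, domain$upper)
  }
  xe <- if (is.null(x_eval)) NULL else as_points(x_eval)
  # evaluation grid: all pivots plus x_eval, deduplicated
  U_all <- do.call(rbind, c(pivots, list(xe)))
  uu <- rescale_points(U_all, domain)
  keep <- !duplicated(round(uu / 1e-9) * 1e-9)
  X <- U_all[keep, , drop = FALSE]
  U <- uu[keep, , drop = FALSE]
  idx_of <- function(p) {
    i <- match_points(rescale_points(p, domain), U, tol = 1e-9)
    if (anyNA(i)) stop("internal: point lookup failed", call. = FALSE)
    i
  }
  piv_idx <- lapply(pivots, idx_of)
  for (t in seq_len(nt)[-1L]) {
    if (!all(piv_idx[[t]] %in% piv_idx[[t - 1L]])) {
      stop(sprintf("pivots of level %d are not nested in level %d", t, t - 1L),
           call. = FALSE)
    }
  }
  z <- matrix(0, nrow(X), nt)
  for (t in seq_len(nt)) {
    lt <- truth$levels[[t]]
    basis <- mean_basis(length(lt$beta), domain$lower, domain$upper)
    mu <- drop(legendre_design_matrix(X, basis, extrapolation_tol = Inf) %*%
                 lt$beta)
    K <- kernel_matrix(U, alpha = lt$alpha,
                       spec = kernel_spec(jitter = sim_jitter))
    R <- chol_with_retry(K, sim_jitter)$R
    set.seed(split_seed(seed, t))
    delta <- mu + lt$sigma * drop(crossprod(R, stats::rnorm(nrow(X))))
    z[, t] <- if (t == 1L) delta else lt$rho * z[, t - 1L] + delta
  }
  ds <- mufi_dataset(lapply(seq_len(nt), function(t)
    list(x = X[piv_idx[[t]], , drop = FALSE], z = z[piv_idx[[t]], t])),
    domain = domain)
  if (!is.null(xe)) {
    attr(ds, "truth_curves") <- z[idx_of(xe), , drop = FALSE]
  }
  attr(ds, "truth") <- truth
  ds
}

#' Two-level mock-data scenario with known truth
#'
#' The reference recovery scenario: two nested levels on \eqn{[-1, 1]},
#' Legendre trends of orders 10 and 4 (i.e. 10 and 4 basis functions),
#' squared-exponential kernels, truth values
#' \eqn{\sigma = (0.1, 0.01)}, \eqn{\rho_1 = 3},
#' \eqn{\alpha = (10.1, 20.1)}, 11 level-2 pivots nested in 41 equispaced
#' level-1 pivots (the level-1 count is this package's choice, dense enough
#' that a 10-function trend is admissible with margin), and generous
#' hyperparameter-prior bounds.
#'
#' @param n_lofi number of equispaced level-1 pivots (default 41; the 11
#'   level-2 pivots are every 4th of them).
#' @return list with `truth`, `pivots`, `domain` and ready-to-fit `specs`.
#' @export
mock_scenario <- function(n_lofi = 41L) {
  beta1 <- c(0.32, -0.40, 0.1, 0.35, -0.51, 0.33, -0.034, -0.142,
             0.1750, -0.1034)
  beta2 <- c(1 / 3, 0.15, 1 / 60, 0)
  truth <- truth_params(list(
    list(beta = beta1, sigma = 0.1, alpha = 10.1),
    list(beta = beta2, sigma = 0.01, alpha = 20.1, rho = 3)))
  x1 <- seq(-1, 1, length.out = n_lofi)
  stride <- max(1L, (n_lofi - 1L) %/% 10L)
  x2 <- x1[seq(1L, by = stride, length.out = 11L)]
  specs <- list(
    level_spec(mean_order = 10L, alpha_bounds = c(1, 40)),
    level_spec(mean_order = 4L, alpha_bounds = c(1, 40)))
  list(truth = truth, pivots = list(x1, x2),
       domain = list(lower = -1, upper = 1), specs = specs)
}

#' Synthetic impedance-cardiography-shaped fixture
#'
#' A purely synthetic stand-in for finite-element admittance simulations of
#' one cardiac cycle: smooth admittance-like time series (slowly varying
#' baseline plus a systolic pulse bump) over a 2-D input (time in seconds
#' over one cycle, dissection radius in mm), generated by [simulate_mufi()]
#' with a configured truth. Shapes follow the motivating application: 24
#' low-fidelity radii (1-24 mm) with 21 time pivots each, and 3
#' high-fidelity radii (5, 11, 18 mm) with 11 time pivots each, nested in
#' the low-fidelity grid. This mimics data shapes and smoothness only, not
#' electrophysics.
#'
#' @param seed integer seed.
#' @return a [mufi_dataset()] with 504 low-fidelity and 33 high-fidelity
#'   rows; attribute `heldout_query` holds the held-out high-fidelity query
#'   points (all 21 cycle times at three radii without any high-fidelity
#'   data), and attribute `fit_specs` admissible ready-to-fit level
#'   specifications.
#' @export
icg_fixture <- function(seed) {
  times_lo <- seq(0, 1, length.out = 21L)
  times_hi <- times_lo[seq(1L, 21L, by = 2L)]
  radii_lo <- 1:24
  radii_hi <- c(5, 11, 18)
  grid <- function(tt, rr) as.matrix(expand.grid(x1 = tt, x2 = rr))
  # trend coefficients on the (total degree, lex)-ordered 2-D Legendre basis
  # (0,0) (0,1) (1,0) (0,2) (1,1) (2,0) (0,3) (1,2) (2,1) (3,0); x1 = time.
  # Baseline admittance ~0.03 1/Ohm with a systolic bump and a radius trend;
  # the GP part carries pulse-shape structure that a 3-radius design cannot
  # resolve on its own (the regime the application lives in).
  beta1 <- c(0.030, 0.0030, -0.0040, -0.0008, -0.0010, -0.0060,
             0, 0, 0.0008, 0.0015)
  beta2 <- c(0.0020, -0.0005, 0.0004, 0)
  truth <- truth_params(list(
    list(beta = beta1, sigma = 0.004, alpha = 20),
    list(beta = beta2, sigma = 2e-4, alpha = 6, rho = 0.9)))
  ds <- simulate_mufi(
    truth,
    pivots = list(grid(times_lo, radii_lo), grid(times_hi, radii_hi)),
    seed = seed,
    domain = list(lower = c(0, 1), upper = c(1, 24)))
  attr(ds, "heldout_query") <- grid(times_lo, c(8, 14, 21))
  attr(ds, "fit_specs") <- list(
    level_spec(3L, alpha_bounds = c(0.5, 60)),
    level_spec(6L, alpha_bounds = c(0.5, 60)))
  ds
}
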