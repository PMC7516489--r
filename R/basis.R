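#' Legendre mean-function basis
#'
#' Constructs the parametric trend basis of one fidelity level: Legendre
#' polynomials \eqn{P_0, P_1, \dots} evaluated after an affine map of the
#' modelling domain onto \eqn{[-1, 1]} per input dimension. "Order n" means
#' n basis functions, i.e. degrees 0 to n-1 in one dimension. For
#' multi-dimensional inputs the basis is the tensor product truncated by
#' total degree, with columns ordered by (total degree, lexicographic
#' multi-index) so the ordering is deterministic; column 1 is always the
#' constant polynomial.
#'
#' @param n_functions number of basis functions (\eqn{N_\beta \ge 1}).
#' @param domain_low,domain_high numeric vectors, one entry per input
#'   dimension, with `domain_low < domain_high` elementwise.
#' @param degree_rule maximum total degree for multi-dimensional truncation;
#'   defaults to the smallest total degree admitting `n_functions` columns.
#' @return an object of class `mean_basis`.
#' @export
mean_basis <- function(n_functions, domain_low = -1, domain_high = 1,
                       degree_rule = NULL) {
  n_functions <- as.integer(n_functions)
  if (n_functions < 1L) stop("n_functions must be >= 1", call. = FALSE)
  domain <- make_domain(domain_low, domain_high)
  d <- length(domain$lower)
  if (is.null(degree_rule)) {
    degree_rule <- 0L
    while (choose(degree_rule + d, d) < n_functions) degree_rule <- degree_rule + 1L
  }
  idx <- total_degree_indices(d, degree_rule)
  if (nrow(idx) < n_functions) {
    stop(sprintf(
      "n_functions = %d exceeds the %d total-degree-%d combinations available",
      n_functions, nrow(idx), degree_rule), call. = FALSE)
  }
  structure(list(n_functions = n_functions, domain = domain,
                 degree_rule = as.integer(degree_rule),
                 indices = idx[seq_len(n_functions), , drop = FALSE]),
            class = "mean_basis")
}

# all multi-indices with total degree <= dmax, ordered by
# (total degree, lexicographic on the index vector)
total_degree_indices <- function(d, dmax) {
  grids <- replicate(d, 0:dmax, simplify = FALSE)
  idx <- as.matrix(do.call(expand.grid, grids))
  colnames(idx) <- NULL
  idx <- idx[rowSums(idx) <= dmax, , drop = FALSE]
  ord <- do.call(order, c(list(rowSums(idx)),
                          lapply(seq_len(d), function(j) idx[, j])))
  idx[ord, , drop = FALSE]
}

# P_0 .. P_{nmax-1} at u (vector in [-1,1]) via the three-term recurrence
legendre_values <- function(u, nmax) {
  out <- matrix(0, length(u), nmax)
  out[, 1L] <- 1
  if (nmax >= 2L) out[, 2L] <- u
  if (nmax >= 3L) {
    for (n in 1L:(nmax - 2L)) {
      out[, n + 2L] <- ((2 * n + 1) * u * out[, n + 1L] - n * out[, n]) / (n + 1)
    }
  }
  out
}

#' Design matrix of a Legendre mean basis
#'
#' Evaluates every basis function of a [mean_basis()] at a set of input
#' points: entry (j, k) is the k-th basis polynomial at the affinely mapped
#' j-th point.
#'
#' @param x input points: a numeric vector (1-D) or a matrix with points in
#'   rows.
#' @param basis a [mean_basis()].
#' @param extrapolation_tol fraction of the mapped domain half-width by which
#'   points may lie outside \eqn{[-1,1]}; beyond a tiny numerical tolerance a
#'   warning is raised, beyond `extrapolation_tol` an error.
#' @return numeric matrix, `nrow(x)` by `basis$n_functions`.
#' @export
legendre_design_matrix <- function(x, basis, extrapolation_tol = 1e-8) {
  stopifnot(inherits(basis, "mean_basis"))
  u <- rescale_points(x, basis$domain)
  over <- max(abs(u)) - 1
  if (over > extrapolation_tol) {
    stop(sprintf("point(s) outside the basis domain by %.3g (mapped units)",
                 over), call. = FALSE)
  }
  dmax <- max(basis$indices)
  P <- lapply(seq_len(ncol(u)), function(j) legendre_values(u[, j], dmax + 1L))
  H <- matrix(1, nrow(u), basis$n_functions)
  for (k in seq_len(basis$n_functions)) {
    for (j in seq_len(ncol(u))) {
      H[, k] <- H[, k] * P[[j]][, basis$indices[k, j] + 1L]
    }
  }
  H
}
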