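#' Covariance kernel specification
#'
#' The per-level covariance kernel. Only the isotropic squared-exponential
#' kernel is provided: \eqn{k(x, x') = \exp(-\alpha \, \|x - x'\|^2)} on
#' domain-rescaled coordinates (each input dimension affinely mapped to
#' \eqn{[-1, 1]}), so the single hyperparameter \eqn{\alpha} is the inverse
#' of the squared correlation length; there is no factor 1/2 in the
#' exponent. The jitter is added to the diagonal of square Gram matrices for
#' conditioning and should sit several orders of magnitude below the
#' conditional process variance.
#'
#' @param kind kernel identifier; only `"squared_exponential"`.
#' @param alpha_dim number of kernel hyperparameters (1 for isotropic SE).
#' @param jitter nonnegative diagonal nugget added to square Gram matrices.
#' @return an object of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = "squared_exponential", alpha_dim = 1L,
                        jitter = 1e-8) {
  kind <- match.arg(kind, "squared_exponential")
  if (jitter < 0) stop("jitter must be >= 0", call. = FALSE)
  if (alpha_dim != 1L) {
    stop("only the isotropic squared-exponential kernel (alpha_dim = 1) is supported",
         call. = FALSE)
  }
  structure(list(kind = kind, alpha_dim = 1L, jitter = as.numeric(jitter)),
            class = "kernel_spec")
}

#' Kernel Gram / cross-covariance matrix
#'
#' Evaluates the squared-exponential kernel between two point sets on
#' domain-rescaled coordinates. When `x2` is omitted the square Gram matrix
#' on `x` is returned with `spec$jitter` added to its diagonal.
#'
#' @param x,x2 input points (vectors or matrices, points in rows), already on
#'   the rescaled \eqn{[-1,1]} scale.
#' @param alpha positive kernel hyperparameter (inverse squared correlation
#'   length).
#' @param spec a [kernel_spec()].
#' @return numeric matrix `nrow(x)` by `nrow(x2)`.
#' @export
kernel_matrix <- function(x, x2 = NULL, alpha, spec = kernel_spec()) {
  if (!all(is.finite(alpha)) || any(alpha <= 0)) {
    stop("kernel hyperparameter alpha must be strictly positive", call. = FALSE)
  }
  u <- as_points(x)
  square <- is.null(x2)
  v <- if (square) u else as_points(x2)
  d2 <- outer(rowSums(u^2), rowSums(v^2), "+") - 2 * tcrossprod(u, v)
  d2[d2 < 0] <- 0
  K <- exp(-alpha[1L] * d2)
  if (square && spec$jitter > 0) K <- K + diag(spec$jitter, nrow(u))
  K
}

# Cholesky with one automatic retry at 10x jitter; returns upper factor R
# with K = R'R and the jitter actually used
chol_with_retry <- function(K, jitter) {
  R <- tryCatch(chol(K), error = function(e) NULL)
  if (!is.null(R)) return(list(R = R, jitter = jitter, escalated = FALSE))
  bump <- if (jitter > 0) 9 * jitter else 1e-10 * mean(diag(K))
  R <- tryCatch(chol(K + diag(bump, nrow(K))), error = function(e) NULL)
  if (is.null(R)) {
    stop("Gram matrix is not positive definite even after jitter escalation",
         call. = FALSE)
  }
  list(R = R, jitter = jitter + bump, escalated = TRUE)
}
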