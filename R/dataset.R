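#' Per-level modelling choices
#'
#' @param mean_order number of Legendre mean-basis functions \eqn{N_\beta}
#'   (degrees 0 to `mean_order - 1` in one dimension).
#' @param kernel kernel identifier, see [kernel_spec()].
#' @param alpha_bounds length-2 positive vector: truncation bounds of the
#'   hyperparameter prior / integration range. Required before fitting; there
#'   is no silent default.
#' @param jitter diagonal nugget on the unit-diagonal correlation matrix;
#'   `NULL` selects 1e-8, i.e. an effective nugget of `1e-8 * sigma_t^2` in
#'   covariance units.
#' @param alpha_prior `"jeffreys"` (1/alpha, truncated) or `"flat"`.
#' @return an object of class `level_spec`.
#' @export
level_spec <- function(mean_order, kernel = "squared_exponential",
                       alpha_bounds = NULL, jitter = NULL,
                       alpha_prior = c("jeffreys", "flat")) {
  mean_order <- as.integer(mean_order)
  if (mean_order < 1L) stop("mean_order must be >= 1", call. = FALSE)
  if (!is.null(alpha_bounds)) {
    alpha_bounds <- as.numeric(alpha_bounds)
    if (length(alpha_bounds) != 2L || any(alpha_bounds <= 0) ||
        alpha_bounds[1L] >= alpha_bounds[2L]) {
      stop("alpha_bounds must be positive with alpha_bounds[1] < alpha_bounds[2]",
           call. = FALSE)
    }
  }
  structure(list(mean_order = mean_order, kernel = kernel,
                 alpha_bounds = alpha_bounds, jitter = jitter,
                 alpha_prior = match.arg(alpha_prior)),
            class = "level_spec")
}

#' Multi-fidelity dataset on a nested design
#'
#' Bundles per-level input locations and simulator outputs into the triples
#' \eqn{D_t = (x_t, z_t(x_t), z_{t-1}(x_t))}. Level 1 is the lowest
#' fidelity. The design must be nested: every pivot of level t must appear
#' (within `tol` on rescaled coordinates) among the pivots of level t-1, so
#' the previous-level outputs `z_prev` are derived internally and never
#' supplied.
#'
#' @param levels list with one entry per fidelity level, each a list with
#'   elements `x` (vector or matrix of input locations, points in rows) and
#'   `z` (numeric output vector).
#' @param domain optional list with `lower`/`upper` per input dimension; by
#'   default the bounding box of the level-1 pivots.
#' @param tol absolute pivot-matching tolerance on rescaled coordinates.
#' @return an object of class `mufi_data`.
#' @export
mufi_dataset <- function(levels, domain = NULL, tol = 1e-9) {
  if (length(levels) < 1L) stop("at least one level is required", call. = FALSE)
  xs <- lapply(levels, function(l) as_points(l$x))
  zs <- lapply(levels, function(l) as.numeric(l$z))
  d <- ncol(xs[[1L]])
  for (t in seq_along(levels)) {
    if (ncol(xs[[t]]) != d) {
      stop("all levels must share the input dimensionality", call. = FALSE)
    }
    if (length(zs[[t]]) != nrow(xs[[t]])) {
      stop(sprintf("level %d: length(z) != number of pivot points", t),
           call. = FALSE)
    }
    if (!all(is.finite(zs[[t]]))) {
      stop(sprintf("level %d: outputs must be finite", t), call. = FALSE)
    }
  }
  if (is.null(domain)) {
    domain <- make_domain(apply(xs[[1L]], 2L, min), apply(xs[[1L]], 2L, max))
  } else {
    domain <- make_domain(domain$lower, domain$upper)
  }
  us <- lapply(xs, rescale_points, domain = domain)
  parent_idx <- vector("list", length(levels))
  z_prev <- vector("list", length(levels))
  for (t in seq_along(levels)) {
    dup <- match_points(us[[t]], us[[t]], tol = tol)
    if (any(dup != seq_len(nrow(us[[t]])))) {
      stop(sprintf("level %d: duplicate pivot points (rows %s)", t,
                   paste(which(dup != seq_len(nrow(us[[t]]))), collapse = ", ")),
           call. = FALSE)
    }
    if (t == 1L) {
      z_prev[[t]] <- numeric(0)
      next
    }
    idx <- match_points(us[[t]], us[[t - 1L]], tol = tol)
    if (anyNA(idx)) {
      bad <- which(is.na(idx))[1L]
      stop(sprintf(
        "broken nesting: level %d pivot (%s) has no match in level %d",
        t, paste(signif(xs[[t]][bad, ], 6), collapse = ", "), t - 1L),
        call. = FALSE)
    }
    parent_idx[[t]] <- idx
    z_prev[[t]] <- zs[[t - 1L]][idx]
  }
  structure(list(n_levels = length(levels), x = xs, u = us, z = zs,
                 z_prev = z_prev, parent_idx = parent_idx, domain = domain,
                 tol = tol),
            class = "mufi_data")
}

#' @export
print.mufi_data <- function(x, ...) {
  cat(sprintf("Multi-fidelity dataset: %d level(s), %d input dimension(s)\n",
              x$n_levels, ncol(x$x[[1L]])))
  for (t in seq_len(x$n_levels)) {
    cat(sprintf("  level %d: %d pivot points\n", t, nrow(x$x[[t]])))
  }
  invisible(x)
}

#' Read / write the dataset CSV interchange format
#'
#' Columns: `level` (integer, 1 = lowest fidelity), one column per input
#' dimension (`x1`, `x2`, ...; a single `x` column is also accepted), and
#' `z`.
#'
#' @param path CSV file path.
#' @param domain,tol passed to [mufi_dataset()].
#' @return a `mufi_data` object.
#' @export
read_mufi_csv <- function(path, domain = NULL, tol = 1e-9) {
  df <- utils::read.csv(path)
  if (!all(c("level", "z") %in% names(df))) {
    stop("dataset CSV needs 'level' and 'z' columns", call. = FALSE)
  }
  xcols <- grep("^x[0-9]*$", names(df), value = TRUE)
  if (length(xcols) == 0L) stop("dataset CSV needs x1, x2, ... columns",
                                call. = FALSE)
  xcols <- xcols[order(nchar(xcols), xcols)]
  lev <- sort(unique(df$level))
  if (!identical(as.integer(lev), seq_along(lev))) {
    stop("levels must be contiguous integers starting at 1", call. = FALSE)
  }
  levels <- lapply(lev, function(t) {
    sub <- df[df$level == t, , drop = FALSE]
    list(x = as.matrix(sub[, xcols, drop = FALSE]), z = sub$z)
  })
  mufi_dataset(levels, domain = domain, tol = tol)
}

#' @rdname read_mufi_csv
#' @param dataset a `mufi_data` object.
#' @export
write_mufi_csv <- function(dataset, path) {
  rows <- lapply(seq_len(dataset$n_levels), function(t) {
    x <- dataset$x[[t]]
    colnames(x) <- paste0("x", seq_len(ncol(x)))
    data.frame(level = t, x, z = dataset$z[[t]])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Validate a nested multi-fidelity design against the model constraints
#'
#' Confirms nesting, absence of duplicate pivots, and the admissibility
#' constraint on the trend order at every level: \eqn{N_{\beta 1} < N_{x1} -
#' 2} on level 1 and \eqn{N_{\beta t} < N_{xt} - 3} above, without which the
#' second moments of the process scale \eqn{\sigma_t} are not defined. Also
#' reports the maximum admissible number of mean-basis functions per level.
#'
#' @param dataset a [mufi_dataset()].
#' @param specs list of [level_spec()], one per level.
#' @return the dataset, invisibly augmented with attribute
#'   `max_admissible` (integer per level).
#' @export
validate_design <- function(dataset, specs) {
  stopifnot(inherits(dataset, "mufi_data"))
  if (length(specs) != dataset$n_levels) {
    stop("need one level_spec per level", call. = FALSE)
  }
  max_adm <- integer(dataset$n_levels)
  for (t in seq_len(dataset$n_levels)) {
    n_x <- nrow(dataset$x[[t]])
    n_b <- specs[[t]]$mean_order
    bound <- if (t == 1L) n_x - 2L else n_x - 3L
    max_adm[t] <- bound - 1L
    if (n_b >= bound) {
      stop(sprintf(
        paste0("level %d: mean_order %d violates the admissibility constraint ",
               "N_beta %s (the second moments of sigma_t are not defined); ",
               "maximum admissible mean_order is %d"),
        t, n_b, if (t == 1L) sprintf("< N_x - 2 = %d", bound)
        else sprintf("< N_x - 3 = %d", bound), max_adm[t]),
        call. = FALSE)
    }
  }
  attr(dataset, "max_admissible") <- max_adm
  invisible(dataset)
}
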