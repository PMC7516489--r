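# numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# coerce input locations to a numeric matrix (points in rows)
as_points <- function(x) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 1L)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  if (!all(is.finite(x))) stop("input points must be finite", call. = FALSE)
  x
}

# affine map of each input dimension onto [-1, 1]
rescale_points <- function(x, domain) {
  x <- as_points(x)
  lo <- domain$lower
  hi <- domain$upper
  if (length(lo) != ncol(x)) {
    stop(sprintf("domain has %d dimension(s) but points have %d",
                 length(lo), ncol(x)), call. = FALSE)
  }
  sweep(sweep(x, 2L, lo), 2L, (hi - lo) / 2, "/") - 1
}

make_domain <- function(lower, upper) {
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  if (length(lower) != length(upper)) {
    stop("domain lower/upper must have the same length", call. = FALSE)
  }
  if (!all(lower < upper)) {
    stop("domain must satisfy lower < upper elementwise", call. = FALSE)
  }
  list(lower = lower, upper = upper)
}

# row index of each point of `child` inside `parent` (both on rescaled
# coordinates), NA where no match within the absolute tolerance
match_points <- function(child, parent, tol = 1e-9) {
  vapply(seq_len(nrow(child)), function(i) {
    d <- abs(sweep(parent, 2L, child[i, ], "-"))
    hit <- which(apply(d, 1L, max) <= tol)
    if (length(hit) == 0L) NA_integer_ else hit[1L]
  }, integer(1L))
}

# derive a per-level seed from a single run seed; kept below 2^31
split_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(stream)) %% 2147483629
}
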