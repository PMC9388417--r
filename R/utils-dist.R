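# Small categorical/Dirichlet utilities shared by the model builders and the
# inference engine. Probabilities are floored at .p_floor inside logarithms.

.p_floor <- 1e-16

.logp <- function(p) log(pmax(p, .p_floor))

#' Normalize nonnegative counts into a probability table
#'
#' Columns (or a bare vector) of nonnegative concentration counts are divided
#' by their sums, yielding categorical distributions. Proportionality within a
#' column is preserved.
#'
#' @param counts A nonnegative numeric vector, matrix, or array. For matrices
#'   and arrays the first dimension indexes outcomes and every remaining
#'   dimension combination is treated as one column.
#' @return An object of the same shape with every column summing to 1.
#' @examples
#' normalize_counts(c(2, 2))
#' normalize_counts(matrix(c(41, 11, 1, 0), nrow = 2))
#' @export
normalize_counts <- function(counts) {
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and nonnegative")
  }
  if (is.null(dim(counts))) {
    s <- sum(counts)
    if (s <= 0) stop("all-zero column: 1")
    return(counts / s)
  }
  d <- dim(counts)
  m <- matrix(counts, nrow = d[1L])
  s <- colSums(m)
  bad <- which(s <= 0)
  if (length(bad)) {
    stop(sprintf("all-zero column: %s", paste(bad, collapse = ", ")))
  }
  out <- sweep(m, 2L, s, "/")
  dim(out) <- d
  dimnames(out) <- dimnames(counts)
  out
}

#' Expected log-probabilities under a Dirichlet distribution
#'
#' Returns `digamma(count) - digamma(column sum)` per entry, the expectation
#' of the log categorical parameter under Dirichlet-distributed beliefs with
#' the given concentration counts. As counts grow the exponentiated,
#' renormalized result converges to [normalize_counts()].
#'
#' @param counts Strictly positive numeric vector, matrix, or array of
#'   concentration counts (first dimension = outcomes).
#' @return Same shape as `counts`, entries are expected log-probabilities.
#' @export
dirichlet_expected_log <- function(counts) {
  if (any(!is.finite(counts)) || any(counts <= 0)) {
    stop("counts must be strictly positive")
  }
  if (is.null(dim(counts))) {
    return(digamma(counts) - digamma(sum(counts)))
  }
  d <- dim(counts)
  m <- matrix(counts, nrow = d[1L])
  out <- digamma(m) - rep(digamma(colSums(m)), each = d[1L])
  dim(out) <- d
  dimnames(out) <- dimnames(counts)
  out
}

#' Softmax of a numeric vector
#'
#' @param x Finite numeric vector (log-weights).
#' @return Probability vector proportional to `exp(x)`.
#' @export
softmax <- function(x) {
  stopifnot(all(is.finite(x)))
  e <- exp(x - max(x))
  e / sum(e)
}

# KL(p || q) for categorical vectors; q floored inside the log.
.kl_div <- function(p, q) {
  d <- p * (.logp(p) - .logp(q))
  sum(d[p > 0])
}

# Shannon entropy in nats.
.entropy <- function(p) {
  -sum((p * .logp(p))[p > 0])
}

# Validate a categorical distribution to tolerance 1e-10.
.check_dist <- function(p, what = "distribution", tol = 1e-10) {
  if (any(p < -tol) || abs(sum(p) - 1) > tol) {
    stop(sprintf("%s is not a valid categorical distribution", what))
  }
  invisible(TRUE)
}
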