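#' @keywords internal
"_PACKAGE"

## Numerical primitives shared by every module.  Probabilities live on the
## simplex; log-space quantities are floored so that messages stay finite.

LOG_FLOOR <- 1e-16

#' Floored natural logarithm
#'
#' Computes \code{ln(max(x, 1e-16))} elementwise.  Zero probabilities are
#' legitimate in deterministic likelihood/transition arrays; the floor keeps
#' log-space messages finite without materially perturbing beliefs.
#'
#' @param x numeric vector, matrix or array of non-negative values.
#' @return object of the same shape with floored logarithms.
#' @export
log_floor <- function(x) log(pmax(x, LOG_FLOOR))

#' Softmax over a numeric vector
#'
#' @param x numeric vector of log-space values (nats).
#' @return probability vector summing to one.
#' @export
softmax <- function(x) {
  x <- x - max(x)
  e <- exp(x)
  e / sum(e)
}

#' Normalize a non-negative vector (or each column of a matrix) to sum to one
#'
#' Columns that sum to zero are replaced by uniform distributions.
#'
#' @param x non-negative vector or matrix.
#' @return normalized object of the same shape.
#' @export
norm_dist <- function(x) {
  if (is.matrix(x)) {
    s <- colSums(x)
    zero <- s <= 0
    if (any(zero)) {
      x[, zero] <- 1
      s[zero] <- nrow(x)
    }
    sweep(x, 2, s, "/")
  } else {
    s <- sum(x)
    if (s <= 0) rep(1 / length(x), length(x)) else x / s
  }
}

#' Shannon entropy of a categorical distribution
#'
#' Returns \eqn{-\sum_i p_i \ln p_i} in nats with the convention
#' \eqn{0 \ln 0 = 0}.
#'
#' @param p probability vector.
#' @param validate check that \code{p} is a valid distribution first.
#' @return entropy in nats, in \code{[0, ln(length(p))]}.
#' @export
entropy_cat <- function(p, validate = TRUE) {
  if (validate) assert_dist(p, "p")
  nz <- p > 0
  -sum(p[nz] * log(p[nz]))
}

## internal: columnwise softmax of a matrix of log-space values; a single
## global shift suffices numerically because message magnitudes are bounded
## by the log floor
col_softmax <- function(m) {
  e <- exp(m - max(m))
  s <- colSums(e)
  if (any(s <= 0)) {
    bad <- s <= 0
    e[, bad] <- exp(sweep(m[, bad, drop = FALSE], 2,
                          apply(m[, bad, drop = FALSE], 2, max)))
    s <- colSums(e)
  }
  e * rep(1 / s, each = nrow(m))
}

## internal: stop unless p is a probability vector
assert_dist <- function(p, name = "distribution", tol = 1e-8) {
  if (!is.numeric(p) || length(p) < 1L)
    stop(name, " must be a numeric vector", call. = FALSE)
  if (any(p < -tol))
    stop(name, " has negative entries", call. = FALSE)
  if (abs(sum(p) - 1) > tol)
    stop(name, " does not sum to 1 (sum = ", format(sum(p)), ")",
         call. = FALSE)
  invisible(TRUE)
}

## internal: outer product of a list of per-factor belief vectors, as a
## vector over joint state combinations (first factor varies fastest).
joint_from_factors <- function(slist) {
  q <- slist[[1]]
  if (length(slist) > 1L)
    for (f in 2:length(slist)) q <- as.vector(outer(q, slist[[f]]))
  q
}

## internal: contract an array over all factor dimensions except `keep`,
## weighting by the belief vectors in `slist` (slist[[keep]] ignored).
## `arr` has dim c(n1, ..., nF) (a slice of A for a fixed outcome, or a
## log-likelihood slice); returns a vector of length n_keep:
##   out[i] = sum over the other factors of arr[..., i, ...] * prod_g s_g
contract_except <- function(arr, slist, keep) {
  nf <- length(slist)
  if (nf == 1L) return(as.vector(arr))
  d <- vapply(slist, length, 1L)
  a <- array(arr, dim = d)
  others <- seq_len(nf)[-keep]
  m <- matrix(aperm(a, c(keep, others)), nrow = d[keep])
  w <- joint_from_factors(slist[others])
  as.vector(m %*% w)
}
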