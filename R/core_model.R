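## Categorical generative-model containers for one MDP level and for
## two-level hierarchies.
##
## A level holds, per outcome modality g and hidden-state factor f:
##   A[[g]] : likelihood array, dim c(n_outcomes[g], n_states[1..F])
##   B[[f]] : transition array, dim c(n_states[f], n_states[f], n_actions[f])
##   C[[g]] : log-preference vector over outcomes (natural-log units)
##   D[[f]] : prior over initial states
## plus a policy set and a horizon.  Posteriors over factors are factorised
## (mean field); factor beliefs are combined multiplicatively inside A.

#' Construct a single-level categorical generative model
#'
#' @param A list of likelihood arrays, one per outcome modality; each has
#'   dimension \code{c(n_outcomes, n_states_1, ..., n_states_F)} and every
#'   column (fixed state combination) is a probability distribution over
#'   outcomes.
#' @param B list of transition arrays, one per hidden-state factor; each has
#'   dimension \code{c(n_states, n_states, n_actions)} and every column
#'   (fixed current state and action) is a distribution over next states.
#' @param C list of numeric log-preference vectors over outcomes, one per
#'   modality (need not normalise: preferences enter only through expected
#'   log-preference in the expected free energy).
#' @param D list of prior distributions over initial states, one per factor.
#' @param policies list of integer matrices, each \code{steps x F}; row k
#'   gives the action index per factor prescribed k steps ahead.  A
#'   single-row policy prescribes the same action tuple at every future step
#'   and is re-evaluated each time step ("plan as you go").
#' @param horizon number of time steps the level spans.
#' @param labels optional list with character vectors \code{states} (per
#'   factor), \code{outcomes} (per modality), \code{actions} (per factor).
#' @return an object of class \code{"generative_level"}.
#' @seealso [validate_level()]
#' @export
generative_level <- function(A, B, C = NULL, D, policies, horizon,
                             labels = NULL) {
  if (!is.list(A)) A <- list(A)
  if (!is.list(B)) B <- list(B)
  if (!is.list(D)) D <- list(D)
  A <- lapply(A, function(a) if (is.null(dim(a))) matrix(a, nrow = length(a)) else a)
  B <- lapply(B, function(b) if (length(dim(b)) == 2L) array(b, c(dim(b), 1L)) else b)
  if (is.null(C)) C <- lapply(A, function(a) rep(0, dim(a)[1]))
  if (!is.list(C)) C <- list(C)
  if (is.matrix(policies)) policies <- list(policies)
  policies <- lapply(policies, function(p) {
    p <- as.matrix(p)
    storage.mode(p) <- "integer"
    p
  })
  lv <- structure(list(
    A = A, B = B, C = C, D = D,
    policies = policies, horizon = as.integer(horizon),
    labels = labels,
    n_states = vapply(D, length, 1L),
    n_outcomes = vapply(A, function(a) dim(a)[1], 1L),
    n_actions = vapply(B, function(b) dim(b)[3], 1L),
    n_factors = length(D), n_modalities = length(A),
    n_policies = length(policies)
  ), class = "generative_level")
  v <- validate_level(lv)
  if (length(v)) stop("invalid generative level:\n  ", paste(v, collapse = "\n  "),
                      call. = FALSE)
  lv
}

#' @export
print.generative_level <- function(x, ...) {
  cat("<generative_level> ", x$n_factors, " factor(s) [",
      paste(x$n_states, collapse = "x"), "], ", x$n_modalities,
      " modality(ies) [", paste(x$n_outcomes, collapse = ","), "], ",
      x$n_policies, " policies, horizon ", x$horizon, "\n", sep = "")
  invisible(x)
}

#' Validate a generative level
#'
#' Checks every type invariant (non-negativity, column normalisation,
#' dimension consistency, policy bounds) and reports violations instead of
#' stopping; an empty result means the level is well formed.
#'
#' @param level a [generative_level()] or a bare list with the same fields.
#' @param tol normalisation tolerance.
#' @return character vector of violation descriptions; each names the array,
#'   the offending index, and the rule broken.
#' @export
validate_level <- function(level, tol = 1e-8) {
  out <- character()
  add <- function(...) out <<- c(out, paste0(...))
  ns <- vapply(level$D, length, 1L)
  nf <- length(ns)
  for (g in seq_along(level$A)) {
    a <- level$A[[g]]
    d <- dim(a)
    if (length(d) != nf + 1L || !all(d[-1] == ns)) {
      add("A[", g, "]: dimensions (", paste(d, collapse = ","),
          ") inconsistent with state cardinalities (", paste(ns, collapse = ","), ")")
      next
    }
    if (any(a < -tol)) add("A[", g, "]: negative entries violate non-negativity")
    cs <- colSums(matrix(a, nrow = d[1]))
    bad <- which(abs(cs - 1) > tol)
    if (length(bad))
      add("A[", g, "]: column ", bad[1] - 1L, " violates normalization (sum = ",
          format(cs[bad[1]]), ")")
  }
  for (f in seq_along(level$B)) {
    b <- level$B[[f]]
    d <- dim(b)
    if (length(d) != 3L || d[1] != ns[f] || d[2] != ns[f]) {
      add("B[", f, "]: dimensions inconsistent with factor cardinality ", ns[f])
      next
    }
    if (any(b < -tol)) add("B[", f, "]: negative entries violate non-negativity")
    cs <- colSums(matrix(b, nrow = d[1]))
    bad <- which(abs(cs - 1) > tol)
    if (length(bad))
      add("B[", f, "]: column ", bad[1] - 1L, " violates normalization (sum = ",
          format(cs[bad[1]]), ")")
  }
  for (g in seq_along(level$C)) {
    if (any(!is.finite(level$C[[g]])))
      add("C[", g, "]: non-finite log-preference entries")
    if (length(level$C[[g]]) != dim(level$A[[g]])[1])
      add("C[", g, "]: length does not match outcome cardinality of modality ", g)
  }
  for (f in seq_along(level$D)) {
    d <- level$D[[f]]
    if (length(d) != ns[f])
      add("D[", f, "]: length does not match factor cardinality")
    if (any(d < -tol)) add("D[", f, "]: negative entries violate non-negativity")
    if (abs(sum(d) - 1) > tol)
      add("D[", f, "]: violates normalization (sum = ", format(sum(d)), ")")
  }
  if (length(level$policies) < 1L) add("policies: at least one policy required")
  nu <- vapply(level$B, function(b) dim(b)[3], 1L)
  for (p in seq_along(level$policies)) {
    pol <- level$policies[[p]]
    if (ncol(pol) != nf) {
      add("policy ", p, ": needs one action column per factor")
      next
    }
    if (nrow(pol) > max(1L, level$horizon - 1L))
      add("policy ", p, ": longer than level horizon allows")
    for (f in seq_len(nf))
      if (any(pol[, f] < 1L | pol[, f] > nu[f]))
        add("policy ", p, ": action index out of range for factor ", f)
  }
  out
}

#' Entropy of a transition-matrix column (volatility)
#'
#' Volatility of a hidden-state factor is the Shannon entropy of the columns
#' of its transition matrix: a deterministic (identity-like) column has zero
#' entropy and preserves beliefs, while dispersed columns erode maintained
#' representations over time.
#'
#' @param B_column a probability vector: one column of a transition matrix
#'   (fixed current state and action).
#' @return entropy in nats, in \code{[0, ln n]}.
#' @export
transition_entropy <- function(B_column) {
  assert_dist(B_column, "B column")
  entropy_cat(B_column, validate = FALSE)
}

#' Entropy of a likelihood-matrix column (sensory precision)
#'
#' The entropy of an outcome distribution conditioned on a hidden state
#' quantifies (im)precision of the sensory mapping: a zero-entropy column
#' means the state produces one and only one outcome, so a precise outcome
#' uniquely identifies its cause.
#'
#' @param A_column a probability vector: one column of a likelihood array
#'   (fixed state combination).
#' @return entropy in nats.
#' @export
likelihood_entropy <- function(A_column) {
  assert_dist(A_column, "A column")
  entropy_cat(A_column, validate = FALSE)
}

#' Banded stochastic kernel with adjustable precision
#'
#' Builds an \code{n x n} column-stochastic matrix whose columns are
#' discretised exponential-decay kernels \code{exp(-precision * d^2)} over
#' index distance \code{d} from the diagonal.  Column entropy decreases
#' monotonically with \code{precision}: the limit of large precision is the
#' identity (zero volatility / perfectly precise likelihood), the limit of
#' zero precision is uniform columns.  With \code{circular = TRUE} distances
#' wrap modulo \code{n}, as appropriate for orientation-like state spaces.
#'
#' @param n number of states (>= 2).
#' @param precision positive decay rate (1/index^2 units).
#' @param circular wrap index distance modulo \code{n}?
#' @return \code{n x n} column-stochastic matrix.
#' @export
make_banded_kernel <- function(n, precision, circular = FALSE) {
  if (n < 2L) stop("n must be at least 2", call. = FALSE)
  if (!is.numeric(precision) || precision <= 0)
    stop("precision must be a positive scalar", call. = FALSE)
  idx <- seq_len(n)
  K <- outer(idx, idx, function(i, j) {
    d <- abs(i - j)
    if (circular) d <- pmin(d, n - d)
    exp(-precision * d^2)
  })
  norm_dist(K)
}

#' Compose generative levels into a deep temporal model
#'
#' Levels are ordered from lowest (fastest) to highest (slowest).  The state
#' at the higher level conditions the lower level's initial-state prior
#' (through \code{link_init}) and its policy prior (through
#' \code{link_policy}); several lower-level time steps elapse for each
#' single higher-level transition.
#'
#' @param levels list of [generative_level()] objects, lowest first.
#' @param link_init matrix \code{n_lower_states(factor link_factor) x
#'   n_upper_joint_states} with column j the distribution of the lower
#'   level's initial state given upper joint state j; defaults to the upper
#'   level's first-modality likelihood array (the conventional construction
#'   in which the lower level's hidden state is the upper level's outcome).
#' @param link_policy matrix \code{n_lower_policies x n_upper_joint_states};
#'   defaults to uniform columns (upper states do not bias lower policies).
#' @param steps_per_epoch maximum lower-level steps per upper-level step.
#' @param link_factor lower-level factor that the hierarchy links into.
#' @return object of class \code{"hierarchical_model"}.
#' @export
hierarchical_model <- function(levels, link_init = NULL, link_policy = NULL,
                               steps_per_epoch = 5L, link_factor = 1L) {
  if (length(levels) < 2L) stop("a hierarchy needs at least two levels", call. = FALSE)
  if (steps_per_epoch < 1L) stop("steps_per_epoch must be >= 1", call. = FALSE)
  lower <- levels[[1]]
  upper <- levels[[2]]
  n_joint <- prod(upper$n_states)
  if (is.null(link_init)) {
    a1 <- upper$A[[1]]
    link_init <- matrix(a1, nrow = dim(a1)[1])
  }
  if (nrow(link_init) != lower$n_states[link_factor] ||
      ncol(link_init) != n_joint)
    stop("link_init has wrong dimensions", call. = FALSE)
  if (is.null(link_policy))
    link_policy <- matrix(1 / lower$n_policies, lower$n_policies, n_joint)
  link_init <- norm_dist(link_init)
  link_policy <- norm_dist(link_policy)
  structure(list(levels = levels,
                 link_init = link_init,
                 link_policy = link_policy,
                 link_factor = as.integer(link_factor),
                 steps_per_epoch = as.integer(steps_per_epoch)),
            class = "hierarchical_model")
}

#' @export
print.hierarchical_model <- function(x, ...) {
  cat("<hierarchical_model> ", length(x$levels), " levels, up to ",
      x$steps_per_epoch, " lower steps per epoch\n", sep = "")
  for (i in seq_along(x$levels)) {
    cat("level ", i, ": ", sep = "")
    print(x$levels[[i]])
  }
  invisible(x)
}

#' Export a level's arrays to CSV files
#'
#' Writes one file per array (A per modality, B per factor, C, D) into
#' \code{dir}, in long format with index columns, for audit.
#'
#' @param level a [generative_level()].
#' @param dir output directory (created if absent).
#' @param prefix filename prefix.
#' @return invisibly, the files written.
#' @export
export_level_csv <- function(level, dir, prefix = "level") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character()
  wr <- function(df, name) {
    f <- file.path(dir, paste0(prefix, "_", name, ".csv"))
    utils::write.csv(df, f, row.names = FALSE)
    files <<- c(files, f)
  }
  for (g in seq_along(level$A)) {
    a <- level$A[[g]]
    d <- dim(a)
    idx <- do.call(expand.grid, lapply(d, seq_len))
    names(idx) <- c("outcome", paste0("state_f", seq_len(length(d) - 1L)))
    wr(cbind(idx, value = as.vector(a)), paste0("A", g))
  }
  for (f in seq_along(level$B)) {
    b <- level$B[[f]]
    idx <- do.call(expand.grid, lapply(dim(b), seq_len))
    names(idx) <- c("next_state", "state", "action")
    wr(cbind(idx, value = as.vector(b)), paste0("B", f))
  }
  for (g in seq_along(level$C))
    wr(data.frame(outcome = seq_along(level$C[[g]]), logpref = level$C[[g]]),
       paste0("C", g))
  for (f in seq_along(level$D))
    wr(data.frame(state = seq_along(level$D[[f]]), prob = level$D[[f]]),
       paste0("D", f))
  invisible(files)
}
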