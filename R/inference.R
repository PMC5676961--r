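## Single-level variational inference.
##
## Beliefs about hidden states are policy-conditioned log-space vectors
## nu[policy][factor][, time]; their softmax s_bar approximates the
## posterior Q(s_t | pi).  Belief updating is a gradient relaxation
##   nu <- nu + step * eps,   eps = (message sum) - nu
## whose fixed point is the self-consistent (sum-product) solution: forward
## and backward messages are computed with cavity division, so that on a
## single-factor chain the converged marginals equal the exact conditional
## posteriors.  Across hidden-state factors the posterior is factorised
## (mean field) and factors are coupled only through the likelihood arrays.

MSG_FLOOR <- 1e-16

## internal: cavity-normalised vector x / y
cavity <- function(x, y) norm_dist(x / pmax(y, MSG_FLOOR))

## internal: uniform vector
unif <- function(n) rep(1 / n, n)

## internal: action prescribed by policy p at transition tau, at current
## time t.  Executed actions override for past transitions; single-row
## policies prescribe their tuple at every future step; policies covering
## the full horizon are read by absolute time index.
action_at <- function(level, executed, p, tau, t) {
  if (!is.null(executed) && tau <= ncol(executed) && !is.na(executed[1, tau]))
    return(executed[, tau])
  pol <- level$policies[[p]]
  if (nrow(pol) >= level$horizon - 1L) return(pol[tau, ])
  pol[min(max(tau - t + 1L, 1L), nrow(pol)), ]
}

## internal: per-level cached quantities (log likelihoods, flattened A,
## per-column outcome entropies).  Cached in an environment attached by
## reference so repeated trials reuse it.
level_cache <- function(level) {
  ce <- attr(level, "cache")
  if (is.null(ce)) {
    ## attribute lost on copy: rebuild (cheap, done once per level object)
    ce <- new.env(parent = emptyenv())
  }
  if (is.null(ce$lnA)) {
    ce$lnA <- lapply(level$A, log_floor)
    ce$Amat <- lapply(level$A, function(a) matrix(a, nrow = dim(a)[1]))
    ce$colH <- lapply(ce$Amat, function(m) -colSums(m * log_floor(m)))
    ce$lnAmat <- lapply(ce$lnA, function(a) matrix(a, nrow = dim(a)[1]))
    ce$lnC <- lapply(level$C, function(cc) log(softmax(cc)))
  }
  ce
}

#' Initialise policy-conditioned beliefs for a level
#'
#' Beliefs start at the prior predictive: the initial-state priors D
#' propagated through the transitions prescribed by each policy.  Forward
#' messages start at the same predictions and backward messages start
#' uninformative.
#'
#' @param level a [generative_level()].
#' @param beta prior inverse precision (1/gamma) over policies.
#' @param lnE log prior over policies (habit term); uniform when `NULL`.
#' @param D_override optional list replacing the level's D (used by the
#'   hierarchy to condition a lower level's initial states).
#' @return object of class \code{"belief_state"}.
#' @export
init_beliefs <- function(level, beta = 1, lnE = NULL, D_override = NULL) {
  TT <- level$horizon
  np <- level$n_policies
  nf <- level$n_factors
  D <- if (is.null(D_override)) level$D else D_override
  if (is.null(lnE)) lnE <- rep(0, np)
  lnE <- lnE - max(lnE)
  sb <- nu <- Fm <- Bk <- vector("list", np)
  for (p in seq_len(np)) {
    sb[[p]] <- Fm[[p]] <- Bk[[p]] <- nu[[p]] <- vector("list", nf)
    for (f in seq_len(nf)) {
      m <- matrix(0, level$n_states[f], TT)
      m[, 1] <- D[[f]]
      if (TT > 1) for (tau in 2:TT) {
        u <- action_at(level, NULL, p, tau - 1L, 1L)
        m[, tau] <- as.vector(level$B[[f]][, , u[f]] %*% m[, tau - 1L])
      }
      sb[[p]][[f]] <- m
      nu[[p]][[f]] <- log_floor(m)
      Fm[[p]][[f]] <- m
      Bk[[p]][[f]] <- matrix(1 / level$n_states[f], level$n_states[f], TT)
    }
  }
  structure(list(nu = nu, s_bar = sb, Fm = Fm, Bk = Bk,
                 q_pi = softmax(lnE), lnE = lnE,
                 beta = beta,
                 bma = lapply(seq_len(nf), function(f)
                   Reduce(`+`, lapply(seq_len(np), function(p)
                     softmax(lnE)[p] * sb[[p]][[f]]))),
                 executed = matrix(NA_integer_, nf, max(TT - 1L, 1L)),
                 D = D),
            class = "belief_state")
}

## internal: log-likelihood message for factor f at time tau, given hard
## observations obs (list per modality, NA = absent) and optional joint
## log-evidence vector evid.
obs_message <- function(level, ce, sbars, f, obs, evid) {
  m <- 0
  if (!is.null(obs)) {
    for (g in seq_along(obs)) {
      o <- obs[[g]]
      if (is.na(o)) next
      lnAg <- ce$lnAmat[[g]][o, ]
      m <- m + contract_except(lnAg, sbars, f)
    }
  }
  if (!is.null(evid)) m <- m + contract_except(evid, sbars, f)
  m
}

#' State prediction error (log-space) for one policy and time
#'
#' Returns the difference between the message sum (forward transition
#' message, backward transition message, log-likelihood of any observation,
#' and the initial-state prior at the first step) and the current log belief
#' \code{nu}.  At the self-consistent fixed point the error is exactly zero
#' and expected states cease to change.
#'
#' @param level a [generative_level()].
#' @param policy policy index.
#' @param t time index within the horizon.
#' @param beliefs a [init_beliefs()] object.
#' @param observation list per modality of outcome indices (NA for
#'   unobserved modalities), or `NULL` if time \code{t} is unobserved.
#' @param t_now current trial time (affects which policy step applies).
#' @param evid optional joint-state log-evidence vector (ascending
#'   hierarchical message).
#' @return list per factor of error vectors \code{eps}.
#' @export
state_error <- function(level, policy, t, beliefs, observation = NULL,
                        t_now = t, evid = NULL) {
  if (t < 1L || t > level$horizon) stop("time index outside horizon", call. = FALSE)
  ce <- level_cache(level)
  nf <- level$n_factors
  TT <- level$horizon
  sb <- beliefs$s_bar[[policy]]
  sbars <- lapply(seq_len(nf), function(f) sb[[f]][, t])
  lapply(seq_len(nf), function(f) {
    ns <- level$n_states[f]
    if (t == 1L) {
      fwd <- beliefs$D[[f]]
    } else {
      u <- action_at(level, beliefs$executed, policy, t - 1L, t_now)
      fwd <- as.vector(level$B[[f]][, , u[f]] %*%
                         cavity(sb[[f]][, t - 1L], beliefs$Bk[[policy]][[f]][, t - 1L]))
    }
    if (t == TT) {
      bwd <- unif(ns)
    } else {
      u <- action_at(level, beliefs$executed, policy, t, t_now)
      bwd <- norm_dist(as.vector(crossprod(level$B[[f]][, , u[f]],
                         cavity(sb[[f]][, t + 1L], beliefs$Fm[[policy]][[f]][, t + 1L]))))
    }
    msg <- log_floor(norm_dist(fwd)) + log_floor(bwd) +
      obs_message(level, ce, sbars, f, observation, evid)
    msg - beliefs$nu[[policy]][[f]][, t]
  })
}

#' Gradient descent on beliefs about hidden states
#'
#' Runs \code{n_iter} synchronous update iterations over all policies,
#' factors and times: messages are refreshed from the current beliefs, the
#' state errors \code{eps} computed, and \code{nu} moved by
#' \code{step * eps}.  The per-iteration increments \code{nu_dot} (the
#' substrate of simulated ERPs) and the policy-averaged beliefs are logged.
#'
#' When \code{track_F = TRUE} the per-policy free energy is evaluated after
#' every iteration and a backtracking safeguard halves that iteration's step
#' (up to 6 times, per policy) if it would increase free energy; with
#' tracking off the plain fixed-step update is used.
#'
#' @param beliefs a [init_beliefs()] object.
#' @param level a [generative_level()].
#' @param observations list over times of per-modality outcome indices
#'   (`NULL` entries for unobserved times).
#' @param n_iter number of gradient iterations (>= 1).
#' @param step step size in (0, 1].
#' @param t_now current trial time.
#' @param evid optional list over times of joint-state log-evidence vectors.
#' @param track_F evaluate and enforce non-increasing free energy.
#' @param conv_tol convergence tolerance on \code{max |nu_dot|} (nats): the
#'   first iteration below it is reported as \code{iters_to_converge}, a
#'   deterministic proxy for computational settling time.
#' @param adaptive stop iterating once converged (\code{n_iter} becomes a
#'   cap): executed iterations then scale with the difficulty of the
#'   update, and the logged arrays are truncated to the executed length.
#' @param active logical vector of policies to update (default all).
#' @param q_pi_weights weights used for the logged policy averages
#'   (defaults to the current policy posterior in \code{beliefs}).
#' @return list with elements \code{beliefs} (updated), \code{vn} and
#'   \code{xn} (per factor, arrays \code{iter x state x time} of
#'   policy-averaged \code{nu_dot} and \code{s_bar}), \code{iters_to_converge},
#'   and \code{F_trace} (matrix iter x policy, when tracked).
#' @export
gradient_update <- function(beliefs, level, observations, n_iter = 16L,
                            step = 0.25, t_now = 1L, evid = NULL,
                            track_F = FALSE, conv_tol = 0.01,
                            adaptive = FALSE, active = NULL,
                            q_pi_weights = NULL) {
  stopifnot(n_iter >= 1L, step > 0, step <= 1)
  np <- level$n_policies
  nf <- level$n_factors
  TT <- level$horizon
  ns <- level$n_states
  ce <- level_cache(level)
  if (is.null(active)) active <- rep(TRUE, np)
  w <- if (is.null(q_pi_weights)) beliefs$q_pi else q_pi_weights
  ## ---- per-call precomputation -------------------------------------------
  ## action tables and transition slices per policy/factor/transition
  Bsl <- lapply(seq_len(nf), function(f)
    lapply(seq_len(level$n_actions[f]), function(u) level$B[[f]][, , u]))
  tBsl <- lapply(Bsl, function(l) lapply(l, t))
  U <- lapply(seq_len(np), function(p) {
    m <- matrix(1L, max(TT - 1L, 1L), nf)
    if (TT > 1L) for (tau in seq_len(TT - 1L))
      m[tau, ] <- action_at(level, beliefs$executed, p, tau, t_now)
    m
  })
  ## per-time observed log-likelihood slices over joint states
  obs_tau <- integer(0)
  slices <- vector("list", TT)
  for (tau in seq_len(TT)) {
    sl <- NULL
    if (tau <= length(observations) && !is.null(observations[[tau]])) {
      ob <- observations[[tau]]
      for (g in seq_along(ob)) {
        o <- ob[[g]]
        if (is.na(o)) next
        v <- ce$lnAmat[[g]][o, ]
        sl <- if (is.null(sl)) v else sl + v
      }
    }
    if (!is.null(evid) && tau <= length(evid) && !is.null(evid[[tau]]))
      sl <- if (is.null(sl)) evid[[tau]] else sl + evid[[tau]]
    if (!is.null(sl)) {
      slices[[tau]] <- sl
      obs_tau <- c(obs_tau, tau)
    }
  }
  last_obs <- if (length(obs_tau)) max(obs_tau) else 0L
  ## pre-permuted likelihood slices: one matrix per (time, factor) so the
  ## per-iteration mean-field contraction is a single matrix product
  Mperm <- vector("list", TT)
  for (tau in obs_tau) {
    if (nf == 1L) next
    arr <- array(slices[[tau]], ns)
    Mperm[[tau]] <- lapply(seq_len(nf), function(f)
      matrix(aperm(arr, c(f, seq_len(nf)[-f])), nrow = ns[f]))
  }
  ## ---- iteration loop ----------------------------------------------------
  vn <- lapply(seq_len(nf), function(f) array(0, c(n_iter, ns[f], TT)))
  xn <- lapply(seq_len(nf), function(f) array(0, c(n_iter, ns[f], TT)))
  F_trace <- if (track_F) matrix(NA_real_, n_iter, np) else NULL
  F_prev <- rep(Inf, np)
  iters_to_converge <- n_iter
  converged <- FALSE
  for (i in seq_len(n_iter)) {
    max_nudot <- 0
    for (p in seq_len(np)) {
      if (!active[p]) next
      sbp <- beliefs$s_bar[[p]]
      nup <- beliefs$nu[[p]]
      Up <- U[[p]]
      eps_p <- vector("list", nf)
      for (f in seq_len(nf)) {
        sb <- sbp[[f]]
        Fm <- beliefs$Fm[[p]][[f]]
        Bk <- beliefs$Bk[[p]][[f]]
        ## recursive forward sweep then backward sweep (self-consistent
        ## sum-product messages with cavity division); messages are damped
        ## (averaged with their previous value) to suppress relaxation
        ## two-cycles without moving the fixed point
        Fm[, 1L] <- beliefs$D[[f]]
        if (TT > 1L) for (tau in 2:TT) {
          cav <- sb[, tau - 1L] / (Bk[, tau - 1L] + MSG_FLOOR)
          v <- Bsl[[f]][[Up[tau - 1L, f]]] %*% cav
          sv <- sum(v)
          Fm[, tau] <- 0.5 * Fm[, tau] +
            0.5 * (if (sv > 0) v / sv else 1 / ns[f])
        }
        ## backward messages carry evidence only: they are exactly
        ## uniform at and beyond the last observed time
        Bk[, TT] <- 1 / ns[f]
        if (TT > 1L) for (tau in (TT - 1L):1L) {
          if (tau + 1L > last_obs) {
            Bk[, tau] <- 1 / ns[f]
            next
          }
          cav <- sb[, tau + 1L] / (Fm[, tau + 1L] + MSG_FLOOR)
          v <- tBsl[[f]][[Up[tau, f]]] %*% cav
          sv <- sum(v)
          Bk[, tau] <- 0.5 * Bk[, tau] +
            0.5 * (if (sv > 0) v / sv else 1 / ns[f])
        }
        beliefs$Fm[[p]][[f]] <- Fm
        beliefs$Bk[[p]][[f]] <- Bk
        msg <- log(Fm + MSG_FLOOR) + log(Bk + MSG_FLOOR)
        eps_p[[f]] <- msg - nup[[f]]
      }
      ## likelihood messages (mean field across factors, synchronous)
      for (tau in obs_tau) {
        if (nf == 1L) {
          eps_p[[1L]][, tau] <- eps_p[[1L]][, tau] + slices[[tau]]
        } else {
          sbars <- lapply(seq_len(nf), function(f) sbp[[f]][, tau])
          for (f in seq_len(nf))
            eps_p[[f]][, tau] <- eps_p[[f]][, tau] +
              Mperm[[tau]][[f]] %*% joint_from_factors(sbars[-f])
        }
      }
      ## step (with optional free-energy backtracking)
      s_use <- step
      repeat_ct <- 0L
      repeat {
        nu_new <- lapply(seq_len(nf), function(f) nup[[f]] + s_use * eps_p[[f]])
        if (!track_F) break
        beliefs$nu[[p]] <- nu_new
        beliefs$s_bar[[p]] <- lapply(nu_new, col_softmax)
        Fc <- free_energy(level, p, beliefs, observations,
                          t_now = t_now, evid = evid)
        if (Fc <= F_prev[p] + 1e-9) break
        if (repeat_ct >= 6L) {
          ## no descending step along this direction: hold the beliefs
          s_use <- 0
          nu_new <- nup
          Fc <- F_prev[p]
          break
        }
        s_use <- s_use / 2
        repeat_ct <- repeat_ct + 1L
      }
      if (track_F) {
        F_prev[p] <- Fc
        F_trace[i, p] <- Fc
      }
      beliefs$nu[[p]] <- nu_new
      beliefs$s_bar[[p]] <- lapply(nu_new, col_softmax)
      for (f in seq_len(nf)) {
        dn <- s_use * eps_p[[f]]
        vn[[f]][i, , ] <- vn[[f]][i, , ] + w[p] * dn
        mx <- max(abs(dn))
        if (mx > max_nudot) max_nudot <- mx
        if (!all(is.finite(nu_new[[f]])))
          stop("belief divergence (non-finite nu) for policy ", p, call. = FALSE)
      }
    }
    for (f in seq_len(nf)) {
      acc <- matrix(0, ns[f], TT)
      for (p in seq_len(np)) acc <- acc + w[p] * beliefs$s_bar[[p]][[f]]
      xn[[f]][i, , ] <- acc
    }
    if (!converged && max_nudot < conv_tol) {
      iters_to_converge <- i
      converged <- TRUE
      if (adaptive) break
    }
  }
  if (adaptive && iters_to_converge < n_iter) {
    keep <- seq_len(iters_to_converge)
    vn <- lapply(vn, function(a) a[keep, , , drop = FALSE])
    xn <- lapply(xn, function(a) a[keep, , , drop = FALSE])
    if (!is.null(F_trace)) F_trace <- F_trace[keep, , drop = FALSE]
  }
  list(beliefs = beliefs, vn = vn, xn = xn,
       iters_to_converge = iters_to_converge, F_trace = F_trace)
}

#' Variational free energy of one policy
#'
#' Evaluates the free energy of the chain-structured variational density
#' implied by the current beliefs: per factor, \code{q(s_1)} is the current
#' first-step marginal and \code{q(s_{t+1}|s_t)} is the transition
#' reweighted by the cavity vector carrying evidence from time t+1 onward
#' (backward messages are computed exactly from the observations).  This is
#' an upper bound on \code{-ln P(o|pi)} for any beliefs, saturated when the
#' beliefs equal the exact conditional posterior.  Only observed time steps
#' contribute likelihood terms; future steps enter through the expected
#' free energy instead.
#'
#' @inheritParams state_error
#' @param observations list over times of per-modality outcome indices.
#' @param evid optional list of joint log-evidence vectors per time.
#' @return scalar free energy (nats).
#' @export
free_energy <- function(level, policy, beliefs, observations,
                        t_now = NULL, evid = NULL) {
  ce <- level_cache(level)
  nf <- level$n_factors
  TT <- level$horizon
  if (is.null(t_now)) t_now <- min(length(observations), TT)
  sb <- beliefs$s_bar[[policy]]
  obs_at <- function(tau) if (tau <= length(observations)) observations[[tau]] else NULL
  evid_at <- function(tau) if (!is.null(evid) && tau <= length(evid)) evid[[tau]] else NULL
  ## per-factor observation likelihood vectors (mean-field across factors)
  lhat <- vector("list", nf)
  for (f in seq_len(nf)) {
    lhat[[f]] <- matrix(1, level$n_states[f], TT)
    for (tau in seq_len(TT)) {
      ob <- obs_at(tau); ev <- evid_at(tau)
      if (is.null(ob) && is.null(ev)) next
      sbars <- lapply(seq_len(nf), function(ff) sb[[ff]][, tau])
      lhat[[f]][, tau] <- exp(obs_message(level, ce, sbars, f, ob, ev))
    }
  }
  Fv <- 0
  margs <- vector("list", nf)
  for (f in seq_len(nf)) {
    ns <- level$n_states[f]
    ## exact backward recursion given the (mean-field) likelihood vectors
    beta_msg <- matrix(1, ns, TT)
    if (TT > 1) for (tau in (TT - 1L):1L) {
      u <- action_at(level, beliefs$executed, policy, tau, t_now)
      beta_msg[, tau] <- as.vector(crossprod(level$B[[f]][, , u[f]],
                                             lhat[[f]][, tau + 1L] * beta_msg[, tau + 1L]))
      beta_msg[, tau] <- norm_dist(beta_msg[, tau])
    }
    ## forward cavity sweep and chain construction
    q1 <- sb[[f]][, 1L]
    Fv <- Fv + sum(q1 * (log_floor(q1) - log_floor(beliefs$D[[f]])))
    mg <- matrix(0, ns, TT)
    mg[, 1L] <- q1
    if (TT > 1) for (tau in seq_len(TT - 1L)) {
      u <- action_at(level, beliefs$executed, policy, tau, t_now)
      Bu <- level$B[[f]][, , u[f]]
      Fm_next <- norm_dist(as.vector(Bu %*% cavity(sb[[f]][, tau], beta_msg[, tau])))
      uvec <- cavity(sb[[f]][, tau + 1L], Fm_next)
      W <- Bu * uvec            # column j: B[, j] * u  (recycled by row)
      W <- norm_dist(W)
      Fv <- Fv + sum((W * (log_floor(W) - log_floor(Bu))) %*% mg[, tau])
      mg[, tau + 1L] <- as.vector(W %*% mg[, tau])
    }
    margs[[f]] <- mg
  }
  ## observation terms under the chain marginals
  for (tau in seq_len(TT)) {
    ob <- obs_at(tau); ev <- evid_at(tau)
    if (is.null(ob) && is.null(ev)) next
    mlist <- lapply(seq_len(nf), function(f) margs[[f]][, tau])
    qjoint <- joint_from_factors(mlist)
    if (!is.null(ob)) for (g in seq_along(ob)) {
      if (is.na(ob[[g]])) next
      Fv <- Fv - sum(qjoint * ce$lnAmat[[g]][ob[[g]], ])
    }
    if (!is.null(ev)) Fv <- Fv - sum(qjoint * ev)
  }
  Fv
}

#' Expected free energy of a policy at a future time
#'
#' Decomposes \code{G(pi, tau)} into a pragmatic part (expected surprise of
#' predicted outcomes relative to the log preferences C) and an epistemic
#' part (negative expected information gain about hidden states):
#' \code{epistemic = E[ln Q(s) - ln P(s|o)] = -I(s; o)} under the predicted
#' state distribution and the likelihood, which is always <= 0.  Summing
#' over future times gives the policy's total expected free energy.
#'
#' @inheritParams state_error
#' @param tau future time index (\code{tau > t_now}).
#' @return list with \code{G}, \code{pragmatic}, \code{epistemic} (scalars,
#'   summed over modalities) and per-modality vectors.
#' @export
expected_free_energy <- function(level, policy, beliefs, tau, t_now = 0L) {
  if (tau <= t_now || tau > level$horizon)
    stop("tau must be a future time within the horizon", call. = FALSE)
  ce <- level_cache(level)
  nf <- level$n_factors
  qs <- lapply(seq_len(nf), function(f) beliefs$s_bar[[policy]][[f]][, tau])
  qjoint <- joint_from_factors(qs)
  ng <- level$n_modalities
  prag <- epi <- numeric(ng)
  for (g in seq_len(ng)) {
    Qo <- as.vector(ce$Amat[[g]] %*% qjoint)
    prag[g] <- -sum(Qo * ce$lnC[[g]])
    epi[g] <- sum(qjoint * ce$colH[[g]]) - entropy_cat(norm_dist(Qo), validate = FALSE)
  }
  list(G = sum(prag) + sum(epi), pragmatic = sum(prag), epistemic = sum(epi),
       pragmatic_g = prag, epistemic_g = epi)
}

#' Posterior over policies
#'
#' \code{Q(pi) = softmax(lnE - gamma * G - F)}: the prior expected-free-
#' energy term is weighted by the precision gamma and corrected by the
#' variational free energy of the evidence accumulated so far.
#'
#' @param F_per_policy free energy per policy (0 when no evidence yet).
#' @param G_per_policy expected free energy per policy.
#' @param gamma policy precision (> 0).
#' @param prior_E log prior over policies (uniform when `NULL`).
#' @return probability vector over policies.
#' @export
policy_posterior <- function(F_per_policy, G_per_policy, gamma, prior_E = NULL) {
  if (length(F_per_policy) != length(G_per_policy))
    stop("F and G must have the same length", call. = FALSE)
  if (!is.numeric(gamma) || gamma < 0) stop("gamma must be positive", call. = FALSE)
  if (is.null(prior_E)) prior_E <- rep(0, length(G_per_policy))
  softmax(prior_E - gamma * G_per_policy - F_per_policy)
}

#' Bayesian model average of state beliefs over policies
#'
#' \code{Q(s_t) = sum_pi Q(pi) Q(s_t|pi)}: each policy is a model of the
#' trajectory, weighted by its posterior probability.
#'
#' @param q_pi policy posterior.
#' @param s_bar_per_policy list over policies of belief vectors (or
#'   matrices) for one factor.
#' @param t optional time column when matrices are supplied.
#' @return averaged belief vector (or matrix).
#' @export
bayesian_model_average <- function(q_pi, s_bar_per_policy, t = NULL) {
  if (length(q_pi) != length(s_bar_per_policy))
    stop("mismatched policy cardinalities", call. = FALSE)
  comps <- lapply(seq_along(q_pi), function(p) {
    x <- s_bar_per_policy[[p]]
    if (!is.null(t)) x <- x[, t]
    q_pi[p] * x
  })
  dims <- vapply(comps, length, 1L)
  if (length(unique(dims)) != 1L)
    stop("mismatched state cardinalities across policies", call. = FALSE)
  out <- Reduce(`+`, comps)
  if (is.matrix(out)) apply(out, 2, norm_dist) else norm_dist(out)
}

#' Update the policy precision (simulated dopamine)
#'
#' Iterates the fixed point \code{beta <- beta_prior + (Q(pi) - P(pi)) . G}
#' with damping, re-deriving the policy prior and posterior with
#' \code{gamma = 1/beta} at each iteration.  When the posterior favours
#' lower-G policies more than the prior does, beta decreases (gamma, the
#' simulated dopaminergic precision, increases).  The gamma trajectory is
#' the substrate of the simulated phasic dopamine signal.
#'
#' @param beta_prior prior inverse precision (> 0).
#' @param G_per_policy expected free energy per policy (current beliefs).
#' @param F_per_policy free energy per policy (defaults to zero).
#' @param lnE log policy prior (uniform when `NULL`).
#' @param n_iter number of fixed-point iterations.
#' @param G_prior,F_prior the expected free energies defining the policy
#'   prior: the values held before the latest observation (defaults:
#'   \code{G_per_policy} and zero, in which case the prior and posterior
#'   coincide whenever F is constant across policies and beta stays at its
#'   prior).  Passing the previous step's values makes gamma respond
#'   phasically to observation-driven revisions of policy beliefs.
#' @return list with \code{beta}, \code{gamma}, \code{gamma_traj} (length
#'   \code{n_iter}), \code{q_pi}, \code{p_pi}, and \code{converged}.
#' @export
update_precision <- function(beta_prior, G_per_policy, F_per_policy = NULL,
                             lnE = NULL, n_iter = 16L,
                             G_prior = NULL, F_prior = NULL) {
  if (beta_prior <= 0) stop("beta_prior must be positive", call. = FALSE)
  np <- length(G_per_policy)
  if (is.null(F_per_policy)) F_per_policy <- rep(0, np)
  if (is.null(lnE)) lnE <- rep(0, np)
  if (is.null(G_prior)) G_prior <- G_per_policy
  if (is.null(F_prior)) F_prior <- rep(0, np)
  beta <- beta_prior
  traj <- numeric(n_iter)
  q_pi <- p_pi <- NULL
  for (i in seq_len(n_iter)) {
    gamma <- 1 / beta
    p_pi <- softmax(lnE - gamma * G_prior - F_prior)
    q_pi <- softmax(lnE - gamma * G_per_policy - F_per_policy)
    target <- beta_prior + sum((q_pi - p_pi) * G_per_policy)
    ## beta stays positive: clamped at an eighth of its prior, bounding the
    ## phasic gain in gamma at 8x baseline
    beta <- beta + (max(target, beta_prior / 8) - beta) / 2
    traj[i] <- 1 / beta
  }
  converged <- abs(target - beta) < 1e-6 * max(1, beta)
  if (!converged)
    attr(traj, "warning") <- "precision update did not converge; last iterate returned"
  list(beta = beta, gamma = 1 / beta, gamma_traj = traj,
       q_pi = q_pi, p_pi = p_pi, converged = converged)
}

#' Select an action from the policy posterior
#'
#' Marginalises the policy posterior onto the action each policy prescribes
#' at time \code{t} and returns, per controllable factor, the most probable
#' action (ties broken toward the lowest action index), or a sample from
#' the sharpened marginal in \code{"sample"} mode.
#'
#' @param q_pi policy posterior.
#' @param level a [generative_level()].
#' @param beliefs beliefs carrying executed actions (may be `NULL`).
#' @param t current time step.
#' @param mode \code{"deterministic"} or \code{"sample"}.
#' @param alpha action precision: in sample mode actions are drawn from
#'   \code{softmax(alpha * ln P(u))}.
#' @param stream optional [seeded_stream()] used for sampling.
#' @return integer vector of action indices, one per factor.
#' @export
select_action <- function(q_pi, level, beliefs = NULL, t = 1L,
                          mode = c("deterministic", "sample"), alpha = 16,
                          stream = NULL) {
  mode <- match.arg(mode)
  nf <- level$n_factors
  executed <- if (is.null(beliefs)) NULL else beliefs$executed
  out <- integer(nf)
  for (f in seq_len(nf)) {
    nu_f <- level$n_actions[f]
    pu <- numeric(nu_f)
    for (p in seq_along(q_pi)) {
      u <- action_at(level, executed, p, t, t)[f]
      pu[u] <- pu[u] + q_pi[p]
    }
    if (mode == "deterministic" || nu_f == 1L) {
      out[f] <- which.max(pu)
    } else {
      pr <- softmax(alpha * log_floor(norm_dist(pu)))
      out[f] <- draw_categorical(pr, stream)
    }
  }
  out
}

## internal: categorical draw through a stream (or the global RNG)
draw_categorical <- function(p, stream = NULL) {
  r <- if (is.null(stream)) stats::runif(1) else stream_runif(stream, 1)
  as.integer(findInterval(r, cumsum(p) + 1e-12) + 1L)
}

#' Run one trial of perception and action at a single level
#'
#' For each time step: an outcome is generated from the generative process
#' (true states advanced through B, outcomes through A, or supplied
#' externally), beliefs are updated by [gradient_update()], free and
#' expected free energies evaluated, the policy posterior and precision
#' updated, beliefs averaged over policies, and an action selected.
#'
#' @param level a [generative_level()].
#' @param config list of settings: \code{n_iter}, \code{step},
#'   \code{beta_prior}, \code{plan_horizon}, \code{action_mode},
#'   \code{alpha}, \code{track_F}, \code{conv_tol}, \code{precision_updates},
#'   \code{n_prec_iter}, \code{deterministic_outcomes}, \code{lnE},
#'   \code{D_override}, \code{terminate} (list with \code{factor} and
#'   \code{threshold} for entropy-based early stopping), \code{prune_pi}
#'   (freeze policies whose posterior falls below 1/(16 n_policies)).
#' @param process list describing the generative process: \code{true_states}
#'   (matrix factors x horizon, NA entries sampled), \code{outcomes}
#'   (matrix modalities x horizon, NA sampled from A), \code{A}, \code{B},
#'   \code{D} overrides (default: the level's own arrays),
#'   \code{stream} (a [seeded_stream()]) and \code{agent_stream}.
#' @param evid optional list over times of joint log-evidence vectors.
#' @return object of class \code{"trial_record"}.
#' @export
run_level_trial <- function(level, config = list(), process = list(),
                            evid = NULL) {
  cfg <- utils::modifyList(list(
    n_iter = 32L, step = 0.25, beta_prior = 1, plan_horizon = NULL,
    action_mode = "deterministic", alpha = 16, track_F = FALSE,
    conv_tol = 0.01, adaptive = FALSE, precision_updates = TRUE,
    n_prec_iter = 16L,
    deterministic_outcomes = FALSE, lnE = NULL, D_override = NULL,
    terminate = NULL, prune_pi = TRUE), config)
  TT <- level$horizon
  np <- level$n_policies
  nf <- level$n_factors
  ng <- level$n_modalities
  plan <- if (is.null(cfg$plan_horizon)) TT else cfg$plan_horizon
  pA <- if (is.null(process$A)) level$A else process$A
  pB <- if (is.null(process$B)) level$B else process$B
  pD <- if (is.null(process$D)) {
    if (is.null(cfg$D_override)) level$D else cfg$D_override
  } else process$D
  pstream <- process$stream
  astream <- process$agent_stream
  beliefs <- init_beliefs(level, beta = cfg$beta_prior, lnE = cfg$lnE,
                          D_override = cfg$D_override)
  true_states <- matrix(NA_integer_, nf, TT)
  if (!is.null(process$true_states)) {
    ts <- process$true_states
    true_states[, seq_len(ncol(ts))] <- ts
  }
  outcomes <- matrix(NA_integer_, ng, TT)
  if (!is.null(process$outcomes)) {
    oc <- process$outcomes
    outcomes[, seq_len(ncol(oc))] <- oc
  }
  observations <- vector("list", TT)
  rec <- list(
    o = outcomes, true_states = true_states,
    actions = matrix(NA_integer_, nf, max(TT - 1L, 1L)),
    F_pi = matrix(NA_real_, np, TT), G_pi = matrix(NA_real_, np, TT),
    q_pi = matrix(NA_real_, np, TT), beta = rep(NA_real_, TT),
    gamma_traj = matrix(NA_real_, cfg$n_prec_iter, TT),
    steps = vector("list", TT), iters = rep(NA_integer_, TT),
    n_steps = TT, config = cfg
  )
  active <- rep(TRUE, np)
  prev_G <- prev_F <- NULL
  for (t in seq_len(TT)) {
    ## generative process: true states
    for (f in seq_len(nf)) {
      if (is.na(true_states[f, t])) {
        if (t == 1L) {
          true_states[f, t] <- draw_state(pD[[f]], pstream, cfg$deterministic_outcomes)
        } else {
          u <- rec$actions[f, t - 1L]
          if (is.na(u)) u <- 1L
          true_states[f, t] <- draw_state(pB[[f]][, true_states[f, t - 1L], u],
                                          pstream, cfg$deterministic_outcomes)
        }
      }
    }
    ## generative process: outcomes
    jt <- joint_index(true_states[, t], level$n_states)
    for (g in seq_len(ng)) {
      if (is.na(outcomes[g, t])) {
        col <- matrix(pA[[g]], nrow = dim(pA[[g]])[1])[, jt]
        outcomes[g, t] <- draw_state(col, pstream, cfg$deterministic_outcomes)
      }
    }
    observations[[t]] <- as.list(outcomes[, t])
    ## inference
    gu <- gradient_update(beliefs, level, observations, n_iter = cfg$n_iter,
                          step = cfg$step, t_now = t, evid = evid,
                          track_F = cfg$track_F, conv_tol = cfg$conv_tol,
                          adaptive = cfg$adaptive, active = active)
    beliefs <- gu$beliefs
    ## policy evaluation
    Fp <- vapply(seq_len(np), function(p)
      free_energy(level, p, beliefs, observations, t_now = t, evid = evid),
      0)
    Gp <- vapply(seq_len(np), function(p) {
      taus <- seq(t + 1L, min(t + plan, TT))
      if (t >= TT) return(0)
      sum(vapply(taus, function(tau)
        expected_free_energy(level, p, beliefs, tau, t_now = t)$G, 0))
    }, 0)
    if (cfg$precision_updates) {
      pu <- update_precision(cfg$beta_prior, Gp, Fp, lnE = beliefs$lnE,
                             n_iter = cfg$n_prec_iter,
                             G_prior = prev_G, F_prior = prev_F)
      beliefs$beta <- pu$beta
      rec$gamma_traj[, t] <- pu$gamma_traj
      q_pi <- pu$q_pi
    } else {
      q_pi <- policy_posterior(Fp, Gp, 1 / beliefs$beta, beliefs$lnE)
    }
    if (cfg$prune_pi && np > 1L)
      active <- active & (q_pi >= 1 / (16 * np))
    if (!any(active)) active <- q_pi == max(q_pi)
    ## frozen policies carry stale beliefs: excluded from the average
    q_pi[!active] <- 0
    q_pi <- norm_dist(q_pi)
    beliefs$q_pi <- q_pi
    ## Bayesian model average
    beliefs$bma <- lapply(seq_len(nf), function(f)
      bayesian_model_average(q_pi, lapply(seq_len(np), function(p)
        beliefs$s_bar[[p]][[f]])))
    rec$F_pi[, t] <- Fp; rec$G_pi[, t] <- Gp; rec$q_pi[, t] <- q_pi
    rec$beta[t] <- beliefs$beta
    prev_G <- Gp; prev_F <- Fp
    rec$steps[[t]] <- list(vn = gu$vn, xn = gu$xn, F_trace = gu$F_trace)
    rec$iters[t] <- gu$iters_to_converge
    ## action and early termination
    if (t < TT) {
      a <- select_action(q_pi, level, beliefs, t, mode = cfg$action_mode,
                         alpha = cfg$alpha, stream = astream)
      rec$actions[, t] <- a
      beliefs$executed[, t] <- a
    }
    if (!is.null(cfg$terminate)) {
      bmat <- beliefs$bma[[cfg$terminate$factor]]
      rec$term_entropy[t] <- entropy_cat(norm_dist(bmat[, t]), validate = FALSE)
      if (t < TT && terminate_epoch(bmat[, t], cfg$terminate$threshold)) {
        rec$n_steps <- t
        break
      }
    }
  }
  rec$o <- outcomes
  rec$true_states <- true_states
  rec$beliefs <- beliefs
  rec$observations <- observations
  class(rec) <- "trial_record"
  rec
}

## internal: draw an index from a categorical column (modal when
## deterministic)
draw_state <- function(p, stream, deterministic = FALSE) {
  p <- norm_dist(as.vector(p))
  if (deterministic || max(p) > 1 - 1e-12) return(which.max(p))
  draw_categorical(p, stream)
}

## internal: linear index of a joint state combination
joint_index <- function(states, n_states) {
  idx <- states[1]
  if (length(states) > 1L) {
    mult <- 1L
    for (f in 2:length(states)) {
      mult <- mult * n_states[f - 1L]
      idx <- idx + (states[f] - 1L) * mult
    }
  }
  as.integer(idx)
}

#' @export
print.trial_record <- function(x, ...) {
  cat("<trial_record> ", x$n_steps, " executed step(s), ",
      nrow(x$q_pi), " policies\n", sep = "")
  invisible(x)
}
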