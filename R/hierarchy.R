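## Deep temporal composition: each higher-level time step spawns a full
## lower-level trial (an "epoch").  Descending messages set the lower
## level's initial-state and policy priors; ascending messages return the
## lower level's evidence about which higher-level state generated it.

#' Descending hierarchical message
#'
#' Maps a belief over the higher level's (joint) states onto the lower
#' level's initial-state prior and policy prior through the link arrays.
#'
#' @param upper_belief probability vector over upper joint states, or a
#'   list of per-factor beliefs (combined as their outer product).
#' @param links a [hierarchical_model()] or a list with \code{link_init}
#'   and \code{link_policy} matrices (column-normalised).
#' @return list with \code{D} (lower initial-state prior) and \code{lnE}
#'   (lower log policy prior).
#' @export
descend <- function(upper_belief, links) {
  if (is.list(upper_belief) && !is.numeric(upper_belief))
    upper_belief <- joint_from_factors(upper_belief)
  if (nrow(links$link_init) < 1L ||
      ncol(links$link_init) != length(upper_belief))
    stop("cardinality mismatch between upper belief and link arrays",
         call. = FALSE)
  list(D = norm_dist(as.vector(links$link_init %*% upper_belief)),
       lnE = log_floor(norm_dist(as.vector(links$link_policy %*% upper_belief))))
}

#' Ascending hierarchical message
#'
#' Returns, for every higher-level (joint) state hypothesis, the
#' log-likelihood of the evidence the lower level accumulated about its
#' linked state factor: \code{ln(link_init' L)}, where \code{L} is the
#' lower level's converged posterior divided by its descended prior (the
#' likelihood the epoch's observations contributed).  Dividing out the
#' prior prevents the higher level from counting its own prediction twice
#' — its forward messages already carry it — and makes a one-step lower
#' level with identity links exactly equivalent to a flat model.  The
#' message is invariant (up to an additive constant absorbed by the
#' softmax) to the normalisation of the lower posterior.
#'
#' @param lower_trial a [run_level_trial()] record (its final
#'   policy-averaged belief over the linked factor is used, with the prior
#'   taken from the record's initial-state prior) or a bare probability
#'   vector, interpreted as an already prior-corrected likelihood.
#' @param links a [hierarchical_model()] or list with \code{link_init}.
#' @param link_factor lower factor carrying the link (default from links).
#' @param prior optional prior to divide out when a bare vector is given.
#' @return log-evidence vector over upper joint states.
#' @export
ascend <- function(lower_trial, links, link_factor = NULL, prior = NULL) {
  if (inherits(lower_trial, "trial_record")) {
    if (is.null(lower_trial$beliefs))
      stop("incomplete lower trial: no beliefs recorded", call. = FALSE)
    lf <- if (is.null(link_factor)) {
      if (is.null(links$link_factor)) 1L else links$link_factor
    } else link_factor
    q_lower <- lower_trial$beliefs$bma[[lf]][, lower_trial$n_steps]
    if (is.null(prior)) prior <- lower_trial$beliefs$D[[lf]]
  } else {
    q_lower <- as.numeric(lower_trial)
  }
  if (length(q_lower) != nrow(links$link_init))
    stop("cardinality mismatch between lower posterior and link array",
         call. = FALSE)
  lik <- norm_dist(q_lower)
  if (!is.null(prior)) lik <- norm_dist(lik / pmax(prior, MSG_FLOOR))
  as.vector(log_floor(crossprod(links$link_init, lik)))
}

#' Epoch termination test
#'
#' An epoch (the lower-level trial spawned by one higher-level step) ends
#' when the entropy of the policy-averaged belief over the scene-identity
#' factor falls below a threshold (uncertainty resolved), or when the step
#' budget is exhausted (enforced by the scheduler).
#'
#' @param lower_beliefs probability vector (policy-averaged belief over the
#'   monitored factor at the current time).
#' @param threshold entropy threshold in nats, in \code{(0, ln n)}.
#' @return logical flag.
#' @export
terminate_epoch <- function(lower_beliefs, threshold) {
  p <- norm_dist(as.numeric(lower_beliefs))
  if (threshold <= 0 || threshold >= log(length(p)) + 1e-12)
    stop("threshold must lie in (0, ln n)", call. = FALSE)
  entropy_cat(p, validate = FALSE) < threshold
}

#' Run a full trial of a two-level hierarchical model
#'
#' For each higher-level time step: the upper predictive belief is passed
#' down ([descend()]) to condition the lower level's initial-state and
#' policy priors; a lower-level trial runs (terminating early once its
#' uncertainty is resolved); its evidence is passed up ([ascend()]) and
#' enters the upper level's belief update together with any directly
#' observed upper outcome modalities; the upper level then evaluates its
#' policies, updates precision, and acts.
#'
#' @param model a [hierarchical_model()].
#' @param config list of settings shared by both levels, with optional
#'   \code{lower} and \code{upper} sub-lists of per-level overrides.
#'   Recognised keys as in [run_level_trial()], plus
#'   \code{entropy_threshold} for epoch termination.
#' @param process list: \code{true_states} (upper factors x horizon, NA
#'   sampled), \code{stream} (process randomness), \code{agent_stream}
#'   (action sampling).
#' @return list of class \code{"hierarchical_record"} with elements
#'   \code{upper} (a trial record), \code{lower} (list of per-epoch trial
#'   records), and \code{schedule} (epoch lengths and iteration offsets).
#' @export
run_hierarchical_trial <- function(model, config = list(), process = list()) {
  lower <- model$levels[[1]]
  upper <- model$levels[[2]]
  base <- config[setdiff(names(config), c("lower", "upper"))]
  lcfg <- utils::modifyList(utils::modifyList(list(
    n_iter = 96L, step = 0.25, beta_prior = 1, plan_horizon = 1L,
    action_mode = "deterministic", alpha = 16, track_F = FALSE,
    conv_tol = 0.01, adaptive = TRUE, precision_updates = TRUE,
    n_prec_iter = 16L,
    deterministic_outcomes = TRUE, entropy_threshold = 0.03,
    prune_pi = TRUE), base), config$lower %||% list())
  ## the slow level uses a gentler step: with strongly coupled factors a
  ## large step lets iterated mean-field feedback break the symmetry of
  ## genuinely mixed (correlated) posteriors within a single update block
  ucfg <- utils::modifyList(utils::modifyList(list(
    n_iter = 32L, step = 0.15, beta_prior = 1, plan_horizon = 1L,
    action_mode = "deterministic", alpha = 16, track_F = FALSE,
    conv_tol = 0.01, adaptive = FALSE, precision_updates = TRUE,
    n_prec_iter = 16L,
    deterministic_outcomes = FALSE, prune_pi = FALSE), base),
    config$upper %||% list())
  TT <- upper$horizon
  np <- upper$n_policies
  nf <- upper$n_factors
  ng <- upper$n_modalities
  lf <- model$link_factor
  pstream <- process$stream
  astream <- process$agent_stream
  beliefs <- init_beliefs(upper, beta = ucfg$beta_prior, lnE = ucfg$lnE)
  true_states <- matrix(NA_integer_, nf, TT)
  if (!is.null(process$true_states)) {
    ts <- process$true_states
    true_states[, seq_len(ncol(ts))] <- ts
  }
  observations <- vector("list", TT)
  evid <- vector("list", TT)
  rec <- list(F_pi = matrix(NA_real_, np, TT), G_pi = matrix(NA_real_, np, TT),
              q_pi = matrix(NA_real_, np, TT), beta = rep(NA_real_, TT),
              gamma_traj = matrix(NA_real_, ucfg$n_prec_iter, TT),
              steps = vector("list", TT), iters = rep(NA_integer_, TT),
              actions = matrix(NA_integer_, nf, max(TT - 1L, 1L)),
              o = matrix(NA_integer_, ng, TT),
              true_states = true_states, n_steps = TT, config = ucfg)
  lowers <- vector("list", TT)
  epoch_len <- integer(TT)
  prev_G <- prev_F <- NULL
  for (t in seq_len(TT)) {
    ## upper generative process
    for (f in seq_len(nf)) {
      if (is.na(true_states[f, t])) {
        if (t == 1L) {
          true_states[f, t] <- draw_state(upper$D[[f]], pstream)
        } else {
          u <- rec$actions[f, t - 1L]
          if (is.na(u)) u <- 1L
          true_states[f, t] <- draw_state(upper$B[[f]][, true_states[f, t - 1L], u],
                                          pstream)
        }
      }
    }
    jt <- joint_index(true_states[, t], upper$n_states)
    ## descending message conditions the lower level
    pred <- lapply(seq_len(nf), function(f) beliefs$bma[[f]][, t])
    dn <- descend(pred, model)
    ## lower-level generative process: linked state drawn from the link
    ## column of the true upper state, held fixed across the epoch
    s1 <- draw_state(model$link_init[, jt], pstream)
    ltrue <- matrix(NA_integer_, lower$n_factors, lower$horizon)
    ltrue[lf, ] <- s1
    lD <- lower$D
    lD[[lf]] <- dn$D
    lowrec <- run_level_trial(lower,
      config = utils::modifyList(lcfg, list(
        D_override = lD, lnE = dn$lnE,
        terminate = list(factor = lf, threshold = lcfg$entropy_threshold))),
      process = list(true_states = ltrue, stream = pstream,
                     agent_stream = astream))
    lowers[[t]] <- lowrec
    epoch_len[t] <- lowrec$n_steps
    ## ascending evidence plus any directly observed upper modalities
    evid[[t]] <- ascend(lowrec, model)
    obs_t <- as.list(rep(NA_integer_, ng))
    if (ng > 1L) for (g in 2:ng) {
      col <- matrix(upper$A[[g]], nrow = dim(upper$A[[g]])[1])[, jt]
      obs_t[[g]] <- draw_state(col, pstream, ucfg$deterministic_outcomes)
      rec$o[g, t] <- obs_t[[g]]
    }
    observations[[t]] <- obs_t
    ## upper-level inference and policy evaluation
    gu <- gradient_update(beliefs, upper, observations, n_iter = ucfg$n_iter,
                          step = ucfg$step, t_now = t, evid = evid,
                          track_F = ucfg$track_F, conv_tol = ucfg$conv_tol,
                          adaptive = ucfg$adaptive)
    beliefs <- gu$beliefs
    Fp <- vapply(seq_len(np), function(p)
      free_energy(upper, p, beliefs, observations, t_now = t, evid = evid), 0)
    Gp <- vapply(seq_len(np), function(p) {
      if (t >= TT) return(0)
      taus <- seq(t + 1L, min(t + (ucfg$plan_horizon %||% TT), TT))
      sum(vapply(taus, function(tau)
        expected_free_energy(upper, p, beliefs, tau, t_now = t)$G, 0))
    }, 0)
    pu <- update_precision(ucfg$beta_prior, Gp, Fp, lnE = beliefs$lnE,
                           n_iter = ucfg$n_prec_iter,
                           G_prior = prev_G, F_prior = prev_F)
    prev_G <- Gp; prev_F <- Fp
    beliefs$beta <- pu$beta
    q_pi <- pu$q_pi
    beliefs$q_pi <- q_pi
    beliefs$bma <- lapply(seq_len(nf), function(f)
      bayesian_model_average(q_pi, lapply(seq_len(np), function(p)
        beliefs$s_bar[[p]][[f]])))
    rec$F_pi[, t] <- Fp; rec$G_pi[, t] <- Gp; rec$q_pi[, t] <- q_pi
    rec$beta[t] <- beliefs$beta
    rec$gamma_traj[, t] <- pu$gamma_traj
    rec$steps[[t]] <- list(vn = gu$vn, xn = gu$xn)
    rec$iters[t] <- gu$iters_to_converge
    if (t < TT) {
      a <- select_action(q_pi, upper, beliefs, t, mode = ucfg$action_mode,
                         alpha = ucfg$alpha, stream = astream)
      rec$actions[, t] <- a
      beliefs$executed[, t] <- a
    }
  }
  rec$true_states <- true_states
  rec$beliefs <- beliefs
  rec$observations <- observations
  rec$evid <- evid
  class(rec) <- "trial_record"
  n_it_low <- lcfg$n_iter
  offsets <- integer(TT)
  run <- 0L
  for (t in seq_len(TT)) {
    offsets[t] <- run                      # iteration ticks before epoch t
    run <- run + epoch_len[t] * n_it_low + ucfg$n_iter
  }
  structure(list(upper = rec, lower = lowers,
                 schedule = list(epoch_len = epoch_len,
                                 lower_iters = n_it_low,
                                 upper_iters = ucfg$n_iter,
                                 offsets = offsets,
                                 total_ticks = run)),
            class = "hierarchical_record")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.hierarchical_record <- function(x, ...) {
  cat("<hierarchical_record> ", length(x$lower), " epoch(s), lengths: ",
      paste(x$schedule$epoch_len, collapse = " "), "\n", sep = "")
  invisible(x)
}
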