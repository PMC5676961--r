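## Scripted drivers for the five simulation studies: reaction-time scaling
## with memory set size, context- and load-dependent simulated ERPs,
## the precision (dopamine) sweep, and the volatility/forgetting grid.
## Every experiment is exactly reproducible from (config, seed): all
## randomness flows through label-separated streams.

## internal: run one delay-task trial with fixed upper true states
delay_trial <- function(model, seed, pair, order, probe,
                        config = list(), process_label = "process",
                        agent_label = "agent") {
  ts <- matrix(c(pair, order, probe, 1L, 1L), ncol = 1L)
  run_hierarchical_trial(model, config = config,
    process = list(true_states = ts,
                   stream = seeded_stream(seed, process_label),
                   agent_stream = seeded_stream(seed, agent_label)))
}

## internal: assemble an experiment_result
experiment_result <- function(label, tables, stats, seed, config) {
  structure(list(label = label, tables = tables, stats = stats,
                 seed = seed, config = config,
                 config_hash = config_hash(config)),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result> ", x$label, " (seed ", x$seed, ", config ",
      x$config_hash, ")\n", sep = "")
  utils::str(x$stats, give.attr = FALSE)
  invisible(x)
}

#' Reaction time versus memory set size
#'
#' Runs the delay task with 3, 4 and 5 possible scenes.  The probe is
#' always drawn outside the remembered pair, so a larger set size leaves
#' more alternatives to eliminate before the report.  Reaction time is the
#' number of belief-update iterations between probe onset and the report
#' ([reaction_time()]).  The trial realisation (pair, order, probe) is
#' identical across conditions and repetitions; a least-squares line is
#' fitted to the per-condition means.
#'
#' @param n_per_condition trials per set size (default 50).
#' @param set_sizes total scene counts (default 3, 4, 5).
#' @param seed master seed.
#' @param config model/inference overrides for [build_delay_task()] and
#'   [run_hierarchical_trial()].
#' @return an \code{experiment_result}; \code{stats} holds per-condition
#'   mean reaction times, the fitted \code{slope} and \code{r_squared},
#'   and any censored trials are tabulated separately.
#' @export
run_rt_experiment <- function(n_per_condition = 50L, set_sizes = c(3L, 4L, 5L),
                              seed = 1L, config = list()) {
  rows <- list()
  for (n in set_sizes) {
    model <- build_delay_task(utils::modifyList(list(n_total_scenes = n),
                                                config$model %||% list()))
    for (r in seq_len(n_per_condition)) {
      ## pair {1,2} shown in order; the probe cycles through the scenes
      ## outside the remembered pair (counterbalanced assignment)
      probe <- 3L + ((r - 1L) %% (n - 2L))
      hrec <- delay_trial(model, seed, 1L, 1L, probe,
                          config = config$run %||% list(),
                          process_label = paste0("process_", r),
                          agent_label = paste0("agent_", r))
      rt <- reaction_time(hrec)
      rows[[length(rows) + 1L]] <- data.frame(
        set_size = n, rep = r, probe = probe, rt = rt$rt,
        censored = rt$censored, response = rt$response)
    }
  }
  tab <- do.call(rbind, rows)
  ok <- !tab$censored
  means <- stats::aggregate(rt ~ set_size, data = tab[ok, ], FUN = mean)
  fit <- stats::lm(rt ~ set_size, data = means)
  stats_out <- list(
    mean_rt = stats::setNames(means$rt, means$set_size),
    slope = unname(stats::coef(fit)[2]),
    r_squared = summary(fit)$r.squared,
    n_censored = sum(tab$censored))
  experiment_result("reaction_time_set_size",
                    list(trials = tab, means = means),
                    stats_out, seed, list(n_per_condition = n_per_condition,
                                          set_sizes = set_sizes,
                                          config = config))
}

## internal: run the matched context/load trial for one validity
erp_trial <- function(validity, seed, config = list()) {
  model <- build_delay_task(utils::modifyList(
    list(retrocue_validity = validity), config$model %||% list()))
  ## probe inside the remembered pair, second presentation position: the
  ## cue (when valid) reduces uncertainty about the probed scene
  delay_trial(model, seed, 1L, 1L, 2L, config = config$run %||% list())
}

#' Context-updating ERP experiment (retrocue-locked)
#'
#' Simulates matched trials with an informative (valid) and an
#' uninformative (50%) retrocue, extracts retrocue-locked simulated ERPs
#' from the higher-level units representing the possible probes, and
#' summarises the valid-minus-invalid difference in the early and late
#' halves of the post-event update block.
#'
#' @param validities retrocue validities compared (first = context
#'   dependent, last = context independent).
#' @param seed master seed.
#' @param config overrides.
#' @return an \code{experiment_result} with the waveforms and the early /
#'   late difference means and signs.
#' @export
run_context_erp_experiment <- function(validities = c(0.9, 0.5), seed = 1L,
                                       config = list()) {
  model0 <- build_delay_task(config$model %||% list())
  task <- attr(model0, "task")
  lock <- task$retrocue_position
  npr <- model0$levels[[2]]$n_states[3]
  waves <- lapply(validities, function(v) {
    hrec <- erp_trial(v, seed, config)
    simulate_erp(hrec, factor = 3L, units = seq_len(npr), lock_event = lock,
                 window_steps = 1L, weighting = "rate",
                 condition = sprintf("validity_%g", v))
  })
  d <- waves[[1]]$value - waves[[length(waves)]]$value
  half <- length(d) %/% 2L
  early <- mean(d[seq_len(half)])
  late <- mean(d[seq(half + 1L, length(d))])
  stats_out <- list(early_diff = early, late_diff = late,
                    early_sign = sign(early), late_sign = sign(late),
                    sign_reversal = sign(early) * sign(late) < 0,
                    max_abs_diff = max(abs(d)))
  experiment_result("context_erp",
                    list(waveforms = waves, difference = d),
                    stats_out, seed, list(validities = validities,
                                          config = config))
}

#' Load-dependency ERP experiment (probe-locked)
#'
#' As [run_context_erp_experiment()], but responses are locked to the
#' probe stimulus.  A valid retrocue discounts the effective memory load
#' before the probe arrives, producing a sustained probe-locked difference
#' between conditions; the onset of sustained divergence is reported.
#'
#' @inheritParams run_context_erp_experiment
#' @return an \code{experiment_result} with waveforms, the difference, and
#'   \code{onset_tick} / \code{onset_ms} of sustained divergence (NA when
#'   none).
#' @export
run_load_erp_experiment <- function(validities = c(0.9, 0.5), seed = 1L,
                                    config = list()) {
  model0 <- build_delay_task(config$model %||% list())
  task <- attr(model0, "task")
  lock <- task$probe_position
  ## the response of the unit representing the probed item (the trial's
  ## true probe is scene 2, see erp_trial)
  waves <- lapply(validities, function(v) {
    hrec <- erp_trial(v, seed, config)
    simulate_erp(hrec, factor = 3L, units = 2L, lock_event = lock,
                 condition = sprintf("validity_%g", v))
  })
  d <- waves[[1]]$value - waves[[length(waves)]]$value
  thr <- 0.1 * max(abs(d))
  onset <- NA_integer_
  if (max(abs(d)) > 0) {
    ## sustained = above threshold for at least half an update block,
    ## which skips the brief transient at probe onset
    above <- abs(d) > thr
    run_len <- 16L
    for (i in seq_len(length(d) - run_len + 1L))
      if (all(above[i:(i + run_len - 1L)])) { onset <- i; break }
  }
  ms_per_iter <- waves[[1]]$ms[1]
  stats_out <- list(onset_tick = onset,
                    onset_ms = if (is.na(onset)) NA_real_ else onset * ms_per_iter,
                    sustained_diff = mean(abs(d[seq(length(d) %/% 2L + 1L, length(d))])),
                    max_abs_diff = max(abs(d)))
  experiment_result("load_erp", list(waveforms = waves, difference = d),
                    stats_out, seed, list(validities = validities,
                                          config = config))
}

#' Precision (dopamine) sweep
#'
#' Re-runs the same trial realisation under increasing prior inverse
#' precision beta (decreasing gamma, emulating graded dopaminergic
#' lesions): the generative-process stream is shared across beta values,
#' only the agent's precision differs.  Actions are sampled (policy choice
#' becomes more stochastic as gamma falls).  Reports fixation sequences,
#' fixations per scene, the frequency of fixations on the uninformative
#' lower-left quadrant, and the probe-locked phasic precision (dopamine)
#' amplitude.
#'
#' @param betas increasing grid of prior beta values.
#' @param seed master seed.
#' @param n_reps repetitions per beta (action sampling varies across reps).
#' @param action_mode \code{"sample"} (default) or \code{"deterministic"}.
#' @param config overrides.
#' @return an \code{experiment_result}; \code{stats} holds per-beta mean
#'   fixations per scene, lower-left fixation counts, and phasic
#'   amplitudes.
#' @export
run_dopamine_sweep <- function(betas = c(0.25, 1, 4), seed = 1L,
                               n_reps = 16L, action_mode = "sample",
                               config = list()) {
  model <- build_delay_task(config$model %||% list())
  task <- attr(model, "task")
  scene_steps <- c(2L, 3L)
  probe_step <- task$probe_position
  ll_pos <- 4L   # lower-left eye position index (center=1, TL, TR, LL, LR)
  rows <- list()
  for (bi in seq_along(betas)) {
    beta <- betas[bi]
    for (r in seq_len(n_reps)) {
      run_cfg <- utils::modifyList(list(beta_prior = beta,
                                        action_mode = action_mode),
                                   config$run %||% list())
      hrec <- delay_trial(model, seed, 1L, 1L, 2L, config = run_cfg,
                          process_label = paste0("process_", r),
                          agent_label = paste0("agent_", r))
      fix_scene <- vapply(scene_steps, function(t) {
        low <- hrec$lower[[t]]
        sum(low$true_states[2L, seq_len(low$n_steps)] != 1L)
      }, 0)
      ll_fix <- sum(vapply(seq_along(hrec$lower), function(t) {
        low <- hrec$lower[[t]]
        sum(low$true_states[2L, seq_len(low$n_steps)] == ll_pos)
      }, 0))
      da <- simulate_dopamine(hrec)
      probe_phasic <- max(c(0, da$phasic[da$step == probe_step]))
      rows[[length(rows) + 1L]] <- data.frame(
        beta = beta, rep = r,
        fix_scene1 = fix_scene[1], fix_scene2 = fix_scene[2],
        fix_per_scene = mean(fix_scene), ll_fixations = ll_fix,
        probe_phasic = probe_phasic)
    }
  }
  tab <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(fix_per_scene, ll_fixations, probe_phasic)
                          ~ beta, data = tab, FUN = mean)
  agg <- agg[order(agg$beta), ]
  stats_out <- list(
    betas = agg$beta,
    mean_fix_per_scene = agg$fix_per_scene,
    mean_ll_fixations = agg$ll_fixations,
    mean_probe_phasic = agg$probe_phasic,
    fix_nondecreasing = !is.unsorted(round(agg$fix_per_scene, 10)),
    phasic_decreasing = !is.unsorted(rev(round(agg$probe_phasic, 10))))
  experiment_result("dopamine_sweep", list(trials = tab, by_beta = agg),
                    stats_out, seed,
                    list(betas = betas, n_reps = n_reps,
                         action_mode = action_mode, config = config))
}

#' Volatility and observation-noise (forgetting) grid
#'
#' Runs the orientation maintenance task over a grid of likelihood (A) and
#' transition (B) kernel precisions.  Per cell it reports the pre-stimulus
#' decay rate of the maximal orientation belief (forgetting) and the
#' belief shift toward the stimulus orientation while it is presented
#' (updating).  A four-point transition-precision sweep extends the grid
#' to test that decay is monotone in the transition-column entropy.
#'
#' @param a_precisions likelihood kernel precisions (high, low).
#' @param b_precisions transition kernel precisions (high, low).
#' @param seed master seed (the task is deterministic; the seed is
#'   recorded for provenance).
#' @param b_sweep transition precisions for the monotonicity sweep.
#' @param config overrides passed to [build_orientation_task()].
#' @return an \code{experiment_result}; \code{stats} holds the 2x2 decay
#'   and shift matrices and the sweep table.
#' @export
run_forgetting_grid <- function(a_precisions = c(8, 1), b_precisions = c(8, 1),
                                seed = 1L, b_sweep = c(16, 8, 2, 0.5),
                                config = list()) {
  run_cell <- function(ap, bp) {
    task <- build_orientation_task(a_precision = ap, b_precision = bp,
                                   schedule = config$schedule %||% list())
    rec <- run_level_trial(task$level,
                           config = utils::modifyList(
                             list(precision_updates = FALSE), config$run %||% list()),
                           process = task$process)
    sch <- task$schedule
    ## the belief held about the current orientation at each step (end of
    ## that step's updates), not the retrospectively smoothed trajectory
    ts <- seq_len(rec$n_steps)
    bma <- vapply(ts, function(t) {
      xn <- rec$steps[[t]]$xn[[1]]
      xn[dim(xn)[1], , t]
    }, numeric(dim(rec$steps[[1]]$xn[[1]])[2]))
    maxb <- vapply(ts, function(t) max(bma[, t]), 0)
    pre <- seq_len(min(sch$onset - 1L, rec$n_steps))
    decay <- if (length(pre) > 1L)
      (maxb[pre[1]] - maxb[pre[length(pre)]]) / (length(pre) - 1L) else 0
    off <- min(sch$offset, rec$n_steps)
    on0 <- min(sch$onset - 1L, rec$n_steps)
    shift <- bma[sch$stim_bin, off] - bma[sch$stim_bin, on0]
    bcol_H <- transition_entropy(task$level$B[[1]][, sch$init_bin, 1])
    list(decay = decay, shift = shift, maxb = maxb, b_entropy = bcol_H)
  }
  decay <- shift <- matrix(NA_real_, length(a_precisions), length(b_precisions),
                           dimnames = list(paste0("A", a_precisions),
                                           paste0("B", b_precisions)))
  cells <- list()
  for (i in seq_along(a_precisions)) for (j in seq_along(b_precisions)) {
    cell <- run_cell(a_precisions[i], b_precisions[j])
    decay[i, j] <- cell$decay
    shift[i, j] <- cell$shift
    cells[[paste0("A", a_precisions[i], "_B", b_precisions[j])]] <- cell
  }
  sweep_tab <- do.call(rbind, lapply(b_sweep, function(bp) {
    cell <- run_cell(a_precisions[1], bp)
    data.frame(b_precision = bp, b_entropy = cell$b_entropy, decay = cell$decay)
  }))
  sweep_tab <- sweep_tab[order(sweep_tab$b_entropy), ]
  stats_out <- list(
    decay = decay, shift = shift,
    decay_monotone_in_entropy = !is.unsorted(round(sweep_tab$decay, 12)),
    shift_larger_precise_A = all(shift[1, ] >= shift[length(a_precisions), ]),
    decay_smaller_precise_B = all(decay[, 1] <= decay[, length(b_precisions)]))
  experiment_result("forgetting_grid",
                    list(cells = cells, sweep = sweep_tab),
                    stats_out, seed,
                    list(a_precisions = a_precisions,
                         b_precisions = b_precisions, b_sweep = b_sweep,
                         config = config))
}
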