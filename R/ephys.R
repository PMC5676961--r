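## Simulated neuronal observables derived from trial records: unit rasters
## (policy-averaged state expectations per gradient iteration), simulated
## ERPs (the rate of change nu_dot of log beliefs, which stands in for
## fluctuations in neuronal depolarisation), phasic dopamine (increments of
## the policy precision gamma), and reaction times (belief-update
## iterations between probe and report).

## internal: pick the upper/lower record out of a hierarchical record
resolve_record <- function(record, level = c("upper", "lower"), epoch = NULL) {
  if (inherits(record, "hierarchical_record")) {
    level <- match.arg(level)
    if (level == "upper") return(record$upper)
    if (is.null(epoch)) stop("epoch required for lower-level records", call. = FALSE)
    return(record$lower[[epoch]])
  }
  record
}

#' Unit raster: policy-averaged beliefs per gradient iteration
#'
#' Returns a matrix of firing-rate analogues: for each requested unit (a
#' state of one hidden factor), the policy-averaged expectation at the
#' currently processed time, across every gradient iteration of every
#' executed step, concatenated on a common iteration clock.
#'
#' @param record a [run_level_trial()] record, or a
#'   [run_hierarchical_trial()] record with \code{level}.
#' @param factor hidden-state factor index.
#' @param units state indices within the factor (default all).
#' @param level \code{"upper"} or \code{"lower"} for hierarchical records.
#' @param epoch epoch index when \code{level = "lower"}.
#' @return matrix \code{units x iterations}, with attribute \code{"step"}
#'   giving the trial step each iteration column belongs to.
#' @export
unit_raster <- function(record, factor = 1L, units = NULL,
                        level = "upper", epoch = NULL) {
  rec <- resolve_record(record, level, epoch)
  cols <- list(); stepid <- integer()
  for (t in seq_len(rec$n_steps)) {
    st <- rec$steps[[t]]
    if (is.null(st)) next
    xn <- st$xn[[factor]]
    if (is.null(units)) units <- seq_len(dim(xn)[2])
    if (any(units > dim(xn)[2])) stop("unknown unit index", call. = FALSE)
    block <- t(xn[, units, t, drop = FALSE][, , 1, drop = TRUE])
    if (length(units) == 1L) block <- matrix(xn[, units, t], nrow = 1L)
    cols[[t]] <- block
    stepid <- c(stepid, rep(t, dim(xn)[1]))
  }
  out <- do.call(cbind, cols)
  rownames(out) <- paste0("f", factor, "s", units)
  attr(out, "step") <- stepid
  out
}

#' Simulated event-related potential
#'
#' Extracts the policy-averaged belief increments \code{nu_dot} for the
#' requested units, averaged over units, locked to an event (a trial step)
#' and spanning the post-event update block (the event step and the
#' following \code{window_steps - 1} steps).  One gradient iteration maps
#' to \code{ms_per_iter} milliseconds for display only.
#'
#' @inheritParams unit_raster
#' @param lock_event trial step index the waveform is locked to.
#' @param window_steps number of update blocks spanned (default 2: the
#'   event block and the following block).
#' @param ms_per_iter display scale (default 8 ms per iteration, so a
#'   32-iteration update block spans ~250 ms).
#' @param weighting \code{"mean"} (plain average of the units' nu_dot) or
#'   \code{"rate"} (each unit's nu_dot weighted by its current
#'   expectation, a population-activity reading that exposes belief-mass
#'   redistribution between units).
#' @param condition label stored with the waveform.
#' @return object of class \code{"erp_waveform"}: list with \code{value}
#'   (mean nu_dot per iteration tick), \code{ms}, \code{condition},
#'   \code{units}, \code{lock_event}.
#' @export
simulate_erp <- function(record, factor, units, lock_event,
                         window_steps = 2L, ms_per_iter = 8,
                         weighting = c("mean", "rate"),
                         level = "upper", epoch = NULL, condition = "") {
  weighting <- match.arg(weighting)
  rec <- resolve_record(record, level, epoch)
  if (lock_event < 1L || lock_event > rec$n_steps)
    stop("lock event absent from record", call. = FALSE)
  vals <- c()
  for (t in seq(lock_event, min(lock_event + window_steps - 1L, rec$n_steps))) {
    vn <- rec$steps[[t]]$vn[[factor]]
    xn <- rec$steps[[t]]$xn[[factor]]
    vals <- c(vals, vapply(seq_len(dim(vn)[1]), function(i) {
      if (weighting == "rate") sum(xn[i, units, t] * vn[i, units, t])
      else mean(vn[i, units, t])
    }, 0))
  }
  structure(list(value = vals,
                 ms = seq_along(vals) * ms_per_iter,
                 condition = condition, units = units,
                 lock_event = lock_event),
            class = "erp_waveform")
}

#' @export
print.erp_waveform <- function(x, ...) {
  cat("<erp_waveform> ", x$condition, ": ", length(x$value),
      " ticks, range [", sprintf("%.4g", min(x$value)), ", ",
      sprintf("%.4g", max(x$value)), "]\n", sep = "")
  invisible(x)
}

#' Simulated dopamine: the precision trajectory and its phasic component
#'
#' Returns the policy precision \code{gamma = 1/beta} per update iteration
#' (concatenated over trial steps) and its first difference, the simulated
#' phasic dopamine signal.
#'
#' @inheritParams unit_raster
#' @return list with \code{gamma} (vector per precision-update iteration),
#'   \code{phasic} (first difference), and \code{step} (the trial step of
#'   each iteration).
#' @export
simulate_dopamine <- function(record, level = "upper", epoch = NULL) {
  rec <- resolve_record(record, level, epoch)
  ts <- seq_len(rec$n_steps)
  g <- as.vector(rec$gamma_traj[, ts])
  step <- rep(ts, each = nrow(rec$gamma_traj))
  keep <- !is.na(g)
  g <- g[keep]; step <- step[keep]
  list(gamma = g, phasic = c(0, diff(g)), step = step)
}

#' Reaction time in belief-update iterations
#'
#' Counts the gradient iterations needed for beliefs to settle
#' (iterations-to-convergence), summed over both levels, from probe onset
#' up to and including the step at which the report is selected.  This is
#' the deterministic proxy for computational time: larger belief spaces
#' and more dispersed priors settle more slowly and require more
#' fixations.
#'
#' @param record a [run_hierarchical_trial()] record of the delay task.
#' @param probe_event upper-level step at which the probe appears.
#' @param response_event upper-level step at which the report is selected.
#' @param report_factor upper factor holding the report state.
#' @return list with \code{rt} (iteration count), \code{censored} (TRUE
#'   when no report was emitted), and \code{response} (the action index).
#' @export
reaction_time <- function(record, probe_event = 6L, response_event = 6L,
                          report_factor = 5L) {
  if (!inherits(record, "hierarchical_record"))
    stop("reaction_time expects a hierarchical record", call. = FALSE)
  up <- record$upper
  if (probe_event > up$n_steps || response_event > up$n_steps ||
      response_event > ncol(up$actions))
    stop("probe or response event absent from record", call. = FALSE)
  rt <- 0L
  for (t in seq(probe_event, response_event)) {
    low <- record$lower[[t]]
    rt <- rt + sum(low$iters[seq_len(low$n_steps)])
    rt <- rt + up$iters[t]
  }
  resp <- up$actions[report_factor, response_event]
  censored <- is.na(resp) || resp == 1L
  list(rt = as.integer(rt), censored = censored, response = resp)
}
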