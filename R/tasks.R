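## The two concrete generative models: the two-level delay-period retrocue
## task and the single-level orientation maintenance (volatility) model.
##
## Delay task geometry.  Each test scene places two images in two of four
## quadrants (TL, TR, LL, LR).  The default layouts satisfy the verbal
## constraints of the paradigm: the lower-left quadrant is blank in every
## scene (the only never-informative location); exactly one of the three
## test scenes is diagonal; once the bird is known to be in the top left,
## the top right distinguishes the scenes; the lower right identifies a
## scene only if seeds are there.

IMG_LABELS <- c("blank", "bird", "cat", "seeds", "cue1", "cue2")
QUADRANTS <- c("TL", "TR", "LL", "LR")
EYE_LABELS <- c("center", QUADRANTS)
REPORT_LABELS <- c("withhold", "same", "different")
FEEDBACK_LABELS <- c("none", "correct", "incorrect")
SEQ_LABELS <- c("delay1", "scene1", "scene2", "retrocue", "delay2",
                "probe", "feedback")

#' Default scene layouts for the delay-period task
#'
#' @param n_total_scenes total number of scenes the model allows (3, 4 or 5).
#' @return matrix \code{n_total_scenes x 4} of image indices into
#'   \code{c("blank","bird","cat","seeds")}, columns TL, TR, LL, LR.
#' @export
default_scenes <- function(n_total_scenes = 3L) {
  blank <- 1L; bird <- 2L; cat_ <- 3L; seeds <- 4L
  ## extra scenes share the top-left image with existing ones, so every
  ## added scene adds real elimination work when the probe lies outside
  ## the remembered pair
  all <- rbind(
    c(bird,  seeds, blank, blank),   # horizontal
    c(bird,  cat_,  blank, blank),   # horizontal
    c(cat_,  blank, blank, seeds),   # the one diagonal scene
    c(cat_,  seeds, blank, blank),   # extra scenes for larger set sizes
    c(cat_,  bird,  blank, blank))
  if (!n_total_scenes %in% 3:5)
    stop("n_total_scenes must be 3, 4 or 5", call. = FALSE)
  m <- all[seq_len(n_total_scenes), , drop = FALSE]
  dimnames(m) <- list(paste0("scene", seq_len(n_total_scenes)), QUADRANTS)
  m
}

#' Validate a scene specification
#'
#' @param scenes matrix as returned by [default_scenes()].
#' @return character vector of violations (empty when valid).
#' @export
validate_scenes <- function(scenes) {
  out <- character()
  blank <- 1L
  nonblank <- scenes != blank
  if (any(rowSums(nonblank) != 2L))
    out <- c(out, "every test scene must have exactly two non-blank quadrants")
  if (any(nonblank[, 3]))
    out <- c(out, "the lower-left quadrant must be blank (uninformative) in every scene")
  diag3 <- apply(nonblank[1:3, , drop = FALSE], 1, function(r)
    (r[1] && r[4]) || (r[2] && r[3]))
  if (sum(diag3) != 1L)
    out <- c(out, "exactly one of the three test scenes must be diagonal")
  out
}

#' Default parameters of the delay-period task
#'
#' @return list: \code{retrocue_validity} (0.9), \code{n_total_scenes} (3),
#'   \code{likelihood_precision} (probability the model assigns to the true
#'   image at a fixated quadrant; 0.85), \code{feedback_prefs} (log
#'   preferences over none/correct/incorrect), \code{steps_per_epoch} (5:
#'   the central fixation step plus up to four quadrant fixations),
#'   \code{entropy_threshold} (0.03 nats).
#' @export
delay_task_params <- function() {
  list(retrocue_validity = 0.9,
       n_total_scenes = 3L,
       likelihood_precision = 0.85,
       feedback_prefs = c(0, 3, -6),
       steps_per_epoch = 5L,
       entropy_threshold = 0.03)
}

## internal: scene-state labels at level 1 (test scenes + blank + 2 cues)
scene_state_count <- function(n) n + 3L

## internal: index helpers
scene_blank_state <- function(n) n + 1L
scene_cue_state <- function(n, k) n + 1L + k

#' Build the two-level delay-period retrocue task
#'
#' Level 1 (fast): factor 1 is the displayed scene (test scenes, a blank
#' scene for fixation/delay periods, and two retrocue scenes); factor 2 is
#' eye position (a central fixation locus plus the four quadrants),
#' controlled through its transition array.  Outcomes are the visual image
#' at the fixated quadrant and proprioceptive eye position.  Level 2
#' (slow): the scene pair to remember, the presentation order, the probe
#' scene, the position in the trial sequence (deterministically
#' incrementing), and the agent's report (withhold / same / different).
#' Level-2 outcomes are the level-1 scene state (carried by the hierarchy
#' link) and feedback, with preferences favouring being correct.  The
#' retrocue link encodes the cue validity: the cue indicates the probed
#' presentation position with probability equal to the validity, and
#' carries no information about whether the probe is in the remembered
#' pair.
#'
#' @param params list overriding [delay_task_params()].
#' @param scenes scene layout matrix (default [default_scenes()]).
#' @return a [hierarchical_model()]; the task description (scene layouts,
#'   pair table, labels) is attached as attribute \code{"task"}.
#' @export
build_delay_task <- function(params = list(), scenes = NULL) {
  p <- utils::modifyList(delay_task_params(), params)
  n <- as.integer(p$n_total_scenes)
  if (p$retrocue_validity < 0.5 || p$retrocue_validity > 1)
    stop("retrocue_validity must lie in [0.5, 1]", call. = FALSE)
  if (is.null(scenes)) scenes <- default_scenes(n)
  if (nrow(scenes) != n)
    stop("scene count inconsistent with n_total_scenes", call. = FALSE)
  v <- validate_scenes(scenes)
  if (length(v)) stop("invalid scenes:\n  ", paste(v, collapse = "\n  "),
                      call. = FALSE)
  ## ---------------- level 1 ----------------
  nsc <- scene_state_count(n)      # displayed-scene states
  npos <- 5L                       # eye positions (center + 4 quadrants)
  a <- p$likelihood_precision
  w <- (1 - a) / 5
  ## visual likelihood: image at the fixated quadrant
  img_at <- function(s, q) {        # s: scene state, q: quadrant 1..4
    if (s <= n) scenes[s, q]
    else if (s == scene_blank_state(n)) 1L
    else 4L + (s - scene_blank_state(n))   # cue image fills every quadrant
  }
  A1v <- array(w, c(6L, nsc, npos))
  for (s in seq_len(nsc)) {
    A1v[, s, 1L] <- w; A1v[1L, s, 1L] <- a + w * 0   # center: blank for all
    A1v[1L, s, 1L] <- a
    for (q in seq_len(4L)) {
      A1v[, s, q + 1L] <- w
      A1v[img_at(s, q), s, q + 1L] <- a
    }
  }
  A1v <- array(apply(matrix(A1v, nrow = 6L), 2, norm_dist), dim(A1v))
  ## proprioception: identity on eye position
  A1p <- array(0, c(npos, nsc, npos))
  for (s in seq_len(nsc)) for (q in seq_len(npos)) A1p[q, s, q] <- 1
  B1s <- array(diag(nsc), c(nsc, nsc, 1L))
  B1e <- array(0, c(npos, npos, npos))
  for (u in seq_len(npos)) B1e[u, , u] <- 1
  D1 <- list(rep(1 / nsc, nsc), c(1, 0, 0, 0, 0))
  pols1 <- lapply(seq_len(npos), function(u) matrix(c(1L, u), 1L, 2L))
  level1 <- generative_level(
    A = list(visual = A1v, proprioceptive = A1p),
    B = list(scene = B1s, eye = B1e),
    C = list(rep(0, 6L), rep(0, npos)),
    D = D1, policies = pols1, horizon = p$steps_per_epoch,
    labels = list(states = list(scene = c(rownames(scenes),
                                          "blank", "cue1", "cue2"),
                                eye = EYE_LABELS),
                  outcomes = list(IMG_LABELS, EYE_LABELS),
                  actions = list("stay", EYE_LABELS)))
  ## ---------------- level 2 ----------------
  pairs <- rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  npair <- 3L; nord <- 2L; npr <- n; nseq <- 7L; nrep <- 3L
  ns2 <- c(npair, nord, npr, nseq, nrep)
  val <- p$retrocue_validity
  ## modality 1: the level-1 scene state generated at each position
  A21 <- array(0, c(nsc, ns2))
  for (pa in seq_len(npair)) for (or in seq_len(nord))
    for (pr in seq_len(npr)) for (sq in seq_len(nseq)) for (rp in seq_len(nrep)) {
      first <- if (or == 1L) pairs[pa, 1L] else pairs[pa, 2L]
      second <- if (or == 1L) pairs[pa, 2L] else pairs[pa, 1L]
      col <- rep(0, nsc)
      if (sq == 2L) col[first] <- 1
      else if (sq == 3L) col[second] <- 1
      else if (sq == 4L) {
        if (pr == first) {
          col[scene_cue_state(n, 1L)] <- val
          col[scene_cue_state(n, 2L)] <- 1 - val
        } else if (pr == second) {
          col[scene_cue_state(n, 2L)] <- val
          col[scene_cue_state(n, 1L)] <- 1 - val
        } else {
          col[scene_cue_state(n, 1L)] <- 0.5
          col[scene_cue_state(n, 2L)] <- 0.5
        }
      } else if (sq == 6L) col[pr] <- 1
      else col[scene_blank_state(n)] <- 1
      A21[, pa, or, pr, sq, rp] <- col
    }
  ## modality 2: feedback on the report
  A22 <- array(0, c(3L, ns2))
  for (pa in seq_len(npair)) for (or in seq_len(nord))
    for (pr in seq_len(npr)) for (sq in seq_len(nseq)) for (rp in seq_len(nrep)) {
      col <- rep(0, 3L)
      if (sq < 7L || rp == 1L) col[1L] <- 1
      else {
        inpair <- pr %in% pairs[pa, ]
        correct <- (rp == 2L && inpair) || (rp == 3L && !inpair)
        col[if (correct) 2L else 3L] <- 1
      }
      A22[, pa, or, pr, sq, rp] <- col
    }
  ident <- function(k) array(diag(k), c(k, k, 1L))
  Bseq <- matrix(0, nseq, nseq)
  for (sq in seq_len(nseq)) Bseq[min(sq + 1L, nseq), sq] <- 1
  Brep <- array(0, c(nrep, nrep, nrep))
  for (u in seq_len(nrep)) Brep[u, , u] <- 1
  D2 <- list(rep(1 / npair, npair), rep(1 / nord, nord), rep(1 / npr, npr),
             c(1, rep(0, nseq - 1L)), c(1, 0, 0))
  pols2 <- lapply(seq_len(nrep), function(u) matrix(c(1L, 1L, 1L, 1L, u), 1L, 5L))
  level2 <- generative_level(
    A = list(scene = A21, feedback = A22),
    B = list(pair = ident(npair), order = ident(nord), probe = ident(npr),
             seq = array(Bseq, c(nseq, nseq, 1L)), report = Brep),
    C = list(rep(0, nsc), p$feedback_prefs),
    D = D2, policies = pols2, horizon = nseq,
    labels = list(states = list(pair = apply(pairs, 1, paste, collapse = "+"),
                                order = c("forward", "reversed"),
                                probe = rownames(scenes),
                                seq = SEQ_LABELS, report = REPORT_LABELS),
                  outcomes = list(c(rownames(scenes), "blank", "cue1", "cue2"),
                                  FEEDBACK_LABELS),
                  actions = list("stay", "stay", "stay", "stay", REPORT_LABELS)))
  model <- hierarchical_model(list(level1, level2),
                              steps_per_epoch = p$steps_per_epoch)
  attr(model, "task") <- list(scenes = scenes, pairs = pairs, params = p,
                              probe_position = 6L, retrocue_position = 4L,
                              feedback_position = 7L)
  model
}

#' Marginal probability that the probe lies in the remembered pair
#'
#' Under the task's probe prior, sums over pairs (weighted by the supplied
#' pair belief) the probability that the probe is one of the pair members.
#' With three possible scenes and a uniform probe prior this is the
#' Monty-Hall-style two-thirds marginal that the agent's beliefs inherit.
#'
#' @param model a [build_delay_task()] model.
#' @param pair_belief probability vector over the three scene pairs.
#' @return scalar probability.
#' @export
monty_hall_marginal <- function(model, pair_belief) {
  task <- attr(model, "task")
  upper <- model$levels[[2]]
  assert_dist(pair_belief, "pair_belief")
  if (length(pair_belief) != nrow(task$pairs))
    stop("pair_belief cardinality mismatch", call. = FALSE)
  probe_prior <- upper$D[[3]]
  sum(vapply(seq_len(nrow(task$pairs)), function(pa)
    pair_belief[pa] * sum(probe_prior[task$pairs[pa, ]]), 0))
}

#' Build the single-level orientation maintenance task
#'
#' One hidden factor is the orientation of a bar over \code{n_bins}
#' discrete angles (transitions given by a banded kernel whose dispersion
#' encodes believed volatility); the second is whether the stimulus is
#' visible.  The single outcome modality reports the observed orientation
#' through a banded likelihood kernel (precision = believed sensory
#' signal-to-noise) when the stimulus is visible, and an "absent" outcome
#' otherwise.  Initial beliefs are peaked close to pi radians; the
#' scheduled stimulus is presented at around pi/2 radians.
#'
#' @param n_bins number of orientation bins (default 20).
#' @param a_precision likelihood kernel precision (0 gives a uniform,
#'   maximally imprecise likelihood; \code{Inf} an identity mapping).
#' @param b_precision transition kernel precision (volatility decreases as
#'   precision grows; \code{Inf} gives the identity, zero volatility).
#' @param schedule list: \code{horizon} (10), \code{onset} (4),
#'   \code{offset} (5), \code{stim_bin} (bin at ~pi/2), \code{init_bin}
#'   (bin at ~pi), \code{init_precision} (sharpness of the initial belief).
#' @param circular treat orientation as circular (wrapping) state space.
#' @return list with \code{level} (a [generative_level()]) and
#'   \code{process} (true states and outcomes implementing the stimulus
#'   schedule), suitable for [run_level_trial()].
#' @export
build_orientation_task <- function(n_bins = 20L, a_precision = 4,
                                   b_precision = 4, schedule = list(),
                                   circular = TRUE) {
  if (n_bins < 2L) stop("n_bins must be at least 2", call. = FALSE)
  if (a_precision < 0 || b_precision < 0)
    stop("precisions must be non-negative", call. = FALSE)
  sch <- utils::modifyList(
    list(horizon = 10L, onset = 4L, offset = 5L,
         stim_bin = round(n_bins / 4) + 1L,
         init_bin = round(n_bins / 2) + 1L,
         init_precision = 2), schedule)
  kern <- function(prec) {
    if (is.infinite(prec)) diag(n_bins)
    else if (prec == 0) matrix(1 / n_bins, n_bins, n_bins)
    else make_banded_kernel(n_bins, prec, circular = circular)
  }
  Bor <- kern(b_precision)
  Aor <- kern(a_precision)
  ## outcome modality: n_bins orientation outcomes + "absent"
  A <- array(0, c(n_bins + 1L, n_bins, 2L))
  A[seq_len(n_bins), , 2L] <- Aor          # visible
  A[n_bins + 1L, , 1L] <- 1                # hidden -> absent
  Bvis <- array(0.5, c(2L, 2L, 1L))        # memoryless visibility belief
  D <- list(kern(sch$init_precision)[, sch$init_bin], c(1, 0))
  level <- generative_level(
    A = list(orientation = A),
    B = list(orientation = array(Bor, c(n_bins, n_bins, 1L)),
             visibility = Bvis),
    C = list(rep(0, n_bins + 1L)),
    D = D, policies = matrix(c(1L, 1L), 1L, 2L), horizon = sch$horizon,
    labels = list(states = list(
      orientation = sprintf("%.2frad", 2 * pi * (seq_len(n_bins) - 1L) / n_bins),
      visibility = c("hidden", "visible"))))
  vis <- as.integer(seq_len(sch$horizon) >= sch$onset &
                      seq_len(sch$horizon) <= sch$offset)
  true_states <- rbind(rep(sch$stim_bin, sch$horizon), vis + 1L)
  outcomes <- matrix(ifelse(vis == 1L, sch$stim_bin, n_bins + 1L), 1L)
  list(level = level,
       process = list(true_states = true_states, outcomes = outcomes),
       schedule = sch)
}
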