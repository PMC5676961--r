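test_that("scene layouts satisfy the task's structural constraints", {
  for (n in 3:5) {
    sc <- default_scenes(n)
    expect_identical(validate_scenes(sc), character(0))
    ## lower-left blank everywhere: the only never-informative quadrant
    expect_true(all(sc[, "LL"] == 1L))
    expect_true(all(rowSums(sc != 1L) == 2L))
  }
  expect_error(default_scenes(6), "3, 4 or 5")
  bad <- default_scenes(3)
  bad[1, "LL"] <- 2L
  expect_true(length(validate_scenes(bad)) > 0)
})

test_that("the delay-task likelihood maps scenes and fixations to the displayed images", {
  model <- build_delay_task()
  lv1 <- model$levels[[1]]
  sc <- attr(model, "task")$scenes
  a <- delay_task_params()$likelihood_precision
  A1 <- lv1$A[[1]]
  ## fixating quadrant q of scene s yields that scene's image there
  for (s in 1:3) for (q in 1:4)
    expect_equal(A1[sc[s, q], s, q + 1], a, tolerance = 1e-9)
  ## the lower-left visual outcome is identical across all test scenes
  for (s in 2:3)
    expect_equal(A1[, s, 4], A1[, 1, 4], tolerance = 1e-12)
  ## central fixation is uninformative about every scene
  for (s in 2:6)
    expect_equal(A1[, s, 1], A1[, 1, 1], tolerance = 1e-12)
  ## proprioception is an identity map on eye position
  for (q in 1:5) expect_equal(lv1$A[[2]][q, 1, q], 1)
})

test_that("the second level encodes the trial grammar", {
  model <- build_delay_task()
  lv2 <- model$levels[[2]]
  ## sequence-position transitions form a deterministic shift matrix
  Bseq <- lv2$B[[4]][, , 1]
  expect_true(all(Bseq %in% c(0, 1)))
  for (sq in 1:6) expect_equal(which(Bseq[, sq] == 1), sq + 1)
  expect_equal(which(Bseq[, 7] == 1), 7)   # absorbing end state
  ## the probe-state prior marginal: with 3 scenes there is a 2/3 chance
  ## the probe lies in the remembered pair
  expect_equal(monty_hall_marginal(model, c(1, 0, 0)), 2 / 3, tolerance = 1e-12)
  expect_equal(monty_hall_marginal(model, rep(1 / 3, 3)), 2 / 3, tolerance = 1e-12)
  ## a probe prior concentrated on a pair member gives certainty
  m2 <- model
  m2$levels[[2]]$D[[3]] <- c(1, 0, 0)
  expect_equal(monty_hall_marginal(m2, c(1, 0, 0)), 1)
  expect_error(monty_hall_marginal(model, c(.5, .5)), "cardinality|pair_belief")
})

test_that("retrocue link columns encode the cue validity", {
  ## validity 0.5: the two cue states are equiprobable whatever the probe
  m5 <- build_delay_task(list(retrocue_validity = 0.5))
  A21 <- m5$levels[[2]]$A[[1]]
  ## pair 1 = scenes {1,2}, forward order, retrocue position (seq = 4);
  ## cue states are 5 and 6 (after the 3 scenes and the blank state)
  for (pr in 1:3)
    expect_equal(A21[5, 1, 1, pr, 4, 1], A21[6, 1, 1, pr, 4, 1])
  ## validity 0.9: cue 2 signals that the probe matches the second-shown
  m9 <- build_delay_task(list(retrocue_validity = 0.9))
  A9 <- m9$levels[[2]]$A[[1]]
  expect_equal(A9[5, 1, 1, 1, 4, 1], 0.9)  # probe = first member -> cue1
  expect_equal(A9[6, 1, 1, 2, 4, 1], 0.9)  # probe = second member -> cue2
  ## probe outside the pair: cues carry no information
  expect_equal(A9[5, 1, 1, 3, 4, 1], 0.5)
  expect_error(build_delay_task(list(retrocue_validity = 1.2)), "0.5, 1")
})

test_that("feedback outcomes reward correct reports at the feedback position only", {
  model <- build_delay_task()
  A22 <- model$levels[[2]]$A[[2]]
  ## before the feedback position: always "none"
  expect_equal(A22[1, 1, 1, 1, 5, 2], 1)
  ## report "same" with the probe in the pair: correct
  expect_equal(A22[2, 1, 1, 1, 7, 2], 1)
  ## report "same" with the probe outside the pair: incorrect
  expect_equal(A22[3, 1, 1, 3, 7, 2], 1)
  ## report "different" with the probe outside the pair: correct
  expect_equal(A22[2, 1, 1, 3, 7, 3], 1)
  ## withholding yields no feedback
  expect_equal(A22[1, 1, 1, 1, 7, 1], 1)
})

test_that("orientation maintenance holds beliefs under an identity transition", {
  task <- build_orientation_task(b_precision = Inf, a_precision = 4,
                                 schedule = list(onset = 99L, offset = 99L))
  rec <- run_level_trial(task$level,
                         config = list(precision_updates = FALSE),
                         process = task$process)
  bma <- rec$beliefs$bma[[1]]
  for (t in 2:10) expect_equal(bma[, t], bma[, 1], tolerance = 1e-3)
})

test_that("a uniform likelihood leaves the maintained orientation unmoved by the stimulus", {
  task <- build_orientation_task(a_precision = 0, b_precision = Inf)
  rec <- run_level_trial(task$level,
                         config = list(precision_updates = FALSE),
                         process = task$process)
  bma <- rec$beliefs$bma[[1]]
  expect_equal(which.max(bma[, 6]), which.max(bma[, 1]))
})

test_that("belief dispersion after unstimulated steps grows with believed volatility", {
  run_h <- function(bp) {
    task <- build_orientation_task(b_precision = bp, a_precision = 4,
                                   schedule = list(onset = 99L, offset = 99L))
    rec <- run_level_trial(task$level,
                           config = list(precision_updates = FALSE),
                           process = task$process)
    xn <- rec$steps[[5]]$xn[[1]]
    entropy_cat(norm_dist(xn[dim(xn)[1], , 5]), validate = FALSE)
  }
  expect_gt(run_h(0.5), run_h(8))
})

test_that("orientation task errors on invalid precisions and bins", {
  expect_error(build_orientation_task(n_bins = 1), "at least 2")
  expect_error(build_orientation_task(a_precision = -1), "non-negative")
})
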