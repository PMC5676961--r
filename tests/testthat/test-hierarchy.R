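test_that("descending messages are link-weighted mixtures", {
  links <- list(link_init = cbind(c(1, 0), c(0, 1)),
                link_policy = matrix(0.5, 2, 2))
  ## delta upper belief selects the corresponding link column
  expect_equal(descend(c(1, 0), links)$D, c(1, 0))
  ## uniform upper belief through an identity link stays uniform
  expect_equal(descend(c(.5, .5), links)$D, c(.5, .5))
  links2 <- list(link_init = cbind(c(.7, .3), c(.2, .8)),
                 link_policy = cbind(c(.9, .1), c(.4, .6)))
  d <- descend(c(.5, .5), links2)
  expect_equal(d$D, as.vector(links2$link_init %*% c(.5, .5)))
  expect_equal(exp(d$lnE), as.vector(links2$link_policy %*% c(.5, .5)),
               tolerance = 1e-9)
  expect_equal(sum(d$D), 1, tolerance = 1e-12)
  expect_error(descend(c(.5, .3, .2), links), "mismatch")
})

test_that("ascending messages carry prior-corrected log evidence", {
  links <- list(link_init = cbind(c(1, 0), c(0, 1)), link_factor = 1L)
  ## delta posterior on state k (no prior correction supplied): message
  ## proportional to ln of row k of the link
  m <- ascend(c(1, 0), links)
  expect_equal(which.max(m), 1L)
  expect_lt(m[2], m[1] - 20)
  ## uniform posterior with a uniform link: constant message
  lu <- list(link_init = matrix(.5, 2, 2), link_factor = 1L)
  mu <- ascend(c(.5, .5), lu)
  expect_equal(mu[1], mu[2], tolerance = 1e-12)
  ## 2x2 toy: hand-computed ln(link' lik)
  l2 <- list(link_init = cbind(c(.7, .3), c(.2, .8)), link_factor = 1L)
  lik <- c(.6, .4)
  expect_equal(ascend(lik, l2), as.vector(log(t(l2$link_init) %*% lik)),
               tolerance = 1e-9)
  ## invariance to rescaling the lower posterior
  expect_equal(ascend(10 * lik, l2), ascend(lik, l2), tolerance = 1e-12)
  expect_error(ascend(c(.5, .3, .2), l2), "mismatch")
})

test_that("epoch termination triggers on resolved uncertainty", {
  expect_true(terminate_epoch(c(1, 0, 0), 0.05))
  expect_false(terminate_epoch(rep(1 / 6, 6), 0.5))
  ## entropy of (.9,.05,.05) is about 0.394 nats
  expect_equal(entropy_cat(c(.9, .05, .05)), 0.39440, tolerance = 1e-4)
  expect_true(terminate_epoch(c(.9, .05, .05), 0.5))
  expect_false(terminate_epoch(c(.9, .05, .05), 0.30))
  expect_error(terminate_epoch(c(.5, .5), 2), "ln n")
  expect_error(terminate_epoch(c(.5, .5), 0), "ln n")
})

test_that("a one-step-per-epoch hierarchy with identity links matches the flat model", {
  set.seed(21)
  ns <- 3
  B_up <- rand_stochastic(ns)
  A_low <- rand_stochastic(ns)
  D_up <- rand_dist(ns)
  ## lower level: single step, observes the linked state through A_low
  lower <- generative_level(A = A_low, B = array(diag(ns), c(ns, ns, 1)),
                            D = rep(1 / ns, ns),
                            policies = matrix(1L, 1, 1), horizon = 1)
  ## upper level: its sole outcome modality is the lower state (identity)
  TT <- 3
  upper <- generative_level(A = array(diag(ns), c(ns, ns)),
                            B = array(B_up, c(ns, ns, 1)), D = D_up,
                            policies = matrix(1L, 1, 1), horizon = TT)
  model <- hierarchical_model(list(lower, upper), steps_per_epoch = 1)
  hrec <- run_hierarchical_trial(model,
    config = list(lower = list(adaptive = FALSE, n_iter = 300L),
                  upper = list(n_iter = 300L)),
    process = list(stream = seeded_stream(3, "process")))
  ## flat oracle: an HMM with transition B_up and likelihood A_low
  o <- vapply(seq_len(TT), function(t)
    as.integer(hrec$lower[[t]]$o[1, 1]), 1L)
  ex <- enum_posterior(A_low, B_up, D_up, o, TT)
  for (t in seq_len(TT))
    expect_lt(max(abs(hrec$upper$beliefs$bma[[1]][, t] - ex$marginals[, t])),
              1e-3)
})

test_that("an uninformative lower level leaves upper beliefs at their priors", {
  ns <- 3
  lower <- generative_level(A = matrix(1 / ns, ns, ns),
                            B = array(diag(ns), c(ns, ns, 1)),
                            D = rep(1 / ns, ns),
                            policies = matrix(1L, 1, 1), horizon = 1)
  B_up <- rand_stochastic(ns)
  D_up <- c(.5, .3, .2)
  upper <- generative_level(A = array(diag(ns), c(ns, ns)),
                            B = array(B_up, c(ns, ns, 1)), D = D_up,
                            policies = matrix(1L, 1, 1), horizon = 2)
  model <- hierarchical_model(list(lower, upper), steps_per_epoch = 1)
  hrec <- run_hierarchical_trial(model,
    config = list(upper = list(n_iter = 120L)),
    process = list(stream = seeded_stream(4, "process")))
  expect_equal(hrec$upper$beliefs$bma[[1]][, 1], D_up, tolerance = 1e-3)
  expect_equal(hrec$upper$beliefs$bma[[1]][, 2], as.vector(B_up %*% D_up),
               tolerance = 1e-3)
})

test_that("hierarchical trials are reproducible from their seeds", {
  r1 <- example_delay_trial()
  model <- attr(r1, "model")
  ts <- matrix(c(1L, 1L, 2L, 1L, 1L), ncol = 1)
  r2 <- run_hierarchical_trial(model, process = list(
    true_states = ts,
    stream = seeded_stream(1, "process"),
    agent_stream = seeded_stream(1, "agent")))
  expect_identical(r1$schedule$epoch_len, r2$schedule$epoch_len)
  expect_identical(r1$upper$o, r2$upper$o)
  expect_equal(r1$upper$beliefs$bma, r2$upper$beliefs$bma, tolerance = 0)
  expect_equal(r1$upper$gamma_traj, r2$upper$gamma_traj, tolerance = 0)
})

test_that("upper-level beliefs change on fewer steps than lower-level ones", {
  ## temporal depth: the fast level re-infers a new scene every epoch; the
  ## slow level's pair belief settles once and persists
  hrec <- example_delay_trial()
  up_pair <- hrec$upper$beliefs$bma[[1]]
  ## pair belief after scene 2 (step 3) stays fixed to the end
  for (t in 4:7)
    expect_equal(up_pair[, t], up_pair[, 3], tolerance = 1e-2)
  ## lower scene beliefs differ radically across epochs
  s2 <- hrec$lower[[2]]$beliefs$bma[[1]][, hrec$lower[[2]]$n_steps]
  s3 <- hrec$lower[[3]]$beliefs$bma[[1]][, hrec$lower[[3]]$n_steps]
  expect_gt(max(abs(s2 - s3)), 0.8)
})
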