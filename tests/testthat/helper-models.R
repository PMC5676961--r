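## Shared fixtures: random single-factor levels, exhaustive-enumeration
## oracles, and a memoised example trial of the delay task.

rand_dist <- function(n) {
  x <- rgamma(n, 1)
  x / sum(x)
}

rand_stochastic <- function(nr, nc = nr) {
  m <- matrix(rgamma(nr * nc, 1), nr, nc)
  sweep(m, 2, colSums(m), "/")
}

## a random single-factor, single-policy level
rand_level <- function(ns = sample(2:4, 1), TT = sample(2:3, 1),
                       no = ns) {
  generative_level(A = rand_stochastic(no, ns),
                   B = array(rand_stochastic(ns), c(ns, ns, 1)),
                   D = rand_dist(ns),
                   policies = matrix(1L, 1, 1), horizon = TT)
}

## exhaustive enumeration of P(s_1..s_T | o_1..o_upto) marginals for a
## single-factor, single-action chain
enum_posterior <- function(A, B, D, o, TT, upto = length(o)) {
  ns <- length(D)
  grids <- do.call(expand.grid, rep(list(seq_len(ns)), TT))
  w <- apply(grids, 1, function(s) {
    p <- D[s[1]] * (if (1 <= upto) A[o[1], s[1]] else 1)
    if (TT > 1) for (t in 2:TT)
      p <- p * B[s[t], s[t - 1]] * (if (t <= upto) A[o[t], s[t]] else 1)
    p
  })
  Z <- sum(w)
  w <- w / Z
  marg <- sapply(seq_len(TT), function(t)
    sapply(seq_len(ns), function(k) sum(w[grids[[t]] == k])))
  list(marginals = marg, logZ = log(Z))
}

## converged beliefs for a level given a full observation list
converge_beliefs <- function(level, o, upto = length(o), n_iter = 160) {
  b <- init_beliefs(level)
  obs <- lapply(o, function(x) list(as.integer(x)))
  gradient_update(b, level, obs, n_iter = n_iter, t_now = upto)
}

## memoised example trial of the default delay task (pair {1,2} in order,
## probe = scene 2, seed 1)
example_delay_trial <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      model <- build_delay_task()
      ts <- matrix(c(1L, 1L, 2L, 1L, 1L), ncol = 1)
      out <- run_hierarchical_trial(model, process = list(
        true_states = ts,
        stream = seeded_stream(1, "process"),
        agent_stream = seeded_stream(1, "agent")))
      attr(out, "model") <- model
      cache <<- out
    }
    cache
  }
})
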