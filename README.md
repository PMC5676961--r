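# actinf

Active-inference simulations of working memory, attention and salience.

`actinf` is an R package for building and simulating categorical
(Markov decision process) generative models in which perception and
action both minimise variational free energy.  It is aimed at
computational neuroscientists who want a tested, fully scriptable
simulator for the classic delay-period working-memory phenomenology:
persistent delay-period activity, retrocue effects, reaction-time
scaling with memory load, simulated event-related potentials, phasic
dopamine as policy precision, and volatility-driven forgetting.

## The model in brief

One level of a generative model is the tuple (**A**, **B**, **C**,
**D**): likelihood arrays `A[o, s]`, action-conditioned transition
arrays `B[s', s, u]`, log outcome preferences `C`, and initial-state
priors `D`, over factorised hidden states.  Beliefs
`Q(s_t | pi) = softmax(nu)` evolve by a gradient relaxation
`nu <- nu + step * (message_sum - nu)` whose fixed point is the exact
(sum-product) conditional posterior on single-factor chains.  Policies
`pi` (sequences of actions) are scored by their expected free energy

    G(pi, tau) = -E[ln P(o_tau)]  +  E[ln Q(s_tau|pi) - ln P(s_tau|o_tau, pi)]
                 (pragmatic value)    (epistemic value = -I(s; o) <= 0)

and selected through `Q(pi) = softmax(lnE - gamma * G - F)`, where the
precision `gamma = 1/beta` is itself updated by a fixed point whose
phasic excursions are read out as simulated dopamine.  Two levels
compose into a deep temporal model: each slow upper step spawns a fast
lower-level trial, conditioned from above (initial-state and policy
priors) and reporting evidence upward.

Two tasks ship with the package: the two-level delay-period retrocue
task (scenes of two images in four quadrants, saccadic sampling, a 90%
valid retrocue, and a same/different report on a probe) and a
single-level orientation maintenance task in which the precision of the
transition and likelihood kernels sets forgetting and attention-like
updating.

## A worked example

```r
library(actinf)

model <- build_delay_task()          # 2-level retrocue task, 3 scenes
trial <- run_hierarchical_trial(
  model,
  process = list(true_states = matrix(c(1L, 1L, 2L, 1L, 1L), ncol = 1),
                 stream = seeded_stream(1, "process"),
                 agent_stream = seeded_stream(1, "agent")))

trial$schedule$epoch_len
#> [1] 1 3 3 3 1 3 1
trial$upper$actions[5, 6]            # report action chosen at the probe
#> [1] 2
trial$upper$o[2, 7]                  # feedback outcome
#> [1] 2
round(trial$upper$beliefs$bma[[1]][, 7], 3)   # pair belief at trial end
#> [1] 1 0 0
reaction_time(trial)$rt
#> [1] 201
```

The agent fixates each scene twice (each scene epoch spends one step at
the central fixation locus and two on quadrants), infers the remembered
pair with certainty (`1 0 0`: scenes {1, 2}), reports "same" (action 2)
when the probe matches a remembered scene, and is told it was correct
(feedback 2).  The reaction time is the number of belief-update
iterations between probe onset and the report.

Experiment drivers reproduce the headline simulations end to end:

```r
rt <- run_rt_experiment(seed = 1)    # 50 trials per set size 3/4/5
rt$stats$mean_rt
#>      3      4      5
#> 201.00 270.76 294.14
rt$stats$r_squared
#> [1] 0.9236551
```

plus `run_context_erp_experiment()` (retrocue-locked ERP difference that
reverses sign), `run_load_erp_experiment()` (sustained probe-locked
difference, abolished by an uninformative cue), `run_dopamine_sweep()`
(fixations per scene rise and phasic dopamine falls as beta grows), and
`run_forgetting_grid()` (forgetting monotone in believed volatility).
A thin command-line wrapper over the same functions is installed at
`inst/cli/actinf.R` (`validate`, `run`, `export-model`).

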