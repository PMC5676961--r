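---
title: "Working memory, attention and salience as active inference: the models behind actinf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Working memory, attention and salience as active inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actinf)
```

## The generative model

`actinf` simulates agents that perceive and act by minimising variational
free energy under a categorical (Markov decision process) generative
model.  One level of such a model is specified by four arrays:

* **A** — the likelihood, `P(o_t | s_t)`, one array per outcome modality,
  with one column per combination of hidden states;
* **B** — the transitions, `P(s_{t+1} | s_t, u)`, one array per hidden
  state factor, with one slice per action `u`;
* **C** — log preferences over outcomes (they need not normalise: they
  enter only through expected log preference);
* **D** — the prior over initial states.

Hidden states are factorised (a mean-field approximation): each factor
carries its own posterior, and factors interact only through the
likelihood arrays.  Policies are sequences of action tuples.  The agent
holds a policy-conditioned posterior over states at every time in the
horizon, a posterior over policies, and a precision (inverse temperature)
`gamma = 1/beta` over the policy prior.

## Belief updating

Beliefs are log-space vectors `nu` whose softmax is the posterior
`Q(s_t | pi)`.  Updating is a gradient relaxation,

    nu <- nu + step * eps,    eps = (message sum) - nu,

where the message sum collects a forward transition message, a backward
transition message, and the log likelihood of observed outcomes.  Two
numerical choices matter here and are deliberate:

* **Messages are sum-product (cavity) messages.**  The forward message
  into time `t` is `B %*% (s_bar[t-1] / backward_message[t-1])`,
  normalised — the division removes the future-derived part of the
  marginal so that evidence is never counted twice.  On a single-factor
  chain the fixed point of the relaxation therefore equals the *exact*
  conditional posterior, which is what the test suite verifies against
  brute-force enumeration.  Backward messages are exactly uniform at and
  beyond the last observed time (no evidence lives there); enforcing this
  structurally removes a spurious feedback loop through unobserved
  futures that otherwise sustains small oscillations.
* **Messages are damped** (averaged with their previous value), which
  suppresses relaxation two-cycles without moving the fixed point.

The default schedule is 32 iterations per time step, with step size 0.25
at the fast level and 0.15 at the slow level.  Sixteen iterations
converge on loosely coupled models but demonstrably under-converge the
five-step lower level of the delay task (evidence takes several
iterations per time-step hop to propagate through an identity-transition
chain); 32 restores the analytic fixed points the task's behaviour was
designed around.  The smaller step at the slow level is not cosmetic:
its factors (pair and presentation order) are strongly coupled, and
after the first scene their joint posterior is a genuinely bimodal
mixture that a factorised posterior can only represent as two elevated
marginals.  With a large step, iterated mean-field feedback within one
update block amplifies any tiny asymmetry and collapses the mixture onto
a single — sometimes wrong — mode; at step 0.15 the mixture survives the
block, which is also what keeps the delay-period pair units in the
sustained two-alternative regime.  The lower (fast) level stops early
once the largest belief increment falls below 0.01 nats, so the number
of iterations it *executes* is a deterministic measure of how hard an
update was; the upper level always runs its full block so that
event-locked waveforms share a common clock.

### Free energy

The per-policy free energy reported by `free_energy()` is evaluated on
the chain-structured variational density implied by the current beliefs
(`q(s_1)` plus cavity-reweighted transition kernels), not on the naive
product of marginals.  This matters: the chain form is a valid upper
bound on `-ln P(o | pi)` for any beliefs, and it is *saturated* — equals
the log evidence exactly — at the sum-product fixed point, which is what
ties free-energy minimisation, exact inference, and the Jensen bound
together in the tests.  The product-of-marginals form does not have its
minimum at the exact posterior and cannot satisfy both properties at
once.  When free-energy tracking is enabled, `gradient_update()` also
backtracks (halving that iteration's step up to six times, holding the
beliefs if necessary) so the logged trace is monotone even on adversarial
random models; with tracking off, the plain fixed-step update runs.

### Policy evaluation, precision and action

The expected free energy of a policy at a future time decomposes into a
pragmatic part (expected surprise of predicted outcomes relative to the
preferences C) and an epistemic part, the negative mutual information
between hidden states and outcomes under the predictive distribution.
The epistemic part is computed by exact Bayes inversion of A against the
predictive state distribution — feasible for categorical models — and
equals the double-sum mutual information oracle to machine precision.

The policy posterior is `softmax(lnE - gamma*G - F)`.  The precision
update iterates the damped fixed point

    beta <- beta_prior + (Q(pi) - P(pi)) . G

re-deriving both distributions with `gamma = 1/beta` at every iteration.
The *prior* `P(pi)` retains the expected free energies held before the
latest observation: when an observation revises `G` (for example, a probe
that suddenly makes one report clearly correct), the posterior shifts
toward lower-G policies relative to that retained prior, `beta` falls and
`gamma` rises — the phasic trajectory read out as simulated dopamine.
`beta` is clamped at an eighth of its prior, bounding the phasic gain at
8x baseline; without a bound the fixed point can cross zero for strongly
preference-laden outcomes.

Policies here are one-step ("plan as you go"): each policy prescribes one
action tuple applied to all future steps and is re-evaluated every step,
with executed actions fixing the past for every policy.  Action selection
marginalises the policy posterior onto the current action and takes the
argmax (ties to the lowest index, making high-precision behaviour exactly
reproducible); a sampling mode draws from the sharpened marginal and is
what the precision sweep uses, since graded stochasticity of choice *is*
the phenomenon under study there.  Policies whose posterior falls below
`1/(16 * n_policies)` are frozen and excluded from the Bayesian model
average (their beliefs are stale by construction).

## The deep temporal model

Two levels compose into a hierarchy: each upper-level time step spawns a
full lower-level trial (an epoch).  Descending messages condition the
lower level's initial-state prior (`link_init %*% upper_belief`) and its
policy prior.  Ascending messages return `ln(link_init' L)` where `L` is
the lower level's converged posterior *divided by its descended prior* —
the likelihood its observations contributed.  Dividing out the prior is
essential: the upper level already carries its own prediction in its
forward messages, and with the raw posterior it would count it twice.
With one lower step per epoch and identity links the two-level scheme is
then exactly equivalent to a flat hidden Markov model, a property the
tests verify against enumeration.

An epoch ends when the entropy of the lower level's policy-averaged
belief over its scene factor falls below a threshold, or when the step
budget (five lower steps) is exhausted.

## The delay-period retrocue task

The lower level has two factors — the displayed scene (the test scenes,
a blank scene for fixation and delays, and two retrocue scenes) and eye
position (a central fixation locus plus four quadrants, set directly by
saccadic actions) — and two modalities: the image at the fixated quadrant
and proprioceptive eye position.  Gaze returns to the center at the start
of every epoch, as in the retrocue paradigms the task emulates; the
center views no quadrant and is uninformative, so fixations are counted
as lower steps spent on a quadrant.

The upper level's factors are the remembered scene pair (three pairs of
the first three scenes), the presentation order, the probe scene, the
position in the trial sequence (delay, scene 1, scene 2, retrocue, delay,
probe, feedback — a deterministic shift), and the report (withhold /
same / different, the only controllable factor).  Its outcomes are the
lower level's scene state (carried by the hierarchy link) and feedback,
with log preferences `(0, +3, -6)` over none/correct/incorrect — the
paper's ordering made concrete; the resulting indifference point for
reporting "same" sits just below a probe-in-pair probability of 2/3,
so the prior two-thirds marginal is exactly what makes the report
decision non-trivial.

### Scene layouts

The verbal constraints pin the geometry but not the images, so the
default layouts are a design choice, recorded once here and in
`default_scenes()`: scene 1 = bird TL + seeds TR, scene 2 = bird TL +
cat TR (horizontal), scene 3 = cat TL + seeds LR (the single diagonal
scene).  The lower-left quadrant is blank everywhere — the only location
that is never informative.  Once the bird is known to be top-left the
top-right disambiguates, and the lower-right identifies a scene only if
seeds are there.  Extra scenes for set sizes 4 and 5 (cat TL + seeds TR;
cat TL + bird TR) deliberately share the cat-TL signature with scene 3:
an added scene that shared nothing would be eliminated by a single
glance and would add no elimination work, contradicting the very
mechanism — more alternatives to rule out — that makes reaction times
grow with set size.

### Calibrated parameters

Three numbers were calibrated, once, against the task's canonical
behaviour (two fixations suffice to interpret a scene at high policy
precision, and elimination work grows with set size):

* the model's visual likelihood precision, 0.85 for the true image (the
  display process itself is deterministic: the 50 runs per condition in
  the reaction-time study differ only in their cue and probe draws);
* the epoch-termination threshold, 0.03 nats.  The residual entropy
  after two informative fixations is ~0.008–0.019 nats when the scene
  prior is concentrated and ~0.03–0.04 when it is diluted across more
  scenes, so this threshold both reproduces the two-fixation pattern and
  makes the probe epoch genuinely harder at larger set sizes;
* the step budget of five lower steps (the center start plus up to four
  quadrant fixations — the four quadrants bound the useful saccades).

No threshold in (0, ln n) can produce exactly two fixations for *both*
initial scenes with gaze carry-over between epochs — after the first
scene the pair prior is binary and a single fixation posterior is always
sharper than the first scene's two-fixation posterior — which is why
epochs restart at the central fixation locus.

## The orientation maintenance task

A single level with an orientation factor (20 circular bins; transitions
a banded kernel `exp(-precision * d^2)` over wrapped index distance,
whose column entropy is the believed volatility) and a visibility factor.
The outcome reports the orientation through a banded kernel of its own
(sensory precision) when the stimulus is visible and an "absent" outcome
otherwise.  Initial beliefs are peaked near pi radians; a stimulus at
about pi/2 radians is presented during steps 4–5 of 10.  Orientation is
treated as circular by default (the wrap-around is the natural reading
of an orientation state space; the flag exposes both choices).  Belief
trajectories are read at the currently processed time — the
"experienced" filtering view — because retrospective smoothing would let
the stimulus rewrite the pre-stimulus past.

## Simulated observables

* **Rasters** are policy-averaged state expectations per gradient
  iteration at the currently processed time.
* **ERPs** are the policy-averaged increments `nu_dot`, locked to an
  event step, either averaged over the requested units or weighted by
  each unit's current expectation (a population-activity reading).  One
  iteration maps to 8 ms — purely a display convention chosen so that a
  32-iteration block spans ~250 ms.  The context experiment uses the
  expectation-weighted waveform over the probe units and the event block
  itself (early/late = its two halves): a contextual cue *redistributes*
  belief mass, so de-cued units dominate the population signal early
  (while they still carry mass) and the cued unit late — which is what
  produces the early difference that later reverses sign.  A plain
  unweighted average largely cancels this redistribution.  The load
  experiment reads the single unit representing the probed item across
  the probe and feedback blocks.
* **Dopamine** is the gamma trajectory across precision-update
  iterations; its first difference is the phasic signal.
* **Reaction time** counts executed belief-update iterations (the
  adaptive lower level's iterations-to-convergence plus the upper block)
  from probe onset to report selection — a deterministic stand-in for
  wall-clock compute time that preserves what that measure tests: more
  alternatives mean more fixations and slower settling.

## What the simulations do and do not show

The experiment drivers reproduce: linear reaction-time growth over set
sizes 3/4/5 (50 trials each; the trial realisation is fixed, the cue and
probe draws vary); an early retrocue-locked difference between
informative and uninformative cues that reverses sign within the update
block; a sustained probe-locked difference abolished when the cue is
uninformative; non-decreasing fixations per scene and decreasing phasic
dopamine amplitude as prior beta grows (the same generative-process
stream is shared across beta values, only the agent differs); and
forgetting that is monotone in transition-column entropy while stimulus
updating is monotone in likelihood precision.

These are simulations of an idealised observer on a four-quadrant toy
world.  The generator does not emulate sensory front-ends, eye-movement
kinematics, neuronal biophysics, or empirical inter-subject variability;
passing tests show that the belief-updating scheme has the claimed
computational properties, not that cortical responses arise this way.
Model parameters (A/B) are fixed — there is no learning — and the
hierarchy is limited to the two levels the tasks need.

## Reproducibility and problem sizes

Every source of randomness flows through label-separated seeded streams;
every experiment result embeds its seed and a configuration hash, and
re-running from that pair is bit-identical.  The shipped study sizes —
150 reaction-time trials, 16 repetitions per beta in the precision
sweep, 20 orientation bins over 10 steps, and the enumeration oracles
capped at 4 states x 3 steps — were chosen so the full suite exercises
every claim in minutes on a single core while keeping the enumeration
spaces exhaustively checkable.
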