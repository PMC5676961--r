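# Default run configuration for actinf (all keys optional; unknown keys
# are rejected).  Values shown are the package defaults.
task: delay                 # task selector: delay | orientation
model:
  retrocue_validity: 0.9    # cue validity, in [0.5, 1]
  n_total_scenes: 3         # memory set size: 3, 4 or 5
  likelihood_precision: 0.85  # model probability of the true image, (0, 1]
  steps_per_epoch: 5        # lower-level step budget per epoch
inference:
  n_iter: 32                # gradient iterations per time step
  step_size: 0.25           # gradient step, (0, 1]
  entropy_threshold: 0.03   # epoch termination threshold (nats)
  beta_prior: 1.0           # prior inverse policy precision (> 0)
  plan_horizon: 1           # future steps entering expected free energy
  action_mode: deterministic  # deterministic | sample
  alpha: 16                 # action precision in sample mode
experiment:
  n_per_condition: 50
  set_sizes: [3, 4, 5]
  validities: [0.9, 0.5]
  betas: [0.25, 1.0, 4.0]
  n_reps: 16
seed: 1
out_dir: results
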