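# stdpnet

Two-layer network simulations of spike-timing dependent plasticity (STDP)
at top-down (feedback) synapses.

## The problem

Neocortical areas talk in both directions: bottom-up connections (weight
matrix **Q**) carry stimulus-driven activity from a lower area to a higher
one, and top-down connections (**W**) feed back the other way. Because the
lower area fires first during sensory events, a top-down synapse mostly
sees its post-synaptic neuron fire *before* its pre-synaptic one — the
mirror image of what a bottom-up synapse sees. `stdpnet` implements the
modelling machinery to ask which pairwise learning rules let top-down
weights develop into a distribution that is **stable** (unchanging under
stationary stimulus statistics), **diverse** (a continuous spread of
strengths), and **weak** (every eigenvalue of the loop matrix **WQ** below
1, so no activity-amplifying "strong loop").

Two rule orientations are compared, each with a depression/potentiation
bias α (α > 1 ⇒ depression dominates):

* classical STDP (cSTDP): pre-before-post potentiates,
  Δw ∝ A⁺·e^(−|Δt|/τ) for Δt > 0, −α·A⁺·e^(−|Δt|/τ) for Δt < 0;
* reverse STDP (rSTDP): the temporal mirror image.

The reproducible headline: **only depression-biased rSTDP** yields stable,
diverse, weak top-down weights; cSTDP (either bias) and potentiation-biased
rSTDP end in runaway weights. For the analytically tractable linear engine
the learned weights converge to the scaled inverse **W\*** = **Q**⁻¹/α, at
which every eigenvalue of **WQ** equals 1/α.

The package provides:

* a **linear rate engine** (`train_linear`) with closed-form expected
  updates, eigenvalue loop-gain diagnostics (`loop_gain_spectrum`), the
  predicted fixed point (`predicted_fixed_point`), and four-way outcome
  classification;
* a **conductance-based leaky integrate-and-fire engine**
  (`train_spiking`, compiled core) with correlated Gaussian stimuli,
  transmission delays, noise, and exact all-pairs exponential-window STDP;
* **rule variants**: homeostatic synaptic scaling, multiplicative
  (soft-bound) STDP, concurrent bottom-up plasticity, higher-layer external
  drive;
* an **experiment layer**: parameter sweeps with per-rule-class outcome
  tables (`run_parameter_sweep`, `summarize_outcomes`) and the
  input-reconstruction experiment (`reconstruction_experiment`);
* a plain-text config/CLI harness (`load_config`, `inst/cli/stdpnet`).

## Worked example

Train the 20×20 linear network with depression-biased rSTDP (α = 3) and
check the three properties:

```r
library(stdpnet)
set.seed(42)

Q  <- generate_bottom_up_matrix(20, 20, epsilon = 0.1, smooth_width = 3)
C  <- build_input_correlation(20)
W0 <- initial_top_down_matrix(20, 20)

res <- train_linear(linear_network(Q, W0), C,
                    linear_rule("reverse", alpha = 3))
res$outcome
#> Outcome: converged after 5620 presentations
#>    std_W = 0.011474
#>    max_eig = 0.33333
#>    delta_norm = 4.2075e-17
#>    corr_fixed_point = 1
#>    std_W0 = 0.0029093

max(res$trace$max_eig)                      # weakness: never exceeds 1/alpha
#> [1] 0.3333333
cor(as.vector(res$net$W), as.vector(solve(Q)))  # converges to Q^-1 / alpha
#> [1] 1
```

The run stops via the convergence criteria after ~5600 presentations; the
maximum-modulus eigenvalue of **WQ** stays at or below 1/α = 0.333 for the
whole run (no strong loop ever forms), and the final weights correlate with
**Q**⁻¹ at 1.00 — the predicted fixed point. Running the classical rule on
the same network instead stops within a few presentations as
`extreme_weights` with `max_eig > 1`.

The same contrast at spiking level, desk scale (30 neurons/layer):

```r
spec <- desk_sweep_preset(alphas = c(0.9, 1.2, 3), replicates = 3)
sweep <- run_parameter_sweep(spec, seed_registry(1))
summarize_outcomes(sweep)
```

which reports, per rule class (orientation × bias), the proportion of runs
classified `converged`, `extreme_weights`, `weights_too_similar`, or
`did_not_converge`: converged outcomes appear only in the
`reverse_depression` class.

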