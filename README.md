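# dhdfc — differential Hebbian learning with deep feedback control

How can a deep network of neurons learn from a supervision signal when
each synapse only sees its own presynaptic and postsynaptic activity?
`dhdfc` implements one answer for computational neuroscientists: let a
global feedback controller *change the firing rates* of neurons until
the network output matches a target, and let every synapse apply a
**differential Hebbian (DH)** rule — the rate-based counterpart of
spike-timing-dependent plasticity (STDP) —

    Δw  ∝  ∫ r_pre(t) · dr_post(t)/dt · dt.

When feedback raises a postsynaptic rate while the presynaptic neuron
is active, the synapse potentiates; when feedback lowers it, the
synapse depresses.  No neuron ever compares compartments or reads an
explicit error: the error is implicit in the *temporal change* of its
own activity.

The package provides, in plain R:

* leaky rate networks (`layered_network`, `integrate_dynamics`) with a
  global PI controller (`controller_state`, `run_closed_loop`) whose
  signal reaches every neuron through a feedback matrix `Q`;
* anti-Hebbian, noise-driven learning of `Q`
  (`train_feedback_weights`);
* plasticity rules on trajectories: differential Hebbian
  (`dh_update`), dendritic-error (`delta_update`), a backpropagation
  reference (`bp_update`), and rule comparison by coefficient of
  determination (`update_correlation`);
* a spiking bridge: inhomogeneous Poisson spike trains from rates
  (`rates_to_poisson_spikes`) and pairwise-kernel STDP
  (`stdp_kernel`, `stdp_pairwise_update`, `stdp_expected_update`);
* the diagnostic loss triad: initial MSE `L` (`mse_loss`), feedback
  cost `H` (`feedback_cost`), and time-to-target `T`
  (`time_to_target`);
* a supervised predictive-coding variant trained with either the
  Hebbian-error or the DH rule (`pc_inference`, `train_pc`);
* desk-scale experiments: single-neuron supervision
  (`run_single_neuron_experiment`), multilayer training on synthetic
  Gaussian-blob classification (`train_dh_dfc`), update-rule
  correlation (`run_correlation_experiment`), and the label-shuffle
  surprise probe (`run_surprise_experiment`); plus an IDX reader
  (`read_idx_images`) for the standard handwritten-digit benchmark.

See the methods vignette
(`vignettes/temporal-hebbian-learning.Rmd`) for the model equations,
default constants and their rationale, and known limitations.

## A worked example

One neuron with two inputs, A and B, must fire when B is shown and
stay silent when A is shown.  The controller supplies the push; STDP
on Poisson spike trains is computed alongside as the biological
counterpart of the applied DH updates:

```r
library(dhdfc)
res <- run_single_neuron_experiment(list(seed = 1))
h <- res$history
round(h[c(1, 20, 40), ], 3)
#>    epoch    w_A   w_B     L      H     T
#> 1      1  0.464 0.513 0.219 71.754 0.520
#> 20    20 -0.135 0.770 0.157 57.006 0.515
#> 40    40 -0.632 1.040 0.113 45.935 0.505
cor(res$updates$dh, res$updates$stdp)
#> [1] 0.844
```

The weight from B rises and the weight from A falls, so the neuron's
spontaneous response drifts toward its targets: the initial error `L`,
the feedback spent per trial `H`, and the latency to reach the target
`T` all shrink together.  The per-trial DH updates correlate strongly
(0.84) with single-realization STDP updates computed from Poisson
spike trains of the same trials.

A multilayer run on a synthetic 4-class task:

```r
ds <- gen_gaussian_classification(4, 25, dim = 2, sep = 6, seed = 46)
fit <- train_dh_dfc(list(seed = 6), ds)
min(fit$metrics$train_error)   # < 0.1 : the hierarchy has learned
```

## Command line

A thin CLI over the same functions lives at `inst/cli/dhdfc.R`:

```sh
Rscript inst/cli/dhdfc.R single-neuron --seed 1 --out out/
Rscript inst/cli/dhdfc.R train --config my.yaml --seed 2 --out out/
```

Subcommands: `single-neuron`, `train`, `correlate`, `surprise`,
`pretrain-q`; each writes epoch-indexed metrics CSV plus a JSON echo
of the merged configuration.

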