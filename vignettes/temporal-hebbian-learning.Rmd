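---
title: "Temporal Hebbian learning with deep feedback control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal Hebbian learning with deep feedback control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhdfc)
```

## The model

`dhdfc` simulates layered networks of leaky rate neurons.  Each
non-input neuron integrates a basal feedforward drive and an apical
feedback signal,

$$\dot v = -v + W\,r_{\mathrm{pre}} + Q\,c(t) + \varepsilon,
  \qquad r = \phi(v),$$

with the membrane time constant fixed to 1 — all times in the package
are expressed in units of it — and $\phi$ a sigmoid by default, so
rates are bounded in $(0,1)$ and double as per-step spike
probabilities for the spiking bridge.  The input layer is clamped to
the stimulus and has no dynamics.  Integration is forward Euler with
`dt = 0.01`; noise $\varepsilon$, when present, enters the potential
derivative, fresh per step and neuron.

The apical signal is produced by a global proportional–integral
controller that compares the output rates with a target,

$$c(t) = c_{\mathrm{int}}(t) + k\,e(t), \qquad
  \tau_u\,\dot c_{\mathrm{int}} = e(t)/\alpha - c_{\mathrm{int}},
  \qquad e(t) = y^\* - r_{\mathrm{out}}(t),$$

and is mapped into every hidden and output neuron by the feedback
matrix $Q$.  Because the integral term is leaky, the loop has a finite
DC gain of $1/\alpha$ per error channel.

Learning of the feedforward weights uses the **differential Hebbian
(DH) rule**: the integral of presynaptic rate times the temporal
derivative of postsynaptic rate,

$$\Delta w \;\propto\; \int r_{\mathrm{pre}}(t)\,
  \dot r_{\mathrm{post}}(t)\,dt
  \;\approx\; \sum_t r_{\mathrm{pre}}(t)\,
  \bigl[r_{\mathrm{post}}(t+dt) - r_{\mathrm{post}}(t)\bigr].$$

When the presynaptic rate is constant the sum telescopes exactly to
the **dendritic-error (delta) rule**
$r_{\mathrm{pre}}\,[r_{\mathrm{post}}(T) - r_{\mathrm{post}}(0)]$;
[`dh_update()`] and [`delta_update()`] implement both, and the test
suite asserts the identity at machine precision.  The discrete
derivative uses forward differences with the presynaptic factor at the
earlier step — pre-before-post causality, which preserves the LTP sign
convention of pairwise STDP.  Updates are computed once per stimulus
presentation from the whole trajectory and applied afterwards; an
online per-step accumulation mode exists and equals the batch sum
exactly.

## Diagnostic losses

Three quantities summarise one closed-loop presentation:

* `mse_loss` — **L**, the squared distance between target and the
  *initial* (pre-feedback) output.  Closed-loop trajectories start at
  the open-loop equilibrium, so this is the conventional feedforward
  loss.
* `feedback_cost` — **H**, $\sum_t \lVert c(t)\rVert^2 dt$, the
  squared-norm control integral (a config flag switches to the plain
  norm).
* `time_to_target` — **T**, the first time the max-norm output error
  falls below a tolerance (default 0.1 rate units) *and stays below
  it*; `Inf` when never reached.  Epoch-level aggregation censors the
  sentinel at the trial duration so that means remain finite.

Successful learning decreases all three: a trained network starts
closer to its target (low L), needs less steering (low H) and gets
there sooner (low T).

## Default constants and why

| constant | default | reason |
|---|---|---|
| `dt` | 0.01 | Euler step, in membrane time constants; halving it changes noise-free endpoints at first order only |
| trial `duration` | 3 (multilayer), 10 (single neuron) | several controller time constants, so the integral term is essentially wound up |
| `k` | 0.5 | proportional path; damps the transient |
| `alpha` | 0.02 | DC gain 50.  Feedback here is *strong*: it must actually hold a sigmoid output at the saturated one-hot levels 0.95/0.05, where $\phi' \approx 0.05$, so a per-channel loop gain of a few is required even before learning.  With a weak loop (e.g. $\alpha = 1$) the target is simply never reached and T is undefined forever |
| `tau_u` | 1 | integral time constant |
| targets | 0.95 / 0.05 | one-hot labels mapped inside the sigmoid range; exact 0/1 is unreachable |
| `lr` | 0.1 (single neuron), 0.02 (multilayer) | largest values that were stable over whole training runs; larger multilayer rates overshoot after convergence and can destroy a trained network |
| STDP kernel | $a_+ = a_- = 0.01$, $\tau_\pm = 0.2$, window $5\tau$ | see below |

## The spiking bridge

Rates are converted to spikes by an inhomogeneous Bernoulli process on
the integration grid: at each step a neuron spikes with probability
equal to its rate.  STDP sums a two-sided exponential kernel over
spike pairs (`all_to_all`, truncated at five kernel time constants;
`nearest_neighbor` available), and `stdp_expected_update()` averages
the resulting per-synapse updates over many independent Poisson
realizations.

Two kernel choices matter and are deliberate:

* **Balance.** The default kernel has equal LTP and LTD areas
  ($a_+\tau_+ = a_-\tau_-$).  For slowly varying rates the expected
  pair sum then reduces to a term proportional to the DH integral; an
  *unbalanced* kernel adds a bias proportional to
  $(a_-\tau_- - a_+\tau_+)\sum_t r_{\mathrm{pre}} r_{\mathrm{post}}$,
  a rate-product offset that is an order of magnitude larger than the
  temporal-derivative signal and anti-correlates with it across
  trials.  With the classical slightly-LTD-biased kernel the
  DH–STDP correlation on the single-neuron task is driven negative;
  with the balanced kernel it is strongly positive (about 0.84 under
  the default configuration).
* **Timescale.** Kernel time constants are expressed in simulation
  units (membrane time constants).  Reading a cortical membrane
  constant as roughly 100 ms, the default $\tau_\pm = 0.2$ corresponds
  to the classical ~20 ms STDP window.  Interpreting "20 ms" literally
  against a 1 s membrane constant makes the kernel span only two
  integration bins; the per-realization Poisson noise then swamps the
  signal entirely (measured single-realization correlation ~0.02).

## Learning the feedback weights

$Q$ is pre-trained once, with the feedforward weights frozen, by the
anti-Hebbian rule $\dot Q = -v\,c^\top - \beta Q$ while zero-mean
noise is injected into every neuron and the controller holds the
network around its own noise-free output.  Three implementation
choices were necessary to make this work, all verified numerically
against the network Jacobian $J$ (the ideal feedback direction is
$Q \propto J^\top$):

1. **Fluctuations, not raw potentials.**  The rule correlates $v$
   relative to its noise-free equilibrium for the current stimulus.
   The DC component of $v$ carries no information about forward
   influence; left in place, the rank-one mean term dominates the
   learned $Q$ and the product $JQ$ acquires negative eigenvalues —
   the closed loop then actively diverges.
2. **Proportional-only controller during pre-training.**  The
   integral term is a low-passed copy of the error; its lag
   decorrelates $c$ from the instantaneous fluctuations.  A weak
   $k$-only controller raises the alignment between the learned $Q$
   and $J^\top$ measurably (correlation ~0.56 versus ~0.44 on a
   2-16-16-4 network).
3. **Post-hoc rescaling.**  The equilibrium magnitude of $Q$ scales
   with the stationary noise variance ($\sim \sigma^2 dt/2$), which is
   tiny; the learned matrix is therefore rescaled — globally by
   default, preserving relative channel gains; per column optionally,
   equalising them — and the loop gain is owned by the controller
   constants.

## The multilayer training protocol

`train_dh_dfc()` trains per sample: simulate the closed loop for one
stimulus, compute the DH update from the whole trajectory, apply it,
move on.  Classification is by argmax of the open-loop output.  Two
protocol details matter at desk scale:

* **Random restarts.**  The per-sample temporal updates interact with
  the coupling asymmetry between output channels: channels whose
  forward influence is weak receive weak feedback, learn slowly, and
  can stay confused for many epochs.  Whether this happens depends
  almost entirely on the random initialisation (the same dataset
  trains cleanly from most seeds and stalls from others), so training
  runs several independent restarts (default 4; 6 for the surprise
  experiment, whose pre-shuffle phase is shorter) and keeps the run
  with the lowest *training* error — standard practice for small
  networks, and no test information is used for the selection.
* **Frozen feedback weights.**  `Q` is pre-trained once and kept fixed
  during feedforward learning.  A re-training cadence is exposed
  (`q_refresh`), but continuous re-learning of `Q` was found to move
  the hidden-layer targets faster than the weights can follow, and it
  degrades training; the default is therefore off.

## The surprise probe

`run_surprise_experiment()` trains normally, then randomly swaps the
class identities (a derangement: every class is consistently
relabelled) and keeps training.  The epoch-mean feedback cost drops
during learning, jumps when the labels are swapped — the network's
predictions are now maximally wrong, so the controller must spend a
large feedback volley on every trial — and then re-decays as the
output layer remaps, faster than the original decline because the
hidden representation is already formed.  Swapping class *identities*
rather than permuting the per-sample label vector is essential: a
per-sample permutation gives samples of the same class different
labels, the post-shuffle task becomes inconsistent, and the feedback
cost can never re-decay.

## What the synthetic tasks emulate — and what they do not

`gen_two_input_task()` is the elementary supervision problem: two
fixed-rate inputs (0.8/0.2), alternating A/B stimuli, low/high target.
`gen_gaussian_classification()` stands in for an image benchmark:
isotropic Gaussian blobs on a randomly rotated circle with a
guaranteed minimum center separation (default 6 SD, Bayes error well
below 1%, confirmed by a nearest-centroid oracle), z-scored and
squashed through the sigmoid so inputs are valid clamped rates and
spike probabilities.  These tasks isolate the *credit-assignment*
question from representation learning: passing them shows the rules
assign credit through depth, not that they scale to natural images,
high class counts, or noisy labels.  The desk-scale problem sizes used
throughout (networks of 2-16-16-4, 100-200 samples, tens of epochs)
were chosen so the full experiment suite runs in minutes; the
framework itself supports the standard 784-256-256-256-10 digit
benchmark through `read_idx_images()`, with per-sample closed-loop
simulation cost (about a hundred controller steps per sample) being
the practical limit.

## Numerical choices and degenerate inputs

* Open-loop equilibria are computed exactly layer by layer (the
  architecture is feedforward and the input clamped), and the Euler
  integrator is verified against them and against damped fixed-point
  iteration.
* Divergence (non-finite or $|v| > 10^6$) raises an error naming the
  step; closed-loop wrappers translate it into advice about gain and
  step size.
* Trajectories with a single step are rejected by plasticity rules;
  zero-variance update sets make correlations undefined and error.
* Identical seeds reproduce every stochastic path bitwise (noise,
  Poisson conversion, sample order).

## The predictive-coding experiments

The predictive-coding networks used in the comparison experiments are
`tanh` networks on centred (z-scored) features rather than sigmoid
networks on squashed rates.  The networks in this package carry no
bias terms, so every separating surface passes through the origin in
feature space; sigmoid rates confine all inputs to the positive
orthant, where a class pair that happens to fall along a ray from the
origin is unseparable without a bias.  Centred features with an odd
activation remove the problem.  (The rate networks cannot use this
trick — their inputs must be valid rates in \[0, 1\] for clamping and
Poisson conversion — but their hidden layers give them more room to
cope.)  Output activity targets are the one-hot rates mapped through
the activation inverse; clamping raw rate values instead parks the
output in the saturated region of the activation and starves the
temporal rule of signal.

## The predictive-coding variant

`pc_inference()` implements supervised predictive coding on the same
weights: activities $x_l$ carry prediction errors
$\epsilon_l = x_l - W_{l-1}\phi(x_{l-1})$ (computed quantities — the
fast-error limit of explicit error neurons), free activities descend
the energy $\sum_l \lVert \epsilon_l \rVert^2/2$, the input is always
clamped and the output is clamped to the target during training.
Activities initialise at the feedforward predictions; the pre-clamp
state is recorded so the clamp transient is part of the trajectory
that `pc_dh_update()` integrates — this is what lets a temporal rule
train the output layer, whose activity is otherwise constant under the
clamp.  `pc_hebbian_update()` is the standard error-times-presynaptic
rule at the inferred equilibrium, and `train_pc()` trains with either.
The formulation follows the standard supervised PC energy; the module
is deliberately plugin-shaped (both update rules produce comparable
`update_set`s) so an alternative formulation can be swapped in.

## Comparing learning rules

`update_correlation()` flattens two update sets over all synapses and
reports the $R^2$ of the least-squares fit (with intercept);
`update_slope()` gives the signed slope.  Two regimes matter when
comparing DH-DFC with backpropagation:

* Under *strong* feedback the controlled state approaches the target
  and the DH/delta update approaches a pseudoinverse-flavoured step
  $Q\,(JQ)^{-1} e$ — a sensible credit-assignment direction, but not
  the gradient; its correlation with BP is diluted by the
  $(JQ)^{-1}$ reweighting.
* Under *weak* feedback the network is only perturbed,
  $\Delta v \approx Q\,e$, and the DH update becomes
  $\phi'\,(Qe)\,r_{\mathrm{pre}}^\top$ — with $Q$ aligned to
  $J^\top$ this *is* the backpropagation update.

`run_correlation_experiment()` therefore takes its mid-training
snapshot with the package's training defaults but computes the
comparison trajectories with a weak probe controller; the probe
constants are config-exposed.

## Known limitations

* The DH update's agreement with the raw backpropagation gradient is
  bounded by the quality of the learned feedback weights: with the
  plain anti-Hebbian phase the alignment between `Q` and the network
  Jacobian transpose is partial (correlation around 0.55 on a
  2-16-16-4 network), and the pooled update-level \(R^2\) against BP
  typically lands near 0.4 (against the dendritic-error rule it is
  ~0.97).  Substituting the exact Jacobian transpose for `Q` raises
  the BP alignment to ~0.75, locating the gap squarely in the
  feedback-learning phase.
* After a label swap the network reliably produces a large feedback
  surge and re-learns the classification, but driving the feedback
  cost all the way back to its pre-swap level faster than the original
  decline — the full latency signature — succeeds on only a fraction
  of seeds at this scale: relearning from trained weights is slower
  than learning from fresh ones.

* Learning through depth depends on the quality of the pre-trained
  feedback: with the simplified anti-Hebbian phase used here the
  alignment with $J^\top$ is partial, and multilayer training at desk
  scale is sensitive to the interaction of loop gain, learning rate
  and class-channel coupling asymmetry; some seeds converge much
  faster than others.
* The leaky integral controller has finite DC gain, so weakly coupled
  error channels retain residual error within a trial; the
  `alpha` default trades this against Euler stability of the
  oscillatory closed-loop modes.
* Spiking is Bernoulli-per-bin (no refractoriness, no
  integrate-and-fire dynamics), and STDP is pairwise exponential only.
* No biases, conductances or multi-compartment dynamics; Dale's law is
  not enforced.
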