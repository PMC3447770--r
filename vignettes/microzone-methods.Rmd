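---
title: "Modeling cerebellar microzone degeneration: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling cerebellar microzone degeneration: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(microzone)
```

This vignette explains the model implemented by **microzone**, the choices
behind its defaults, and what its simulations can and cannot say about real
cerebellar degeneration.

## The circuit

The package simulates a single cerebellar microzone: mossy fibers (24) and
climbing fibers (3) as inputs; granule (3300), Golgi (300), basket (130) and
Purkinje (15) cells as the cortical stage; and two deep cerebellar neurons
(DCN) as the output. Purkinje cells form three subgroups of five, each
innervated by exactly one climbing fiber. Golgi-to-granule,
basket-to-Purkinje and Purkinje-to-DCN connections are inhibitory; all other
connections are excitatory. The climbing-fiber-to-Purkinje synapse is 26,000
times stronger than baseline, and mossy-fiber-to-granule four times
stronger. Excitatory collaterals from both input systems onto the deep
nuclei are included by default (`include_nuclear_collaterals`): with purely
inhibitory Purkinje drive the output layer has no excitatory pathway that
could express a positive conditioned response, and nuclear collaterals are a
standard feature of the circuit this model follows.

## Neuron and layer dynamics

Each unit is a rate-coded point neuron with three conductance channels
(excitatory, leak, inhibitory) with normalized reversal potentials
`E_inhib = 0.15 <= E_leak = 0.30 < E_excit = 1` and maximum conductances
`(1, 0.1, 2)`. The membrane potential relaxes toward the
conductance-weighted mixture of reversal potentials with time constant
`tau = 0.2` per cycle; the per-cycle step factor `tau * G` is capped at 1,
so the extremely strong climbing-fiber drive moves the potential directly to
its equilibrium instead of overshooting (an uncapped explicit step is
unstable whenever `tau * G > 2`).

The rate code is a hard-thresholded saturating logistic of
`gain * (V_m - threshold)` with `gain = 1000` and `threshold = 0.60`
(above the leak reversal, so resting units are silent). The high gain gives
a near-binary code in which a strongly driven unit reaches 1.0 exactly in
double precision; this matters because training terminates only when the
association error is 0% to six significant figures, which a strictly
sub-saturating code could never reach.

Layer activity is controlled by the fast k-winners-take-all (kWTA)
approximation: each unit's "threshold conductance" (the inhibition that
would hold it exactly at threshold) is computed, and the layer-wide
inhibitory conductance is placed midway between the k-th and (k+1)-th
largest values. Winner counts default to 10% of the layer (5% for granule
cells), with three deliberate overrides in the canonical configuration:

* **basket k = 65 (50%)** — basket cells are tonically active interneurons;
  with only 10% of them active their pooled inhibition cannot silence
  Purkinje cells that lack climbing drive, and the Purkinje code degenerates
  to "always on".
* **Purkinje k = 15 (no competition)** — each subgroup must relay its
  private climbing fiber; competition across subgroups would discard that
  code.
* **DCN k = 2 (no competition)** — the two output units encode a one-hot
  response that is read out independently; under kWTA the losing unit is
  pinned at zero and receives no error gradient, which blocks learning.

Net input is normalized per projection by fan-in times the expected source
activity (`k/n` for kWTA layers, 0.5 for inputs), so a projection's drive is
roughly "average weight x average active-unit rate" regardless of layer
size, and removing a fraction of a source population removes the same
fraction of its drive (the normalizer is fixed at the intact size).

Settling runs 60 synchronous cycles per phase. The circuit is effectively a
five-stage chain (mossy -> granule -> basket -> Purkinje -> DCN), and
activity needs roughly 25 cycles just to traverse it; with substantially
fewer cycles the output layer reads a pre-inhibition transient in which
Purkinje cells appear tonically active. Sixty cycles reach the settled state
(doubling to 120 changes activations negligibly).

## Learning

Training alternates an expectation (minus) phase, with the output free, and
an outcome (plus) phase, with the output clamped to the target. The
error-driven (contrastive) rule is
`delta_w = eps * (x_plus * y_plus - x_minus * y_minus)`; a Hebbian
conditional-PCA term `eps * y * (x - w)` can be mixed in with weight
`lambda`. Three application details:

* **Sign-aware application.** Inhibitory projections receive the negated
  error-driven delta, so that learning always moves the postsynaptic unit
  toward its target. Without this the Purkinje-to-DCN pathway — the only
  route by which the "respond" unit can be switched *off* — would learn in
  the wrong direction.
* **Soft weight bounding.** Error-driven increases are scaled by `1 - w`
  and decreases by `w`. This keeps weights in [0, 1] smoothly and damps the
  oscillation that full-batch updates with a saturating, derivative-free
  rule otherwise produce.
* **Per-epoch aggregation.** Deltas are averaged over the epoch and applied
  once (per-pattern application is available via
  `dynamics_params(aggregation = "per_pattern")`). Because the output layer
  projects to nothing, the two phases agree on every other layer and the
  contrastive term exists only on projections into the DCN, where the two
  modes share their fixed points.

`lambda` defaults to 0 (pure error-driven). In this feedforward circuit the
contrastive term vanishes on all intracortical projections, so a nonzero
`lambda` makes slow Hebbian drift the *only* intracortical plasticity; that
drift does not serve the association and was observed to push the Purkinje
operating point around during long runs. With `lambda = 0` the cortical
stage is a fixed random expansion — the classical view of the granule layer
as a fixed high-dimensional basis with plasticity concentrated at the
readout — and the trainer exploits it: the cortex is settled once per run
and only the output layer's cycles are replayed each epoch (this replay is
bit-compatible with the full settle; the test suite checks the equivalence).
Setting `lambda > 0` in the config restores the full per-epoch settle.

Every non-input unit also carries a non-negative trainable bias (error-driven
only, capped at 5); the deep nuclei need it as tonic excitatory drive
against Purkinje inhibition.

The base learning rate is `epsilon = 0.8`, scaled per projection by
`min(strength, 4)`. Training stops when the epoch error drops below
`5e-7`% — "zero percent to six significant figures" — or at 2000 epochs;
non-convergent runs are flagged and excluded from lesion averages. With the
defaults above, convergence was observed on every seed tried at both the
full and the granule-330 scales (typically 400–700 epochs).

All of these constants were chosen to make training converge reliably to
the zero-error criterion; none were selected by comparing lesion outcomes
against reference values.

## The conditioning task

`generate_training_set()` builds 140 samples of 27 inputs: 24 mossy-fiber
channels and 3 climbing-fiber channels, with 2 one-hot targets. Mossy values
are reflecting random walks on [0, 1] with per-step increments bounded by
0.15 — slowly changing contextual signals whose long-run marginal is uniform
(reflection preserves the uniform law; the bound 0.15 was fixed once as a
plausible "small variation between consecutive samples"). Climbing fibers
follow the 3-bit reflected gray sequence cyclically, so exactly one bit
changes per step, including the wrap-around; a plain binary-counting variant
(which violates the one-bit property) is available as `code = "binary"`.
The target is `(1, 0)` when the first climbing bit is 0 and `(0, 1)` when
it is 1. One training sample represents 0.25 s, so the 0–3 s
inter-stimulus-interval sweep spans cyclic shifts of 0–12 samples.

What the generator emulates: bounded, slowly varying mossy context; sparse
binary climbing events; a deterministic conditioned-response mapping. What
it does not: real airpuff/tone physics, spike timing, trial-to-trial
variability in the teaching signal, or any temporal credit assignment —
each sample is settled independently. Passing tests therefore demonstrate
the circuit-level consequences of cell removal on a learned static mapping,
not the temporal structure of eyeblink conditioning.

## Lesion experiments

Cell death is modeled as permanent removal: a lesioned unit's activation is
pinned to zero, it contributes nothing to any net input, and it is excluded
from the kWTA winner count; weights are never retrained (no recovery or
compensatory plasticity). Schedules: granule, Golgi and basket cells are
removed in cumulative 1% steps to 30% of the group; mossy fibers one per
step to 8 (32%); climbing fibers a single cell (1 of 3); Purkinje cells one
per step to 5 (33%). The printed study totals differ for basket cells (29
rather than 39); `mode = "table"` reproduces that count, and the summary
tables use it.

Random degeneration draws cells without replacement from the pooled
intrinsic population (granule + Golgi + basket + Purkinje = 3745 cells;
granule share 88%), in 1% steps of the pool to 30%. Inputs and the deep
nuclei are excluded from the pool.

Each trial re-derives weight, stream and removal seeds from the base seed,
trains to criterion, then walks the schedule measuring the association
error (free-phase output vs. target, averaged sum of squares, in percent)
on the same set used for training — the quantity of interest is loss of the
*trained* association, so no held-out set exists. Because the trained state
for a given trial seed does not depend on which group is later lesioned,
`run_full_study()` and the acceptance script train each trial once and
share the fitted networks across damage types.

## Inter-stimulus-interval sweep

`run_hull_test()` evaluates the trained network on stimulus sets whose
climbing stream (and targets) are cyclically delayed relative to the mossy
stream, at checkpoints taken as fractions of the epochs-to-criterion
(reconstructed by deterministic re-training). Association strength at a
checkpoint is the epoch error min–max rescaled across the sweep —
conditioned-response curves are conventionally reported normalized to peak
response — and divergence is the mean absolute gap to a parametric
stimulus-trace reference `(t/0.25) * exp(1 - t/0.25)` peaking at 0.25 s
(config-replaceable by tabulated values).

A known limitation: this model settles each sample independently and has no
intrinsic temporal dynamics, so its association-vs-interval curve is nearly
flat (the readout is dominated by the climbing-fiber code, which determines
the targets at any shift), and the divergence from the peaked reference does
*not* decrease over training checkpoints. The package computes and reports
the sweep, but reproducing stimulus-trace tuning would require mechanisms —
delayed eligibility traces, adaptive timing in the granule layer — that are
outside this model's scope. Note also that the climbing sequence has period
8 samples (2 s), so the sweep is periodic in the shift.

## Degradation-curve analysis

`fit_trend()` fits the trial-mean curve against removed fraction with a
line and with `a + b * log(1 + c f)`, `c` fixed at `n_steps / max_fraction`
so both fits are linear in their parameters; a curve is called sublinear
when the logarithmic R² exceeds the linear R² by at least 0.02. Constant
curves are flagged degenerate. Curves with fewer than four steps (the
single-step climbing schedule) are reported without a trend.

## Numerical and degenerate-input notes

* kWTA boundary ties: exactly tied k-th/(k+1)-th drives place the layer
  threshold on both units, leaving both at threshold and hence silent;
  continuous drives make this a measure-zero event.
* `k = 0` silences a layer; `k >= n` disables competition; the winner count
  is clamped to the remaining units as lesions shrink a layer.
* Weakly driven units can sit below threshold even with zero inhibition; the
  kWTA inhibition is floored at zero (it never *excites*), so fewer than k
  units may be active.
* Settling aborts with an informative error if any state becomes
  non-finite; evaluation never modifies weights (checked bit-wise in the
  tests).
* Training error is measured on the free-phase output *before* each epoch's
  update, and the run stops without a further update once the criterion is
  met, so the returned weights are exactly the ones that achieved it.

## Known limitations

* The near-binary rate code plus kWTA makes intermediate layers robust:
  Golgi loss in particular is compensated almost exactly by the kWTA
  threshold recomputation, so simulated Golgi degeneration is nearly
  harmless here, and granule/basket lesion effects are smaller than a model
  with graded codes would produce. The headline proximity effect — Purkinje
  loss being by far the most damaging, several-fold beyond basket or granule
  loss — is robust across seeds and scales, but the absolute deficit of
  intermediate layers is sensitive to learning constants that the modeled
  system leaves unspecified.
* Only one microzone, no stellate cells, no neuron-subtype physiology, no
  spiking, no post-lesion plasticity.

## Problem sizes used by the shipped tests

The unit tests run a miniature microzone (8/3/40/8/6/6/2 cells, 40 samples)
that preserves the full wiring pattern; the acceptance-level checks train
the canonical 3745-cell circuit (10 trials for the lesion tables, 2 for the
spot checks) and the granule-330 variant. These sizes keep a full test run
in the minutes range on a single core while exercising every code path at
the canonical scale.
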