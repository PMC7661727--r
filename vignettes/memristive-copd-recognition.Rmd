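---
title: "Simulating mixed-signal memristive recognition of COPD saliva samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating mixed-signal memristive recognition of COPD saliva samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memsaliva)
```

## The problem and the model

Chronic obstructive pulmonary disease (COPD) can be screened at the point of
care from the dielectric properties of a saliva sample combined with simple
demographics (age, gender, smoking history). A classifier small enough to
live on an energy-frugal neuromorphic chip makes such screening practical on
a low-power device: synaptic weights are stored as the conductance states of
resistive random-access memory (RRAM) cells, and inference reads currents
instead of multiplying floats.

`memsaliva` simulates that whole chain in software:

1. **Binarization.** Each subject becomes a 23-bit pattern: 1 gender bit,
   3 thermometer smoking bits, 9 thermometer age bits, 10 thermometer
   permittivity bits. In thermometer coding, bit $i$ fires when the value
   reaches the $i$-th threshold, so the code is ordinal and monotone.
2. **Analog network.** A dense 23–4–2 network with sigmoid activations in
   both the hidden and read-out layer, trained with mini-batch Adam
   (learning rate $10^{-4}$, batch 10, 3000 epochs) under 20% hidden-layer
   dropout, minimising the summed binary cross-entropy of the two outputs.
   It has $23{\cdot}4 + 4 + 4{\cdot}2 + 2 = 106$ parameters.
3. **10-level quantization.** With $\Delta = \max_j |\theta_j| / 5$, each
   parameter's magnitude is shifted *up* to the next multiple of $\Delta$
   and clipped to level magnitude 5, preserving sign: levels lie in
   $\{-5,\dots,5\}$.
4. **Hardware deployment.** Each parameter maps to a *synapse group* of 10
   binary memristive devices, five read at positive and five at negative
   polarity. Level $k>0$ switches $k$ positive-half devices to the
   low-resistance state (LRS, nominally 30 µA at 0.2 V; the
   high-resistance state HRS reads 5 µA), so the group's net nominal
   current is exactly $25k$ µA — 25, 50, 75, 100, 125 µA for $k=1..5$.
   The 106 groups need 1060 devices of the 64×64 (4-kbit) array.
5. **Mixed-signal inference.** Input bits with value 1 drive their synapse
   row at ±0.2 V (nothing is applied for 0-bits; bias rows are always
   driven). Group currents are summed, normalized by
   $n = \max|\theta| / 125\,\mu A$ — so the full-scale 125 µA current feeds
   the sigmoid at exactly the magnitude of the largest analog parameter —
   and squashed by software sigmoid neurons into activations
   $X_i \in [0,1]$. These drive the read-out synapses as pulses of
   amplitude $X_i \cdot 0.2$ V with 10 mV precision; the normalized output
   currents give the COPD/HC probabilities, argmax decides (exact ties go
   to COPD so they stay visible in logs).

## Device non-idealities

Three mechanisms separate the hardware path from its software surrogate:

* **Device-to-device variability** — in `measured` mode each device's
  0.2 V read current is drawn once, at programming time, from the
  characterised distributions LRS $35.5 \pm 3.7$ µA and HRS
  $3.9 \pm 1.0$ µA (truncated positive) and then frozen until the array is
  re-programmed. `nominal` mode uses the exact 30/5 µA values.
* **Switching failures** — every device independently lands in the wrong
  resistance state with probability `p_fail` (default 0.0025, the
  characterised 0.25% per-run rate); flips are modelled symmetric because
  only an aggregate rate is characterised.
* **Non-linear read-out** — real cells conduct sub-linearly below the full
  read voltage. The closed form of that curve is not available, so the
  package uses an explicit power-law dialect
  $I(V) = I(0.2\,V)\,\mathrm{sign}(V)\,(|V|/0.2)^{\gamma}$ with
  configurable $\gamma \ge 1$. The default $\gamma = 1$ (ohmic) makes the
  ideal-condition hardware path *exactly* equal to the dequantized software
  network, which is what the equivalence tests pin down; $\gamma > 1$
  demonstrates the distortion qualitatively and is deliberately not
  presented as a fitted device model.

Only the read-out layer feels $\gamma$ and the 10 mV drive precision:
first-layer drives are either 0 or the full 0.2 V, where the power law
rescales by 1. The 10 mV rounding moves any amplitude by at most 5 mV,
hence any nominal group current by at most $(5/200)\cdot 125$ µA.

Read energy assumes serial read-out, so device energies add:
$E = \sum |I(V)\,V|\,t_\text{pulse}$. One LRS device read at 0.2 V for the
500 µs default pulse costs 3 nJ, and energy is exactly linear in the pulse
duration (500 µs → 10 µs divides it by 50).

## What the synthetic generator emulates — and what it does not

The public Exasens saliva deposit (ingestible with `read_exasens()`)
contains 40 COPD and 40 HC subjects once incomplete permittivity rows are
dropped. So that every stage is testable without a download, `cohort_spec()`
/ `simulate_cohort()` draw an 80-subject stand-in: truncated-normal ages
(COPD ~ 65 ± 8 years in [40, 85], HC ~ 50 ± 10 in [25, 80]), normal
permittivity minima (COPD 14 ± 2, HC 18 ± 2 — a 2-sd class gap at the
default separation scale `d = 1`), smokers enriched in COPD
(probabilities .5/.4/.1 versus .2/.3/.5 over smoker/ex/non), and mildly
male-biased COPD (.6 vs .5). These shapes were chosen once as a plausible
screening cohort; the study that motivated the package publishes no
distribution parameters, so none of these numbers are claims about the real
data. Consequently, passing tests demonstrate the *pipeline* — encoding,
training, quantization, fault tolerance — under a controlled,
well-separated cohort; they do not certify accuracy on real saliva
measurements, whose attribute correlations, outliers and measurement noise
the generator does not model. `d = 0` collapses the permittivity gap and is
used as a null-signal control.

## Numerical choices

* **Initialisation** — Glorot-uniform weights, zero biases, seeded;
  identical seeds give bit-identical fits. Adam uses the standard
  $(\beta_1, \beta_2, \epsilon) = (0.9, 0.999, 10^{-8})$; only the learning
  rate is part of the published recipe.
* **Loss scaling** — batch-mean of the per-sample summed two-output binary
  cross-entropy (two independent sigmoids, not softmax, matching the
  sigmoid read-out layer).
* **Dropout** — inverted scaling at train time; inference never drops.
* **Quantization ties** — a magnitude exactly on a level boundary keeps
  that level (ceiling semantics); the implementation subtracts $10^{-9}$
  from the ratio before the ceiling so floating-point noise just above an
  exact multiple of $\Delta$ cannot jump a level. An exact zero maps to
  level 0 (all devices HRS, nominal 0 µA), since the shift-up rule is only
  defined for nonzero magnitudes.
* **Fold-local scales** — $\Delta$ (and hence $n = 5\Delta/125$, shared by
  both layers) is computed per fold from that fold's trained parameters;
  the permittivity thermometer edges are likewise fitted per fold on the
  training split (10 uniform edges over its min–max) so the test split
  never leaks into the encoding. Age edges default to 9 uniform edges over
  35–75 years. The literal bin edges of the original encoding are not
  published; both edge sets are configurable in `encoding_spec()`.
* **Smoking bits** — all four attributes are thresholded, so smoking is
  thermometer-coded over its ordinal 1/2/3 codes (non-smoker 100,
  ex-smoker 110, smoker 111), keeping the 3-bit budget and the ordinal
  structure; a one-hot over the three categories is the documented
  alternative.
* **Seed fan-out** — `run_experiment()` expands one master seed
  deterministically into the split seed, per-fold training seeds and
  per-repeat programming seeds, so every table reproduces byte for byte.

## The cross-validated experiment

`run_experiment()` mirrors the published protocol: stratified 5-fold
cross-validation (64 training / 16 test subjects per fold on an 80-subject
cohort), per fold an analog fit, its 10-level surrogate, and five
independent hardware deployments (fresh current draws and fault injection
each repeat) whose metrics are averaged. It reports accuracy, sensitivity,
specificity and precision per fold and on average for all three model
tiers, the per-fold confusion matrices, the realized wrong-state device
count of every run, and the per-sample read energy. Undefined ratios (zero
denominators) print as `NA` and are excluded from averages with a warning
rather than silently zeroed.

```{r, eval = FALSE}
cohort <- simulate_cohort(cohort_spec(), seed = 5)
exp <- run_experiment(cohort, seed = 5)
exp
```

On the default synthetic cohort this takes roughly twenty seconds (five
3000-epoch fits of a 106-parameter network plus 25 hardware evaluations)
and lands all three average accuracies near 90%, with the hardware tier
within a fraction of a point of its software surrogate — the
variability-tolerance property the design is meant to show. Note that on a
well-separated cohort the 10-level surrogate loses essentially nothing
relative to the analog model: the shift-up rule slightly inflates weight
magnitudes and the grid is fine enough for a 106-parameter network, so the
analog-versus-quantized gap sits within sampling noise (either sign can
come out ahead on a given seed) rather than showing the clear degradation
expected on harder, real measurements. Property tests
that need many repeated fits (null-signal and separation-monotonicity
checks) use shortened training, since they probe orderings rather than the
full recipe.

## Known limitations

* The power-law I–V dialect is a stand-in for an uncharacterised curve;
  conclusions about $\gamma > 1$ are qualitative only.
* Programming physics (incremental pulse trains, retention, endurance) is
  abstracted to a single wrong-state probability per programming event.
* Training the tiny network on 64 subjects is deliberately faithful to the
  published recipe, not optimised: no early stopping, no architecture
  search, no quantization-aware training.
* Whether the original folds were stratified is not stated; stratified
  splits are used because they reproduce the implied 8 + 8 class balance of
  a 16-subject test fold.
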