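---
title: "An adaptive dopamine-gating model of prefrontal executive function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An adaptive dopamine-gating model of prefrontal executive function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

People with autism spectrum conditions often show a dissociation within
executive function: cognitive *flexibility* is impaired (elevated
perseverative errors on the Wisconsin Card Sorting Test, WCST), while
cognitive *control* is spared (Stroop interference no larger than in
controls), and executive deficits tend to appear late in development.
`xtgate` implements a neurocomputational account of this profile: a
rate-coded network in which prefrontal cortex (PFC) actively maintains
rule-like representations that bias posterior processing, and a
dopamine-based adaptive gate — driven by the temporal-difference (TD)
error — decides when those representations are protected and when they
are released.  A single parameter, the dopamine efficacy `kappa`
multiplying the TD error,

$$\delta(t) = \kappa\,\bigl(r(t) + \gamma V(t+1) - V(t)\bigr),$$

is 1.0 for typical modulation and 0.54 for the reduced-modulation
("autism") model.  Because the WCST depends on rapid updating of PFC
contents while Stroop depends only on stable maintenance, attenuating
`delta` raises perseveration without touching interference.

## The substrate

The network engine is a deliberately simplified, fully specified analog of
rate-coded cortical frameworks:

* **Units** follow `x' = x + dt (sigma(gain (net - inhibition - bias)) - x)`
  with a logistic `sigma`, `gain = 40`, `bias = 0.08`, `dt = 0.3`.  The PFC
  layer integrates more slowly (`dt_pfc = 0.05`): top-down control builds
  gradually, which is what makes conflict trials slow.
* **Inhibition** is pooled k-winners-take-all per layer: a shared
  inhibition level is placed between the k-th and (k+1)-th largest net
  inputs (ties to the lowest index; exact boundary ties at positive drive
  give winners a fixed margin; ties at or below zero fall back to the zero
  floor so the resting state is quiescent).
* **Architecture**: two 5-dimension x 4-feature stimulus input layers, a
  4-unit Task layer, a 5-unit Dimension Cue layer, a 40-unit Hidden layer,
  a 20-unit PFC layer with a recurrent self-projection and intrinsic
  maintenance currents, and a 5 x 4 Response layer.  Projections carry
  fixed relative net-input scales (the analog of per-projection input
  scaling in rate-coded frameworks); without them a single cue unit could
  never compete with the 40-unit hidden projection at the PFC.
* **Learning** is two-phase contrastive: an expectation phase (the network
  settles to its own response) and an outcome phase (the target clamped on
  the Response layer); weights move with the difference of co-activation
  products, with soft bounds (potentiation scaled by headroom `w_max - w`,
  depression by `w - w_min`) that keep weights interior — without soft
  bounding the rule saturates and learning collapses.

Three design choices deserve emphasis because the design was genuinely
open:

1. **Direct stimulus-to-response projections.**  The sketch of the
   architecture routes stimuli through the hidden layer only.  With a
   40-unit random hidden pool, within-dimension feature identity is not
   reliably learnable by the contrastive rule, so direct
   input-to-response projections carry feature evidence while the hidden
   pathway carries task/attention modulation.
2. **Topographic cue-to-PFC projection.**  Contrastive learning cannot
   differentiate PFC patterns per cue because the outcome phase has no
   feedback path into PFC (a learnable response-to-hidden feedback exists
   in the container but destabilised training in every regime tested, so
   its scale defaults to 0).  Each Dimension Cue unit therefore projects
   strongly onto its own pool of four PFC units.  What those pools *mean*
   — the dimension-banded PFC-to-Response mapping read out by
   `dimensional_selectivity()` — is entirely learned over development,
   and is the quantity that matures slowly and in both groups.
3. **Label-pooled response competition.**  Response units sharing a
   feature column pool into one verbal-label coalition; coalitions
   compete winner-take-all and the winning coalition's best member is
   expressed.  With plain unit-level inhibition, congruent Stroop trials
   contain a spurious within-label "which dimension said it" duel and the
   congruency effect inverts.  Stroop reaction times are the settling time
   of the label activity (`label_cycles`).

## The gate

The critic is linear over PFC activations **plus a learned intercept**;
both are trained by TD(0) with the kappa-scaled error.  The intercept
makes the reward expectation generalise across PFC states — without it,
off-distribution states have `V ~ 0`, the TD error vanishes, and the WCST
search deadlocks.

Gate actions per trial:

* `delta > 0`: **strengthen** — maintenance currents of currently active
  PFC units are set to `maintenance_gain` (0.7), others zeroed;
  maintenance persists until destabilised.
* `delta < 0`: **destabilise** — graded by
  `g = min(1, max(|delta|, kappa * gate_floor))^gate_power` with
  `gate_floor = 0.8` and `gate_power = 2`: maintenance is attenuated by
  `1 - g` and Gaussian noise of sd `noise_sd * g` (`noise_sd = 1.2`) is
  injected into PFC net inputs on the next settle, letting a new
  representation be sampled.
* `|delta| < 1e-9`: **hold**.

Two deviations from a minimal sign-based gate are deliberate and central.
A purely binary gate makes `kappa` behaviourally inert (actions depend
only on the sign of `delta`), contradicting the phenomenon being
modelled; grading by `|delta|` expresses dopamine efficacy behaviourally.
The supralinear exponent makes the *release* of a maintained rule
sensitive enough to dopamine attenuation: at `kappa = 1` a failed,
previously rewarded sort clears maintenance essentially completely
(`g ~ 1`, exactly the binary rule), while at `kappa = 0.54` roughly 70%
of the maintenance survives each error, producing runs of perseverative
sorts.  The exploration floor keeps search alive when value estimates are
uninformative, and is itself kappa-scaled.

During WCST administration the value readout is treated as a reward
probability clamped to `[0, 0.95]` — capped just below certainty so that
a rewarded sort always produces a small positive surprise that re-closes
the gate — and the critic's within-session learning rate defaults to 0
(the expectation consolidated over development is not relearned inside a
single administration; with the developmental rate the critic tracks the
session failure rate and the TD error collapses).

## The developmental curriculum

Development consists of epochs of 2000 supervised trials over the
4^5 = 1024 factorial stimuli (20% held out as novel items that never
appear in training), with the gate and critic active and `kappa` in force
throughout, alternating with generalization tests of 250 novel-stimulus
trials; training stops at 10% error or after 100 epochs.  Four tasks are
drawn uniformly: naming the cued feature of one stimulus; matching (two
stimuli share their feature only on the relevant dimension); comparison
(respond with the higher feature level on the cued dimension); and cued
naming of a sparse stimulus carrying only the relevant and one distractor
dimension — the fourth task is the Stroop trial format, which the named
task set requires but does not pin down.  One dimension (the future
"colour naming" pathway) is relevant only 25% as often as each other
dimension; one ordinary dimension is designated "word reading".  The
WCST uses three further dimensions, so the pathway-strength manipulation
never touches the card-sorting stimuli.

What a green test does and does not establish: the generator emulates the
*statistics* the protocol states (task mix, relevance frequencies, novel
split, trial counts); it does not emulate realistic childhood experience,
and the absolute magnitudes of settling times or error counts are
properties of this substrate, not of children.

## Known limitations

* **Total WCST errors run high.**  Perseverative errors, their
  percentages and the reduced-dopamine/control ratio reproduce the
  reference magnitudes quantitatively, but total errors are roughly
  1.7-2x larger: this substrate's reward-driven search phase (sampling
  PFC pools through destabilisation noise) frequently passes through
  mixed states that yield no response, each costing an error card.  The
  acceptance script reports these honestly.
* **Development survives very low kappa.**  In the original model,
  training failed to reach criterion below `kappa = 0.5`.  Here the
  supervised contrastive pathway is dopamine-independent and the
  dimension cue overrides stale maintenance, so development succeeds even
  at `kappa = 0.4`; every mechanism we found that blocked development at
  low kappa also blocked it at `kappa = 1`.  The corresponding acceptance
  clause is left failing, with this analysis.
* **Development is compressed in time.**  PFC dimensional selectivity and
  gate-dependent flexibility mature within roughly ten epochs here,
  against fifty-plus in the original: the perseveration group difference
  emerges between the first and second probes of the trajectory study
  rather than midway through development.  The *ordering* (selectivity
  and the deficit both arrive with maturation, in both groups) is
  reproduced; the prescribed half-split unmasking statistic is not, and
  the corresponding acceptance check is left failing.
* In the initial-simulation (post-hoc) design, Stroop performance is
  identical across groups by construction, since Stroop involves no
  gating plasticity; the Stroop-sparing comparison is therefore run on
  developmental-mode groups.

## Numerical choices

Settling uses `tol = 1e-4` with a 200-cycle budget; non-convergence is
reported, never raised.  All stochasticity flows through R's RNG (weight
initialisation, curriculum sampling, deck shuffles, gate noise); the C++
engine is purely deterministic, so identical seeds give bit-identical
runs on any platform.  Ties everywhere resolve to the lowest index.
Weight bounds are `[0, 1]`; the uniform initialisation upper bound is
0.25.  The default group size in `run_group_experiment()` is 10 and the
acceptance script uses 20 per group; both are scaled from the published
100 per group, a knob (`n_per_group`), never a constant.

## A worked example

```{r}
library(xtgate)

dev <- run_development(kappa = 1, seed = 101)
dev
# <xt_development>
#   kappa 1.00, seed 101: 9 epoch(s), criterion met
#   final train error 0.149, generalization error 0.096

control <- administer_wcst(dev$network, dev$critic, seed = 1)
reduced_critic <- dev$critic
reduced_critic$kappa <- 0.54
autism <- administer_wcst(dev$network, reduced_critic, seed = 1)
control$perseverative_errors
autism$perseverative_errors

st <- run_stroop(dev$network, build_stroop_block(16, seed = 5))
stroop_interference(st, "weak")    # positive: colour naming is slowed
stroop_interference(st, "strong")  # near zero: word reading is not
```
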