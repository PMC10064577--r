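---
title: "Simulating, labeling and estimating patient-ventilator asynchrony with pvsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating, labeling and estimating patient-ventilator asynchrony with pvsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsim)
```

## The model

`pvsim` simulates a single-compartment, linear active respiratory system
coupled to a ventilator. All pressures are in cmH2O, flow in L/s
(inspiratory positive), volume in L above the end-expiratory baseline,
compliance in mL/cmH2O. The governing relation is the equation of motion

$$P_{aw}(t) = R\,\dot V(t) + \frac{V(t)}{C} + \mathrm{PEEP} - P_{mus}(t),$$

with the muscle pressure stored nonnegative and subtracted: inspiratory
effort lowers alveolar pressure, which is the convention in which Pmus is
displayed to clinicians. The ventilator imposes a boundary condition that
switches with phase:

* **Inspiration** — PSV/PCV: airway pressure follows a first-order rise to
  PEEP + support with time constant `rise_time_s` (default 0.1 s; ventilator
  pressurization is device-specific, so this is a settable model choice) and
  the flow follows from the equation of motion. VCV: flow is the set square
  wave and pressure follows.
* **Expiration** — with a flow trigger, the PEEP valve holds
  $P_{aw} = \mathrm{PEEP}_{set}$ and flow is free in both directions; with a
  pressure trigger, the demand valve blocks inspiratory flow, so patient
  effort reads as a pressure dip below set PEEP (this is what a pressure
  trigger senses physically).

**Triggering.** Patient triggers arm only in expiration after a refractory
time (`refractory_s`, default 0.2 s — it prevents one effort from counting as
trigger plus retrigger unless breaths are genuinely stacked). Flow triggers
fire on sensed inspiratory flow (threshold in L/min); pressure triggers on
the occlusion dip (cmH2O). Machine (mandatory) breaths fire on a fixed
schedule at `set_rate_bpm`, first insufflation at t = 0.5 s. Cycling:
PSV cycles at `cycling_flow_fraction` of the peak inspiratory flow (or at
`max_insp_time_s`); PCV/VCV at the set inspiratory time.

**Integration.** Each sample advances by an implicit trapezoidal
(Crank–Nicolson) step. The step is solvable in closed form for every
boundary regime because the system is linear, it is unconditionally stable
for the stiff time constants of restrictive mechanics, and — the property we
care most about — it makes the exported channels mutually consistent: the
volume channel is *exactly* the trapezoidal integral of the recorded system
flow, and the equation of motion holds at every noiseless sample to numerical
precision. (An explicit sub-stepped Euler loop was the obvious alternative;
it leaves O(dt) inconsistencies at flow discontinuities that are larger than
the 0.1-cmH2O self-consistency budget, which is why the implicit one-step
form was adopted.) Sampling is 100 Hz by default, the scale of a ventilator
display; it is configurable.

**Measurement noise** is Gaussian, added only to the *exported* pressure and
flow channels (sd `noise_sd` on paw; one tenth of that value on flow, the
relative scale of typical pressure vs flow sensor noise). The gold
`pmus_true` channel stays noiseless because it is the answer key, and the
trigger logic runs on the noiseless internal signals — the noise models the
display/export path, not the ventilator's own sensing.

**Auto-trigger artifacts** are brief (150 ms) half-sine flow blips
superimposed on the *sensed* flow during expiration — condensation or
cardiogenic oscillations. They can cross a flow trigger with
`pmus_true ≡ 0`, which is precisely auto-triggering. Because they are sensed
rather than system flow they do not enter the equation of motion; the
simulator exports the artifact component (attribute `artifact_flow`) so that
consistency checks can reconstruct the system flow and volume.

## Effort model and gold standard

Efforts are a train of stereotyped profiles (half-sine, or
ramp–hold–release) at programmed onsets, or — for reverse triggering — an
*entrained* train firing at machine-insufflation onset plus a fixed delay.
Gold effort episodes are emitted from the programmed train itself, not
re-detected. For detection (from gold or estimated Pmus) an episode is a
maximal run with Pmus ≥ 0.5 cmH2O lasting ≥ 100 ms; onset is the first
crossing, end the last sample of the run, peak the within-run maximum. The
0.5-cmH2O / 100-ms pair suppresses numerical chatter while passing every
clinically plausible effort (amplitudes of interest are ≥ 1 cmH2O); both are
arguments, not constants.

## The labeler

Classification works on effort episodes plus the ventilator event log.
Association first: a breath owns an effort when its trigger falls in
[onset − 0.1 s, end + 0.3 s], **or** when the effort *begins during the
breath's inspiration* — the second branch is what lets an entrained effort
(which starts 0.3–0.5 s *after* the machine trigger) pair with its breath;
without it reverse triggering is undetectable by construction. An effort may
own several breaths (stacking); a breath owns at most one effort, nearest
onset first.

Rules, first match wins, evaluated per effort then per breath:

1. **ineffective_effort** — effort without ventilator triggering (unpaired).
2. **double_triggering** — one effort owning ≥ 2 breaths whose trigger gap is
   shorter than effort duration + window, *with the first stacked breath
   patient-triggered*. The qualifier matters: without it every
   reverse-triggering-with-double-cycling breath would also satisfy the
   stacking predicate and the variant below could never fire; in true
   double-triggering the effort triggers the first breath itself.
3. **auto_triggering** — patient- or artifact-triggered breath with no paired
   effort.
4. **reverse_triggering** — machine-triggered breath whose paired effort
   begins after the trigger with delay stable across ≥ 3 consecutive machine
   breaths (sd < 0.1 s); with a stacked second breath, both breaths become
   **reverse_triggering_double_cycling**.
5. **premature_cycling** — cycle-off before the effort's peak.
6. **delayed_cycling** — cycle-off more than 0.1 s after the effort's end.
7. **synchronous** otherwise.

The 0.3-s window, 0.1-s entrainment-delay sd and 0.1-s delayed-cycling grace
are display-resolution-scale tolerances, exposed as arguments; the bedside
definitions give predicates without tolerances. Scenario-level scoring takes
the most frequent non-synchronous label, ties broken by the rule order above
(trigger-phase asynchronies are defined on effort/breath cardinality and must
outrank cycling-phase timing rules); `synchronous` only when nothing else
occurred.

## The 49-scenario battery

The battery is deterministic: 6 scenarios per asynchrony category (three
mechanics presets × two effort amplitudes, or two artifact magnitudes for
auto-triggering) plus 7 synchronous ones. Mechanics presets are conventional
teaching values — normal (R = 10, C = 50), obstructive (R = 20, C = 60),
restrictive (R = 10, C = 25), PEEP 5 — recorded in the manifest and not
claimed to be anything else. Category recipes:

* *synchronous*: assisted PCV, Ti = 0.7 s, efforts (T = 1 s) every 3 s —
  cycle-off lands between effort peak and end on every preset.
* *ineffective effort*: weak efforts (1.2 / 2 cmH2O) between mandatory PCV
  breaths, against an insensitive (3 cmH2O) pressure trigger.
* *auto-triggering*: passive patient; expiratory blips (0.08 / 0.12 L/s)
  cross a 2 L/min flow trigger.
* *double-triggering*: long strong efforts (T = 1.6 s, 12 / 16 cmH2O)
  against a short (0.5 s) low-pressure inspiration; the effort remainder
  retriggers a stacked breath.
* *reverse triggering*: mandatory PCV with entrained efforts at +0.3 s,
  amplitudes too modest (and the refractory too long) to retrigger.
* *reverse triggering with double cycling*: entrained efforts at +0.5 s,
  strong enough (12 / 16 cmH2O) to outlast the 0.7-s inspiration and
  retrigger.
* *premature cycling*: Ti = 0.4 s against T = 1.4 s efforts, a long
  expiratory refractory suppressing the (physically real) retrigger
  tendency so the scenario isolates the cycling error.
* *delayed cycling*: assisted Ti = 2.0 s against T = 0.8 s efforts. A very
  low PSV flow-cycling fraction also produces late cycling on obstructive
  mechanics, but on normal/restrictive presets the first-order
  pressurization equilibrates before a 5% criterion is reached; the long
  fixed inspiratory time produces the defining event — cycle-off after
  effort end — on every preset, so it is the recipe used.

Every recipe was designed so the intended asynchrony *arises from the
closed-loop physics* and is then recoverable by the labeler from gold Pmus:
that closed-loop recovery (49/49) is the battery's core invariant and is
asserted in the tests. Rendering at the default measurement noise
(sd 0.1 cmH2O) or adding noise up to sd 0.2 to the Pmus channel before
detection changes no scenario label.

What the generator does *not* emulate: chaotic or breath-varying effort
shapes, intrinsic-PEEP gas trapping, leaks and NIV, nonlinear or
multi-compartment mechanics, esophageal-signal artifacts. Passing tests on
this battery therefore demonstrate correctness of the machinery on
stereotyped efforts and linear mechanics — the regime bench simulators
operate in — not robustness to real patient recordings.

## Pmus estimation

**Model-based inversion.** With mechanics estimates
$(\hat R, \hat C, \hat P_0)$,
$\hat P_{mus} = \hat R \dot V + V/\hat C + \hat P_0 - P_{aw}$, re-zeroed on
the median of the record's expiratory samples, floored at 0, smoothed with a
50-ms centered moving average. The baseline is record-level rather than
per-breath: when a strong effort fills a breath's entire expiration (breath
stacking), a per-breath median is badly biased and destroys exactly the
scenarios the estimator is most needed for, while mechanics-misfit offsets
it is meant to absorb are record-level anyway.

**Mechanics identification.** On records with known passive breaths,
ordinary least squares of $P_{aw}$ on flow and volume over those breaths.
All channels first receive an identical short moving average (90 ms): the
equation of motion is linear, so filtered channels satisfy it exactly, while
noise on the flow *regressor* — which would otherwise attenuate $\hat R$
(errors-in-variables) — is suppressed. Without known passive breaths,
`fit_mechanics_robust()` works in two stages: resistance interrupter-style
from the pressure/flow jump across cycle-off transitions (volume and Pmus
are continuous across one sample, so $\Delta P_{aw}/\Delta \dot V = R$,
median over transitions), then elastance and PEEP by asymmetric reweighted
least squares on $P_{aw} - \hat R\dot V$ vs volume, down-weighting samples
with strongly negative residuals (effort only ever lowers the left side).
A plain three-parameter asymmetric fit is the fallback when a record has
fewer than three usable transitions. The two-stage form exists because a
record whose every inspiration contains effort leaves passive expiration as
the only clean data, and passive expiration alone cannot separate R from
elastance (it identifies only their ratio); the transition jumps restore
identifiability.

On the noiseless battery the inversion with true mechanics has RMS error
< 0.15 cmH2O everywhere; with blind robust fits, end-to-end labeling from
estimated Pmus recovers 48/49 primary labels. The one stubborn scenario is a
restrictive premature-cycling record in which every high-volume sample
carries effort, so elastance is genuinely weakly identifiable — the
degradation is reported, not hidden.

**Recurrent estimator.** A deliberately small Elman recurrent network
(16 tanh units, linear readout; inputs paw/flow/volume z-scored on the
training set, output Pmus scaled by 10 cmH2O) trained by full
backpropagation through time with Adam (lr 0.02, gradient-norm clip 5,
30 epochs) on records downsampled to 20 Hz. The train/eval split is by
scenario id — two 30-s renders of the same scenario are near-duplicates, so
a sample-level split would leak. Training is deterministic given the seed,
takes well under a minute on one CPU at the documented sizes (about two
dozen records), and reaches a pooled held-out RMS around 1.5 cmH2O — a
concept demonstration that Pmus is learnable from airway signals, not a
competitor to the transparent inversion, which remains the package's
reference method and the one all acceptance properties use.

## Trial statistics

Randomization is permuted-block (block 2) within profession × experience
strata, so per-stratum imbalance never exceeds 1 (98 participants in
even-sized strata give exactly 49 per arm). Scoring counts an asynchronous
scenario correct only on an exact type match — per-type sensitivities are
meaningless otherwise — and also reports the looser any-asynchrony
sensitivity separately; specificity is the proportion of synchronous
scenarios called synchronous. Group comparison gates on Shapiro–Wilk at
α = 0.05 in each arm: both normal → two-sample t (Welch by default, with a
pooled-variance flag since "Student's t" is ambiguous in the field's
reporting), otherwise Mann–Whitney with median (IQR); zero-variance groups
fail the normality gate by definition and fall to the rank test. Sample size
iterates the exact noncentral-t power: the smallest n per group with power
≥ target; 10-pp difference, 15-pp sd, 90% power, two-sided α 0.05 gives 49
per group (98 total), with Monte-Carlo agreement within 1.5 pp.

The published human-rater outcomes (mean sensitivity near 66% with the Pmus
display vs 53% without) are measurements of people and are **not**
reproduction targets for software. What the package does show, end to end
through the rater simulator, scoring and the gated comparison, is that a
10-pp true difference at the designed spread is detected with the designed
power.

## Numerical and degenerate-input choices

* Unstable parameter combinations (nonpositive R, C, hence time constant)
  are rejected before integration.
* Records with no flow excitation are declared unidentifiable rather than
  fitted; requesting a passive-breath fit without passive breaths raises an
  error directing the caller to the robust fit.
* Scenario ties in per-scenario labeling break by rule precedence;
  the tie-break is documented and tested rather than incidental.
* Waveform CSVs carry `#` provenance headers (version, seed, noise, rate)
  above a fixed column contract; numeric channels are written with 8
  significant digits, which round-trips within 1e-6; shuffled or
  non-monotone files are rejected with the offending line numbers.
* All randomness (simulation noise, allocation, rater fixtures, network
  initialization) flows from explicit integer seeds; identical seeds give
  bit-identical outputs.

## Problem sizes used by the test suite and acceptance script

The suite renders the full 49-scenario battery several times (gold recovery,
noise robustness, estimator evaluation), runs 20-replicate noisy
mechanics-recovery studies, a 10,000-replicate Monte-Carlo power check, and
trains the recurrent network on a 12-record subset at reduced temporal
resolution; the acceptance script repeats the same computations at the same
or larger sizes (24 training records, 10 replicate simulated trials). These
sizes were chosen so the whole cycle completes in a few minutes on a single
CPU while leaving every statistical check comfortably powered.

## Known limitations

Single linear compartment; no intrinsic PEEP, leak, or circuit dynamics; one
stereotyped effort profile per scenario; entrainment is deterministic 1:1;
the labeler assumes a trustworthy event log (it re-derives events from flow
only for imported records); the recurrent estimator is a desk-scale
demonstration. Clinical validation of any Pmus display is explicitly out of
scope.
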