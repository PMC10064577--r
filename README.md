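# pvsim

Patient–ventilator asynchronies — ineffective effort, auto-triggering,
double-triggering, reverse triggering (with or without double cycling),
premature cycling, delayed cycling — are usually detected by visual
inspection of ventilator waveforms, with notoriously low sensitivity. Showing
clinicians an estimate of the inspiratory muscle pressure (Pmus) alongside
airway pressure and flow is one proposed remedy, and evaluating that idea
requires three pieces of computational machinery. `pvsim` provides all three
for R users working in respiratory physiology and mechanical-ventilation
research:

1. **A closed-loop waveform simulator** of a single-compartment active
   respiratory system coupled to a ventilator (PSV/PCV/VCV, flow or pressure
   triggering, first-order pressurization, flow-fraction or time cycling),
   driven by the equation of motion

   `Paw(t) = R·V̇(t) + V(t)/C + PEEP − Pmus(t)`

   with Pmus ≥ 0 by display convention. A deterministic battery of **49
   labeled 30-s scenarios** spans seven asynchrony types plus synchronous
   cycles over three mechanics presets, each carrying gold-standard Pmus as
   the answer key.

2. **A rule-based asynchrony labeler** — the executable form of the standard
   bedside definitions — classifying each breath from effort episodes plus
   the ventilator event log, and aggregating to a per-scenario primary label.

3. **A noninvasive Pmus estimator**: transparent equation-of-motion inversion
   (with passive-breath or robust full-record mechanics identification) plus
   a small recurrent-network estimator trained on simulator output; and the
   **trial statistics** used to evaluate raters — stratified 1:1
   randomization, answer-key scoring into sensitivity/specificity, a
   Shapiro–Wilk-gated t/Mann–Whitney comparison, and noncentral-t power and
   sample-size computation.

## Worked example

```r
library(pvsim)

battery <- build_default_battery()
b <- battery[[32]]
b
#> <pv_scenario 32> reverse_triggering_double_cycling | normal mechanics | PCV mode

r <- render_scenario(b, seed = 7)   # 30-s record + event log + gold efforts
r$signals
#> <breath_signals> 3001 samples @ 100 Hz (30.0 s), 12 breaths, pmus present

label_scenario(r, "gold")$primary
#> [1] "reverse_triggering_double_cycling"
```

All 12 breaths carry the injected label: six mandatory insufflations each
entrain a delayed effort strong enough to retrigger a stacked second breath.
Estimating Pmus blindly from the airway signals alone:

```r
mech <- fit_mechanics_robust(r$signals)
mech
#> <mechanics_estimate> R = 10.04 cmH2O.s/L, C = 52.7 mL/cmH2O, PEEP = 5.07 cmH2O (rms 0.200, n=2251)

estimate_pmus_model_based(r$signals, mech)
#> <pmus_estimate> method=model_based, 3001 samples, rms vs gold: 0.257 cmH2O
```

The true mechanics were R = 10, C = 50, PEEP = 5: the robust fit recovers
them from a record in which every breath contains effort, and the inverted
Pmus tracks the gold standard to within 0.26 cmH2O RMS. Finally, the trial
design calculation:

```r
required_sample_size(delta_pp = 10, sd_pp = 15, power = 0.90, alpha = 0.05)
#> $n_per_group
#> [1] 49
#> $n_total
#> [1] 98
#> $achieved_power
#> [1] 0.904
```

i.e. 49 raters per arm give 90% power to detect a 10-percentage-point
difference in mean detection sensitivity (sd 15 pp, two-sided α = 0.05).

## Command line

A thin wrapper is installed at `inst/cli/pvsim`:

```sh
pvsim battery --out-dir battery/ --seed 7      # 49 waveform pairs + manifest + answer key
pvsim simulate --config scenario.yaml --seed 3 --out w.csv --events e.csv
pvsim label --waveform w.csv --events e.csv --out labels.csv
pvsim estimate --waveform w.csv --out est.csv
pvsim trial --power --delta 10 --sd 15 --power-target 0.9 --alpha 0.05
```

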