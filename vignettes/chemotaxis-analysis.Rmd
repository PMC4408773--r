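---
title: "Quantifying and simulating run-and-turn chemotaxis in larval Drosophila"
author: "larvatax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and simulating run-and-turn chemotaxis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvatax)
```

## The behavioral model

A crawling *Drosophila* larva navigating an odor gradient alternates
between **runs** (forward peristaltic crawling) and **turns**
(reorientation maneuvers prepared by lateral **head casts**). Chemotactic
performance is then determined by three sensory-motor decisions: how fast
to run, when to turn, and where to direct the turn. `larvatax` measures
all three from multi-animal tracking tables and re-expresses them as a
generative two-state Markov model that can be simulated.

Throughout, behavior is referenced to the **bearing** $\beta \in
(-180^\circ, 180^\circ]$, the signed angle between the larva's heading
and the direction to the odor source ($\beta = 0$: heading at the
source), and to the distance $d$ from the midpoint to the source.

The analysis side computes, per assay dish:

* the filmed preference
  $\mathrm{PREF} = (T_{\mathrm{odor}} - T_{\mathrm{no\,odor}}) /
  T_{\mathrm{total}}$, the normalized tracked time spent on the odor
  half of the arena, and the analogous counted preference
  $(\#_{\mathrm{odor}} - \#_{\mathrm{no\,odor}})/\#_{\mathrm{total}}$
  from end-point animal counts;
* the run speed (duration-weighted mean midpoint speed during runs);
* the turn rate $60 \cdot \sum N_T / \sum T$ in turns/min, overall and
  split by bearing class (toward: $|\beta| < 90^\circ$; away:
  $|\beta| > 90^\circ$; the boundary belongs to neither class);
* the proportion of turns directed toward the odor, a turn counting as
  "toward" iff $|\beta_{\mathrm{after}}| < |\beta_{\mathrm{before}}|$
  (strict; ties count as not toward).

Pooled across dishes it computes bearing-resolved profiles (1° grid,
circular sliding window of ±30°), bearing × distance maps (2° × 2 mm
grid, box filter ±30° × ±15 mm), a toward-proportion map over time ×
distance (7.5 s × 2.5 mm grid, box filter ±22.5 s × ±10 mm), and a
spatial density map (2 mm grid, 30 mm square filter). All sliding
filters are inclusive at their edges and the bearing dimension wraps
circularly, so the profile values at −180° and +180° coincide.

## Event detection

Turns are detected primarily from the **reorientation speed**, the time
derivative of the circularly unwrapped body-axis (tail-to-midpoint)
angle. Using the body axis rather than the heading means head casts do
not register as reorientation. A **Schmitt trigger** provides
hysteresis: a candidate event opens when |reorientation speed| reaches
the high threshold (default 35 °/s) and closes at the first frame at or
below the low threshold (default 15 °/s); candidates shorter than
0.25 s, or separated by less than 0.25 s, are discarded or merged. A
candidate becomes a turn only if the larva actually bends (peak
|head angle| ≥ 20° within the event) and the net body-orientation
change, measured δ = 0.25 s outside the event to avoid within-turn
transients, exceeds **20°** — smaller events show no directional bias
and are not scored as turns. The 20° cutoff is fixed by the method; the
Schmitt and posture thresholds are empirical surrogates exposed in
`turn_config()` and validated by implanted-event recovery (see below),
not published constants. The original method also gated on two
additional posture variables ("kink" and "curve") whose definitions are
not public; the posture gate here is a single head-angle criterion, and
the configuration leaves room for extra gates.

Head casts are detected from |head angle| with a second Schmitt trigger
(defaults 20°/10°). A cast is **flanking** a turn if it starts within
5 s before the turn's start to 0.5 s after its end; casts also occur
mid-run. A **run** spans from a turn's end to the first flanking cast
of the next turn (or that turn's start if it has no flanking cast).

**Sign conventions.** Angles are counterclockwise-positive and a
positive bearing puts the source on the larva's left. The turning angle
is the signed body-orientation difference across the turn. No published
sign convention exists for these quantities; any consistent choice
leaves all magnitude statistics invariant, which the test suite asserts
by mirror symmetry (mirroring the arena about the odor axis negates
bearings and turning angles and leaves rate statistics unchanged).
Bearing is computed from the midpoint position; whether the original
analysis used midpoint or head is not documented, and the difference is
bounded by the 2.15 mm head-segment length.

## The two-state Markov simulator

Model larvae are two rigid segments (head and tail) of 2.15 mm each —
half of the 4.3 mm grand-average body length — joined at the midpoint,
stepped at dt = 0.0625 s (16 Hz, the tracking frame rate):

* **Run state**: both segments advance along the heading at the
  policy's constant run speed; per step a uniform noise angle from
  [−1.8°, +1.8°] is added to the heading, redrawn whenever the proposed
  head endpoint would leave the 75 mm arena, so larvae gradually align
  to the border. The run→turn transition fires with probability
  $P = r_{\mathrm{turn}}(\beta, d)\,\mathrm{dt}$, with the rate looked
  up from the policy at the current bearing and distance.
* **Turn state**: a turning angle is drawn from the policy's **event
  bank** — the empirically observed (or synthetic) triples (pre-turn
  bearing, distance, turning angle) — restricted to events within ±30°
  and ±15 mm of the current state. The head segment pivots about the
  joint at 53.7 °/s until the head–tail angle reaches the drawn angle
  (or the head would rotate into the border), whereupon the body axis
  adopts the head heading and the run resumes.

Four modes ablate the two modulated decisions: `realistic_rate` uses
the bearing/distance-dependent rate, `random_rate` replaces it by the
policy's scalar mean rate; `realistic_dir` samples the bank around the
true current state, `random_dir` first replaces bearing and distance by
uniform draws from [−180°, 180°] and [0, 100] mm. The scalar rate for
`random_rate` is the occupancy-weighted mean (identical to the overall
turns-per-tracked-time rate); whether a grand mean over bearings was
intended instead is not documented — the occupancy-weighted choice is
used because it preserves the overall event count.

A trial is 13 larvae over 5 min started in the 45 × 8.5 mm start zone
with uniform random headings (the empirical start distribution and
initial headings are not documented; uniform sampling is the stand-in,
and `simulate_trial()` accepts an empirical start-position set).
Trials are then **fragmented** like the experimental data: frames with
midpoint radius > 67 mm or within 5 mm of another larva are discarded
and surviving episodes become independent track fragments. Experiments
summarize each trial by its filmed preference; per-trial child seeds
derive deterministically from the master seed, so trials are
reproducible and order-independent.

### Numerical choices

* The noise distribution on [−1.8°, +1.8°] is taken as uniform (only
  the interval is documented).
* "Head segment moved into the border" is operationalized as: proposed
  head endpoint at radius > 75 mm. If 100 redraws all fail (head-on
  approach at the wall), the larva holds its position for that step and
  adopts the proposal minimizing the head radius, preserving both the
  alignment behavior and the invariant that the midpoint never leaves
  the arena.
* Turn completion clamps the realized head–tail angle to exactly the
  drawn angle on the final step; discrete 0.0625 s steps would
  otherwise overshoot by up to 3.36°.
* $r\,\mathrm{dt}$ is clipped at 1 (and the event logged) to guard
  against pathological synthetic rates.
* If a bank subsample is empty, the distance window doubles once, then
  the distance constraint is dropped, then the full bank is used; every
  fallback is counted and reported. This matters only for small
  synthetic banks.
* Empirical rate maps are looked up by nearest cell; cells with no
  occupancy carry an explicit undefined flag (never a zero) and fall
  back to the policy's mean rate.

## The synthetic ground-truth generator

`generate_dataset()` closes the validation loop. It synthesizes
track-TSV-compatible trajectories from a deliberately low-dimensional
policy family — rate $r(\beta) = r_0 (1 - a \cos\beta)$ (for $a > 0$,
turning is rarer when heading toward the source, as in real larvae),
turn direction toward the source with probability $p$, magnitudes
uniform on 25–120°, constant run speed — so that every expectation has
a closed form or a brute-force integral (`ground_truth_summary()`,
computed by `stats::integrate`, independent of any simulation).

Two deliberate differences from the Markov simulator: the generator's
**runs are straight lines** (turn times drawn by thinning against the
bearing-dependent rate along the analytic path), and its **turns
reorient the body smoothly** at a finite angular speed (default 80 °/s)
with a head-angle excursion leading the turn. The minimal Markov model
snaps the tail into alignment at turn completion — adequate for
trajectory statistics, but physically undetectable by a
reorientation-speed trigger with a minimum duration. The generator
therefore emulates what the detector actually faces in tracker output,
and carries a sidecar of true events for sensitivity/precision scoring.
Like the real tracker, it does not record frames beyond the 67 mm
cutoff radius: tracks split into fragments there, and wall events
(forced turns back into the arena, whose direction still follows $p$
where geometrically possible) are excluded from the scored truth
because they are unobservable in the emulated data.

Optional stressors: Gaussian positional jitter (default off; 0.02 mm
is a realistic centroid noise level that keeps the induced
reorientation-speed noise well inside the hysteresis band) and
sub-threshold distractor wiggles — 10–15° sinusoidal head oscillations
during runs, straddling neither the 20° posture gate nor the 20°
orientation cutoff, which must produce zero false positives.

What the generator does **not** emulate: odor-plume physics (the
policy is driven by bearing and distance only, as in the model),
peristaltic speed fluctuations, posture beyond the three tracked
points, collisions between larvae, and curved or noisy run paths.
Passing tests on synthetic data therefore certify the pipeline's
internal consistency and its estimators' statistical behavior — not
robustness to every artifact of real video tracking.

## Parameter recovery and closure

Dish-level toward/away rates are biased estimators of the rate
modulation whenever bearing occupancy is non-uniform (larvae linger at
bearings where they turn less). `recover_policy_parameters()` therefore
estimates the modulation from the bearing-resolved **profile**, which
divides events by occupancy at each bearing and is occupancy-independent:
a cosine is fitted by least squares, and its amplitude corrected for the
known attenuation of a cosine under the ±30° boxcar,
$\mathrm{sinc} = \sin(\pi/6)/(\pi/6) \approx 0.955$. The toward-bias
$p$ is estimated as the fraction of turns whose direction sign matches
the pre-turn bearing sign — unlike the strict toward-proportion, this
is insensitive to overshoot past $\beta = 0$. The toward/away rate
ratio is reported as the mean profile rate over $|\beta| < 90^\circ$
divided by the mean over $|\beta| > 90^\circ$, directly comparable to
the uniform-bearing integral $(1 - 2a/\pi)/(1 + 2a/\pi)$.

The closure (self-consistency) check runs the profile machinery on
simulations driven by a known policy and compares against the policy's
smoothed rate curve. Because the policy rate is a run→turn hazard while
the dish-level denominator is all tracked time (which includes the
~4–5% of time spent turning at default rates), the closure computation
uses run-state occupancy as the denominator; the profile functions take
occupancy as an explicit argument for exactly this purpose. The
simultaneous deviation band is 4 SE across all 361 (strongly
correlated) grid points.

## Validation problem sizes

The test suite and the acceptance script use: 4 dishes × 13 larvae ×
300 s for detector recovery (several hundred implanted turns); 2 × 10 ×
300 s with distractors for the false-positive check; 200 trials × 13
larvae × 300 s per simulator mode for the null-preference and
mode-ablation checks; 20 dishes × 13 × 300 s (≈ 2,200 turns) for
parameter recovery; and 20 trials for closure. These sizes put the
Monte-Carlo error comfortably below the tolerances being asserted
(e.g. the null median preference is checked against ±0.05 with an SE
near 0.005) while keeping a full validation run around a minute.

## Known limitations

* Detection thresholds are surrogate values tuned for implanted-event
  recovery, not the original empirical tables; on real tracker output
  they are starting points, not drop-in constants.
* The posture gate uses head angle only; larvae that turn without a
  detectable head bend (rare, but possible at low frame rates) would be
  missed.
* Bearing-resolved rates use occupancy-time denominators; the
  alternative (track-count) convention would scale profiles where
  occupancy varies.
* The simulator has no head casts, no speed modulation and no
  interaction between larvae beyond post-hoc collision culling.
* The counted preference's neutral middle stripe applies to end-point
  counts only; the filmed preference is a pure midline split (the two
  scores answer slightly different questions near the midline).
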