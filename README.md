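# larvatax

Quantitative analysis and agent-based simulation of run-and-turn
chemotaxis in *Drosophila* larvae.

Larvae crawling in an odor gradient alternate straight **runs** with
reorienting **turns**, prepared by lateral **head casts**. Their
chemotactic performance is set by three decisions — how fast to run,
when to turn, and where to direct the turn — each of which can be
modulated by the innate or learned attractiveness of the odor.
`larvatax` is for behavioral neuroscientists and computational
ethologists who have multi-animal tracking tables (one row per animal
per frame: head, midpoint and tail coordinates at 16 Hz) and want to

1. **measure** those decisions: odor preference scores, run speed,
   bearing-resolved turn rates and turning-direction statistics;
2. **re-express** them as a generative two-state Markov model and
   simulate it, including ablation modes that randomize turn rate
   and/or turning direction to ask which modulation carries the
   preference;
3. **validate** the whole loop on synthetic trajectories with
   closed-form ground truth.

## The statistics at the core

With bearing β ∈ (−180°, 180°] the signed angle between heading and the
direction to the odor source (0° = toward) and T tracked time:

* preference (filmed) `PREF = (T_odor − T_no_odor) / T_total` ∈ [−1, 1];
  counted variant `(#odor − #no_odor) / #total` from end-point counts;
* turn rate `60 · Σ N_T / Σ T` (turns/min), overall, by bearing class
  (toward: |β| < 90°; away: |β| > 90°), and as pooled profiles/maps
  over β (1° grid, circular ±30° sliding filter) and β × distance
  (2° × 2 mm grid, ±30° × ±15 mm box filter);
* turn toward odor: `|β_after| < |β_before|` (strict), as per-dish
  proportions and a time × distance map;
* turns are detected by a Schmitt trigger on the body-axis
  reorientation speed (hysteresis 35/15 °/s) with a posture gate and
  the defining cutoff: only body-orientation changes > 20° count.

The simulator implements a two-state Markov process on a jointed
two-segment body (2 × 2.15 mm, dt = 0.0625 s): runs at constant speed
with ±1.8° per-step heading noise, transition to turning with
probability `r_turn(β, d)·dt`, turning angles drawn from a bank of
observed `(β, d, angle)` events within ±30°/±15 mm of the current
state, head pivoting at 53.7 °/s. Trials (13 larvae, 5 min, 150 mm
arena) are fragmented like tracker data (radius > 67 mm, pairwise
distance < 5 mm) before scoring.

## Worked example

Generate a synthetic experiment from a known policy (turn rate
modulation a = 0.5, toward-bias p = 0.7), fit it, recover the
parameters, and simulate from the fitted model:

```r
library(larvatax)

spec <- parametric_policy_spec(base_rate_per_min = 2, amplitude = 0.5,
                               toward_bias = 0.7)
syn <- generate_dataset(spec, n_dishes = 4, n_larvae = 13,
                        duration_s = 300, seed = 101)
fit <- fit_chemotaxis(syn$dataset)
fit
#> Chemotaxis fit [synthetic]
#>   4 dish(es), 437 turns, 440 head casts, 580 runs, 13804 s tracked
#>   median filmed preference 0.349; median run speed 0.99 mm/s
#>   overall turn rate 1.90/min (toward 1.35, away 2.46)

round(coef(fit), 3)
#>         pref_filmed      run_speed_mm_s   turn_rate_per_min rate_toward_per_min
#>               0.349               0.994               1.899               1.351
#>   rate_away_per_min         prop_toward
#>               2.457               0.686
```

The fitted larvae prefer the odor side (median PREF 0.349), turn about
half as often while heading toward the source as away (1.35 vs 2.46
turns/min — the a = 0.5 modulation), and direct ~69% of turns toward
it (the p = 0.7 bias). Recovery returns the generating parameters:

```r
est <- recover_policy_parameters(fit)
sprintf("a = %.3f (true 0.5), p = %.3f (true 0.7)", est$amplitude,
        est$toward_bias)
#> "a = 0.485 (true 0.5), p = 0.691 (true 0.7)"
```

`simulate()` builds the empirical policy (turn-rate map + turning-angle
bank + median run speed) from the fit and runs the Markov model:

```r
simulate(fit, nsim = 50, seed = 42)
#> Simulated chemotaxis experiment (realistic_rate+realistic_dir)
#>   50 trials; median filmed preference 0.316
#>   quartiles [0.183, 0.410]; 90% interval [0.066, 0.573]
```

The simulated preference (0.316) reproduces the analyzed one (0.349):
turn-rate and turning-direction modulation alone account for the
spatial preference. `plot(fit)` draws the rate and turning-angle
profiles; `predict(fit, bearing)` interpolates the fitted rate.

A command-line wrapper over the same functions lives in
`inst/cli/larvatax.R` (`synth`, `analyze`, `simulate`, `recover`
subcommands; see `?larvatax_cli`).

## Vignette

`vignettes/chemotaxis-analysis.Rmd` documents the detection method, the
Markov model and its numerical choices, what the synthetic generator
does and does not emulate, and the estimators used for parameter
recovery.
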