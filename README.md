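# tirfkin

Analysis of two-color single-molecule TIRF recordings of ligand binding to
surface-immobilized multimeric proteins — the kind of experiment in which a
green-tagged holoenzyme (e.g. a 12–14-subunit CaMKII assembly carrying one
Venus tag per subunit) is imaged together with a red-labelled ligand
(rhodamine-calmodulin) under alternating two-laser excitation on two
synchronized EMCCD cameras.

From interleaved camera stacks (or from the package's own virtual-movie
simulator) `tirfkin` computes, per diffraction-limited spot:

* **Subunit stoichiometry** `S` by stepwise-photobleaching counting in the
  green channel,
* **Ligand occupancy** `N(t)` and its population distribution (Poisson and
  two-Poisson mixture fits) from the red channel,
* **Binding kinetics**: up/down event frequencies `f_on`, `f_off`; signed
  residence times τ (signed by the entering transition, truncated at
  ±30 s); the decay rate `k_tau` of the |τ| distribution; its
  photobleaching-corrected value `k_tau_corr = k_tau − k_pb`; and the
  affinity index `A_i = [ligand]·k_tau/f_on`, a heuristic substitute for a
  dissociation constant,
* **Colocalization** as the peak of the 9×9 shifted Pearson
  cross-correlation matrix between channel projections (CC(G–R), CC(G–FRET),
  CC(R–FRET)).

The core detector is a four-pass step finder on per-spot intensity traces:
(1) a `b`-point running-average smooth, (2) a rolling-window first
derivative of length `a` with quality-indexed peak calling at threshold
`q`, (3) amplitude acceptance within one calibrated standard deviation of
integer multiples of the single-fluorophore step, and (4) level refinement
with a minimum 0.3 s dwell and an unequal-variance t-test between adjacent
levels. Preprocessing covers channel registration, deinterleaving,
spectral-leakage subtraction (default 10% of the green intensity),
rolling-ball uneven-field correction (radius 100 px), and dual-exponential
autofluorescence removal.

Everything user-facing takes and returns tibbles, pipes cleanly, and has
`tidy()`/`glance()`/`autoplot()` methods for fitted objects.

## Worked example

Simulate a holoenzyme-like virtual experiment (40 spots, S = 14, 30 nM
ligand, 40 s records) and run the full chain:

```r
library(tirfkin)

cfg <- sim_config(field_size_px = c(192, 192), n_frames = 400,
                  n_spots = 40, seed = 73)
res <- run_pipeline(cfg, tau_model = "single")
res
#> <pipeline_result> 41 spots analyzed, 442 steps; CC_G-R = 0.840

dplyr::select(res$kinetics, f_on, f_off, k_tau, k_tau_corr, a_i, n_intervals)
#> # A tibble: 1 × 6
#>     f_on f_off k_tau k_tau_corr         a_i n_intervals
#>    <dbl> <dbl> <dbl>      <dbl>       <dbl>       <int>
#> 1 0.0573 0.108 0.218      0.138 0.000000114         162

head(res$stoichiometry, 5)
#> # A tibble: 5 × 4
#>   spot_id s_camkii s_censored n_cam
#>     <int>    <int> <lgl>      <int>
#> 1       1       10 FALSE          2
#> 2       2        8 FALSE          3
#> 3       3       12 FALSE          3
#> 4       4        8 FALSE          5
#> 5       5        9 FALSE          2

glance(res$occupancy_fit)
#> # A tibble: 1 × 8
#>   model   lambda  mean    se     n gof_p   aic delta_aic_vs_single
#>   <chr>    <dbl> <dbl> <dbl> <int> <dbl> <dbl>               <dbl>
#> 1 poisson   2.71  2.71 0.237    41 0.303  149.                  NA
```

Reading the output: the detected green spots colocalize strongly with the
red channel (peak CC(G–R) = 0.84); step counting recovers ~8–12 of the 14
subunits per spot (a 20% dark-tag fraction plus the known ~2-subunit
counting undercount); the mean initial occupancy is 2.7 bound ligands per
holoenzyme and the occupancy histogram is consistent with a Poisson law
(goodness-of-fit p = 0.30), as expected for independent per-subunit
binding; `f_off` exceeds `f_on` because photobleaching adds loss events,
and `k_tau_corr` subtracts the ligand photobleaching hazard (0.08 s⁻¹ here)
from the apparent residence decay rate.

Individual stages are exported too — `simulate_movie()`, `deinterleave()`,
`estimate_leakage()`, `correct_uneven_field()`, `correct_autofluorescence()`,
`detect_spots()`, `extract_traces()`, `calibrate_step_distribution()`,
`find_steps()`, `count_bleach_steps()`, `residence_intervals()`,
`fit_tau()`, `fit_poisson()`, `fit_two_poisson()`, `cc_matrix()` — so any
step can be run standalone on the previous stage's output. See the methods
vignette (`vignettes/tirfkin-methods.Rmd`) for the model, parameter
defaults and numerical choices.

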