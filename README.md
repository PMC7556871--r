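# saltadyn

Quantitative analysis of saltatory cell migration, cellular energetics and
autophagic flux from time-lapse microscopy.

Migrating neuroblasts (e.g. in the rostral migratory stream) advance in a
stop-and-go pattern: migratory bursts near 110–120 µm/h intercalated with
stationary pauses. `saltadyn` implements the full quantitative chain used
to analyse such recordings:

- **tracks** — trajectory import (Imaris/TrackMate-style CSV with a column
  map) and kinematics: instantaneous speed `v_i = ‖p_{i+1} − p_i‖ / Δt_i`
  (µm/h), net displacement, path length.
- **phases** — segmentation of speed traces into migratory/stationary
  phases (moving-average smoothing + hysteresis at `v_on`/`v_off` with
  raw-speed boundary refinement), and the three standard migration
  metrics: distance of migration, percent migratory, migratory-phase
  speed.
- **ratiometry** — dual-excitation biosensor quantification (PercevalHR
  ATP/ADP, pHRed pH): ratio of channel means inside a cell mask after
  per-wavelength max projection, and the per-phase **charge**

  charge = ∫ (r(t) − r_base) dt / (t₁ − t₀),

  the baseline-relative area under the ratio curve divided by phase
  duration, with r_base the mean ratio over the movie's stationary frames.
- **puncta** — Laplacian-of-Gaussian spot detection on the RFP channel of
  a tandem RFP-GFP-LC3 reporter, secondary-channel classification
  (GFP → autophagosome, Lamp1 → autolysosome), autophagosome percentages
  (GFP⁺RFP⁺/RFP⁺), phase-resolved densities normalised to the first
  stationary phase, and kymographs.
- **profiles** — rolling-ball (50 px) + median (2 px) preprocessing and
  soma / 20-µm arc-length-bin intensity profiles of the leading process
  (first bin proximal, last distal).
- **statsrep** — unpaired two-sided t-test with F-test variance screening
  (Welch fallback), one-way ANOVA with Fisher LSD post hoc, mean ± SEM
  summaries with conventional significance stars.
- **synthio** — a synthetic-data generator (two-state saltatory
  trajectories, coupled biosensor traces, two-channel puncta scenes,
  leading-process images) with exported ground truth, so every stage is
  testable without microscope data.

## Worked example

```r
library(saltadyn)

sim <- simulate_trajectory(saltatory_params(seed = 42))
seg <- segment_phases(instantaneous_speed(sim$traj))
seg
#> <phase_segmentation> cell 'synth': 11 phases (5 migratory)
migration_metrics(sim$traj, seg)
#>   cell_id distance_um percent_migratory speed_migratory_um_h n_phases_mig
#> 1   synth    49.99001          49.16667             114.6689            5

en <- simulate_energy_trace(sim$truth$states, energy_params(seed = 7))
tr <- ratio_trace(en$trace$t, num = en$trace$num, den = en$trace$den)
phase_charge(tr, seg)[4:6, ]
#>   state t_start t_end duration        auc        charge flagged
#> 4   MIG     300   540      240 -0.7076457 -0.0029485239   FALSE
#> 5  STAT     540  1320      780  0.3562233  0.0004566966   FALSE
#> 6   MIG    1320  1470      150 -0.8304999 -0.0055366661   FALSE
```

The cell migrated 50 µm in the hour, spending 49% of it in five migratory
phases at a mean speed of 115 µm/h; the ATP/ADP charge is negative during
migratory phases (the ratio dips below the stationary baseline, here
−0.0029 and −0.0055 ratio units) and near zero during pauses.

An end-to-end synthetic experiment, from a YAML scenario:

```r
cfg <- read_scenario_config(system.file("extdata", "demo_scenario.yaml",
                                        package = "saltadyn"))
res <- run_scenario(cfg, out_dir = "demo_out")
res$migration_summary
```

or from the shell via the thin CLI wrapper:

```sh
exec/saltadyn run --config inst/extdata/demo_scenario.yaml --seed 1 --out demo_out
```

Each run writes per-stage CSVs plus a `manifest.json` recording the seed
and the complete parameter set; identical config + seed reproduces the
output files byte for byte.

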