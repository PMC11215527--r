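# motorforge

Quantitative analysis of microtubule-motor mechanics from three data
classes, built around the workflows used to characterize force-sensitive
dynein mutants:

* **Optical-trap force traces** — thermal calibration of trap stiffness
  from the Lorentzian power spectrum; stall detection in 250-Hz
  downsampled traces with the stall force defined as the mean force over
  the last 20% of a stall and the stall time as the dwell at ≥80% of the
  stall force; pooled force-probability histograms fit with three
  Gaussians and the unbound 0-pN peak subtracted; stall-time survival
  (1-CDF) fit with a double exponential; and force–velocity curves from
  200-point median-filtered traces via events in 1-pN bins centred on
  2–5 pN, with velocity `v = ΔF / (k Δt)` and negative-velocity events
  excluded.
* **TIRF kymograph tracks** — processive/static/diffusive classification
  with the ≥1.5 s binding and ≥500 nm travel rules (105-nm pixels),
  segment-based mean velocities, and run lengths.
* **MD trajectories of the dynein MTBD on tubulin** — microtubule
  principal axes (PA1 longitudinal, PA2 radial towards the A3295/W3395
  Cα anchors, PA3 tangential), signed per-frame MTBD angles and stalk
  angles relative to the long axis, Gaussian fits of angular histograms,
  per-residue RMSF with respect to the microtubule, and salt-bridge
  (≤4 Å), hydrogen-bond (≤3.5 Å, ≤30°) and hydrophobic (≤8 Å) contact
  occupancy.

A synthetic-data module generates every input class with programmed
ground truth — Langevin bead dynamics in a harmonic trap driven by a
motor with a linear force–velocity law `v(F) = v0 (1 − F/Fs)`,
drift/diffusion particle tracks, and rigid-body rotation trajectories —
so the full pipeline is testable end to end without external data.

## Worked example

Simulate a wild-type-like bead trace (stall force 4.3 pN, trap stiffness
0.06 pN/nm), detect stalls with the wild-type criteria (>2.5 pN,
>100 ms), and summarize:

```r
library(motorforge)
tr <- simulate_trap_trace(ddb_trap_params("wt", duration = 12, seed = 42),
                          label = "wt_demo")
tr
#> <trap_trace 'wt_demo'> 60000 samples at 5000 Hz (12.000 s), k = 0.06 pN/nm
#>   force: mean 2.846 pN, range [-1.921, 6.196] pN
#>   ground truth: 31 programmed intervals

ev <- detect_stalls(tr, stall_criteria("wt"))
head(ev[, c("start_s", "end_s", "stall_force_pN", "stall_time_s", "outcome")], 3)
#>   start_s end_s stall_force_pN stall_time_s outcome
#> 1   1.148 1.756       4.288136        0.516  detach
#> 2   1.968 2.524       4.259447        0.488  detach
#> 3   3.180 3.648       4.277914        0.420  detach

summarize_stalls(ev, "wt")
#>   construct mean_stall_force_pN      sem_pN n_stalls mean_stall_time_s
#> 1        wt             4.28166 0.008499638       10            0.6956
```

The detected stall forces cluster at the programmed 4.3 pN (the mean over
one 12-s trace is 4.28 ± 0.01 pN from 10 stalls), and each event carries
its stall time and outcome (`detach` = the bead snapped back to the trap
centre). Calibration works the same way:

```r
cal <- fit_lorentzian(power_spectrum(simulate_trap_trace(
  motor_trap_params(reattach_rate = 0, sample_rate = 50000,
                    duration = 20, seed = 1))),
  fit_band = c(20, 5000), drag = 1.68e-5)
cal
#> <calibration_result> fc = 565.9 Hz, D = 4.87e+05 nm^2/s, k = 0.05973 pN/nm (lorentzian)
```

The corner frequency of 566 Hz returns the programmed stiffness
(0.0597 vs 0.06 pN/nm). `run_pipeline(demo_config())` chains the whole
trap workflow for a wild-type-like and a mutant-like construct and
reports the stall-force reduction between them;
`inst/scripts/motorforge.R` exposes the same pipeline on the command
line with a YAML config.

See `vignette source in vignettes/motorforge-methods.Rmd` for the models,
parameter choices, and known limitations.

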