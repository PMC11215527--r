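---
title: "Models and methods behind motorforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind motorforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motorforge)
```

motorforge analyses three kinds of single-molecule and simulation data
produced in studies of cytoplasmic dynein mechanics: bead-force traces from
fixed optical traps, single-particle tracks from TIRF kymographs, and MD
trajectories of the microtubule-binding domain (MTBD) bound to tubulin.
This vignette explains the models behind each stage, the parameters that
matter, and the design decisions that were genuinely open.

## The trap-motor simulator

Every analysis stage can be exercised against synthetic data with known
ground truth. The bead model is an overdamped Langevin equation for the
bead coordinate $x$ (nm, displacement from trap centre),

$$\gamma\,\dot x = -k\,(x - m) + \sqrt{2 k_B T \gamma}\;\xi(t),$$

where $k$ is the trap stiffness, $\gamma$ the bead drag, and $m$ the motor
attachment coordinate. The motor obeys a linear force-velocity law
$v(F) = v_0 (1 - F/F_s)$, clipped to $[0, v_0]$ — the simplest law with a
well-defined stall force $F_s$, which is all that recovery testing of the
detector requires. The motor-bead linkage is rigid (bead force = trap
force = motor load); linkage compliance is never modelled in the analysis
either, so the simulator does not pretend to resolve it.

Three choices deserve comment:

* **Integration and decimation.** A fixed Euler-Maruyama step of
  $2\times10^{-6}$ s sits more than 100-fold below the bead relaxation time
  $\gamma/k \approx 0.28$ ms at the default $k = 0.06$ pN/nm and
  $\gamma = 1.68\times10^{-5}$ pN s/nm (a 1-µm-radius bead in water; drag
  and temperature are configurable because they are instrument properties,
  with $k_BT = 4.114$ pN nm at 298 K). Decimation to the recording rate
  uses non-overlapping block means, emulating detector anti-alias
  filtering. Block averaging attenuates variance once the sample interval
  approaches $\gamma/k$: at 5 kHz the recorded force variance is ~80% of
  $k\,k_BT$, at 50 kHz ~98%. Calibration-grade traces are therefore
  generated at 50 kHz, mirroring the practice of recording calibration
  scans at full detector bandwidth.
* **Quasi-static motor load.** The motor's stepping rate responds to
  $k\,m$, not to the instantaneous noisy bead force. Driving $v(F)$ with
  the noisy force turns $m$ into a ratchet (only forward force excursions
  move it, since $v$ is clipped at zero) and biases recovered stall forces
  upward by an amount that depends on the dwell time. Physically, stepping
  kinetics average over bead fluctuations that decorrelate in ~0.3 ms.
* **Stall entry.** The linear law approaches $F_s$ only asymptotically, so
  the simulator enters an explicit stall state — motor frozen, detachment
  after an exponential dwell with rate `detach_rate_at_stall`, then the
  bead snaps back to the trap centre — once $k\,m$ reaches 99.5% of
  $F_s$. This leaves a deliberate, known bias of $-0.005\,F_s$
  (~0.02 pN) in the programmed stall force, far inside the ±0.1 pN
  recovery band used throughout.

Mutant-like behaviour adds a force-gated pause channel: while moving, the
motor pauses with hazard `pause_entry_rate * min(F/F_s, 1)`; a pause ends
with rate `pause_exit_rate` (default 12 /s, mean ~83 ms — visible at
250 Hz yet mostly shorter than the 150-ms mutant stall criterion), upon
which the motor detaches with probability `pause_exit_detach_prob` or
resumes. The defaults make pause-then-detach contamination of stall
statistics a <1% effect, consistent with pauses being transient
interruptions rather than terminal stalls.

The generator emulates thermal bead noise, motor stepping, pausing,
detachment and rebinding. It does **not** emulate trap anharmonicity, bead
rotation, linkage compliance, slow drift, or step-scale discreteness, so
green recovery tests demonstrate correctness of the analysis pipeline
under the stated model, not robustness to every artefact of real traces.

## Trap calibration

`power_spectrum()` computes a one-sided, segment-averaged periodogram
(Welch-style, non-overlapping rectangular segments, default $2^{13}$
samples) of the bead position $x = F/k$; `fit_lorentzian()` fits

$$S(f) = \frac{D}{2\pi^2 (f_c^2 + f^2)}$$

in log-density space with uniform weights, which keeps the dense
high-frequency bins from dominating the fit. Stiffness follows from the
corner frequency as $k = 2\pi\gamma f_c$ when the drag is supplied, with
the equipartition estimate $k = k_BT/\mathrm{var}(x)$ as an independent
cross-check (the two agree within a few percent on 20-s traces). The
amplitude convention above is two-sided, so on a one-sided spectrum the
fitted $D$ is about twice $k_BT/\gamma$; $f_c$ and the stiffness are
unaffected. No estimator or fit band is canonical for this measurement;
both are exposed as configuration with the defaults stated here.

## Stall detection and statistics

Traces are downsampled to 250 Hz by block means. A stall event is a
maximal interval with force above `min_force` and a centred rolling SD
within `stationarity_sd_max` over `stationarity_window`, lasting longer
than `min_duration`. The presets encode the two published criteria sets:
wild type >2.5 pN / >100 ms, mutant >1 pN / >150 ms. "Stationary" has no
published operational definition; the rolling-SD bound (default 0.35 pN
over 40 ms) sits between the post-downsampling thermal noise floor
(~0.19 pN SD at the default stiffness) and genuine motion. In place of
the original manual review of every event, `detect_stalls(qc = TRUE)`
flags borderline events (force or duration within 10% of threshold) for
inspection.

Per event, the **stall force** is the mean force over the last 20% of the
event and the **stall time** is the dwell at or above 80% of that stall
force. Whether the dwell is the contiguous run ending at detachment or the
total supra-threshold time is not specified anywhere; the contiguous run
is the default because the defining signature of a stall is the
detachment snap that ends it, and the total-time variant is available via
`method = "total"`. Event outcomes are `detach` (force drops by
`snap_drop_fraction` of the stall force shortly after the event — the
snap lookahead extends one stationarity window beyond the event because
the rolling-SD guard trims event edges by half a window), `resume`, or
`censored`; only detachment-terminated events enter stall statistics,
since a censored stall has no observed end and a resume event lacks the
snap that defines a stall.

Population statistics follow the published workflow: pooled
force-probability histograms (default 0.2-pN bins; no published width) fit
with a sum of three Gaussians by nonlinear least squares — curve fitting,
not EM, with deterministic initialization at the three largest smoothed
local maxima — after which the component nearest 0 pN (the unbound bead)
is subtracted bin-wise, floored at zero and not renormalized. Stall-time
survival is the empirical 1-CDF evaluated at the event times (no binning,
uniform weights) fit to $A e^{-t/\tau_f} + (1-A) e^{-t/\tau_s}$, with SEMs
from the fit covariance.

## Force-velocity analysis

Traces at the 5-kHz recording rate are median-filtered with a 200-point
window (odd-adjusted; runmed with truncated end windows), then maximal
runs inside half-open 1-pN bins centred on 2, 3, 4 and 5 pN are
extracted. The published velocity conversion divides the force change by
the spring constant; dimensional consistency additionally requires the
event duration, so the implemented estimator is

$$v = \frac{\Delta F}{k\,\Delta t},$$

the only reading that yields nm/s. Events with negative velocity are
discarded (detachments, not motor-driven motion); zero-velocity events are
kept. Events shorter than `min_event_samples` (default 25, i.e. 5 ms) are
dropped to suppress single-crossing noise events. Concatenated recordings
are processed per trace and pooled afterwards, so no event spans a
concatenation joint. Bin boundary membership uses $[c - 0.5, c + 0.5)$;
no boundary convention is published.

## Track classification

Kymograph counting rules are threshold-inclusive as printed: binding
events of at least 1.5 s are counted, and travel of at least 500 nm is
processive (105-nm pixels). Processivity is decided by the best *forward
run*: the largest displacement accumulated while the position never drops
more than `segment_tolerance` (default 50 nm, about half a pixel) below
its running maximum. A pure drawup criterion was rejected because for
driftless Brownian motion the maximum drawup is a roughly fixed fraction
(~0.5-0.8) of the positional range, while the 500/250-nm threshold pair
demands a ratio of 2 — no diffusion coefficient can then separate
diffusive tracks from both the static and the processive class. Even with
the forward-run rule a Brownian path that happens to climb 500 nm without
backtracking is *observationally* processive; with the cohort defaults
(D = 1,000 nm²/s, characteristic of lattice diffusion) this residual
ambiguity affects well under 1% of tracks.

Remaining tracks are static when their total range stays within 250 nm —
sub-2.5-pixel wander indistinguishable from localization noise — else
diffusive; the published rules give no static/diffusive split, so this
threshold is this package's choice. Velocities come from bottom-up
piecewise-linear segmentation (merge while the per-segment RMS residual
stays within 50 nm), replacing the original manual multi-point tracking;
the track mean velocity is the unweighted mean over segments, which
matches the segment-based convention and differs from net displacement
over total time whenever phase durations are unequal. Run length is net
displacement (first to last point); total path length is available by
flag, since the published figures do not disambiguate the two.

## MD geometry

The microtubule frame is built from the tubulin body: origin at its
centre of mass, PA1 the smallest-inertia (protofilament) axis with its
sign fixed by a reference structure, PA2 the component of the vector to
the dynein anchor centre (Cα of A3295/W3395) orthogonal to PA1, and
PA3 = PA1 × PA2. The MTBD vector runs from that anchor centre to the Cα
centre of A3288/Y3402. Two readings of the projection plane are possible
— the stated plane spanned by PA1 and PA2 versus the stated goal of
angles in the plane perpendicular to the long axis — so the plane is an
explicit option: the default `PA2PA3` implements the perpendicular-plane
reading (tilting *around* PA1 is only visible there), and the literal
`PA1PA2` reading is available. The sign convention is stated in code and
output: positive ("clockwise") is rotation from PA2 towards +PA3 viewed
down +PA1. Peaks are reported relative to an explicit `reference_zero`,
implementing the convention that the wild-type peak defines zero.

The stalk tip (R3191/S3501) lies outside the simulated fragment, so a
full-length structure is superposed onto each frame via stalk-base Cα
atoms (Kabsch superposition with a proper rotation enforced; frames whose
alignment RMSD exceeds a threshold are flagged) and the stalk angle is
the unsigned angle between the stalk vector and PA1 — the longitudinal
axis itself, which is the natural reading of "relative to the
longitudinal axis". RMSF aligns every frame to the reference on the
tubulin selection and reports per-residue fluctuations; region-restricted
comparisons (e.g. an H3-to-CC2 subrange) take a user-supplied residue
selection because region names do not fix residue bounds. Angular
histogram fits reuse the deterministic Gaussian least-squares machinery.

Angle operations are exact to 1e-6 degrees on noiseless rigid rotations,
and all geometry is equivariant under a global rotation of every frame
plus the reference; both properties are enforced by tests. The synthetic
reference (`demo_mtbd_reference()`) is a labelled, fully synthetic
stand-in — a symmetrized prolate cloud whose inertia axes are exact by
construction, carrying the real anchor residue numbers — not a deposited
structure.

## MD contacts

Interaction criteria are fixed distance/angle cutoffs, all inclusive at
the boundary: salt bridges at ≤4 Å between basic nitrogens (Lys NZ, Arg
NE/NH1/NH2, His ND1/NE2 — histidine counts as basic by default because
the criterion names "basic nitrogen" without enumerating, and a flag
excludes it) and acidic oxygens (Asp OD1/OD2, Glu OE1/OE2, terminal OXT);
hydrophobic contacts at ≤8 Å between side-chain carbons (backbone C and
CA excluded); hydrogen bonds at ≤3.5 Å donor-acceptor with the
H-donor-acceptor angle ≤30°. Hydrogens must be explicit — all-atom
trajectories carry them — and are never inferred. Because "percent of
simulations" can mean frames or trajectories, `contact_occupancy()`
reports both the pooled per-frame fraction and the per-trajectory
fractions.

## Problem sizes and numerics

The recovery suites run at sizes chosen to make Monte-Carlo error small
against each tolerance while keeping the full suite fast on one CPU: 150
traces of 12 s per construct for the stall-force contrast (>1,000 events
per arm, SEM ≈ 0.005 pN against a ±0.1 pN band), 50 seeds of 20-s traces
for calibration, 500 events per survival fit, 5,000 angle samples per
histogram fit, 10,000 frames for the RMSF closed form, and 1,000
randomized frames against brute-force contact oracles. Fits use
Levenberg-Marquardt least squares with deterministic initialization
throughout, so every fit is reproducible without a seed; degenerate
inputs (constant spectra, identical dwell times, collapsed mixture modes,
collinear selections, near-spherical inertia) raise errors or warnings
rather than returning silently clamped values.

## Known limitations

The simulator's linear force-velocity law and single-rate detachment are
deliberately minimal; recovered contrasts test the analysis chain, not
motor biophysics. Classification of genuinely ambiguous Brownian tracks
is irreducibly uncertain at the stated thresholds. The calibration stage
omits aliasing and hydrodynamic corrections to the Lorentzian. Contact
detection is geometric only — no energies, no water-mediated bridges —
and the stalk coiled-coil registry is not analysed.
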