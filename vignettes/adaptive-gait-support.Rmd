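---
title: "Assist-as-needed gait training: the controller, the synthetic cohort, and the analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assist-as-needed gait training: the controller, the synthetic cohort, and the analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptgait)
```

## The problem

Robot-assisted treadmill training with a gait exoskeleton conventionally uses
a *guidance force*: a normalized joint impedance, constant over the gait
cycle, that the therapist sets manually. An assist-as-needed alternative
adapts the normalized stiffness `K` and damping `B` of the robotic hip and
knee joints automatically, separately in 30 windows of the gait cycle,
based on how well the patient tracks a reference trajectory. Two research
questions hang off such a controller: does it reach *lower* support levels
than therapists choose (training value), and are the support levels it
settles at *valid and reliable markers* of walking ability (assessment
value)?

`adaptgait` implements the controller, a synthetic patient cohort and study
simulator, the per-session feature extraction, and the statistical analyses
those questions require, all at desk scale. Clinical recordings of such
studies are not publicly deposited, so the synthetic cohort is a first-class
module: it generates data with the statistical structure the analyses
assume, which makes every stage of the pipeline testable against known
ground truth.

## The adaptation law

In every gait cycle $s$ and window $w$, the controller updates the active
leg's impedance as

$$K_{s+1,w} = \gamma_1\,K_{s,w} + g_1\, f_1(e)_{s,w}, \qquad
  B_{s+1,w} = \gamma_2\,B_{s,w} + g_2\, f_2(\dot e)_{s,w},$$

with the result clamped into $[K_{\min}, 1]$. The error metric is the
deadband-clipped, scaled mean absolute deviation within the window:
$f = \max(0, \bar{|e|} - d)/e_{\text{scale}}$. Support starts at 100%,
decays exponentially (factor $\gamma < 1$ per cycle) while the patient
tracks within the deadband, and rises quickly when deviations grow. A 4%
floor is never undercut.

The published description of the device leaves the exact error metric and
the constants $\gamma_i, g_i$ to an earlier engineering reference that does
not print them either. We therefore chose a clipped-linear error metric and
defaults $\gamma_1 = \gamma_2 = 0.95$ per cycle, $g_1 = g_2 = 0.5$,
deadband $4^\circ$, error scale $10^\circ$ (velocity: $20^\circ/s$ and
$50^\circ/s$). This reproduces the documented qualitative behaviour —
exponential decay toward a patient-specific plateau, fast recovery after
large errors — while staying analytically tractable: with the linear
tracking model below, the stiffness plateau has the closed form

$$K^\* = \frac{g\,(c - d)}{e_{\text{scale}}(1-\gamma) + g\,c},$$

valid while the plateau deviation $c(1-K^\*)$ still exceeds the deadband;
otherwise support decays to the floor. Two exact oracles fall out of this
and anchor the test suite: a perfectly tracking patient gives
$K_s = \max(0.04,\ 0.95^s)$ (the floor is reached by the update after cycle
63), and a deterministic patient with uniform impairment $c = 20^\circ$
plateaus at $8/10.5 \approx 0.762$.

```{r}
fixed_point_stiffness(20)
blk <- run_adaptive_block(patient_profile(0), duration_min = 2,
                          keep_deviation = FALSE)
blk$final_k[1, 1] # floor reached
```

## Gait geometry

The reference trajectories are smooth two-harmonic curves per joint,
rescaled so the peak-to-peak excursion equals the configured range of
motion exactly; knee flexion peaks in mid swing, hip flexion near terminal
swing. The device's proprietary trajectory shape is not published, and none
of the analyses depend on it — only deviations from the reference matter.
Default cadence is 40 cycles/min, i.e. 200 cycles per 5-minute adaptive
block, comfortably past the decay plateau.

The cycle is divided into 30 equal windows (impedance adaptation) and into
four subphases (analysis): stance 62.5%, initial swing 10.5%, mid swing
14%, terminal swing 13%. The three swing fractions are the study's
published values; stance is their complement, which makes the four
fractions sum to one exactly. Stance is never analyzed — tracking there is
dominated by body-weight support and ground contact. A window that
straddles a subphase boundary belongs to the subphase covering the majority
of its width (ties to the earlier subphase), so the window-to-subphase map
is a deterministic total function; samples inherit the subphase of their
window, which also makes the extracted features independent of the log
sampling rate.

## The synthetic cohort

Each patient carries a latent ability score drawn uniformly on
(0.05, 0.95). Patients above 0.45 are ambulatory (can perform overground
walking tests); the rest are not, and their walking outcomes are absent, as
in realistic neurorehabilitation cohorts. The tracking impairment — the
mean absolute deviation a patient would show at zero support — is

$$c = c_{\max}\,(1 - \text{ability}) \cdot w(\text{subphase}) \cdot
  \text{joint factor} \cdot \text{jitter} \cdot \text{asymmetry},$$

and the cycle-level tracking model is $e = c\,(1-K)(1+\eta)$, truncated at
zero: deviations vanish under full support and grow as support is removed.
Velocity deviations are proportional to position deviations with their own
per-joint/subphase factors, so the damping features carry independent
information.

Choices worth spelling out:

* **Initial swing is the hardest subphase** (weight 1 versus 0.45/0.55 for
  mid/terminal swing and 0.3 for stance; hip impairment half the knee's).
  Initial swing is where foot clearance is generated, and it is the
  subphase clinical analyses single out.
* **The knee initial-swing impairment is jitter-free**; every other
  (joint, subphase) pair gets independent log-normal jitter (SD 0.25).
  The knee-IS plateau *defines* the severity axis that the walking
  outcomes are coupled to; the jitter on the remaining 11 variables keeps
  them from being collinear copies of it, which is exactly the structure
  the variable-selection analyses need to have any chance of isolating the
  true driver. `c_max = 13` degrees, together with a 6.5° ceiling on the
  ambulatory knee-IS impairment (an ambulatory patient, by definition,
  achieves foot clearance), places ambulatory knee-IS plateaus in roughly
  the 4–35% band, the range over which the linear outcome coupling stays
  physiological. Left–right asymmetry *redistributes* impairment between
  the legs (one leg scaled by the square root of the asymmetry ratio, the
  other by its inverse) without changing overall severity.
* **Variability is split by timescale**: a session-level multiplicative
  factor (SD 0.08) shifts a whole session's impairment — this is what
  test-retest reliability sees — while cycle-level noise (SD 0.04) jitters
  individual cycles. Body-weight-support differences between sessions are
  not modelled mechanically; they are absorbed into the session-level term.
* **Force capacity** rises linearly with ability (0.85 Nm/kg at ability 1,
  additive noise SD 0.03), independently of the impairment jitter. With
  the ambulatory threshold at 0.45 this keeps non-ambulatory normalized
  force below the clinical 0.4 Nm/kg mark. Among non-ambulatory patients,
  20% are sampled as a "regained control, persistent weakness" subtype
  (impairment scaled by 0.25, force unchanged) so the weak-but-low-support
  cluster of the force-versus-control plane is populated.
* **The simulated therapist is conservative**: the conventional guidance
  force is the patient's worst-window analytic plateau plus a 0.15 safety
  margin (capped at 1, small session-to-session drift). That mirrors
  clinical practice, where the guidance force can only be lowered as far
  as the weakest gait phase allows, and it guarantees — by construction,
  in expectation — that adaptive training reaches lower mean support.
* **Walking outcomes** are coupled to the patient's *current* simulated
  knee-IS plateau $k$ (percent): speed $= 1.9 - 0.04\,k + \varepsilon$
  (SD 0.15 m/s, floored at 0.05 m/s), TUG time $= 12 + 3.38\,k +
  \varepsilon'$ (SD 10 s). The slopes are the generator's ground truth;
  the intercepts and noise SDs are calibrated so that speeds stay positive
  over the attainable plateau range (the floor essentially never binds —
  a binding floor censors the linear coupling and biases its recovery)
  and the cross-sectional association is strong but noisy, in the spirit
  of the moderate coefficients of determination such cohorts report. The 10-m walk test produces two run times per
  assessment (speed = 10 m / mean run time); isometric torques are force
  capacity × body weight with per-movement jitter, normalized back to body
  weight and averaged over four movements at analysis time.
* **Schedule**: eight weeks, at least eight training sessions (a 40%
  chance of up to eight extra), each session warm-up → adaptive left (5
  min) → adaptive right (5 min) → conventional training; assessments in
  weeks 1, 5 and 8 attach to the nearest training session. A slow
  per-patient improvement trend (mean 1% of impairment per session, SD
  1.5%, sign free) makes first-to-last changes heterogeneous, as seen in
  practice.

What the generator does **not** emulate: disease-specific progression,
spasticity dynamics, stance-phase mechanics, pelvis kinematics,
body-weight-support physics, gait-event detection (cycle boundaries are
simulator-annotated), and any cognitive or quality-of-life instruments
(their scores are stored, never modelled). Tests passing on this generator
therefore validate the *pipeline* — controller arithmetic, feature
extraction, statistical machinery — under a favourable, known-structure
world; they do not certify the clinical findings themselves.

## Feature extraction

Per adaptive block and leg: (1) per-cycle means of stiffness and damping in
each swing subphase for hip and knee (12 series); (2) the first minute is
discarded — support starts at 100% and needs that long to decay to a level
the patient can influence; (3) an exponential decay $y = A e^{-\lambda s} +
C$ ($A, \lambda \ge 0$) is fitted per series; (4) the feature is the fitted
plateau $C$ when a plateau is detected, otherwise the mean of the last 4
minutes of the block.

The fit uses variable projection: for each candidate rate the amplitude and
plateau are solved in closed form, the rate is found by a deterministic
grid search refined with one-dimensional optimization. This cannot fail to
converge (flat, noisy and non-decaying series are all well-defined), which
matters because the fit runs thousands of times per study; it is
cross-checked against an independent Levenberg–Marquardt fit in the test
suite. "Plateau detected" means the series spans at least three time
constants of the fitted rate (≈95% settled) *and* the fit RMSE is at most
0.05 — the fallback rule needs an operational criterion, and none is
published; both thresholds are configurable. The decay abscissa is the
cycle index, and the "last 4 minutes" are wall time mapped to cycles
through the cadence.

Features are stored as fractions and reported as percentages at every I/O
boundary. Left and right legs are averaged element-wise into the 6 + 6
stiffness/damping variables the clinical analyses use; a missing leg
propagates the available one with a warning.

## Statistical pipeline

* **Training value**: per patient, mean adaptive support (hip + knee, both
  legs, post-transient cycles) versus mean conventional guidance; paired
  two-sided t-test with a Shapiro–Wilk normality check reported alongside
  (not gating — the check is descriptive, the test is the analysis).
  Identical differences are flagged as degenerate rather than producing a
  p-value.
* **Validity**: forward selection over the 12 leg-averaged variables
  (entry at p < 0.05, no multiplicity correction — the ~46% per-dataset
  false-entry rate of twelve uncorrected candidates is demonstrated in the
  null-calibration test rather than "fixed"), run separately for walking
  speed and TUG; only patients with complete walking tests enter.
  Stability is probed with a repeated cross-validated elastic net (L1
  share 0.75, 3 folds, penalty at the CV minimum, 100 repetitions with
  fresh fold assignments) and reported as per-variable selection
  frequency. Constant candidates are excluded from the penalized fit.
* **Reliability**: per patient, the two sessions closest in time in the
  second half of the study period (minimal gap, ties to the earlier pair);
  Spearman's rho for relative reliability, Bland–Altman bias ±
  1.96·SD(differences) for absolute agreement. The limits are expressed as
  a percentage of the mean of the data; published reports are ambiguous
  about whether that percentage refers to the half- or full width, so both
  are returned.
* **Force versus control**: deterministic quadrant assignment of (mean
  normalized isometric force, knee-IS stiffness) at 0.4 Nm/kg and 30%
  (boundaries to the high side; the stiffness threshold is not published —
  30% visually separates the expected clusters and is configurable), plus
  per-leg linear regressions of stiffness on force.
* **Longitudinal change** is deliberately descriptive: per-session
  trajectories and the first-to-last change of the leg-averaged knee-IS
  stiffness, with no inferential model — the study design (heterogeneous
  diagnoses, n = 10) does not support one.
* **10-m walk conversion**: run times are averaged first, then converted
  (speed = 10 / mean time). Averaging speeds instead would weight the
  faster run more; with two runs a few percent apart the difference is
  negligible, but a convention had to be fixed.

## Numerical and degenerate-input conventions

Clamping happens after the affine update, never before. Cycle indices are
1-based in tables; window indices are 0-based (they name grid cells, not
observations). `fit_decay` requires ten points; shorter series trigger the
fallback. Constant series fit with amplitude ≈ 0 and are served by either
branch identically. Logs must have exactly uniform timestamps per phase and
leg, verified on read. All randomness flows through explicit seeds; a study
object is bit-reproducible from its seed.

## Problem sizes

Desk-scale defaults keep every stage fast: 10-patient studies simulate in a
few seconds (the per-cycle controller loop is vectorized over all windows
and joints); the replicated parameter-recovery analysis in the acceptance
suite uses 100 studies of 20 patients × 8 sessions with features extracted
for assessment-linked sessions, a few minutes on one CPU. Full 4-ms session
logs are rendered on demand from the per-cycle arrays rather than stored,
which is what makes hundred-study replication tractable; the extracted
features are invariant to the rendering rate, which the suite verifies.

## Known limitations

The controller constants are plausible stand-ins, not the device's; all
quantitative conclusions are therefore about the *class* of controller, not
the commercial implementation. The tracking model is linear in (1 − K)
with multiplicative noise — real patients saturate, fatigue and co-contract.
The plateau-existence criterion is a declared operationalization. Clinical
couplings are linear with Gaussian noise; floor/ceiling effects of real
outcome measures are not modelled beyond the hard speed floor. The
force-versus-control clustering is a fixed-threshold rule, not a learned
partition.
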