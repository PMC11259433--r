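---
title: "Modeling myelin dystrophy from axon biophysics to working memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling myelin dystrophy from axon biophysics to working memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Cortical aging (and several demyelinating diseases) degrades myelin:
sheaths split and balloon, some internodes lose their lamellae entirely,
and remyelination replaces single long internodes with pairs of shorter,
thinner ones. `myelinwm` implements a two-level model of how such changes
could impair spatial working memory: a biophysical double-cable model of a
myelinated cortical axon quantifies how demyelination and remyelination
change conduction velocity (CV) and cause action-potential (AP)
transmission failures, and a 20,000-neuron spiking ring-attractor network
performing a delayed response task (DRT) translates those per-neuron
failure probabilities into working-memory performance. This vignette
documents the models, their assumptions, the tunable parameters, the
numerical choices, and what the shipped tests do and do not establish.

## The axon model

### Architecture

One model neuron is a chain: a cylindrical soma standing in for the whole
somatodendritic tree, an axon hillock (5 compartments) and initial segment
(5 compartments), and then 101 nodes of Ranvier (13 compartments each)
alternating with 100 myelinated segments. Each myelinated segment has, in
order, four paranodes (5 compartments each), a juxtaparanode (5), an
internode (9), a juxtaparanode (5), and four more paranodes (5), for 59
compartments per segment. Paranode and juxtaparanode lengths are fixed
(2.3 and 5 um per structure, rescaled proportionally in very short
segments so the internode keeps at least 20% of the segment); the
internode takes the remainder.

Myelinated compartments are double-cable: the axolemma faces a periaxonal
space, which connects axially along the segment and drains to the bath
through the myelin sheath (radial resistance `n_lamellae * r_lam`,
capacitance `c_lam / n_lamellae`: lamellae stack in series) and through a
paranodal tight-junction seal at each sheath end (resistance
`rho_tj * n_lamellae / (pi * d)`, growing with the spiral mesaxon path and
shrinking with seal circumference). Nodes, hillock, and initial segment
carry NaF and KDR channels plus leak; paranodes, juxtaparanodes, and
internodes carry leak only. Fully demyelinated ("bare") segments lose the
periaxonal layer altogether, exposing passive axolemma to the bath — the
loss of insulation, not a change in channels, is what degrades conduction.

### Channel kinetics and the AP source

Channel kinetics are Wang–Buzsak&iacute;-style NaF/KDR rate functions. Two
deliberate departures from the textbook form were needed and are exposed
as constants:

* **Nodal NaF activation is a gating state** (not instantaneous) with a
  rate factor `phi_m = 2.5`. The nodal upstroke speed is the main
  determinant of saltatory CV in thin fibers; with instantaneous
  activation the model conducts at 3–5 m/s, far above the 0.3–0.8 m/s
  band measured for thin cortical axons. The slower upstroke trades off
  against nodal NaF density (`gbar_naf_node = 6 S/cm^2` reference) and
  the per-lamella capacitance (`c_lam = 2.2 uF/cm^2`), which together
  set both the CV scale and the conduction safety margin.
* **The somatic KDR deactivates slowly** (`phi_n_source = 0.15`),
  producing spike-frequency adaptation. Without it the source's
  rate–current curve near rheobase is so steep that the 13–16 Hz
  selection band at +380 pA becomes a measure-zero target; the reference
  somatodendritic model achieves the same flattening with its slow
  potassium currents. Nodal KDR is fast (`phi_gate = 5`) and dense enough
  (`gbar_kdr_node = 1.2 S/cm^2` reference) that nodes have a unique
  resting state — with weaker nodal KDR the sodium window current makes
  distal nodes bistable, and a soma sitting near threshold between spikes
  latches the whole axon into a depolarized plateau that blocks every AP
  after the first.

All electrical constants live in `axon_constants()` with per-value
provenance tags and are overridable. They were calibrated once, against
the selection criteria that define a plausible control neuron (13–16 Hz at
+380 pA, silence at 0 pA, CV in 0.3–0.8 m/s, saltatory conduction:
suprathreshold nodes, subthreshold internodes), and then frozen; the
calibration reference point is the mid-range axon
(`axon_spec(0.76, 1.1, 120, 12, 0.016, 0.55, 0.55, 0.55)`), which fires at
14 Hz with CV 0.82 m/s and no failures (just above the top of the
selection band — accepted cohort members sit at 0.57–0.69 m/s at the
shipped test scale).

### Numerics

The coupled two-layer cable is integrated implicitly: states are ordered
along the cable with each periaxonal potential interleaved after its
axolemma potential, making the linear system pentadiagonal; a
Crank–Nicolson-style theta scheme (theta = 0.5 by default, 1 for pure
backward Euler) with per-step channel linearization and
exact-exponential gating updates is solved by an unpivoted banded LU (the
matrix is weakly diagonally dominant by construction). The time step is
fixed at 0.025 ms; refining it tenfold changes CV by under 2% (tested).
The holding state is found by a pinned-soma steady-state solve (the
somatic potential is constrained to −70 mV and the holding current becomes
the unknown in that row), which replaces an iterative bisection and is
exact to the solver tolerance. Simulations abort with a diagnostic if any
potential passes ±250 mV.

Spikes are upward crossings of 0 mV (configurable) with sub-step linear
interpolation. CV is distance/median-latency over matched AP pairs
(window 0–50 ms) between the first node after the initial segment and the
penultimate node; unmatched proximal APs are failures. The matching is
*anchored* nearest-latency: every pairwise latency in the window is tried
as a candidate conduction latency, proximal spikes greedily take the
unused distal spike closest to the anchor, and the accepted matching has
the most pairs, then the tightest median deviation from its anchor
(quantized to 0.1 ms), with remaining ties broken by closeness to the
latency of the first observed pair — the first distal spike precedes
every possible echo, so it is the one uncontaminated observation of the
conduction time. This matters because distal trains are not one-to-one
with proximal ones: control axons fire a short-interval doublet at the
penultimate node for each conducted AP (a local echo off the sealed
terminal), and some heavily perturbed axons sustain re-excitation at
demyelinated boundaries that multiplies the distal train several-fold.
The anchored matcher reads through both and reports the first-arrival
conduction latency. Each protocol run
extends 60 ms past the step so in-flight APs reach the distal probe
rather than being counted as spurious failures.

### Cohort, perturbations, grids

`sample_axon_lhs()` draws a maximin Latin hypercube over the eight
parameter ranges; `screen_axon_candidates()` applies the four selection
criteria (optionally pre-screening with a 0.4 s conduction check that can
only reject models the full 2 s protocol would also reject);
`select_models()` takes a seeded random subset when more models pass than
needed. Demyelination removes `round(n * fraction)` lamellae (half-up
ties) from seeded random segment lists shared across removal levels and
axons within a trial; remyelination replaces a stride-selected subset of
the demyelinated segments (generalizing the every-alternate rule) with two
half-length children and a new standard node. `run_demyelination_grid()`
and `run_remyelination_grid()` cross the perturbation factors over trials
and axons into tidy tables; `cv_change()`, `cv_recovery()` and
`ap_failure_pct()` implement the response arithmetic, with complete
propagation failure coded −100% where a regression response needs a
number.

The full reference experiment (50 axons x 30 trials x all factor grids) is
tens of thousands of 2-second simulations; the shipped tests run the same
machinery at a documented reduced scale (28 screened candidates, up to 4
accepted axons, 2 randomized trials, the 100%-removal column plus two
removal levels and two restoration levels), chosen so the whole suite
completes in tens of minutes on one core. At that scale the cohort-mean
perturbation statistics are dominated by which four axons the seed
selects (see *Known limitations*).

### Parameter importance

Twelve predictors (six sampled parameters, myelin thickness =
`n_lamellae * lamella_thickness`, and five per-axon electrical quantities
derived from geometry and constants — axoplasmic resistance and axolemma
capacitance per unit length, radial myelin resistance and capacitance,
total tight-junction resistance; the g-ratio is excluded as collinear) are
z-scored and fit by lasso (`glmnet`), with the penalty chosen by seeded,
response-stratified 10-fold cross-validation and the final coefficients
refit on all data. `validate_predictions()` reports the Pearson r between
z-scored predictions and observations on a held-out cohort.

## The network model

### Dynamics

16,000 excitatory and 4000 inhibitory leaky integrate-and-fire neurons sit
on a ring of preferred directions; each receives 400 excitatory and 100
inhibitory inputs through independent Bernoulli draws with wrapped-
Gaussian probability profiles (footprints 30°–35° by pathway), normalized
so expected in-degrees are exact. Membrane potentials follow
`tau dV/dt = -V + I` with threshold 20 mV and reset −3.33 mV; excitatory
synapses carry AMPA (3 ms) and NMDA (50 ms) single-exponential traces,
inhibition GABA (4 ms). E-to-E synapses facilitate: per presynaptic neuron
`u` relaxes to U = 0.03 with 450 ms and `x` to 1 with 200 ms; at each
*transmitted* spike `u <- u + U(1-u)` first, then the jump scales by
`u x` and `x <- x(1-u)`. The cue is a Gaussian current bump (width 61.2°)
on the excitatory ring during the 1 s cue epoch of the 2/1/4 s DRT.

Three printed-notation ambiguities in the parameter table were resolved
jointly by an internal consistency requirement that the model itself
states: the correlated-input variant replaces half the constant drive with
structured Poisson input *calibrated to leave the time-averaged total
input unchanged*. That identity holds (to under 2% for both E and I
targets) only when couplings are the tabulated numerators divided by
sqrt(K_pop), external drives (and the cue amplitude) scale by sqrt(KE),
and a transmitted spike increments the receptor current by `g / tau`
(per-spike voltage-time integral `g`). With these conventions the network
sits in a low-rate asynchronous state (E about 1 Hz, I about 15 Hz), the
cue ignites a bump that persists through the delay, and the variant's
calibration check passes by construction; all three scalings are exposed
as arguments of `ring_params()`.

### Transmission failures and delays

Axon-level outcomes enter as per-neuron transmission probabilities:
`failure_histogram()` bins the cohort's per-axon failure fractions (width
0.05), and `transmission_probabilities()` partitions the excitatory
population to match (largest-remainder rounding, seeded assignment). One
Bernoulli draw per presynaptic spike gates delivery to *all* targets and
the facilitation update — the failing axon's AP never reaches any
terminal — while the somatic reset still occurs. CV slowing maps to
per-connection uniform delays on the AMPA/NMDA pathways (a ring buffer in
the simulator); as in the reference analysis, delays up to 40 ms leave
performance statistically unchanged (tested at reduced scale), because the
asynchronous state depends on rates, not spike timing.

### Numerics and performance

Exponential-Euler updates at dt = 0.1 ms (halving dt changes control
memory duration by under 10%), event-driven delivery over compressed
adjacency, xoshiro-free deterministic RNG (`std::mt19937_64`) seeded per
trial: identical seeds give identical event lists. Connectivity sampling
uses thinning with geometric jumps under the per-pathway maximum
probability, so building the full network costs a few seconds. A trial of
the full-size network takes 6–7 s on one core; a runaway guard aborts if
the population rate exceeds 200 Hz for 500 ms. No refractory period is
modeled (the reference formulation lists none); NMDA voltage dependence
and saturation are omitted (single-exponential current-based kernels).

### Readout

Rates are spike counts in 250 ms windows; the population vector
`Z(t) = sum_j r_j e^{i theta_j} / sum_j r_j = M e^{i Psi}` gives memory
strength M and decoded location Psi. Memory duration is the time from
delay onset to the (interpolated) first crossing of M below 0.4, or the
full 4 s. Per-trial decoded locations are unwrapped for continuity
starting at the cue (an attribute flags trajectories straying beyond 150°,
where unwrapping against the cue would be unreliable). Across trials,
drift is the bias `<Phi(t)> - theta_cue` and diffusion the variance
`<(Phi - <Phi>)^2>`; their rates are least-squares slopes over the delay
windows whose across-trial mean M stays at or above threshold. Diffusion
is reported in deg^2/s — the reference value 0.064 is printed without
units, and the comparison convention is documented wherever the two are
compared. Trial aggregation is mean over trials, then networks.

## Multiscale composition experiments

`build_axon_groups()` assembles groups of model neurons mixing intact and
perturbed axons; aligning them and sectioning every 0.5 um (up to the
shortest member) gives the percent of normal sheaths (bare stretches count
as altered profiles by default — they are scored as dystrophic in
cross-section micrographs; a switch drops them from the denominator) and
the percent of new sheaths (each remyelinated parent counts two). Each
group maps through its members' failure probabilities onto one designated
base network, and `run_composition_experiment()` regresses memory duration
and diffusion on composition. At the shipped test scale the assertion is
directional (duration rises and diffusion falls with percent normal
myelin), not the reference correlation magnitudes.

## Synthetic fixtures

`fixture_failure_histogram()` (a zero-failure point mass mixed with a
Beta distribution) emulates the bimodal cohort histograms so the network
layer can be tested without the axon layer; `synthetic_bump_trajectories()`
generates Brownian drift-diffusion trajectories directly from the
estimators' generative model for parameter-recovery tests. Neither
reproduces real features such as rate-dependent failure correlations or
non-Brownian bump dynamics; tests that pass on fixtures validate the
estimators and plumbing, not the biology.

## Known limitations

* The axon's fixed constants are a self-consistent calibration to the
  selection criteria, not a fit to voltage-clamp data; absolute CV
  changes under perturbation inherit that uncertainty, and individual
  constants are not identifiable from the selection bands.
* At the shipped scale (4 accepted axons, 2 trials) several reference
  perturbation bands are missed, and the tests report this honestly
  rather than widening the bands. The cause is visible in the per-cell
  tables: per-axon responses are close to all-or-none. Two of the four
  selected axons have long myelinated segments (182–187 um); a bare
  segment of that length is a purely passive stretch comparable to the
  fiber's space constant, so those axons block completely at *every*
  demyelination fraction (and one still blocks after remyelination with
  10% of lamellae), while the short-segment axons conduct with moderate
  slowing and no failures. Cohort means over eight such near-binary
  cells land at −65% CV change and 50% failures for the 25% condition
  (reference −38 ± 10 and 35 ± 13) and 73% failures for the 75%
  condition (reference 45 ± 13). The reference cohort (50 axons,
  30 trials) reports intermediate failure percentages, implying graded
  within-train failures that this calibration reproduces only rarely
  (one axon shows 92% partial failure); a 4-axon sample of a bimodal
  response cannot estimate a cohort mean to ±SD precision. The ordering
  properties (more demyelination → more slowing and more failures) and
  the downstream network conclusions are unaffected.
* The accepted-cohort g-ratio concentrates near the unconditioned mean of
  the sampled ranges (about 0.65) rather than 0.71 — none of the four
  selection criteria measures sheath thickness directly, so the strong
  g-ratio concentration the reference cohort reports is not reproduced by
  selection alone here.
* The full-size network's bump is marginally stable: memory strength
  decays slowly from about 0.6 to the 0.4 threshold near the end of the
  4 s delay, giving a control memory duration of about 3.5 s rather than
  a saturated 4.0, and a control diffusion constant several-fold above
  0.064 in deg^2/s (bump diffusion scales inversely with squared bump
  amplitude). A scaled ring with the same in-degree but 4000 neurons
  holds a stronger bump for the full delay, so the marginality is a
  finite-footprint/quenched-disorder effect of the full-size parameter
  set under these kernel conventions, not of the implementation of the
  dynamics (which reproduces every closed-form limit tested).
* Oscillations/synchrony, conductance-based synapses, NMDA nonlinearity,
  the activity-silent maintenance variant, spatially clustered lesions,
  and axon collaterals are out of scope.
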