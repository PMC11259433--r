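# myelinwm

Cortical aging — and demyelinating conditions such as multiple sclerosis —
degrades myelin: internodal sheaths split, balloon, lose lamellae, and are
replaced by shorter, thinner sheaths when remyelination partially
compensates. `myelinwm` is a two-level computational model, for
computational neuroscientists and quantitative physiologists, of how such
myelin dystrophy could impair spatial working memory:

1. **Axon level.** A double-cable multicompartment model of a thin
   myelinated cortical axon (soma/hillock/initial-segment source, then 101
   nodes of Ranvier alternating with 100 myelinated segments, each with
   paranodes, juxtaparanodes, an internode, a periaxonal space, and
   tight-junction seals). Demyelination removes lamellae from randomly
   chosen segments; remyelination replaces segments with two shorter,
   thinner children and a new node. Across a Latin-hypercube cohort of
   plausible axons, the package measures conduction-velocity (CV) changes
   and action-potential (AP) failure percentages, and lasso regression
   (`glmnet`) ranks the 12 morpho-electrical parameters driving the
   responses.
2. **Network level.** A 20,000-neuron spiking ring attractor (16,000
   excitatory with facilitating AMPA/NMDA synapses, 4000 inhibitory)
   performs the oculomotor delayed response task (2 s fixation, 1 s cue,
   4 s delay). Per-neuron AP-failure probabilities from the axon cohort
   gate spike transmission (one Bernoulli draw per presynaptic spike,
   withheld from all targets and from the facilitation update). The
   population vector `Z(t) = Σ r_j e^{iθ_j} / Σ r_j = M e^{iΨ}` decodes
   the remembered location; memory duration (time until `M < 0.4`), drift
   (bias slope, deg/s), and diffusion (variance slope, deg²/s) quantify
   performance.

The two levels meet in `failure_histogram()` /
`transmission_probabilities()`, and in composition experiments that mix
intact and perturbed axons, section them every 0.5 µm as in electron
micrographs, and relate the percentage of normal (or new) myelin sheaths
to network performance.

See the methods vignette (`vignettes/multiscale-methods.Rmd`) for the
model equations, assumptions, calibration choices, and limitations.

## Worked example

```r
library(myelinwm)

# one mid-range axon: evaluate under the standard +380 pA / 2 s protocol
sp  <- axon_spec(axon_diameter = 0.76, node_length = 1.1,
                 segment_length = 120, n_lamellae = 12,
                 lamella_thickness = 0.016,
                 scale_leak = 0.55, scale_naf = 0.55, scale_kdr = 0.55)
ev  <- evaluate_axon(build_axon(sp))
ev[, c("firing_rate_hz", "cv_m_per_s", "ap_failure_pct", "saltatory")]
#> # A tibble: 1 x 4
#>   firing_rate_hz cv_m_per_s ap_failure_pct saltatory
#>            <dbl>      <dbl>          <dbl> <lgl>
#> 1             14      0.815              0 TRUE

# demyelinate 25% of its segments completely and re-measure
plan <- demyelinate(perturbation_plan(sp),
                    draw_segment_lists(100, 0.25, 1, seed = 7)[[1]], 1.0)
pert <- evaluate_axon(build_axon(sp, plan), check_silence = FALSE)
cv_change(ev$cv_m_per_s, pert$cv_m_per_s)
#> [1] -45.1
ap_failure_pct(pert$n_first, pert$n_distal)
#> [1] 0

# a control network trial and its decoded memory
p    <- ring_params()
conn <- build_ring_connectivity(p, seed = 1)
trial <- simulate_drt_trial(p, conn, cue_deg = 135, seed = 101)
traj  <- decode_trajectory(trial)
memory_duration(traj)
#> [1] 3.47
```

The axon numbers say the unperturbed model conducts at 0.82 m/s with
saltatory conduction and no failures, and that stripping all lamellae
from a quarter of its 120-µm segments slows conduction by ~45% while
every AP still arrives. Axons with longer myelinated segments are far
less forgiving — in the cohort grids many block outright under the same
perturbation, and those failure probabilities are what make the network
below forget. The control network trial holds the cue location for most
of the 4 s delay before its memory strength decays below threshold.

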