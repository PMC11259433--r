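library(tibble)
library(withr)

# Shared fixtures, computed lazily once per test session and cached.
# The heavy objects (screened candidate set, reduced cohort, perturbation
# grid cells, the full-size control network) are reused across test files.

the_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = the_cache)) {
    assign(name, force(expr), envir = the_cache)
  }
  get(name, envir = the_cache)
}

# a single passive compartment model for the raw integrator
passive_one <- function(C = 0.1, g = 0.01, e = -70) {
  list(has_peri = 0L, c_ax = C, g_pas = g, e_pas = e, gna = 0, gk = 0,
       c_my = 0, g_my = 0, g_seal = 0, active = 0L, phi_gate = 5,
       axial_i_a = integer(0), axial_i_b = integer(0),
       axial_i_g = numeric(0), axial_p_a = integer(0),
       axial_p_b = integer(0), axial_p_g = numeric(0),
       ena = 55, ek = -90, inj_comp = 0L)
}

# three passive compartments in a chain
passive_three <- function(C = c(0.1, 0.05, 0.08), g = c(0.01, 0.004, 0.006),
                          ga = c(0.02, 0.015), e = -70) {
  list(has_peri = rep(0L, 3), c_ax = C, g_pas = g, e_pas = rep(e, 3),
       gna = rep(0, 3), gk = rep(0, 3), c_my = rep(0, 3), g_my = rep(0, 3),
       g_seal = rep(0, 3), active = rep(0L, 3), phi_gate = rep(5, 3),
       axial_i_a = c(0L, 1L), axial_i_b = c(1L, 2L), axial_i_g = ga,
       axial_p_a = integer(0), axial_p_b = integer(0),
       axial_p_g = numeric(0), ena = 55, ek = -90, inj_comp = 0L)
}

# small axon spec for machinery tests (not for cohort statistics)
small_axon_spec <- function(n_segments = 8, n_lamellae = 12) {
  axon_spec(0.76, 1.1, 120, n_lamellae, 0.016, 0.55, 0.55, 0.55,
            n_segments = n_segments)
}

# mid-range full axon spec (the calibration reference point)
mid_axon_spec <- function() {
  axon_spec(0.76, 1.1, 120, 12, 0.016, 0.55, 0.55, 0.55)
}

# ---- heavy shared fixtures -------------------------------------------------

# candidate screening under the study protocol (2 s step); the cohort and
# every reduced grid below reuse this
get_screened <- function() {
  cached("screened", {
    cand <- sample_axon_lhs(28, seed = 1)
    screen_axon_candidates(cand)
  })
}

get_cohort <- function(n_max = 4) {
  cached(paste0("cohort", n_max), {
    cohort <- select_models(get_screened(), n = n_max, seed = 2)
    attr(cohort, "constants") <- axon_constants()
    cohort
  })
}

# reduced demyelination grid: the statistics fractions (two randomized
# trials) plus the remaining fractions at one trial for the histogram map
get_demyel_cells <- function() {
  cached("demyel_cells", {
    run_demyelination_grid(
      get_cohort(),
      segment_fractions = c(0.25, 0.75),
      removal_fractions = 1.00,
      n_trials = 2, seed = 11)
  })
}

get_demyel_cells_extra <- function() {
  cached("demyel_cells_extra", {
    run_demyelination_grid(
      get_cohort(),
      segment_fractions = c(0.10, 0.50),
      removal_fractions = 1.00,
      n_trials = 1, seed = 11)
  })
}

get_all_demyel_cells <- function() {
  dplyr::bind_rows(get_demyel_cells(), get_demyel_cells_extra())
}

# reduced mild-removal cells (negligible-effect check) on one fraction
get_mild_cells <- function() {
  cached("mild_cells", {
    run_demyelination_grid(
      get_cohort(),
      segment_fractions = 0.25,
      removal_fractions = c(0.25, 0.75),
      n_trials = 1, seed = 11)
  })
}

# reduced remyelination cells: full remyelination at two restoration levels
get_remyel_cells <- function() {
  cached("remyel_cells", {
    run_remyelination_grid(
      get_cohort(),
      demyel_fractions = 0.25,
      remyel_fractions = 1.00,
      restore_fractions = c(0.10, 0.75),
      initial = "complete",
      n_trials = 1, seed = 11)
  })
}

# full-size Table-2 network: connectivity and a 20-trial control run
get_full_params <- function() cached("full_params", ring_params())

get_full_conn <- function() {
  cached("full_conn", build_ring_connectivity(get_full_params(), seed = 1))
}

get_control_run <- function() {
  cached("control_run", {
    run_drt_trials(get_full_params(), get_full_conn(), n_trials = 20,
                   cue_deg = 135, seed = 100)
  })
}

# scaled-down network (4000 neurons, same in-degree) for property tests
get_small_params <- function() {
  cached("small_params",
         ring_params(NE = 3200, NI = 800, KE = 400, KI = 100))
}

get_small_conn <- function() {
  cached("small_conn", build_ring_connectivity(get_small_params(), seed = 3))
}
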