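#' Fixed electrical constants of the axon model
#'
#' The double-cable axon model depends on a set of electrical constants that
#' are not varied when building model cohorts: axoplasmic resistivity, the
#' per-lamella radial resistivity and capacitance of compact myelin, the
#' periaxonal-space geometry, the paranodal tight-junction seal, nodal channel
#' reference densities, and the geometry/densities of the action-potential
#' source (a soma + hillock + initial-segment chain standing in for the full
#' somatodendritic compartment model, calibrated so that a +380 pA somatic
#' step elicits 13-16 Hz firing and zero current elicits silence).
#'
#' Values follow the conventions of detailed double-cable node-paranode
#' models of thin (< 1 um) cortical fibers; each entry carries a provenance
#' tag (`"reference"` for the shipped calibration, `"user"` for overrides).
#' All are overridable, which is how perturbation and sensitivity studies
#' change the electrical assumptions without touching the geometry code.
#'
#' @param ... Named overrides, e.g. `axon_constants(rho_tj = 3000)`.
#'
#' @return An object of class `axon_constants`: a named list of numeric
#'   values with a `provenance` attribute naming, per constant, whether the
#'   shipped reference value or a user override is in force.
#'
#' @section Units:
#' * resistivities `rho_ax`, `rho_peri`: Ohm cm
#' * specific membrane values: S/cm^2 (conductances), uF/cm^2 (capacitances)
#' * `r_lam`: Ohm cm^2 radial resistance contributed per myelin lamella;
#'   `c_lam`: uF/cm^2 capacitance of one lamella (lamellae stack in series,
#'   so a sheath of n lamellae has radial resistance `n * r_lam` and
#'   capacitance `c_lam / n` per unit area)
#' * `w_peri`: um periaxonal-space width; `rho_tj`: MOhm um, the paranodal
#'   tight-junction seal resistance scales as `rho_tj * n_lamellae /
#'   (pi * axon_diameter)` per segment end (the mesaxon path lengthens with
#'   each wrap and the seal circumference grows with diameter)
#' * potentials: mV; lengths: um
#' @export
#' @examples
#' cst <- axon_constants()
#' cst$rho_ax
#' axon_constants(rho_tj = 1500)
axon_constants <- function(...) {
  ref <- list(
    # cytoplasm / periaxonal fluid
    rho_ax = 120, rho_peri = 70, w_peri = 0.006,
    # axolemma
    cm = 1, e_pas = -70,
    g_pas_myel = 3e-4,            # internodal/paranodal axolemma leak
    # nodal reference densities (scale factors multiply these)
    g_pas_node = 0.007, gbar_naf_node = 6, gbar_kdr_node = 1.2,
    ena = 55, ek = -90, phi_gate = 5, phi_m = 2.5, phi_m_source = 5,
    phi_n_source = 0.15, h_shift_node = 0,
    # compact myelin, per lamella
    r_lam = 2000, c_lam = 2.2,
    # paranodal tight-junction seal
    rho_tj = 500,
    # segment sub-structure (um); rescaled proportionally when a segment is
    # too short to fit them at 80% internode share
    paranode_len = 2.3, juxtaparanode_len = 5.0,
    # AP source: soma standing in for the somatodendritic tree
    soma_len = 80, soma_diam = 80,
    g_pas_soma = 1.15e-4, e_pas_soma = -65,
    gna_soma = 0.035, gk_soma = 0.12,
    hillock_len = 10, hillock_diam = 3,
    gna_hillock = 0.1, gk_hillock = 0.02,
    ais_len = 20, ais_diam = 1.2,
    gna_ais = 0.6, gk_ais = 0.12,
    g_pas_ax = 1e-4               # hillock/AIS leak
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(ref))
    if (length(bad)) {
      abort(paste0("unknown constant(s): ", paste(bad, collapse = ", ")))
    }
    ref[names(over)] <- over
  }
  prov <- setNames(rep("reference", length(ref)), names(ref))
  prov[names(over)] <- "user"
  structure(ref, provenance = prov, class = "axon_constants")
}

#' @export
print.axon_constants <- function(x, ...) {
  cat("<axon_constants> (", sum(attr(x, "provenance") == "user"),
      " user override(s))\n", sep = "")
  print(as_tibble_constants(x))
  invisible(x)
}

#' Constants table with provenance
#'
#' @param x an [axon_constants()] object.
#' @return A tibble with columns `constant`, `value`, `provenance`.
#' @export
as_tibble_constants <- function(x) {
  tibble(constant = names(x),
         value = unlist(x, use.names = FALSE),
         provenance = unname(attr(x, "provenance")))
}

#' Parameter ranges for cohort construction
#'
#' The eight axon parameters sampled when building a model cohort, with the
#' biologically plausible ranges used for the Latin hypercube design:
#' axon diameter measured at nodes (0.5-1.02 um), node length (0.25-2.02 um),
#' myelinated segment length (50-200 um), number of myelin lamellae (5-20),
#' lamella thickness (0.013-0.019 um), and the three nodal conductance scale
#' factors (0.1-1 relative to the reference densities).
#'
#' @return A tibble with columns `parameter`, `min`, `max`.
#' @export
axon_parameter_ranges <- function() {
  tibble(
    parameter = c("axon_diameter", "node_length", "segment_length",
                  "n_lamellae", "lamella_thickness",
                  "scale_leak", "scale_naf", "scale_kdr"),
    min = c(0.5, 0.25, 50, 5, 0.013, 0.1, 0.1, 0.1),
    max = c(1.02, 2.02, 200, 20, 0.019, 1, 1, 1)
  )
}
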