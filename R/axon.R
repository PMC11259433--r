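#' Specify one myelinated axon model
#'
#' An `axon_spec` collects the eight sampled morpho-electrical parameters of
#' one model axon: diameter (measured at nodes), node length, myelinated
#' segment length, number of myelin lamellae, lamella thickness, and the
#' three nodal conductance scale factors (leak, NaF, KDR, relative to the
#' reference nodal densities in [axon_constants()]). The axon has
#' `n_segments` myelinated segments alternating with `n_segments + 1` nodes,
#' attached to the soma/hillock/initial-segment action-potential source.
#'
#' @param axon_diameter um, diameter at nodes (and of the axolemma under
#'   the sheath).
#' @param node_length um, length of one node of Ranvier.
#' @param segment_length um, length of one myelinated segment (four
#'   paranodes, juxtaparanode, internode, juxtaparanode, four paranodes).
#' @param n_lamellae integer >= 1, myelin wraps per unperturbed segment.
#' @param lamella_thickness um, radial thickness of one lamella (enters the
#'   g-ratio; the electrical stack is parameterized per lamella).
#' @param scale_leak,scale_naf,scale_kdr nodal conductance scale factors in
#'   (0, 1].
#' @param n_segments number of myelinated segments (default 100).
#' @param constants an [axon_constants()] object.
#' @return An object of class `axon_spec`.
#' @export
#' @examples
#' sp <- axon_spec(0.76, 1.1, 120, 12, 0.016, 0.5, 0.5, 0.5)
#' g_ratio(sp)
axon_spec <- function(axon_diameter, node_length, segment_length,
                      n_lamellae, lamella_thickness,
                      scale_leak, scale_naf, scale_kdr,
                      n_segments = 100, constants = axon_constants()) {
  vals <- c(axon_diameter = axon_diameter, node_length = node_length,
            segment_length = segment_length, n_lamellae = n_lamellae,
            lamella_thickness = lamella_thickness, scale_leak = scale_leak,
            scale_naf = scale_naf, scale_kdr = scale_kdr)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all axon_spec parameters must be positive and finite")
  }
  if (n_lamellae < 1) abort("n_lamellae must be >= 1 for an unperturbed axon")
  if (any(c(scale_leak, scale_naf, scale_kdr) > 1)) {
    abort("scale factors must lie in (0, 1]")
  }
  structure(list(axon_diameter = axon_diameter, node_length = node_length,
                 segment_length = segment_length,
                 n_lamellae = as.integer(round(n_lamellae)),
                 lamella_thickness = lamella_thickness,
                 scale_leak = scale_leak, scale_naf = scale_naf,
                 scale_kdr = scale_kdr, n_segments = as.integer(n_segments),
                 constants = constants),
            class = "axon_spec")
}

#' @export
print.axon_spec <- function(x, ...) {
  cat(sprintf(
    "<axon_spec> d=%.3f um, node=%.2f um, segment=%.1f um x %d, %d lamellae (g-ratio %.3f)\n",
    x$axon_diameter, x$node_length, x$segment_length, x$n_segments,
    x$n_lamellae, g_ratio(x)))
  invisible(x)
}

#' g-ratio of an axon specification
#'
#' Ratio of axon diameter to fiber diameter (axon + two sheath thicknesses).
#'
#' @param spec an [axon_spec()].
#' @return Numeric in (0, 1).
#' @export
g_ratio <- function(spec) {
  spec$axon_diameter /
    (spec$axon_diameter + 2 * spec$n_lamellae * spec$lamella_thickness)
}

# sub-structure lengths of one myelinated segment of total length L:
# fixed paranode/juxtaparanode lengths, shrunk proportionally when the
# internode would drop below 20% of the segment
segment_partition <- function(L, cst, scale = 1) {
  pl <- cst$paranode_len * scale
  jl <- cst$juxtaparanode_len * scale
  fixed <- 8 * pl + 2 * jl
  il <- L - fixed
  if (il < 0.2 * L) {
    shrink <- 0.8 * L / fixed
    pl <- pl * shrink
    jl <- jl * shrink
    il <- 0.2 * L
  }
  list(paranode = pl, juxtaparanode = jl, internode = il)
}

# one myelinated segment as a block of 59 compartments
segment_block <- function(L, n_lam, seg_id, cst, scale = 1) {
  p <- segment_partition(L, cst, scale)
  role <- c(rep("paranode", 20), rep("juxtaparanode", 5), rep("internode", 9),
            rep("juxtaparanode", 5), rep("paranode", 20))
  len <- c(rep(p$paranode / 5, 20), rep(p$juxtaparanode / 5, 5),
           rep(p$internode / 9, 9), rep(p$juxtaparanode / 5, 5),
           rep(p$paranode / 5, 20))
  list(role = role, len = len, n_lam = rep(n_lam, 59),
       seg_id = rep(seg_id, 59))
}

node_block <- function(node_length, nid) {
  list(role = rep("node", 13), len = rep(node_length / 13, 13),
       n_lam = rep(0L, 13), seg_id = rep(-nid, 13))
}

#' Build the compartment graph of an axon
#'
#' Discretizes an [axon_spec()] (optionally perturbed by a plan from
#' [demyelinate()] / [remyelinate()]) into the full double-cable compartment
#' chain: soma, hillock (5 compartments), initial segment (5), then nodes of
#' Ranvier (13 compartments each) alternating with myelinated segments (59
#' compartments: 4+4 paranodes of 5, two juxtaparanodes of 5, an internode
#' of 9). Remyelinated segments become two half-length child segments with a
#' new, standard node between them. Electrical parameters are derived from
#' the spec and its constants: axial conductances from diameter and
#' axoplasmic resistivity, myelin admittance and capacitance from the
#' lamella stack (conductance per unit area falls as 1/n, capacitance as
#' 1/n), and a paranodal tight-junction seal draining each sheath end to
#' bath. Bare segments (0 lamellae, only produced by the perturbation
#' engine) lose the periaxonal layer entirely and expose the axolemma.
#'
#' @param spec an [axon_spec()].
#' @param plan optional perturbation plan: a tibble with columns `segment`,
#'   `state` (`"normal"`, `"demyelinated"`, `"remyelinated"`) and `n_lam`
#'   (lamellae after perturbation; for remyelinated segments, lamellae on
#'   each child segment). Defaults to all-normal.
#' @return An object of class `axon_graph`: the compartment table, the flat
#'   model arrays consumed by the integrator, probe compartment indices, and
#'   geometry metadata (probe distance, total length, node count).
#' @export
build_axon <- function(spec, plan = NULL) {
  stopifnot(inherits(spec, "axon_spec"))
  cst <- spec$constants
  ns <- spec$n_segments
  if (is.null(plan)) {
    plan <- tibble(segment = seq_len(ns), state = "normal",
                   n_lam = spec$n_lamellae)
  }
  if (nrow(plan) != ns) abort("plan must describe every segment")
  if (any(plan$state == "normal" & plan$n_lam < 1)) {
    abort("a normal segment cannot have 0 lamellae; use the perturbation engine")
  }
  if (any(plan$state == "remyelinated" & plan$n_lam < 1)) {
    abort("remyelination must add at least one lamella")
  }

  blocks <- vector("list", 4 * ns + 8)
  bi <- 0L
  add <- function(b) { bi <<- bi + 1L; blocks[[bi]] <<- b }
  # AP source
  add(list(role = "soma", len = cst$soma_len, n_lam = 0L, seg_id = 0L))
  add(list(role = rep("hillock", 5), len = rep(cst$hillock_len / 5, 5),
           n_lam = rep(0L, 5), seg_id = rep(0L, 5)))
  add(list(role = rep("ais", 5), len = rep(cst$ais_len / 5, 5),
           n_lam = rep(0L, 5), seg_id = rep(0L, 5)))
  nid <- 1L
  add(node_block(spec$node_length, nid))
  for (s in seq_len(ns)) {
    st <- plan$state[s]
    nl <- plan$n_lam[s]
    if (st == "remyelinated") {
      add(segment_block(spec$segment_length / 2, nl, s, cst, scale = 0.5))
      nid <- nid + 1L
      add(node_block(spec$node_length, nid))
      add(segment_block(spec$segment_length / 2, nl, s, cst, scale = 0.5))
    } else {
      add(segment_block(spec$segment_length, nl, s, cst))
    }
    nid <- nid + 1L
    add(node_block(spec$node_length, nid))
  }
  blocks <- blocks[seq_len(bi)]
  comp <- tibble(
    role = unlist(lapply(blocks, `[[`, "role")),
    len = unlist(lapply(blocks, `[[`, "len")),
    n_lam = as.integer(unlist(lapply(blocks, `[[`, "n_lam"))),
    seg_id = as.integer(unlist(lapply(blocks, `[[`, "seg_id")))
  )
  nc <- nrow(comp)
  d_ax <- spec$axon_diameter
  comp$diam <- dplyr::case_when(
    comp$role == "soma" ~ cst$soma_diam,
    comp$role == "hillock" ~ cst$hillock_diam,
    comp$role == "ais" ~ cst$ais_diam,
    TRUE ~ d_ax
  )
  myel_role <- comp$role %in% c("paranode", "juxtaparanode", "internode")
  comp$has_peri <- myel_role & comp$n_lam >= 1L

  # sheath runs: contiguous stretches with a periaxonal layer
  run <- cumsum(c(TRUE, diff(comp$has_peri) != 0L))
  run[!comp$has_peri] <- NA_integer_
  comp$sheath_run <- run

  area <- pi * comp$diam * comp$len                       # um^2 (cylinder)
  # membrane densities by role
  g_pas_d <- dplyr::case_when(
    comp$role == "soma" ~ cst$g_pas_soma,
    comp$role %in% c("hillock", "ais") ~ cst$g_pas_ax,
    comp$role == "node" ~ cst$g_pas_node * spec$scale_leak,
    TRUE ~ cst$g_pas_myel
  )
  gna_d <- dplyr::case_when(
    comp$role == "soma" ~ cst$gna_soma,
    comp$role == "hillock" ~ cst$gna_hillock,
    comp$role == "ais" ~ cst$gna_ais,
    comp$role == "node" ~ cst$gbar_naf_node * spec$scale_naf,
    TRUE ~ 0
  )
  gk_d <- dplyr::case_when(
    comp$role == "soma" ~ cst$gk_soma,
    comp$role == "hillock" ~ cst$gk_hillock,
    comp$role == "ais" ~ cst$gk_ais,
    comp$role == "node" ~ cst$gbar_kdr_node * spec$scale_kdr,
    TRUE ~ 0
  )
  e_pas <- ifelse(comp$role == "soma", cst$e_pas_soma, cst$e_pas)

  c_ax <- cst$cm * area * 1e-5                            # nF
  g_pas <- g_pas_d * area * 1e-2                          # uS
  gna <- gna_d * area * 1e-2
  gk <- gk_d * area * 1e-2
  g_my <- ifelse(comp$has_peri, area / (pmax(comp$n_lam, 1L) * cst$r_lam) * 1e-2, 0)
  c_my <- ifelse(comp$has_peri, cst$c_lam / pmax(comp$n_lam, 1L) * area * 1e-5, 0)

  # paranodal tight-junction seal at each sheath-run end (uS = 1/MOhm)
  g_seal <- numeric(nc)
  if (any(comp$has_peri)) {
    idx <- which(comp$has_peri)
    ends <- idx[c(TRUE, diff(idx) > 1)]                   # run starts
    ends2 <- idx[c(diff(idx) > 1, TRUE)]                  # run ends
    seal_g <- function(i) pi * comp$diam[i] / (cst$rho_tj * comp$n_lam[i])
    g_seal[ends] <- g_seal[ends] + seal_g(ends)
    g_seal[ends2] <- g_seal[ends2] + seal_g(ends2)
  }

  # intracellular axial conductances between consecutive compartments
  r_half <- cst$rho_ax * (comp$len / 2) / (pi / 4 * comp$diam^2) * 1e4  # Ohm
  g_axial <- 1e6 / (r_half[-nc] + r_half[-1])             # uS
  ai_a <- seq_len(nc - 1L) - 1L
  ai_b <- seq_len(nc - 1L)

  # periaxonal axial conductances within a sheath run
  a_peri <- pi * comp$diam * cst$w_peri                   # um^2 annulus
  rp_half <- cst$rho_peri * (comp$len / 2) / a_peri * 1e4
  same_run <- !is.na(run[-nc]) & !is.na(run[-1]) & run[-nc] == run[-1]
  ap_a <- which(same_run) - 1L
  ap_b <- which(same_run)
  gp <- 1e6 / (rp_half[ap_a + 1L] + rp_half[ap_b + 1L])

  model <- list(
    has_peri = as.integer(comp$has_peri),
    c_ax = c_ax, g_pas = g_pas, e_pas = e_pas, gna = gna, gk = gk,
    c_my = c_my, g_my = g_my, g_seal = g_seal,
    active = as.integer(gna > 0),
    phi_gate = rep(cst$phi_gate, nc),
    axial_i_a = ai_a, axial_i_b = ai_b, axial_i_g = g_axial,
    axial_p_a = ap_a, axial_p_b = ap_b, axial_p_g = gp,
    ena = cst$ena, ek = cst$ek,
    phi_m = ifelse(comp$role == "node", cst$phi_m, cst$phi_m_source),
    phi_n = ifelse(comp$role == "node", cst$phi_gate, cst$phi_n_source),
    h_shift = ifelse(comp$role == "node", cst$h_shift_node, 0),
    inj_comp = 0L
  )

  # probes: soma, middle compartment of first and penultimate node
  node_first <- which(comp$seg_id == -1L)
  node_ids <- sort(unique(-comp$seg_id[comp$seg_id < 0]))
  penult <- node_ids[length(node_ids) - 1L]
  node_pen <- which(comp$seg_id == -penult)
  probe <- c(soma = 0L,
             first_node = as.integer(node_first[7] - 1L),
             penultimate_node = as.integer(node_pen[7] - 1L))
  pos <- cumsum(comp$len) - comp$len / 2
  distance_um <- pos[probe["penultimate_node"] + 1L] - pos[probe["first_node"] + 1L]

  structure(list(comp = comp, model = model, probes = probe,
                 distance_um = unname(distance_um),
                 axon_length_um = sum(comp$len[comp$seg_id != 0L]),
                 n_nodes = length(node_ids), spec = spec, plan = plan),
            class = "axon_graph")
}

#' @export
print.axon_graph <- function(x, ...) {
  cat(sprintf(
    "<axon_graph> %d compartments, %d nodes, axon length %.3f cm, probe distance %.3f cm\n",
    nrow(x$comp), x$n_nodes, x$axon_length_um * 1e-4, x$distance_um * 1e-4))
  invisible(x)
}

#' Current-clamp protocol
#'
#' Somatic current clamp used for all cohort simulations: pre-equilibration
#' to a -70 mV holding potential (holding current found by a steady-state
#' solve), then a constant current step.
#'
#' @param step_pA step amplitude (default +380 pA).
#' @param step_s step duration in seconds (default 2).
#' @param hold_mV somatic holding potential (default -70).
#' @param dt_ms integration step (default 0.025 ms).
#' @param theta implicitness of the integration scheme (0.5 =
#'   Crank-Nicolson-like, 1 = backward Euler).
#' @param pre_ms settling time simulated before the step (default 20 ms).
#' @param post_ms tail simulated after step offset so in-flight spikes reach
#'   the distal probe (default 60 ms).
#' @return A list of class `axon_protocol`.
#' @export
axon_protocol <- function(step_pA = 380, step_s = 2, hold_mV = -70,
                          dt_ms = 0.025, theta = 0.5, pre_ms = 20,
                          post_ms = 60) {
  structure(list(step_pA = step_pA, step_s = step_s, hold_mV = hold_mV,
                 dt_ms = dt_ms, theta = theta, pre_ms = pre_ms,
                 post_ms = post_ms),
            class = "axon_protocol")
}

#' Integrate an axon model under a current-clamp protocol
#'
#' Solves the holding state (somatic potential pinned at the protocol's
#' holding level, holding current recovered from the current balance), then
#' integrates the full double-cable system at the protocol's fixed time step
#' with the semi-implicit scheme. Records membrane-potential traces at the
#' probe compartments (soma, first node after the initial segment,
#' penultimate node) and the peak membrane potential attained in every
#' compartment (used by the saltatory-conduction check).
#'
#' @param graph an [build_axon()] result.
#' @param protocol an [axon_protocol()].
#' @return An object of class `axon_sim` with elements `traces` (tibble:
#'   `time_ms`, `probe`, `v_mv`), `vmax` (per-compartment peak membrane
#'   potential), `i_hold_nA`, and the originating `graph`/`protocol`.
#' @export
simulate_axon <- function(graph, protocol = axon_protocol()) {
  stopifnot(inherits(graph, "axon_graph"))
  ss <- .cable_steady_cpp(graph$model, protocol$hold_mV)
  nsteps <- as.integer(round((protocol$pre_ms + protocol$step_s * 1e3 +
                                protocol$post_ms) / protocol$dt_ms))
  t_on <- protocol$pre_ms
  t_off <- protocol$pre_ms + protocol$step_s * 1e3
  out <- .cable_integrate_cpp(graph$model, ss$phi, ss$h, ss$n,
                              protocol$dt_ms, nsteps,
                              i_hold = ss$i_hold,
                              i_step = protocol$step_pA * 1e-3,  # pA -> nA
                              t_on = t_on, t_off = t_off,
                              probe_comps = unname(graph$probes),
                              theta = protocol$theta)
  tm <- seq(0, nsteps) * protocol$dt_ms
  traces <- tibble(
    time_ms = rep(tm, times = length(graph$probes)),
    probe = rep(names(graph$probes), each = length(tm)),
    v_mv = as.vector(out$traces)
  )
  structure(list(traces = traces, vmax = out$vmax,
                 i_hold_nA = ss$i_hold, steady = ss,
                 t_on = t_on, t_off = t_off,
                 graph = graph, protocol = protocol),
            class = "axon_sim")
}

#' @export
print.axon_sim <- function(x, ...) {
  cat(sprintf("<axon_sim> %d probes x %d samples, holding current %.1f pA\n",
              length(unique(x$traces$probe)),
              sum(x$traces$probe == x$traces$probe[1]), x$i_hold_nA * 1e3))
  invisible(x)
}

#' Detect action potentials by threshold crossing
#'
#' Upward threshold crossings of a uniformly sampled membrane-potential
#' trace, with sub-step linear interpolation of the crossing time.
#'
#' @param time_ms,v_mv numeric vectors of equal length (or `time_ms` may be
#'   a data frame with columns `time_ms` and `v_mv`).
#' @param threshold crossing threshold in mV (default 0, appropriate for
#'   full-height nodal spikes).
#' @return Numeric vector of crossing times (ms), possibly empty.
#' @export
#' @examples
#' t <- seq(0, 10, by = 0.1)
#' detect_spikes(t, 30 * sin(t))       # crossings of 0 from below
detect_spikes <- function(time_ms, v_mv = NULL, threshold = 0) {
  if (is.data.frame(time_ms)) {
    v_mv <- time_ms$v_mv
    time_ms <- time_ms$time_ms
  }
  if (length(v_mv) == 0) return(numeric(0))
  above <- v_mv > threshold
  ix <- which(!above[-length(above)] & above[-1])
  if (!length(ix)) return(numeric(0))
  frac <- (threshold - v_mv[ix]) / (v_mv[ix + 1] - v_mv[ix])
  time_ms[ix] + frac * (time_ms[ix + 1] - time_ms[ix])
}

#' Conduction velocity from paired spike trains
#'
#' Matches action potentials detected at the proximal probe to action
#' potentials at the distal probe by nearest latency (within a 0-50 ms
#' window, each distal spike used at most once), and converts the median
#' latency over matched pairs into a conduction velocity. Because a
#' perturbed axon can carry distal activity that is not one-to-one with
#' the proximal train (echoes reflected at demyelinated boundaries, or in
#' pathological cases sustained re-excitation), the matcher is anchored:
#' every pairwise latency in the window is tried as a candidate anchor,
#' each proximal spike greedily takes the unused distal spike whose
#' latency is closest to the anchor, and the accepted matching is the one
#' with the most pairs and, among those, the smallest median deviation
#' from its anchor. A clean one-to-one train reduces to plain
#' nearest-latency matching; a train contaminated by echoes locks onto
#' the self-consistent conduction latency instead of the echo intervals.
#' Proximal spikes without a distal match are propagation failures and do
#' not enter the latency.
#'
#' @param t_first,t_distal spike times (ms) at the first and penultimate
#'   nodes.
#' @param distance_um propagation distance between the probes.
#' @param max_latency_ms matching window (default 50).
#' @return A list with `cv_m_per_s` (NA when nothing propagates), the
#'   `median_latency_ms`, `n_first`, `n_distal`, `n_matched`.
#' @export
#' @examples
#' measure_cv(c(10, 50), c(30, 70), 1e4)   # 1 cm in 20 ms = 0.5 m/s
measure_cv <- function(t_first, t_distal, distance_um,
                       max_latency_ms = 50) {
  n1 <- length(t_first)
  if (n1 == 0) {
    return(list(cv_m_per_s = NA_real_, median_latency_ms = NA_real_,
                n_first = 0L, n_distal = length(t_distal), n_matched = 0L,
                flag = "no proximal APs"))
  }
  cand <- unlist(lapply(t_first, function(tf) {
    dl <- t_distal - tf
    dl[dl > 0 & dl <= max_latency_ms]
  }))
  if (!length(cand)) {
    return(list(cv_m_per_s = NA_real_, median_latency_ms = NA_real_,
                n_first = n1, n_distal = length(t_distal), n_matched = 0L,
                flag = "no propagated APs"))
  }
  match_at <- function(anchor) {
    used <- rep(FALSE, length(t_distal))
    lat <- numeric(0)
    for (tf in t_first) {
      dl <- t_distal - tf
      ok <- which(dl > 0 & dl <= max_latency_ms & !used)
      if (length(ok)) {
        j <- ok[which.min(abs(dl[ok] - anchor))]
        used[j] <- TRUE
        lat <- c(lat, dl[j])
      }
    }
    lat
  }
  # among candidate anchors keep the matching with the most pairs, then
  # the tightest dispersion (quantized to 0.1 ms so timing jitter cannot
  # break ties), then the latency closest to the first observed pair:
  # the first distal spike precedes every possible echo, so its latency
  # from the last proximal spike before it is the one uncontaminated
  # observation of the conduction time
  pre <- which(t_first < t_distal[1] & t_distal[1] - t_first <= max_latency_ms)
  l0 <- if (length(pre)) t_distal[1] - t_first[max(pre)] else min(cand)
  best <- NULL
  for (a in unique(round(cand, 3))) {
    lat <- match_at(a)
    dev <- round(median(abs(lat - a)), 1)
    ml <- median(lat)
    if (is.null(best) || length(lat) > length(best$lat) ||
        (length(lat) == length(best$lat) &&
           (dev < best$dev ||
              (dev == best$dev && abs(ml - l0) < abs(best$ml - l0))))) {
      best <- list(lat = lat, dev = dev, ml = ml)
    }
  }
  lat <- best$lat
  ml <- median(lat)
  list(cv_m_per_s = distance_um * 1e-3 / ml, median_latency_ms = ml,
       n_first = n1, n_distal = length(t_distal),
       n_matched = length(lat), flag = NA_character_)
}

#' Percentage of propagation failures
#'
#' Failed action potentials at the distal axon end, relative to the count at
#' the first node, clipped to \[0, 100\].
#'
#' @param n_first,n_distal spike counts at the first and penultimate nodes.
#' @return Percentage in \[0, 100\] (NA with a warning when `n_first` = 0).
#' @export
#' @examples
#' ap_failure_pct(29, 18)   # 37.9
ap_failure_pct <- function(n_first, n_distal) {
  if (n_first < 1) {
    warn("no APs at the first node; failure percentage undefined")
    return(NA_real_)
  }
  min(100, max(0, 100 * (n_first - n_distal) / n_first))
}

#' Evaluate one axon model under the standard protocol
#'
#' Runs the current-clamp protocol on a (possibly perturbed) axon and
#' summarizes everything the cohort-selection and perturbation analyses
#' need: somatic firing rate during the step, silence at zero current,
#' conduction velocity between first and penultimate node, failure
#' percentage, and the saltatory-conduction check (peak membrane potential
#' above the spike threshold in every node, below it in every juxtaparanode
#' and internode).
#'
#' @param graph an [build_axon()] result (or an [axon_spec()], built
#'   on the fly).
#' @param protocol an [axon_protocol()].
#' @param spike_threshold nodal spike threshold, mV.
#' @param check_silence whether to also run a zero-step simulation (500 ms)
#'   to confirm silence at the holding potential.
#' @return A one-row tibble: `firing_rate_hz`, `silent_0pA`, `cv_m_per_s`,
#'   `ap_failure_pct`, `n_first`, `n_distal`, `saltatory`, `i_hold_pA`.
#' @export
evaluate_axon <- function(graph, protocol = axon_protocol(),
                          spike_threshold = 0, check_silence = TRUE) {
  if (inherits(graph, "axon_spec")) graph <- build_axon(graph)
  sim <- simulate_axon(graph, protocol)
  tr <- sim$traces
  step_window <- function(t) t >= sim$t_on & t <= sim$t_off
  sp_soma <- detect_spikes(tr$time_ms[tr$probe == "soma"],
                           tr$v_mv[tr$probe == "soma"], spike_threshold)
  sp_first <- detect_spikes(tr$time_ms[tr$probe == "first_node"],
                            tr$v_mv[tr$probe == "first_node"], spike_threshold)
  sp_dist <- detect_spikes(tr$time_ms[tr$probe == "penultimate_node"],
                           tr$v_mv[tr$probe == "penultimate_node"],
                           spike_threshold)
  sp_soma <- sp_soma[step_window(sp_soma)]
  cv <- measure_cv(sp_first, sp_dist, graph$distance_um)
  fail <- if (length(sp_first)) ap_failure_pct(length(sp_first), length(sp_dist)) else NA_real_

  comp <- graph$comp
  vmax <- sim$vmax
  node_ok <- all(vmax[comp$role == "node"] > spike_threshold)
  sub <- comp$role %in% c("juxtaparanode", "internode")
  myel_ok <- all(vmax[sub] < spike_threshold)
  silent <- NA
  if (check_silence) {
    p0 <- protocol
    p0$step_pA <- 0
    p0$step_s <- 0.2
    p0$post_ms <- 0
    sim0 <- simulate_axon(graph, p0)
    s0 <- detect_spikes(sim0$traces$time_ms[sim0$traces$probe == "soma"],
                        sim0$traces$v_mv[sim0$traces$probe == "soma"],
                        spike_threshold)
    silent <- length(s0) == 0
  }
  tibble(firing_rate_hz = length(sp_soma) / protocol$step_s,
         silent_0pA = silent,
         cv_m_per_s = cv$cv_m_per_s,
         ap_failure_pct = fail,
         n_first = length(sp_first), n_distal = length(sp_dist),
         saltatory = node_ok && myel_ok,
         i_hold_pA = sim$i_hold_nA * 1e3)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
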