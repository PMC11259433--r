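#' Failure-probability histogram of a cohort condition
#'
#' Per-axon failure probabilities (mean failure fraction over the
#' randomized trials of one grid cell) binned into a histogram with
#' population fractions — the quantity that maps single-neuron
#' perturbation outcomes onto the network: the fraction of neurons with
#' failure probability 0, 1, or anything between.
#'
#' @param grid a demyelination or remyelination response grid.
#' @param ... filter conditions selecting exactly one cell, e.g.
#'   `segment_fraction == 0.25, removal_fraction == 1`.
#' @param binwidth probability bin width (default 0.05); per-axon values
#'   are rounded to the nearest bin center, keeping exact 0 and 1.
#' @return Tibble of class `failure_histogram`: `p_failure`, `fraction`,
#'   `n_axons`, with `provenance = "cohort-run"`.
#' @export
failure_histogram <- function(grid, ..., binwidth = 0.05) {
  cell <- dplyr::filter(grid, ..., .data$complete)
  if (nrow(cell) == 0) abort("empty grid cell; simulate it first")
  per_axon <- cell %>%
    group_by(.data$axon_id) %>%
    summarise(p_fail = mean(.data$ap_failure_pct, na.rm = TRUE) / 100,
              .groups = "drop")
  binned <- round(per_axon$p_fail / binwidth) * binwidth
  tab <- table(binned)
  out <- tibble(p_failure = as.numeric(names(tab)),
                fraction = as.vector(tab) / nrow(per_axon),
                n_axons = as.vector(tab))
  attr(out, "provenance") <- "cohort-run"
  class(out) <- c("failure_histogram", class(out))
  out
}

#' Build mixed groups of intact and perturbed axons
#'
#' Groups of `size` model neurons combining intact axons with axons
#' carrying a perturbation (demyelination of a given fraction of segments,
#' optionally remyelinated), mirroring the heterogeneity of real tissue.
#' The number of perturbed members, each member's segment fraction, and
#' its realized segment list (one of the stored randomized trials) are
#' drawn from `seed`.
#'
#' @param cohort cohort tibble (recycled to fill a group).
#' @param n_groups number of groups.
#' @param size group size (reference: 50).
#' @param perturbed_range range for the random fraction of perturbed
#'   members per group.
#' @param segment_fractions segment fractions sampled per perturbed axon.
#' @param mode `"demyelinate"` or `"remyelinate"`.
#' @param removal_fraction lamellae removal for demyelinated members.
#' @param remyelination_fraction,restore_fraction remyelination settings
#'   (used when `mode = "remyelinate"`; initial demyelination is partial,
#'   50% of lamellae, per the composition experiment's design).
#' @param n_trials stored randomized segment lists to draw from.
#' @param seed seed.
#' @return A list of `axon_group` objects; each is a tibble (one row per
#'   member: `member`, `axon_id`, `status`, `segment_fraction`, `trial`)
#'   with the member plans in a list column `plan`.
#' @export
build_axon_groups <- function(cohort, n_groups, size = 50,
                              perturbed_range = c(0, 0.6),
                              segment_fractions = c(0.10, 0.25, 0.50, 0.75),
                              mode = "demyelinate",
                              removal_fraction = 1,
                              remyelination_fraction = 0.5,
                              restore_fraction = 0.25,
                              n_trials = 30, seed = 1) {
  mode <- match.arg(mode, c("demyelinate", "remyelinate"))
  withr::with_seed(seed, {
    lapply(seq_len(n_groups), function(g) {
      n_pert <- round(stats::runif(1, perturbed_range[1], perturbed_range[2]) * size)
      members <- tibble(
        member = seq_len(size),
        axon_id = cohort$axon_id[((seq_len(size) - 1) %% nrow(cohort)) + 1],
        status = c(rep("perturbed", n_pert), rep("intact", size - n_pert)),
        segment_fraction = c(sample(segment_fractions, n_pert, replace = TRUE),
                             rep(0, size - n_pert)),
        trial = c(sample.int(n_trials, n_pert, replace = TRUE),
                  rep(0L, size - n_pert)))
      members$plan <- lapply(seq_len(size), function(i) {
        row <- cohort[cohort$axon_id == members$axon_id[i], ][1, ]
        spec <- spec_from_row(row, attr(cohort, "constants") %||% axon_constants())
        pl <- perturbation_plan(spec)
        if (members$status[i] == "perturbed") {
          segs <- draw_segment_lists(spec$n_segments,
                                     members$segment_fraction[i],
                                     n_trials, seed)[[members$trial[i]]]
          if (mode == "demyelinate") {
            pl <- demyelinate(pl, segs, removal_fraction)
          } else {
            pl <- demyelinate(pl, segs, 0.5)
            pl <- remyelinate(pl, spec$n_lamellae, remyelination_fraction,
                              restore_fraction)
          }
        }
        attr(pl, "spec") <- spec
        pl
      })
      structure(members, class = c("axon_group", class(members)),
                mode = mode, seed = seed, group_id = g)
    })
  })
}

# cross-section bookkeeping: for one axon plan, the segment state at a
# given axial position (positions measured from the first node, um)
section_states <- function(plan, spec, positions) {
  unit <- spec$node_length + spec$segment_length
  seg <- pmin(floor(positions / unit) + 1, nrow(plan))
  within <- positions - (seg - 1) * unit
  in_node <- within < spec$node_length
  st <- plan$state[seg]
  st[st == "demyelinated" & plan$n_lam[seg] == 0] <- "bare"
  # remyelinated segments contain a new central node
  if (any(st == "remyelinated")) {
    mid0 <- spec$node_length + spec$segment_length / 2
    mid1 <- mid0 + spec$node_length
    in_new_node <- st == "remyelinated" & within >= mid0 & within < mid1
    in_node <- in_node | in_new_node
  }
  ifelse(in_node, "node", st)
}

#' Percentage of normal myelin sheaths in a group
#'
#' Sections the aligned axons of a group every `stride` um (up to the
#' shortest member's axon length) and, among the axons whose plane lies in
#' a myelin-sheath region (nodes excluded), counts the fraction whose
#' sheath is unperturbed; the section values are then averaged. Bare,
#' fully demyelinated stretches count as altered sheath crossings by
#' default (`bare_counts = "altered"`), mirroring how dystrophic profiles
#' are scored in cross-section micrographs; set `bare_counts = "absent"`
#' to drop them from the denominator.
#'
#' @param group an `axon_group` from [build_axon_groups()].
#' @param stride section spacing, um (reference: 0.5).
#' @param bare_counts `"altered"` or `"absent"`.
#' @return Percentage in \[0, 100\].
#' @export
percent_normal_sheaths <- function(group, stride = 0.5,
                                   bare_counts = "altered") {
  bare_counts <- match.arg(bare_counts, c("altered", "absent"))
  specs <- lapply(group$plan, attr, "spec")
  lens <- vapply(specs, function(s) {
    s$n_segments * (s$node_length + s$segment_length) + s$node_length
  }, numeric(1))
  positions <- seq(stride / 2, min(lens), by = stride)
  states <- vapply(seq_len(nrow(group)), function(i) {
    section_states(group$plan[[i]], specs[[i]], positions)
  }, character(length(positions)))
  normal <- states == "normal"
  sheathed <- states != "node"
  if (bare_counts == "absent") sheathed <- sheathed & states != "bare"

  denom <- rowSums(sheathed)
  frac <- rowSums(normal) / ifelse(denom > 0, denom, NA_real_)
  if (all(is.na(frac))) {
    warn("no sheath crossings in any section")
    return(NA_real_)
  }
  100 * mean(frac, na.rm = TRUE)
}

#' Percentage of new (remyelinated) myelin sheaths in a group
#'
#' As [percent_normal_sheaths()], but counting remyelinated parent-segment
#' crossings; each counts twice (a remyelinated segment carries two new
#' sheaths), against the total sheath crossings counted the same way.
#'
#' @inheritParams percent_normal_sheaths
#' @return Percentage in \[0, 100\].
#' @export
percent_new_sheaths <- function(group, stride = 0.5) {
  specs <- lapply(group$plan, attr, "spec")
  lens <- vapply(specs, function(s) {
    s$n_segments * (s$node_length + s$segment_length) + s$node_length
  }, numeric(1))
  positions <- seq(stride / 2, min(lens), by = stride)
  states <- vapply(seq_len(nrow(group)), function(i) {
    section_states(group$plan[[i]], specs[[i]], positions)
  }, character(length(positions)))
  new2 <- 2 * rowSums(states == "remyelinated")
  other <- rowSums(states != "node" & states != "remyelinated")
  denom <- new2 + other
  frac <- new2 / ifelse(denom > 0, denom, NA_real_)
  if (all(is.na(frac))) {
    warn("no sheath crossings in any section")
    return(NA_real_)
  }
  100 * mean(frac, na.rm = TRUE)
}

#' Failure histogram of a mixed axon group
#'
#' Maps each group member to its failure probability: intact members fail
#' with probability 0; perturbed members take the per-axon failure
#' probability measured in the corresponding grid cell (matched on axon
#' and segment fraction).
#'
#' @param group an `axon_group`.
#' @param grid demyelination (or remyelination) response grid covering the
#'   group's conditions.
#' @param binwidth histogram bin width.
#' @return A `failure_histogram` tibble.
#' @export
group_failure_histogram <- function(group, grid, binwidth = 0.05) {
  key <- if ("segment_fraction" %in% names(grid)) "segment_fraction" else "demyel_fraction"
  per_axon <- grid %>%
    filter(.data$complete) %>%
    group_by(.data$axon_id, .data[[key]]) %>%
    summarise(p_fail = mean(.data$ap_failure_pct, na.rm = TRUE) / 100,
              .groups = "drop")
  p <- vapply(seq_len(nrow(group)), function(i) {
    if (group$status[i] == "intact") return(0)
    hit <- per_axon[per_axon$axon_id == group$axon_id[i] &
                      per_axon[[key]] == group$segment_fraction[i], ]
    if (nrow(hit) == 0) {
      abort(sprintf("no grid cell for axon %d at fraction %.2f",
                    group$axon_id[i], group$segment_fraction[i]))
    }
    hit$p_fail[1]
  }, numeric(1))
  binned <- round(p / binwidth) * binwidth
  tab <- table(binned)
  out <- tibble(p_failure = as.numeric(names(tab)),
                fraction = as.vector(tab) / length(p),
                n_axons = as.vector(tab))
  attr(out, "provenance") <- "cohort-run"
  class(out) <- c("failure_histogram", class(out))
  out
}

#' Sheath composition versus working-memory performance
#'
#' For each axon group: quantify its sheath composition (percent normal
#' sheaths for demyelination experiments, percent new sheaths for
#' remyelination experiments), map its members' failure probabilities onto
#' one base network, simulate delayed-response trials, and regress memory
#' duration and diffusion on composition.
#'
#' @param groups list of `axon_group`s.
#' @param grid response grid supplying per-axon failure probabilities.
#' @param params,conn the base network ([ring_params()], one designated
#'   control connectivity).
#' @param composition `"normal"` or `"new"` sheath percentage on the x
#'   axis.
#' @param n_trials trials per group.
#' @param seed base seed.
#' @param cue_deg cue angle.
#' @return A list of class `composition_experiment`: per-group tibble
#'   (`group`, `composition_pct`, `duration_s`, `diffusion_deg2_s`) and
#'   the Pearson r and linear-fit slopes of both measures against
#'   composition.
#' @export
run_composition_experiment <- function(groups, grid, params, conn,
                                       composition = "normal",
                                       n_trials = 3, seed = 1,
                                       cue_deg = 135) {
  composition <- match.arg(composition, c("normal", "new"))
  rows <- purrr::imap(groups, function(g, i) {
    comp <- if (composition == "normal") {
      percent_normal_sheaths(g)
    } else {
      percent_new_sheaths(g)
    }
    hist <- group_failure_histogram(g, grid)
    pt <- transmission_probabilities(hist, params, seed = seed + i)
    run <- tryCatch(
      run_drt_trials(params, conn, n_trials = n_trials, cue_deg = cue_deg,
                     p_trans = pt, seed = seed + 1000 * i),
      error = function(e) NULL)
    if (is.null(run)) {
      warn(sprintf("group %d simulation failed; dropped", i))
      return(NULL)
    }
    tibble(group = i, composition_pct = comp,
           duration_s = run$summary$duration_s,
           diffusion_deg2_s = run$summary$diffusion_deg2_s)
  })
  res <- dplyr::bind_rows(rows)
  fit1 <- lm(duration_s ~ composition_pct, data = res)
  r1 <- suppressWarnings(cor(res$composition_pct, res$duration_s))
  ok2 <- !is.na(res$diffusion_deg2_s)
  fit2 <- lm(diffusion_deg2_s ~ composition_pct, data = res[ok2, ])
  r2 <- suppressWarnings(cor(res$composition_pct[ok2],
                             res$diffusion_deg2_s[ok2]))
  structure(list(groups = res, composition = composition,
                 duration_r = r1, duration_slope = unname(coef(fit1)[2]),
                 diffusion_r = r2, diffusion_slope = unname(coef(fit2)[2])),
            class = "composition_experiment")
}

#' @export
print.composition_experiment <- function(x, ...) {
  cat(sprintf(
    "<composition_experiment> %d groups vs %% %s sheaths: duration r = %.3f, diffusion r = %.3f\n",
    nrow(x$groups), x$composition, x$duration_r, x$diffusion_r))
  invisible(x)
}
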