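#' Conduction-velocity change under a perturbation
#'
#' Percentage change relative to the unperturbed model:
#' `100 * (cv_perturbed - cv_control) / cv_control`. A control CV of 1 m/s
#' falling to 0.6 m/s is a change of -40%. When the perturbed model
#' propagates no action potentials (`cv_perturbed` is `NA`), the change is
#' coded as -100% (the coding the regression responses use).
#'
#' @param cv_control,cv_perturbed conduction velocities, m/s.
#' @return Percentage (negative = slowing).
#' @export
#' @examples
#' cv_change(1.0, 0.6)   # -40
cv_change <- function(cv_control, cv_perturbed) {
  if (is.na(cv_control) || cv_control <= 0) {
    warn("control CV undefined; cv_change is NA")
    return(NA_real_)
  }
  if (is.na(cv_perturbed)) return(-100)
  100 * (cv_perturbed - cv_control) / cv_control
}

#' Conduction-velocity recovery under remyelination
#'
#' Percentage improvement relative to the change of the completely
#' demyelinated case: `100 * (cv_remyel - cv_demyel) / (cv_control -
#' cv_demyel)`. A model with control CV 1 m/s, 0.6 m/s after complete
#' demyelination, and 0.8 m/s after remyelination has recovered 50%.
#' Values above 100% occur for the rare models whose CV rises above
#' control after remyelination.
#'
#' @param cv_control,cv_demyel,cv_remyel conduction velocities, m/s; a
#'   failed (`NA`) CV is treated as 0.
#' @return Percentage.
#' @export
#' @examples
#' cv_recovery(1.0, 0.6, 0.8)   # 50
cv_recovery <- function(cv_control, cv_demyel, cv_remyel) {
  if (is.na(cv_control)) {
    warn("control CV undefined; cv_recovery is NA")
    return(NA_real_)
  }
  if (is.na(cv_demyel)) cv_demyel <- 0
  if (is.na(cv_remyel)) cv_remyel <- 0
  if (cv_control == cv_demyel) {
    warn("no demyelination-induced CV change; cv_recovery undefined")
    return(NA_real_)
  }
  100 * (cv_remyel - cv_demyel) / (cv_control - cv_demyel)
}

# simulate one perturbed axon and measure cv / failures
perturbed_response <- function(spec, plan, protocol, spike_threshold = 0) {
  gr <- build_axon(spec, plan)
  ev <- evaluate_axon(gr, protocol, spike_threshold = spike_threshold,
                      check_silence = FALSE)
  ev[, c("cv_m_per_s", "ap_failure_pct", "n_first", "n_distal")]
}

cohort_constants <- function(cohort, constants) {
  constants %||% attr(cohort, "constants") %||% axon_constants()
}

#' Demyelination response grid
#'
#' Full cross of segment fractions x lamellae-removal fractions x
#' randomized trials x cohort axons. For every cell the perturbed axon is
#' rebuilt and simulated under the standard protocol; the tidy result rows
#' carry the measured CV, the CV change relative to that axon's
#' unperturbed CV (complete propagation failure coded -100%), and the
#' failure percentage. Segment lists are shared across removal fractions
#' (and axons) within a trial. Failed simulation cells are kept as `NA`
#' rows with `complete = FALSE` rather than dropped.
#'
#' @param cohort a [build_cohort()] / [select_models()] tibble (its
#'   `cv_m_per_s` column is the unperturbed reference).
#' @param segment_fractions fractions of segments demyelinated (reference
#'   grid: 0.10, 0.25, 0.50, 0.75).
#' @param removal_fractions fractions of lamellae removed (reference grid:
#'   0.25, 0.50, 0.55, 0.60, 0.65, 0.70, 0.75, 1.00).
#' @param n_trials randomized segment lists per fraction (reference: 30).
#' @param seed seed for the segment lists.
#' @param protocol an [axon_protocol()].
#' @param constants an [axon_constants()]; defaults to the cohort's.
#' @param n_segments segments per axon.
#' @param progress print a line per axon x fraction.
#' @return Tidy tibble: `axon_id`, `segment_fraction`, `removal_fraction`,
#'   `trial`, `cv_m_per_s`, `cv_change`, `ap_failure_pct`, `n_first`,
#'   `n_distal`, `complete`.
#' @export
run_demyelination_grid <- function(cohort,
                                   segment_fractions = c(0.10, 0.25, 0.50, 0.75),
                                   removal_fractions = c(0.25, 0.50, 0.55, 0.60,
                                                         0.65, 0.70, 0.75, 1.00),
                                   n_trials = 30, seed = 1,
                                   protocol = axon_protocol(),
                                   constants = NULL, n_segments = 100,
                                   progress = FALSE) {
  constants <- cohort_constants(cohort, constants)
  out <- list()
  for (sf in segment_fractions) {
    lists <- draw_segment_lists(n_segments, sf, n_trials, seed)
    for (ai in seq_len(nrow(cohort))) {
      row <- cohort[ai, ]
      spec <- spec_from_row(row, constants, n_segments)
      if (progress) {
        cat(sprintf("axon %d, %d%% of segments\n", row$axon_id, round(100 * sf)))
      }
      for (tr in seq_len(n_trials)) {
        for (rf in removal_fractions) {
          plan <- demyelinate(perturbation_plan(spec), lists[[tr]], rf)
          res <- tryCatch(perturbed_response(spec, plan, protocol),
                          error = function(e) NULL)
          ok <- !is.null(res)
          out[[length(out) + 1]] <- tibble(
            axon_id = row$axon_id, segment_fraction = sf,
            removal_fraction = rf, trial = tr,
            cv_m_per_s = if (ok) res$cv_m_per_s else NA_real_,
            cv_change = if (ok) cv_change(row$cv_m_per_s, res$cv_m_per_s) else NA_real_,
            ap_failure_pct = if (ok) {
              if (res$n_first > 0) res$ap_failure_pct else NA_real_
            } else NA_real_,
            n_first = if (ok) res$n_first else NA_integer_,
            n_distal = if (ok) res$n_distal else NA_integer_,
            complete = ok)
        }
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Remyelination response grid
#'
#' Crosses initial demyelination fractions, remyelination fractions, and
#' lamellae-restoration fractions over randomized trials and cohort axons.
#' The initially demyelinated segments lose either all lamellae
#' (`initial = "complete"`) or half (`initial = "partial"`); the selected
#' fraction of them is then replaced by two half-length child segments
#' (with `restore_fraction` of the original lamellae each) and a new node.
#' CV recovery is measured against the completely demyelinated case of the
#' same axon/fraction/trial, which is simulated once per trial and reused
#' (it also provides the 0%-remyelination consistency column).
#'
#' @inheritParams run_demyelination_grid
#' @param demyel_fractions initial demyelination fractions (reference:
#'   0.25, 0.50, 0.75).
#' @param remyel_fractions fractions of the demyelinated segments
#'   remyelinated (reference: 0.25, 0.50, 0.75, 1.00).
#' @param restore_fractions lamellae restoration fractions (reference:
#'   0.10, 0.25, 0.50, 0.75).
#' @param initial `"complete"` or `"partial"` initial demyelination.
#' @return Tidy tibble: `axon_id`, `initial`, `demyel_fraction`,
#'   `remyel_fraction`, `restore_fraction`, `trial`, `cv_m_per_s`,
#'   `cv_demyel`, `cv_recovery`, `ap_failure_pct`, `complete`.
#' @export
run_remyelination_grid <- function(cohort,
                                   demyel_fractions = c(0.25, 0.50, 0.75),
                                   remyel_fractions = c(0.25, 0.50, 0.75, 1.00),
                                   restore_fractions = c(0.10, 0.25, 0.50, 0.75),
                                   initial = "complete",
                                   n_trials = 30, seed = 1,
                                   protocol = axon_protocol(),
                                   constants = NULL, n_segments = 100,
                                   progress = FALSE) {
  initial <- match.arg(initial, c("complete", "partial"))
  init_removal <- if (initial == "complete") 1.0 else 0.5
  constants <- cohort_constants(cohort, constants)
  out <- list()
  for (df in demyel_fractions) {
    lists <- draw_segment_lists(n_segments, df, n_trials, seed)
    for (ai in seq_len(nrow(cohort))) {
      row <- cohort[ai, ]
      spec <- spec_from_row(row, constants, n_segments)
      if (progress) {
        cat(sprintf("axon %d, %d%% initially demyelinated (%s)\n",
                    row$axon_id, round(100 * df), initial))
      }
      for (tr in seq_len(n_trials)) {
        # reference: complete demyelination of the same segment list
        plan_ref <- demyelinate(perturbation_plan(spec), lists[[tr]], 1.0)
        ref <- tryCatch(perturbed_response(spec, plan_ref, protocol),
                        error = function(e) NULL)
        cv_dem <- if (!is.null(ref)) ref$cv_m_per_s else NA_real_
        base_plan <- demyelinate(perturbation_plan(spec), lists[[tr]],
                                 init_removal)
        for (rmf in remyel_fractions) {
          for (rsf in restore_fractions) {
            plan <- tryCatch(
              remyelinate(base_plan, spec$n_lamellae, rmf, rsf),
              error = function(e) NULL)
            res <- if (is.null(plan)) NULL else {
              tryCatch(perturbed_response(spec, plan, protocol),
                       error = function(e) NULL)
            }
            ok <- !is.null(res)
            out[[length(out) + 1]] <- tibble(
              axon_id = row$axon_id, initial = initial,
              demyel_fraction = df, remyel_fraction = rmf,
              restore_fraction = rsf, trial = tr,
              cv_m_per_s = if (ok) res$cv_m_per_s else NA_real_,
              cv_demyel = cv_dem,
              cv_recovery = if (ok) {
                cv_recovery(row$cv_m_per_s, cv_dem, res$cv_m_per_s)
              } else NA_real_,
              ap_failure_pct = if (ok) {
                if (res$n_first > 0) res$ap_failure_pct else NA_real_
              } else NA_real_,
              complete = ok)
          }
        }
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Cell means of a response grid
#'
#' Mean and standard error over axons and trials for each condition cell.
#'
#' @param grid result of [run_demyelination_grid()] or
#'   [run_remyelination_grid()].
#' @param response column to summarize (default `cv_change` when present,
#'   else `cv_recovery`).
#' @return Tibble of cell means with `mean`, `sem`, `n`.
#' @export
grid_cell_means <- function(grid, response = NULL) {
  response <- response %||%
    (if ("cv_change" %in% names(grid)) "cv_change" else "cv_recovery")
  keys <- intersect(c("segment_fraction", "removal_fraction", "initial",
                      "demyel_fraction", "remyel_fraction",
                      "restore_fraction"), names(grid))
  grid %>%
    group_by(across(all_of(keys))) %>%
    summarise(
      mean = mean(.data[[response]], na.rm = TRUE),
      sem = sd(.data[[response]], na.rm = TRUE) /
        sqrt(sum(!is.na(.data[[response]]))),
      mean_failure = mean(.data$ap_failure_pct, na.rm = TRUE),
      n = dplyr::n(), .groups = "drop")
}
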