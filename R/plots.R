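#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_tile
#'   geom_raster geom_hline geom_vline geom_smooth labs facet_wrap
#'   scale_fill_gradient2 theme_minimal annotate
NULL

#' @export
ggplot2::autoplot

#' Plot membrane-potential traces of an axon simulation
#'
#' @param object an [simulate_axon()] result.
#' @param ... unused.
#' @return A ggplot: one panel per probe, step onset/offset marked.
#' @export
autoplot.axon_sim <- function(object, ...) {
  ggplot(object$traces, aes(x = .data$time_ms, y = .data$v_mv)) +
    geom_line(linewidth = 0.3) +
    geom_vline(xintercept = c(object$t_on, object$t_off),
               linetype = "dotted", colour = "grey50") +
    facet_wrap(~probe, ncol = 1, scales = "free_y") +
    labs(x = "time (ms)", y = "membrane potential (mV)") +
    theme_minimal()
}

#' Heat map of a demyelination response grid
#'
#' Cell-mean CV change (or failure percentage) by segment fraction and
#' lamellae-removal fraction.
#'
#' @param grid result of [run_demyelination_grid()].
#' @param response `"cv_change"` or `"ap_failure_pct"`.
#' @return A ggplot.
#' @export
plot_demyelination_grid <- function(grid, response = "cv_change") {
  cells <- grid_cell_means(grid, response = response)
  ggplot(cells, aes(x = factor(100 * .data$removal_fraction),
                    y = factor(100 * .data$segment_fraction),
                    fill = .data$mean)) +
    geom_tile() +
    scale_fill_gradient2(low = "black", mid = "red", high = "white",
                         midpoint = min(0, min(cells$mean) / 2)) +
    labs(x = "% lamellae removed", y = "% segments demyelinated",
         fill = response) +
    theme_minimal()
}

#' Plot a spike raster of one trial
#'
#' @param object a `drt_trial`.
#' @param max_points subsample cap for plotting.
#' @param ... unused.
#' @return A ggplot of the excitatory raster (neurons labeled by preferred
#'   direction), cue period shaded.
#' @export
autoplot.drt_trial <- function(object, max_points = 2e5, ...) {
  sp <- object$spikes
  if (nrow(sp) > max_points) {
    sp <- sp[seq(1, nrow(sp), length.out = max_points), ]
  }
  sp$theta <- 360 * sp$neuron / object$NE
  ggplot(sp, aes(x = .data$time_ms / 1e3, y = .data$theta)) +
    annotate("rect", xmin = object$fixation_ms / 1e3,
             xmax = (object$fixation_ms + object$cue_ms) / 1e3,
             ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "grey40") +
    geom_point(size = 0.05, alpha = 0.25, shape = ".") +
    geom_hline(yintercept = object$cue_deg, colour = "red",
               linetype = "dashed", linewidth = 0.3) +
    labs(x = "time (s)", y = "preferred direction (deg)") +
    theme_minimal()
}

#' Plot memory strength and decoded location of a trajectory
#'
#' @param object a [decode_trajectory()] result.
#' @param threshold memory-strength threshold to mark.
#' @param ... unused.
#' @return A ggplot with M(t) and the decoded angle.
#' @export
autoplot.bump_trajectory <- function(object, threshold = 0.4, ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(as_tibble(object), "t_mid_ms", "M", "phi_deg"),
    c("M", "phi_deg"), names_to = "what", values_to = "value")
  hline <- tibble(what = c("M", "phi_deg"),
                  y = c(threshold, attr(object, "cue_deg")))
  ggplot(df, aes(x = .data$t_mid_ms / 1e3, y = .data$value)) +
    geom_line() +
    geom_hline(data = hline, aes(yintercept = .data$y),
               linetype = "dashed", colour = "red", linewidth = 0.3) +
    facet_wrap(~what, ncol = 1, scales = "free_y",
               labeller = ggplot2::as_labeller(
                 c(M = "memory strength", phi_deg = "decoded angle (deg)"))) +
    labs(x = "time (s)", y = NULL) +
    theme_minimal()
}

#' Scatter of working-memory performance against sheath composition
#'
#' @param object a [run_composition_experiment()] result.
#' @param ... unused.
#' @return A ggplot with linear fits for duration and diffusion.
#' @export
autoplot.composition_experiment <- function(object, ...) {
  df <- tidyr::pivot_longer(object$groups,
                            c("duration_s", "diffusion_deg2_s"),
                            names_to = "measure", values_to = "value")
  ggplot(df, aes(x = .data$composition_pct, y = .data$value)) +
    geom_point() +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                linewidth = 0.4, colour = "red") +
    facet_wrap(~measure, scales = "free_y") +
    labs(x = sprintf("%% %s myelin sheaths", object$composition), y = NULL) +
    theme_minimal()
}
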