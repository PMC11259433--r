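#' Parametric failure-histogram fixture
#'
#' Synthetic cohort-level distribution of failure probabilities: a point
#' mass at zero failure with weight `w` (the intact or robust neurons)
#' mixed with Beta(`a`, `b`)-distributed failure probabilities with weight
#' `1 - w` (the perturbed neurons). Emulates the bimodal histograms the
#' single-neuron cohort produces, so the network layer can be exercised
#' and tested without running the axon layer.
#'
#' @param w weight of the zero-failure point mass, in \[0, 1\].
#' @param a,b Beta shape parameters (> 0).
#' @param n_draws Beta draws used to populate the bins.
#' @param binwidth histogram bin width.
#' @param seed RNG seed.
#' @return A `failure_histogram` tibble with `provenance = "fixture"`.
#' @export
#' @examples
#' fixture_failure_histogram(w = 1)            # control: all intact
#' fixture_failure_histogram(0.6, 2, 2, seed = 7)
fixture_failure_histogram <- function(w, a = 2, b = 2, n_draws = 200,
                                      binwidth = 0.05, seed = 1) {
  if (w < 0 || w > 1) abort("w must lie in [0, 1]")
  if (w < 1 && (a <= 0 || b <= 0)) abort("Beta parameters must be positive")
  if (w >= 1) {
    out <- tibble(p_failure = 0, fraction = 1, n_axons = n_draws)
  } else {
    draws <- withr::with_seed(seed, rbeta(n_draws, a, b))
    binned <- round(draws / binwidth) * binwidth
    n0 <- round(w * n_draws / (1 - w))
    all_p <- c(rep(0, n0), binned)
    tab <- table(all_p)
    out <- tibble(p_failure = as.numeric(names(tab)),
                  fraction = as.vector(tab) / length(all_p),
                  n_axons = as.vector(tab))
  }
  attr(out, "provenance") <- "fixture"
  class(out) <- c("failure_histogram", class(out))
  out
}

#' Synthetic bump trajectories (Brownian drift-diffusion fixture)
#'
#' Decoded-location trajectories built directly from the generative model
#' the drift/diffusion estimators assume: `Phi(t) = theta_cue + b t + W(t)`
#' with linear bias rate `b` (deg/s) and Brownian increments of variance
#' rate `v` (deg^2/s), sampled on the decoding-window grid; memory
#' strength is held at a constant supra-threshold value. Used to verify
#' estimator calibration (parameter recovery) independently of the
#' network.
#'
#' @param n_trials number of trajectories.
#' @param v diffusion variance rate, deg^2/s.
#' @param bias drift rate, deg/s.
#' @param cue_deg cue angle.
#' @param delay_s,fixation_s,cue_s epochs (s).
#' @param window_ms decoding window.
#' @param M constant memory strength of the fixture.
#' @param seed RNG seed.
#' @return List of `bump_trajectory` tibbles (as [decode_trajectory()]).
#' @export
synthetic_bump_trajectories <- function(n_trials, v, bias = 0,
                                        cue_deg = 135, delay_s = 4,
                                        fixation_s = 2, cue_s = 1,
                                        window_ms = 250, M = 0.8,
                                        seed = 1) {
  t_total <- (fixation_s + cue_s + delay_s) * 1e3
  tmid <- seq(window_ms / 2, t_total - window_ms / 2, by = window_ms)
  delay_on <- (fixation_s + cue_s) * 1e3
  epoch <- dplyr::case_when(tmid < fixation_s * 1e3 ~ "fixation",
                            tmid < delay_on ~ "cue",
                            TRUE ~ "delay")
  dt_s <- window_ms / 1e3
  withr::with_seed(seed, {
    lapply(seq_len(n_trials), function(i) {
      phi <- rep(cue_deg, length(tmid))
      idx <- which(epoch == "delay")
      ts <- (tmid[idx] - delay_on) / 1e3
      incr <- rnorm(length(idx), mean = bias * dt_s, sd = sqrt(v * dt_s))
      phi[idx] <- cue_deg + bias * (ts[1] - dt_s / 2) * 0 + cumsum(incr)
      tr <- tibble(t_mid_ms = tmid, M = M, psi_deg = phi %% 360,
                   phi_deg = phi, epoch = epoch)
      attr(tr, "cue_deg") <- cue_deg
      attr(tr, "delay_on_ms") <- delay_on
      attr(tr, "delay_ms") <- delay_s * 1e3
      attr(tr, "unwrap_ok") <- TRUE
      class(tr) <- c("bump_trajectory", class(tr))
      tr
    })
  })
}
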