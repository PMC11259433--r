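#' Windowed firing-rate estimates from a spike raster
#'
#' Spike counts in tiled windows (default 250 ms), converted to Hz, for
#' every excitatory neuron. Empty rasters give all-zero rates.
#'
#' @param trial a `drt_trial` (or a tibble with `neuron`, `time_ms`).
#' @param n_neurons number of neurons (taken from the trial when given).
#' @param window_ms window length.
#' @param t_total_ms raster duration (taken from the trial when given).
#' @return A list: `rates` (matrix, windows x neurons, Hz), `t_mid`
#'   (window centers, ms).
#' @export
rate_estimate <- function(trial, n_neurons = NULL, window_ms = 250,
                          t_total_ms = NULL) {
  if (inherits(trial, "drt_trial")) {
    spikes <- trial$spikes
    n_neurons <- trial$NE
    t_total_ms <- trial$t_total_ms
  } else {
    spikes <- trial
    if (is.null(n_neurons) || is.null(t_total_ms)) {
      abort("n_neurons and t_total_ms are required for a bare raster")
    }
  }
  nw <- max(1L, floor(t_total_ms / window_ms))
  win <- pmin(nw - 1L, floor(spikes$time_ms / window_ms))
  keep <- spikes$time_ms < nw * window_ms
  counts <- matrix(0L, nw, n_neurons)
  if (any(keep)) {
    ij <- win[keep] + nw * spikes$neuron[keep]  # 0-based linear index
    tab <- tabulate(ij + 1L, nbins = nw * n_neurons)
    counts <- matrix(tab, nw, n_neurons)
  }
  list(rates = counts * (1000 / window_ms),
       t_mid = (seq_len(nw) - 0.5) * window_ms)
}

#' Population vector of a rate profile
#'
#' Complex resultant of the firing-rate profile over preferred directions:
#' `Z = sum(r_j exp(i theta_j)) / sum(r_j) = M exp(i Psi)`. The modulus M
#' in \[0, 1\] is the memory strength (0 = homogeneous activity, 1 = a
#' single sharp location); the argument Psi is the decoded location.
#'
#' @param rates numeric vector of rates (one per neuron), or a matrix
#'   (windows x neurons) for a whole trajectory.
#' @param theta_deg preferred directions, degrees (default evenly spaced).
#' @return For a vector: list `M`, `psi_deg` (`NA` with a flag when all
#'   rates are zero). For a matrix: tibble with one row per window.
#' @export
#' @examples
#' population_vector(c(0, 0, 5, 0), theta_deg = c(0, 90, 135, 270))
population_vector <- function(rates, theta_deg = NULL) {
  if (is.matrix(rates)) {
    nn <- ncol(rates)
    if (is.null(theta_deg)) theta_deg <- 360 * (seq_len(nn) - 1) / nn
    e <- exp(1i * theta_deg * pi / 180)
    tot <- rowSums(rates)
    z <- as.vector(rates %*% e) / ifelse(tot > 0, tot, NA_real_)
    return(tibble(M = Mod(z), psi_deg = (Arg(z) * 180 / pi) %% 360,
                  total_rate = tot))
  }
  if (is.null(theta_deg)) theta_deg <- 360 * (seq_along(rates) - 1) / length(rates)
  tot <- sum(rates)
  if (tot <= 0) {
    return(list(M = NA_real_, psi_deg = NA_real_, flag = "all rates zero"))
  }
  z <- sum(rates * exp(1i * theta_deg * pi / 180)) / tot
  list(M = Mod(z), psi_deg = (Arg(z) * 180 / pi) %% 360, flag = NA_character_)
}

#' Decode the bump trajectory of one trial
#'
#' Windowed rates, population vector per window, and the per-trial decoded
#' location `Phi(t)` unwrapped for continuity starting from the cue angle
#' (the variance analyses need unwrapped angles; an attribute records if
#' any window strayed more than 150 degrees from the cue, which would make
#' unwrapping against the cue unreliable).
#'
#' @param trial a `drt_trial`.
#' @param window_ms decoding window (default 250 ms).
#' @return A tibble of class `bump_trajectory`: `t_mid_ms`, `M`, `psi_deg`,
#'   `phi_deg` (unwrapped), `epoch` (fixation/cue/delay), with the cue
#'   angle and epochs as attributes.
#' @export
decode_trajectory <- function(trial, window_ms = 250) {
  re <- rate_estimate(trial, window_ms = window_ms)
  pv <- population_vector(re$rates)
  # unwrap relative to the cue: each window's decoded angle mapped into
  # (cue - 180, cue + 180], then chained for continuity
  phi <- pv$psi_deg
  ref <- trial$cue_deg
  out <- numeric(length(phi))
  for (i in seq_along(phi)) {
    if (is.na(phi[i])) {
      out[i] <- NA_real_
      next
    }
    d <- phi[i] - ref
    d <- d - 360 * round(d / 360)
    out[i] <- ref + d
    ref <- out[i]
  }
  epoch <- dplyr::case_when(
    re$t_mid < trial$fixation_ms ~ "fixation",
    re$t_mid < trial$fixation_ms + trial$cue_ms ~ "cue",
    TRUE ~ "delay"
  )
  tr <- tibble(t_mid_ms = re$t_mid, M = pv$M, psi_deg = pv$psi_deg,
               phi_deg = out, epoch = epoch)
  attr(tr, "cue_deg") <- trial$cue_deg
  attr(tr, "delay_on_ms") <- trial$fixation_ms + trial$cue_ms
  attr(tr, "delay_ms") <- trial$delay_ms
  delay_phi <- out[epoch == "delay"]
  attr(tr, "unwrap_ok") <- all(is.na(delay_phi) |
                                 abs(delay_phi - trial$cue_deg) <= 150)
  class(tr) <- c("bump_trajectory", class(tr))
  tr
}

#' Memory duration from a memory-strength series
#'
#' Time from delay onset until the memory strength first falls below the
#' threshold (default 0.4); the full delay length when it never does.
#' Windows whose population vector is undefined (no spikes) count as below
#' threshold.
#'
#' @param traj a [decode_trajectory()] result, or a tibble with `t_mid_ms`,
#'   `M`, `epoch`.
#' @param threshold memory-strength threshold.
#' @param delay_on_ms,delay_ms delay epoch (taken from `traj` attributes
#'   when present).
#' @return Duration in seconds.
#' @export
memory_duration <- function(traj, threshold = 0.4, delay_on_ms = NULL,
                            delay_ms = NULL) {
  delay_on_ms <- delay_on_ms %||% attr(traj, "delay_on_ms")
  delay_ms <- delay_ms %||% attr(traj, "delay_ms")
  d <- traj[traj$epoch == "delay", ]
  below <- is.na(d$M) | d$M < threshold
  if (!any(below)) return(delay_ms / 1e3)
  j <- which(below)[1]
  # crossing time interpolated between window centers (the window before
  # the first sub-threshold one is above threshold by construction)
  if (j == 1) {
    t_cross <- d$t_mid_ms[1] - (d$t_mid_ms[2] - d$t_mid_ms[1]) / 2
  } else if (is.na(d$M[j])) {
    t_cross <- (d$t_mid_ms[j - 1] + d$t_mid_ms[j]) / 2
  } else {
    f <- (d$M[j - 1] - threshold) / (d$M[j - 1] - d$M[j])
    t_cross <- d$t_mid_ms[j - 1] + f * (d$t_mid_ms[j] - d$t_mid_ms[j - 1])
  }
  min(delay_ms, max(0, (t_cross - delay_on_ms))) / 1e3
}

#' Drift and diffusion of the decoded location across trials
#'
#' Across-trial bias `b(t) = <Phi(t)> - theta_cue` and variance
#' `sigma2(t) = <(Phi(t) - <Phi(t)>)^2>` of the unwrapped decoded location,
#' per window, plus the drift rate (deg/s) and diffusion constant
#' (deg^2/s) as slopes of least-squares linear fits over the delay windows
#' within the cohort memory duration (windows where the across-trial mean
#' memory strength stays at or above the threshold).
#'
#' @param trajectories list of [decode_trajectory()] results from repeated
#'   trials of the same cue and condition.
#' @param threshold memory-strength threshold bounding the fit region.
#' @return A list: `by_window` tibble (`t_mid_ms`, `mean_M`, `bias_deg`,
#'   `var_deg2`, `n_trials`), `drift_rate_deg_s`, `diffusion_deg2_s`,
#'   `duration_s` (mean over trials), `flag`.
#' @export
drift_and_diffusion <- function(trajectories, threshold = 0.4) {
  stopifnot(length(trajectories) >= 2)
  cue <- attr(trajectories[[1]], "cue_deg")
  delay_on <- attr(trajectories[[1]], "delay_on_ms")
  phi <- sapply(trajectories, function(tr) tr$phi_deg)
  m <- sapply(trajectories, function(tr) tr$M)
  tmid <- trajectories[[1]]$t_mid_ms
  epoch <- trajectories[[1]]$epoch
  mean_m <- rowMeans(m, na.rm = TRUE)
  bias <- rowMeans(phi, na.rm = TRUE) - cue
  v <- apply(phi, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) return(NA_real_)
    mean((x - mean(x))^2)
  })
  by_window <- tibble(t_mid_ms = tmid, epoch = epoch, mean_M = mean_m,
                      bias_deg = bias, var_deg2 = v,
                      n_trials = length(trajectories))
  fit_rows <- which(epoch == "delay" & mean_m >= threshold & !is.na(v))
  flag <- NA_character_
  drift <- diff_const <- NA_real_
  if (length(fit_rows) < 3) {
    flag <- "fewer than 3 windows within the memory duration"
  } else {
    ts <- (tmid[fit_rows] - delay_on) / 1e3
    drift <- unname(coef(lm(bias[fit_rows] ~ ts))[2])
    diff_const <- unname(coef(lm(v[fit_rows] ~ ts))[2])
  }
  durations <- vapply(trajectories, memory_duration, numeric(1),
                      threshold = threshold)
  list(by_window = by_window, drift_rate_deg_s = drift,
       diffusion_deg2_s = diff_const, duration_s = mean(durations),
       flag = flag)
}

#' Run repeated delayed-response trials and summarize performance
#'
#' Convenience wrapper: simulates `n_trials` trials (seeds `seed + 0:n`),
#' decodes each, and returns per-trial metrics plus the across-trial drift
#' and diffusion estimates.
#'
#' @inheritParams simulate_drt_trial
#' @param n_trials number of trials.
#' @param window_ms decoding window.
#' @param threshold memory-strength threshold.
#' @return A list of class `drt_run`: `trials` tibble (trial, seed,
#'   duration_s, mean_delay_M), `summary` from [drift_and_diffusion()],
#'   and the trajectories.
#' @export
run_drt_trials <- function(params, conn, n_trials = 10, cue_deg = 135,
                           p_trans = NULL, delay_max_ms = 0, seed = 1,
                           window_ms = 250, threshold = 0.4) {
  trajs <- vector("list", n_trials)
  rows <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    tr <- simulate_drt_trial(params, conn, cue_deg = cue_deg,
                             p_trans = p_trans,
                             delay_max_ms = delay_max_ms,
                             seed = seed + i - 1L)
    trajs[[i]] <- decode_trajectory(tr, window_ms = window_ms)
    rows[[i]] <- tibble(
      trial = i, seed = seed + i - 1L,
      duration_s = memory_duration(trajs[[i]], threshold = threshold),
      mean_delay_M = mean(trajs[[i]]$M[trajs[[i]]$epoch == "delay"],
                          na.rm = TRUE))
  }
  summ <- drift_and_diffusion(trajs, threshold = threshold)
  structure(list(trials = dplyr::bind_rows(rows), summary = summ,
                 trajectories = trajs, cue_deg = cue_deg),
            class = "drt_run")
}

#' @export
print.drt_run <- function(x, ...) {
  cat(sprintf(
    "<drt_run> %d trials, cue %g deg: mean duration %.2f s, diffusion %.4g deg^2/s, drift %.3g deg/s\n",
    nrow(x$trials), x$cue_deg, x$summary$duration_s,
    x$summary$diffusion_deg2_s, x$summary$drift_rate_deg_s))
  invisible(x)
}
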