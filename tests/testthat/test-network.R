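# Ring connectivity, LIF/STP dynamics, transmission failures, delays, and
# the correlated-input variant. Property tests run on a reduced ring
# (4000 neurons) with the full in-degree; the full-size network is
# exercised by the acceptance tests.

test_that("realized in-degrees match the binomial expectation", {
  p <- get_small_params()
  conn <- get_small_conn()
  indeg_e <- tabulate(conn$ee_idx + 1L, nbins = p$NE)
  expect_equal(mean(indeg_e), p$KE,
               tolerance = 3 * sqrt(p$KE / p$NE) / p$KE)
  indeg_i <- tabulate(conn$ie_idx + 1L, nbins = p$NE)
  expect_equal(mean(indeg_i), p$KI, tolerance = 3 * sqrt(p$KI / p$NE) / p$KI)
  expect_identical(conn$ee_idx,
                   build_ring_connectivity(p, seed = 3)$ee_idx)
})

test_that("connection probability peaks at zero angular distance", {
  p <- get_small_params()
  conn <- get_small_conn()
  # empirical connection counts by |target - source| ring distance
  src <- rep(seq_len(p$NE) - 1L, diff(conn$ee_ptr))
  d <- abs(conn$ee_idx - src)
  d <- pmin(d, p$NE - d) * 360 / p$NE
  h <- hist(d, breaks = seq(0, 180, by = 15), plot = FALSE)$counts
  expect_equal(which.max(h), 1)
  expect_true(all(diff(h) <= 0))
  # sigma -> infinity limit: flat profile at K/N
  pu <- ring_params(NE = 1600, NI = 400, KE = 400, KI = 100,
                    sigma_ee = 1e6, sigma_ei = 1e6, sigma_ie = 1e6,
                    sigma_ii = 1e6)
  cu <- build_ring_connectivity(pu, seed = 5)
  su <- rep(seq_len(pu$NE) - 1L, diff(cu$ee_ptr))
  du <- abs(cu$ee_idx - su)
  du <- pmin(du, pu$NE - du) * 360 / pu$NE
  hu <- hist(du, breaks = seq(0, 180, by = 45), plot = FALSE)$counts
  expect_lt(max(abs(hu / mean(hu) - 1)), 0.05)
})

test_that("identical seeds reproduce the event list exactly", {
  p <- get_small_params()
  conn <- get_small_conn()
  t1 <- simulate_drt_trial(p, conn, cue_deg = 90, seed = 7)
  t2 <- simulate_drt_trial(p, conn, cue_deg = 90, seed = 7)
  expect_identical(t1$spikes, t2$spikes)
  t3 <- simulate_drt_trial(p, conn, cue_deg = 90, seed = 8)
  expect_false(identical(t1$spikes, t3$spikes))
})

test_that("STP stays in bounds and matches the periodic-train fixed point", {
  # disconnected network: each neuron fires periodically under its
  # constant drive, so the u/x update-decay map has a closed-form cycle
  p <- ring_params(NE = 40, NI = 10, KE = 400, KI = 100, fixation_s = 0,
                   cue_s = 0, delay_s = 4)
  conn <- suppressWarnings(build_ring_connectivity(p, seed = 1))
  conn$ee_ptr[] <- 0L; conn$ee_idx <- integer(0)
  conn$ei_ptr[] <- 0L; conn$ei_idx <- integer(0)
  conn$ie_ptr[] <- 0L; conn$ie_idx <- integer(0)
  conn$ii_ptr[] <- 0L; conn$ii_idx <- integer(0)
  tr <- simulate_drt_trial(p, conn, seed = 2)
  expect_true(all(tr$u_final >= p$U - 1e-12 & tr$u_final <= 1))
  expect_true(all(tr$x_final > 0 & tr$x_final <= 1))
  # oracle: iterate the exact between-spike decay + spike update map at the
  # simulated period (the drive is suprathreshold and deterministic)
  sp0 <- tr$spikes$time_ms[tr$spikes$neuron == 0]
  isi <- median(diff(sp0))
  u <- p$U; x <- 1
  for (i in 1:400) {
    u <- p$U + (u - p$U) * exp(-isi / p$tau_f)
    x <- 1 + (x - 1) * exp(-isi / p$tau_d)
    u <- u + p$U * (1 - u)
    x <- x * (1 - u)
  }
  # decay the post-spike state to the end of the simulation (the final
  # state is read between spikes, not at one)
  dt_end <- tr$t_total_ms - max(sp0)
  u <- p$U + (u - p$U) * exp(-dt_end / p$tau_f)
  x <- 1 + (x - 1) * exp(-dt_end / p$tau_d)
  expect_equal(tr$u_final[1], u, tolerance = 0.02)
  expect_equal(tr$x_final[1], x, tolerance = 0.02)
})

test_that("transmission probabilities partition the population as counted", {
  p <- get_small_params()
  h <- tibble(p_failure = c(0, 0.5), fraction = c(0.6, 0.4))
  pt <- transmission_probabilities(h, p, seed = 3)
  expect_equal(sum(pt == 1), round(0.6 * p$NE))
  expect_equal(sum(pt == 0.5), round(0.4 * p$NE))
  expect_error(transmission_probabilities(
    tibble(p_failure = 0, fraction = 0.7), p), "sum to 1")
})

test_that("realized transmission fractions match the assigned probabilities", {
  p <- get_small_params()
  conn <- get_small_conn()
  h <- tibble(p_failure = c(0, 0.4), fraction = c(0.5, 0.5))
  pt <- transmission_probabilities(h, p, seed = 4)
  tr <- simulate_drt_trial(p, conn, p_trans = pt, seed = 5)
  realized <- tr$n_transmitted / tr$n_e_spikes
  # expected fraction weighted by each group's spike count; groups are
  # random so rate differences are second order
  expect_equal(realized, 0.8, tolerance = 0.05)
})

test_that("without transmission the bump cannot outlive the cue", {
  p <- get_small_params()
  conn <- get_small_conn()
  ctrl <- decode_trajectory(simulate_drt_trial(p, conn, seed = 11))
  dead <- decode_trajectory(simulate_drt_trial(
    p, conn, p_trans = rep(0, p$NE), seed = 11))
  expect_gte(memory_duration(ctrl), 3)
  expect_lt(memory_duration(dead), 1)
})

test_that("rotating the cue rotates the decoded trajectory", {
  p <- get_small_params()
  conn <- get_small_conn()
  t1 <- decode_trajectory(simulate_drt_trial(p, conn, cue_deg = 90, seed = 13))
  t2 <- decode_trajectory(simulate_drt_trial(p, conn, cue_deg = 210, seed = 13))
  d1 <- t1[t1$epoch == "delay" & t1$M >= 0.4, ]
  d2 <- t2[t2$epoch == "delay" & t2$M >= 0.4, ]
  rot <- mean(d2$phi_deg) - mean(d1$phi_deg)
  expect_equal(rot, 120, tolerance = 15)
})

test_that("uniform delays up to 40 ms leave performance unchanged", {
  p <- get_small_params()
  conn <- get_small_conn()
  base <- sapply(21:23, function(s) {
    memory_duration(decode_trajectory(simulate_drt_trial(p, conn, seed = s)))
  })
  del <- sapply(21:23, function(s) {
    memory_duration(decode_trajectory(
      simulate_drt_trial(p, conn, delay_max_ms = 40, seed = s)))
  })
  expect_lt(abs(mean(del) - mean(base)), 1)
})

test_that("the correlated-input variant is calibrated and correlates neighbors", {
  p <- get_small_params()
  pv <- correlated_input_variant(p)
  expect_equal(pv$ie_ext, p$ie_ext / 2)
  expect_equal(pv$n_ext, 16000L)
  # calibration identity: Poisson mean input equals the removed drive
  # (per-spike voltage-time integral is the coupling itself)
  per_spike <- pv$g_ext_e
  expect_equal(pv$k_ext * pv$r_ext * 1e-3 * per_spike, 0.5 * p$ie_ext,
               tolerance = 0.02 * 0.5 * p$ie_ext)
  conn <- get_small_conn()
  tr <- simulate_drt_trial(pv, conn, seed = 31)
  # shared structured input: co-fluctuations of population spike counts
  # (50 ms bins over the fixation epoch) are stronger for adjacent groups
  # than for groups on opposite sides of the ring
  grp_counts <- function(lo, hi) {
    s <- tr$spikes[tr$spikes$neuron >= lo & tr$spikes$neuron < hi &
                     tr$spikes$time_ms < 2000, ]
    tabulate(floor(s$time_ms / 50) + 1L, nbins = 40)
  }
  a <- grp_counts(0, 160)
  b <- grp_counts(160, 320)
  c_opp <- grp_counts(p$NE / 2, p$NE / 2 + 160)
  expect_gt(cor(a, b), cor(a, c_opp))
})

test_that("invalid perturbation configurations are rejected", {
  p <- get_small_params()
  conn <- get_small_conn()
  expect_error(simulate_drt_trial(p, conn, p_trans = rep(1.2, p$NE)),
               "\\[0, 1\\]")
  expect_error(simulate_drt_trial(p, conn, p_trans = c(1, 1)), "length NE")
})
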