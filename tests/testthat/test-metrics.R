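# Population-vector decoding and the working-memory performance measures.

fake_trial <- function(spikes, NE = 8, t_total = 7000, cue = 135) {
  structure(list(spikes = spikes, cue_deg = cue, seed = 1, NE = NE, NI = 2,
                 fixation_ms = 2000, cue_ms = 1000, delay_ms = 4000,
                 t_total_ms = t_total),
            class = "drt_trial")
}

test_that("windowed rates are counts over the window in Hz", {
  sp <- tibble(neuron = c(rep(0L, 5), 3L), time_ms = c(1:5 * 40, 260))
  re <- rate_estimate(fake_trial(sp), window_ms = 250)
  expect_equal(re$rates[1, 1], 20)          # 5 spikes / 250 ms
  expect_equal(re$rates[2, 4], 4)
  expect_equal(sum(re$rates), 24)
  empty <- rate_estimate(fake_trial(sp[0, ]), window_ms = 250)
  expect_true(all(empty$rates == 0))
})

test_that("Poisson spike trains give back their rate", {
  r <- 200
  sp <- withr::with_seed(21, {
    t <- cumsum(rexp(20000, r / 1000))
    tibble(neuron = 0L, time_ms = t[t < 7000])
  })
  re <- rate_estimate(fake_trial(sp), window_ms = 250)
  # ~1400 events: the window mean recovers the rate within 3 SEs
  expect_equal(mean(re$rates[, 1]), r, tolerance = 3 * sqrt(r * 7) / (7 * r))
})

test_that("the population vector hits the analytic extremes", {
  expect_equal(population_vector(rep(3, 16))$M, 0, tolerance = 1e-12)
  pv <- population_vector(c(0, 0, 5, 0), theta_deg = c(0, 90, 135, 270))
  expect_equal(pv$M, 1)
  expect_equal(pv$psi_deg, 135)
  z <- population_vector(rep(0, 8))
  expect_true(is.na(z$M))
  expect_match(z$flag, "zero")
})

test_that("a von Mises profile decodes to its center and resultant", {
  th <- 360 * (0:359) / 360
  kappa <- 2
  r <- exp(kappa * cos((th - 90) * pi / 180))
  pv <- population_vector(r, theta_deg = th)
  expect_equal(pv$psi_deg, 90, tolerance = 1e-6)
  # brute-force circular resultant
  z <- sum(r * exp(1i * th * pi / 180)) / sum(r)
  expect_equal(pv$M, Mod(z), tolerance = 1e-12)
})

test_that("the decoder is equivariant under rotation", {
  th <- 360 * (0:99) / 100
  r <- withr::with_seed(22, runif(100))
  p0 <- population_vector(r, th)
  for (delta in c(30, 117, 301)) {
    p1 <- population_vector(r, (th + delta) %% 360)
    expect_equal(p1$M, p0$M, tolerance = 1e-9)
    expect_equal(p1$psi_deg, (p0$psi_deg + delta) %% 360, tolerance = 1e-6)
  }
})

fake_traj <- function(M, phi = NULL, cue = 135) {
  nw <- length(M)
  tmid <- seq(125, by = 250, length.out = nw)
  epoch <- ifelse(tmid < 2000, "fixation", ifelse(tmid < 3000, "cue", "delay"))
  tr <- tibble(t_mid_ms = tmid, M = M,
               psi_deg = (phi %||% rep(cue, nw)) %% 360,
               phi_deg = phi %||% rep(cue, nw), epoch = epoch)
  attr(tr, "cue_deg") <- cue
  attr(tr, "delay_on_ms") <- 3000
  attr(tr, "delay_ms") <- 4000
  tr
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("memory duration is the threshold-crossing time", {
  expect_equal(memory_duration(fake_traj(rep(0.8, 28))), 4)
  # crossing 0.4 exactly at 1.5 s into the delay
  M <- rep(0.8, 28)
  delay_idx <- which(seq(125, by = 250, length.out = 28) >= 3000)
  tt <- (seq(125, by = 250, length.out = 28)[delay_idx] - 3000) / 1e3
  M[delay_idx] <- 0.8 - (0.8 - 0.2) * tt / 3   # hits 0.4 at t = 2 s
  expect_equal(memory_duration(fake_traj(M)), 2, tolerance = 0.01)
  # pointwise-lower strength never lengthens the duration
  M2 <- M - 0.05
  expect_lte(memory_duration(fake_traj(M2)), memory_duration(fake_traj(M)))
})

test_that("drift and diffusion vanish for perfect trajectories", {
  trs <- lapply(1:5, function(i) fake_traj(rep(0.8, 28)))
  s <- drift_and_diffusion(trs)
  expect_equal(s$drift_rate_deg_s, 0, tolerance = 1e-12)
  expect_equal(s$diffusion_deg2_s, 0, tolerance = 1e-12)
  expect_equal(s$duration_s, 4)
})

test_that("a constructed linear bias is recovered exactly", {
  trs <- lapply(1:4, function(i) {
    tmid <- seq(125, by = 250, length.out = 28)
    phi <- ifelse(tmid >= 3000, 135 + 2 * (tmid - 3000) / 1e3, 135)
    fake_traj(rep(0.8, 28), phi = phi)
  })
  s <- drift_and_diffusion(trs)
  expect_equal(s$drift_rate_deg_s, 2, tolerance = 1e-9)
})

test_that("the diffusion estimator is unbiased on Brownian trajectories", {
  # the slope of a Brownian variance curve is a noisy statistic even at
  # 200 trials (the window variances share early increments), so the
  # unbiasedness check averages the estimator over independent batches
  for (v in c(0.05, 0.5, 5)) {
    est <- sapply(1:5, function(b) {
      trs <- synthetic_bump_trajectories(200, v = v,
                                         seed = round(31 + v * 10) + 100 * b)
      drift_and_diffusion(trs)$diffusion_deg2_s
    })
    expect_equal(mean(est), v, tolerance = 0.10)
  }
})

test_that("trajectory fixtures honor their bias and zero-noise limits", {
  trs <- synthetic_bump_trajectories(6, v = 0, bias = 2, seed = 40)
  s <- drift_and_diffusion(trs)
  expect_equal(s$diffusion_deg2_s, 0, tolerance = 1e-9)
  expect_equal(s$drift_rate_deg_s, 2, tolerance = 1e-6)
})
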