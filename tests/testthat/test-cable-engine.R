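# Integrator correctness on problems with independent solutions.

test_that("a passive compartment follows the analytic exponential charging", {
  m <- passive_one(C = 0.1, g = 0.01)
  ss <- myelinwm:::.cable_steady_cpp(m, -70)
  expect_equal(ss$i_hold, 0, tolerance = 1e-10)
  out <- myelinwm:::.cable_integrate_cpp(m, ss$phi, ss$h, ss$n,
                                         dt = 0.025, nsteps = 4000,
                                         i_hold = 0, i_step = 0.1,
                                         t_on = 0, t_off = 1e9,
                                         probe_comps = 0L, theta = 0.5)
  t <- seq(0, 4000) * 0.025
  v_ana <- -70 + (0.1 / 0.01) * (1 - exp(-t / (0.1 / 0.01)))
  # < 0.1% of the 10 mV deflection
  expect_lt(max(abs(out$traces[, 1] - v_ana)), 0.01)
})

test_that("three-compartment cable matches a fine ODE solution", {
  skip_if_not_installed("deSolve")
  m <- passive_three()
  ss <- myelinwm:::.cable_steady_cpp(m, -70)
  out <- myelinwm:::.cable_integrate_cpp(m, ss$phi, ss$h, ss$n,
                                         dt = 0.025, nsteps = 2000,
                                         i_hold = 0, i_step = 0.05,
                                         t_on = 0, t_off = 1e9,
                                         probe_comps = c(0L, 1L, 2L),
                                         theta = 0.5)
  rhs <- function(t, y, p) {
    ia <- c(m$axial_i_g[1] * (y[2] - y[1]),
            m$axial_i_g[1] * (y[1] - y[2]) + m$axial_i_g[2] * (y[3] - y[2]),
            m$axial_i_g[2] * (y[2] - y[3]))
    inj <- c(0.05, 0, 0)
    list((ia + inj - m$g_pas * (y - m$e_pas)) / m$c_ax)
  }
  sol <- deSolve::lsoda(rep(-70, 3), seq(0, 50, by = 0.025), rhs, NULL,
                        rtol = 1e-10, atol = 1e-10)
  expect_lt(max(abs(out$traces - sol[, 2:4])), 1e-3)
})

test_that("backward-Euler step conserves charge to machine precision", {
  m <- passive_three()
  ss <- myelinwm:::.cable_steady_cpp(m, -70)
  dt <- 0.025
  nst <- 400
  out <- myelinwm:::.cable_integrate_cpp(m, ss$phi, ss$h, ss$n,
                                         dt = dt, nsteps = nst,
                                         i_hold = 0, i_step = 0.04,
                                         t_on = 0, t_off = 1e9,
                                         probe_comps = c(0L, 1L, 2L),
                                         theta = 1)
  v <- out$traces
  # discrete balance of the implicit step, summed over compartments:
  # injected charge = capacitive charge + leak charge (axial cancels)
  inj <- 0.04 * dt * nst
  cap <- sum(m$c_ax * (v[nst + 1, ] - v[1, ]))
  leak <- sum(sapply(1:3, function(k) {
    sum(m$g_pas[k] * (v[-1, k] - m$e_pas[k]) * dt)
  }))
  expect_equal(inj, cap + leak, tolerance = 1e-12)
})

test_that("identical spec and protocol give bit-identical traces", {
  sp <- small_axon_spec()
  g <- build_axon(sp)
  pr <- axon_protocol(step_s = 0.05, post_ms = 0)
  s1 <- simulate_axon(g, pr)
  s2 <- simulate_axon(build_axon(sp), pr)
  expect_identical(s1$traces$v_mv, s2$traces$v_mv)
  expect_identical(s1$i_hold_nA, s2$i_hold_nA)
})

test_that("holding solve pins the soma and recovers the holding current", {
  # two-compartment oracle: algebraic steady state with the soma pinned
  m <- passive_three(C = c(0.1, 0.05, 0.08), g = c(0.01, 0.005, 0.004),
                     ga = c(0.02, 0.01), e = -60)
  ss <- myelinwm:::.cable_steady_cpp(m, -70)
  # solve the 2x2 linear system for the free compartments by hand
  A <- rbind(c(0.005 + 0.02 + 0.01, -0.01),
             c(-0.01, 0.004 + 0.01))
  b <- c(0.005 * -60 + 0.02 * -70, 0.004 * -60)
  v23 <- solve(A, b)
  expect_equal(ss$phi[2:3], v23, tolerance = 1e-7)
  ih <- 0.01 * (-70 - -60) - 0.02 * (v23[1] - -70)
  expect_equal(ss$i_hold, ih, tolerance = 1e-7)
})

test_that("integration aborts with a diagnostic on divergence", {
  m <- passive_one()
  ss <- myelinwm:::.cable_steady_cpp(m, -70)
  expect_error(
    myelinwm:::.cable_integrate_cpp(m, ss$phi, ss$h, ss$n, dt = 0.025,
                                    nsteps = 2000, i_hold = 0,
                                    i_step = 50, t_on = 0, t_off = 1e9,
                                    probe_comps = 0L, theta = 0.5),
    "diverged")
})

test_that("graph construction enforces the geometry preconditions", {
  expect_error(axon_spec(-0.5, 1, 120, 12, 0.016, 0.5, 0.5, 0.5), "positive")
  expect_error(axon_spec(0.7, 1, 120, 0, 0.016, 0.5, 0.5, 0.5),
               "positive|lamellae")
  sp <- small_axon_spec()
  plan <- perturbation_plan(sp)
  plan$n_lam[2] <- 0L
  expect_error(build_axon(sp, plan), "perturbation engine")
})
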