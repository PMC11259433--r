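# Compartment-graph structure and electrical derivations.

test_that("the reference axon discretizes to the canonical counts", {
  g <- build_axon(mid_axon_spec())
  comp <- g$comp
  expect_equal(g$n_nodes, 101)
  expect_equal(sum(comp$role == "node"), 101 * 13)
  expect_equal(length(unique(comp$seg_id[comp$seg_id > 0])), 100)
  # each segment: 4+4 paranodes of 5, two juxtaparanodes of 5, internode 9
  one <- comp[comp$seg_id == 37, ]
  expect_equal(nrow(one), 59)
  expect_equal(as.vector(table(one$role)[c("paranode", "juxtaparanode",
                                           "internode")]), c(40, 10, 9))
  expect_equal(one$role[c(1, 21, 26, 34, 39, 59)],
               c("paranode", "juxtaparanode", "internode", "internode",
                 "juxtaparanode", "paranode"))
})

test_that("axon length is the sum of its parts", {
  sp <- mid_axon_spec()
  g <- build_axon(sp)
  expect_equal(g$axon_length_um, 100 * 120 + 101 * 1.1, tolerance = 1e-9)
  # ~1.2 cm for mid-range parameters
  expect_equal(g$axon_length_um * 1e-4, 1.21, tolerance = 0.01)
})

test_that("doubling the lamella count halves myelin admittance and capacitance", {
  g1 <- build_axon(axon_spec(0.76, 1.1, 120, 8, 0.016, 0.5, 0.5, 0.5,
                             n_segments = 4))
  g2 <- build_axon(axon_spec(0.76, 1.1, 120, 16, 0.016, 0.5, 0.5, 0.5,
                             n_segments = 4))
  i1 <- g1$comp$has_peri
  expect_equal(g2$model$g_my[i1], g1$model$g_my[i1] / 2, tolerance = 1e-12)
  expect_equal(g2$model$c_my[i1], g1$model$c_my[i1] / 2, tolerance = 1e-12)
})

test_that("g-ratio follows the fiber geometry and stays in (0, 1)", {
  sp <- axon_spec(0.76, 1.1, 120, 12, 0.016, 0.5, 0.5, 0.5)
  expect_equal(g_ratio(sp), 0.76 / (0.76 + 2 * 12 * 0.016))
  rng <- axon_parameter_ranges()
  g_lo <- 0.5 / (0.5 + 2 * 20 * 0.019)
  expect_gt(g_lo, 0)
  expect_lt(g_lo, 1)
})

test_that("remyelination inserts standard nodes and half-length children", {
  sp <- small_axon_spec()
  plan <- demyelinate(perturbation_plan(sp), c(2, 5, 7), 1.0)
  plan <- remyelinate(plan, sp$n_lamellae, 1.0, 0.5)
  g <- build_axon(sp, plan)
  g0 <- build_axon(sp)
  expect_equal(g$n_nodes, g0$n_nodes + 3)
  # children: two blocks of 59 per remyelinated segment, total length kept
  seg2 <- g$comp[g$comp$seg_id == 2, ]
  expect_equal(nrow(seg2), 2 * 59)
  expect_equal(sum(seg2$len), sp$segment_length, tolerance = 1e-9)
  expect_true(all(seg2$n_lam == 6))
  expect_equal(sum(g$comp$len) - sum(g0$comp$len), 3 * sp$node_length,
               tolerance = 1e-9)
})

test_that("a plan restoring the original lamellae without splitting is electrically identical", {
  sp <- small_axon_spec()
  plan <- perturbation_plan(sp)
  plan$state[c(2, 5)] <- "demyelinated"   # marked, but full lamellae kept
  g0 <- build_axon(sp)
  g1 <- build_axon(sp, plan)
  for (fld in c("c_ax", "g_pas", "gna", "gk", "c_my", "g_my", "g_seal",
                "axial_i_g", "axial_p_g")) {
    expect_identical(g1$model[[fld]], g0$model[[fld]])
  }
  pr <- axon_protocol(step_s = 0.05, post_ms = 0)
  expect_identical(simulate_axon(g1, pr)$traces$v_mv,
                   simulate_axon(g0, pr)$traces$v_mv)
})

test_that("bare segments lose the periaxonal layer entirely", {
  sp <- small_axon_spec()
  plan <- demyelinate(perturbation_plan(sp), 3, 1.0)
  g <- build_axon(sp, plan)
  expect_true(all(!g$comp$has_peri[g$comp$seg_id == 3]))
  expect_true(all(g$comp$has_peri[g$comp$seg_id == 4]))
})

test_that("conduction velocity converges under step refinement", {
  # a tenth of the step changes CV by < 2% (short axon keeps this quick)
  sp <- small_axon_spec(n_segments = 6)
  g <- build_axon(sp)
  cvs <- sapply(c(0.025, 0.0025), function(dtv) {
    sim <- simulate_axon(g, axon_protocol(step_s = 0.15, dt_ms = dtv,
                                          post_ms = 20))
    tr <- sim$traces
    cv <- measure_cv(
      detect_spikes(tr[tr$probe == "first_node", ]),
      detect_spikes(tr[tr$probe == "penultimate_node", ]),
      g$distance_um)
    cv$cv_m_per_s
  })
  expect_lt(abs(cvs[2] - cvs[1]) / cvs[2], 0.02)
})
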