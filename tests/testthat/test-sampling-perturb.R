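# Latin hypercube cohort sampling and the perturbation engine.

test_that("the Latin property holds in every dimension", {
  s <- sample_axon_lhs(4, seed = 7)
  rng <- axon_parameter_ranges()
  for (p in setdiff(rng$parameter, "n_lamellae")) {   # integers are rounded
    lo <- rng$min[rng$parameter == p]
    hi <- rng$max[rng$parameter == p]
    q <- floor(4 * (s[[p]] - lo) / (hi - lo))
    expect_setequal(q, 0:3)
  }
  expect_true(all(s$axon_diameter >= 0.5 & s$axon_diameter <= 1.02))
  expect_error(sample_axon_lhs(1), ">= 2")
})

test_that("the maximin design beats the median random Latin hypercube", {
  s <- sample_axon_lhs(12, seed = 5)
  rng <- axon_parameter_ranges()
  unit <- sapply(seq_len(nrow(rng)), function(j) {
    (s[[rng$parameter[j]]] - rng$min[j]) / (rng$max[j] - rng$min[j])
  })
  # n_lamellae was rounded after sampling; a half-stratum jitter is possible
  d_chosen <- min(dist(unit))
  d_random <- withr::with_seed(13, {
    replicate(100, min(dist(lhs::randomLHS(12, 8))))
  })
  expect_gte(d_chosen, median(d_random) * 0.95)
})

test_that("seeded designs and segment lists are reproducible", {
  expect_identical(sample_axon_lhs(6, seed = 3), sample_axon_lhs(6, seed = 3))
  l1 <- draw_segment_lists(100, 0.25, n_trials = 5, seed = 9)
  l2 <- draw_segment_lists(100, 0.25, n_trials = 5, seed = 9)
  expect_identical(l1, l2)
  expect_true(all(lengths(l1) == 25))
  expect_false(identical(l1, draw_segment_lists(100, 0.25, 5, seed = 10)))
})

test_that("demyelination removes lamellae with half-up rounding", {
  sp <- small_axon_spec(n_segments = 100, n_lamellae = 12)
  plan <- demyelinate(perturbation_plan(sp), 1:25, 0.25)
  expect_equal(sum(plan$state == "demyelinated"), 25)
  expect_true(all(plan$n_lam[1:25] == 9))
  expect_equal(demyelinate(perturbation_plan(sp), 1, 0.5)$n_lam[1], 6)
  expect_equal(demyelinate(perturbation_plan(sp), 1, 1.0)$n_lam[1], 0)
  # ties round up: 11 lamellae, remove 50% -> keep 6 (5.5 -> 6)
  sp11 <- small_axon_spec(n_segments = 4, n_lamellae = 11)
  expect_equal(demyelinate(perturbation_plan(sp11), 1, 0.5)$n_lam[1], 6)
  expect_error(demyelinate(perturbation_plan(sp), 1, 0), "removal_fraction")
  expect_error(demyelinate(perturbation_plan(sp), 1, 1.2), "removal_fraction")
})

test_that("stride selection generalizes the every-alternate rule", {
  expect_equal(stride_select(c(2, 3, 5, 8), 0.5), c(2, 5))
  expect_equal(stride_select(c(2, 3, 5, 8), 0.25), 2)
  expect_equal(stride_select(1:8, 1), 1:8)
  expect_equal(stride_select(1:4, 0.75), c(1, 2, 3))
  expect_length(stride_select(1:100, 0.5), 50)
})

test_that("remyelination updates the plan and refuses zero lamellae", {
  sp <- small_axon_spec()
  plan <- demyelinate(perturbation_plan(sp), c(1, 3, 5, 7), 1.0)
  out <- remyelinate(plan, sp$n_lamellae, 0.25, 0.5)
  expect_equal(sum(out$state == "remyelinated"), 1)
  expect_equal(sum(out$state == "demyelinated"), 3)
  expect_equal(out$n_lam[out$state == "remyelinated"], 6)
  out2 <- remyelinate(plan, sp$n_lamellae, 1.0, 0.75)
  expect_equal(sum(out2$state == "remyelinated"), 4)
  expect_true(all(out2$n_lam[out2$state == "remyelinated"] == 9))
  expect_error(remyelinate(plan, 12, 0.5, 0.02), "at least one lamella")
})

test_that("full remyelination of heavy demyelination leaves no bare segments", {
  sp <- small_axon_spec(n_segments = 100)
  plan <- demyelinate(perturbation_plan(sp), 1:75, 1.0)
  out <- remyelinate(plan, sp$n_lamellae, 1.0, 0.75)
  expect_equal(sum(out$state == "remyelinated"), 75)
  expect_false(any(out$n_lam == 0))
  g <- build_axon(sp, out)
  expect_equal(g$n_nodes, 101 + 75)
})
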