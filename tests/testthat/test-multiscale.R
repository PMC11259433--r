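# Failure histograms, mixed axon groups, sheath-composition geometry, and
# the composition-versus-performance experiment at reduced scale.

test_that("failure histograms tabulate per-axon failure probabilities", {
  grid <- tibble(
    axon_id = rep(1:4, each = 2), segment_fraction = 0.25,
    removal_fraction = 1, trial = rep(1:2, 4),
    cv_m_per_s = 0.5, cv_change = -50,
    ap_failure_pct = c(0, 0, 100, 100, 100, 100, 30, 50),
    n_first = 28L, n_distal = 14L, complete = TRUE)
  h <- failure_histogram(grid, segment_fraction == 0.25)
  expect_equal(sum(h$fraction), 1)
  expect_equal(h$fraction[h$p_failure == 0], 0.25)
  expect_equal(h$fraction[h$p_failure == 1], 0.5)
  expect_equal(h$fraction[h$p_failure == 0.4], 0.25)
  expect_error(failure_histogram(grid, segment_fraction == 0.9), "empty")
})

test_that("fixture histograms match their construction", {
  h0 <- fixture_failure_histogram(w = 1)
  expect_equal(h0$p_failure, 0)
  expect_equal(h0$fraction, 1)
  h <- fixture_failure_histogram(0.5, 2, 2, n_draws = 4000, seed = 7)
  expect_equal(sum(h$fraction), 1, tolerance = 1e-9)
  expect_equal(sum(h$fraction[h$p_failure > 0] * h$p_failure[h$p_failure > 0]),
               0.5 * 0.5, tolerance = 0.03)   # Beta(2,2) mean, weight 1/2
  expect_error(fixture_failure_histogram(0.5, -1, 2), "positive")
})

small_cohort <- function() {
  cand <- sample_axon_lhs(3, seed = 17)
  cohort <- dplyr::bind_cols(tibble(axon_id = 1:3), cand)
  attr(cohort, "constants") <- axon_constants()
  cohort
}

group_of <- function(cohort, ...) {
  build_axon_groups(cohort, n_groups = 1, size = 10, n_trials = 4,
                    seed = 5, ...)[[1]]
}

test_that("axon groups are seeded, sized, and composition-deterministic", {
  cohort <- small_cohort()
  g1 <- build_axon_groups(cohort, 2, size = 10, perturbed_range = c(0.4, 0.4),
                          n_trials = 4, seed = 5)
  expect_length(g1, 2)
  expect_equal(nrow(g1[[1]]), 10)
  expect_equal(sum(g1[[1]]$status == "perturbed"), 4)
  g2 <- build_axon_groups(cohort, 2, size = 10, perturbed_range = c(0.4, 0.4),
                          n_trials = 4, seed = 5)
  expect_identical(g1[[1]]$plan, g2[[1]]$plan)
})

test_that("an all-intact group has only normal sheaths", {
  g <- group_of(small_cohort(), perturbed_range = c(0, 0))
  expect_equal(sum(g$status == "perturbed"), 0)
  expect_equal(percent_normal_sheaths(g), 100)
  expect_equal(percent_new_sheaths(g), 0)
})

test_that("composition percentages track the demyelinated length", {
  # every axon demyelinated on half its segments -> about 50% normal
  cohort <- small_cohort()
  g <- build_axon_groups(cohort, 1, size = 6, perturbed_range = c(1, 1),
                         segment_fractions = 0.5, n_trials = 4,
                         seed = 8)[[1]]
  pn <- percent_normal_sheaths(g)
  expect_equal(pn, 50, tolerance = 0.1 * 50)
  expect_true(percent_normal_sheaths(g) >= 0 && pn <= 100)
})

test_that("composition is invariant to member ordering", {
  g <- group_of(small_cohort(), perturbed_range = c(0.5, 0.5))
  gp <- g[withr::with_seed(2, sample(nrow(g))), ]
  attr(gp, "mode") <- attr(g, "mode")
  expect_equal(percent_normal_sheaths(gp), percent_normal_sheaths(g))
})

test_that("a fully remyelinated axon sections to all-new sheaths", {
  cohort <- small_cohort()[1, ]
  g <- build_axon_groups(cohort, 1, size = 1, perturbed_range = c(1, 1),
                         segment_fractions = 1, mode = "remyelinate",
                         remyelination_fraction = 1, restore_fraction = 0.25,
                         n_trials = 4, seed = 3)[[1]]
  expect_equal(percent_new_sheaths(g), 100)
  expect_lt(percent_normal_sheaths(g), 1)
})

test_that("group failure histograms follow the member grid cells", {
  cohort <- small_cohort()
  grid <- tibble(
    axon_id = rep(1:3, each = 2),
    segment_fraction = rep(c(0.25, 0.50), 3),
    removal_fraction = 1, trial = 1L, cv_m_per_s = NA, cv_change = -100,
    ap_failure_pct = c(10, 20, 30, 40, 50, 60),
    n_first = 28L, n_distal = 0L, complete = TRUE)
  g <- build_axon_groups(cohort, 1, size = 6, perturbed_range = c(0.5, 0.5),
                         segment_fractions = c(0.25, 0.5), n_trials = 4,
                         seed = 9)[[1]]
  h <- group_failure_histogram(g, grid)
  expect_equal(sum(h$fraction), 1)
  expect_equal(sum(h$n_axons), 6)
  # intact members contribute the zero-failure mass
  expect_gte(h$fraction[h$p_failure == 0], sum(g$status == "intact") / 6)
})

test_that("performance declines with fewer normal sheaths (reduced scale)", {
  # deterministic composition -> duration mapping through the network:
  # three groups spanning intact to heavily perturbed axons
  p <- get_small_params()
  conn <- get_small_conn()
  cohort <- small_cohort()
  grid <- tibble(
    axon_id = rep(1:3, each = 2),
    segment_fraction = rep(c(0.25, 0.75), 3),
    removal_fraction = 1, trial = 1L, cv_m_per_s = NA, cv_change = -100,
    ap_failure_pct = rep(c(40, 95), 3),
    n_first = 28L, n_distal = 0L, complete = TRUE)
  fracs <- c(0, 0.5, 1)
  rows <- lapply(seq_along(fracs), function(i) {
    g <- build_axon_groups(cohort, 1, size = 10,
                           perturbed_range = rep(fracs[i], 2),
                           segment_fractions = c(0.25, 0.75),
                           n_trials = 4, seed = 40 + i)[[1]]
    comp <- percent_normal_sheaths(g)
    pt <- transmission_probabilities(group_failure_histogram(g, grid), p,
                                     seed = i)
    run <- run_drt_trials(p, conn, n_trials = 2, p_trans = pt,
                          seed = 500 + i)
    tibble(composition_pct = comp, duration_s = run$summary$duration_s)
  })
  res <- dplyr::bind_rows(rows)
  expect_true(all(diff(res$composition_pct) < 0))
  # more normal myelin, longer memory
  expect_gt(cor(res$composition_pct, res$duration_s), 0)
  expect_gt(res$duration_s[1], res$duration_s[3])
})
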