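# Parameter-importance regression: penalized fit, selection behavior,
# validation, and the response construction.

fake_predictors <- function(n, seed = 1) {
  withr::with_seed(seed, {
    as_tibble(setNames(as.data.frame(matrix(rnorm(n * 12), n, 12)),
                       names(axon_predictors(tibble(
                         axon_diameter = 0.7, node_length = 1,
                         segment_length = 100, scale_leak = 0.5,
                         scale_naf = 0.5, scale_kdr = 0.5, n_lamellae = 10,
                         lamella_thickness = 0.015)))))
  })
}

test_that("the unpenalized limit agrees with the normal equations", {
  x <- fake_predictors(80, seed = 2)
  y <- withr::with_seed(3, {
    2 * x[[1]] - 1 * x[[3]] + 0.5 * x[[7]] + rnorm(80, sd = 0.3)
  })
  xz <- scale(as.matrix(x))
  yz <- as.vector(scale(y))
  ols <- solve(crossprod(xz), crossprod(xz, yz))
  fit <- glmnet::glmnet(xz, yz, alpha = 1, lambda = 0, standardize = FALSE,
                        thresh = 1e-12)
  expect_equal(as.vector(coef(fit))[-1], as.vector(ols), tolerance = 1e-4)
})

test_that("sparse structure is recovered at the cross-validated lambda", {
  x <- fake_predictors(60, seed = 4)
  y <- withr::with_seed(5, 2 * x[[1]] - 1 * x[[3]] + rnorm(60, sd = 0.15))
  fit <- fit_importance_lasso(x, y, seed = 6)
  b <- fit$beta_z
  expect_gt(b[1], 0.5)
  expect_lt(b[3], -0.2)
  expect_true(all(abs(b[-c(1, 3)]) < 0.2 * abs(b[1])))
  expect_gt(fit$r2, 0.9)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(tidy(fit)), 12)
  expect_equal(glance(fit)$n_selected, sum(b != 0))
})

test_that("sparsity is monotone along the regularization path", {
  x <- fake_predictors(60, seed = 7)
  y <- withr::with_seed(8, x[[2]] - 0.6 * x[[5]] + rnorm(60, sd = 0.2))
  fit <- fit_importance_lasso(x, y, seed = 9)
  nz <- colSums(as.matrix(fit$glmnet_fit$beta) != 0)
  lam <- fit$glmnet_fit$lambda
  ord <- order(lam, decreasing = TRUE)
  expect_true(all(diff(nz[ord]) >= 0))
})

test_that("z-scored coefficients reproduce unstandardized predictions", {
  x <- fake_predictors(50, seed = 10)
  y <- withr::with_seed(11, 3 + x[[1]] + rnorm(50, sd = 0.1))
  fit <- fit_importance_lasso(x, y, seed = 12)
  pz <- predict(fit, x, z = TRUE)
  p <- predict(fit, x, z = FALSE)
  expect_equal(p, fit$y_center + pz * fit$y_scale, tolerance = 1e-12)
})

test_that("held-out validation behaves at the analytic extremes", {
  x <- fake_predictors(50, seed = 13)
  y <- 2 * x[[1]]
  fit <- fit_importance_lasso(x, y, seed = 14)
  xv <- fake_predictors(50, seed = 15)
  expect_equal(validate_predictions(fit, xv, 2 * xv[[1]])$pearson_r, 1,
               tolerance = 1e-6)
  expect_equal(validate_predictions(fit, xv, -2 * xv[[1]])$pearson_r, -1,
               tolerance = 1e-6)
  # permuted responses decorrelate (|r| < 0.3 at n = 50 for most seeds)
  rs <- sapply(1:8, function(s) {
    yp <- withr::with_seed(s, sample(2 * xv[[1]]))
    validate_predictions(fit, xv, yp)$pearson_r
  })
  expect_gt(mean(abs(rs) < 0.3), 0.8)
})

test_that("constant responses yield an all-zero fit with a warning", {
  x <- fake_predictors(30, seed = 16)
  expect_warning(fit <- fit_importance_lasso(x, rep(1, 30)), "constant")
  expect_true(all(fit$beta_z == 0))
})

test_that("responses are built by the stated averaging rules", {
  grid <- tibble(
    axon_id = rep(1:2, each = 6),
    segment_fraction = rep(c(0.25, 0.50, 0.75), 4),
    removal_fraction = rep(c(1, 1, 1, 0.5, 0.5, 0.5), 2),
    trial = 1L,
    cv_change = c(-30, -50, -70, -5, -10, -15,
                  -100, -100, -100, -20, -30, -40),
    ap_failure_pct = 0, complete = TRUE)
  r <- build_lasso_responses(grid)
  expect_equal(r$demyel_response, c(mean(c(-30, -50, -70)), -100))
  # zero-perturbation rows average to zero
  grid0 <- dplyr::mutate(grid, cv_change = 0)
  expect_equal(build_lasso_responses(grid0)$demyel_response, c(0, 0))
})
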