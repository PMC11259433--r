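#' Derived electrical predictors of an axon model
#'
#' The per-axon quantities used (with the sampled parameters) as lasso
#' predictors. The five electrical predictors are computed from each
#' axon's geometry and the fixed constants, so they vary across a cohort:
#' axoplasmic resistance per unit length (`4 rho_ax / (pi d^2)`, MOhm/um),
#' axolemma capacitance per unit length (`cm pi d`, pF/um), radial myelin
#' resistance of the unperturbed sheath (`n r_lam`, Ohm cm^2), myelin
#' capacitance per area (`c_lam / n`, uF/cm^2), and the total
#' tight-junction seal resistance (`rho_tj n / (pi d)` per segment end,
#' times `2 n_segments`, MOhm).
#'
#' @param cohort cohort tibble (one row per axon).
#' @param constants an [axon_constants()]; defaults to the cohort's.
#' @return Tibble of 12 named predictor columns, one row per axon.
#' @export
axon_predictors <- function(cohort, constants = NULL) {
  cst <- constants %||% attr(cohort, "constants") %||% axon_constants()
  d <- cohort$axon_diameter
  n <- cohort$n_lamellae
  tibble(
    axon_diameter = d,
    node_length = cohort$node_length,
    segment_length = cohort$segment_length,
    scale_leak = cohort$scale_leak,
    scale_naf = cohort$scale_naf,
    scale_kdr = cohort$scale_kdr,
    myelin_thickness = n * cohort$lamella_thickness,
    axoplasmic_resistance = 4 * cst$rho_ax / (pi * d^2) * 1e-2,
    axon_capacitance = cst$cm * pi * d * 1e-2,
    myelin_resistance = n * cst$r_lam,
    myelin_capacitance = cst$c_lam / n,
    tight_junction_resistance = 2 * 100 * cst$rho_tj * n / (pi * d)
  )
}

#' Scalar regression responses from the perturbation grids
#'
#' One demyelination response and one remyelination response per axon:
#' the demyelination response averages the CV change over all randomized
#' trials with 100% of lamellae removed from 25%, 50%, and 75% of
#' segments (complete propagation failure coded as -100%); the
#' remyelination response averages the CV recovery over all trials where
#' 25%, 50%, or 75% of segments were completely demyelinated and then all
#' of them remyelinated with 75% of lamellae restored.
#'
#' @param demyel_grid result of [run_demyelination_grid()].
#' @param remyel_grid result of [run_remyelination_grid()] (complete
#'   initial demyelination), or `NULL` to skip.
#' @param segment_fractions fractions entering the averages.
#' @return Tibble: `axon_id`, `demyel_response`, `remyel_response`; axons
#'   with no complete cells are dropped with a warning.
#' @export
build_lasso_responses <- function(demyel_grid, remyel_grid = NULL,
                                  segment_fractions = c(0.25, 0.50, 0.75)) {
  dem <- demyel_grid %>%
    filter(.data$removal_fraction == 1,
           .data$segment_fraction %in% segment_fractions,
           .data$complete) %>%
    group_by(.data$axon_id) %>%
    summarise(demyel_response = mean(.data$cv_change), .groups = "drop")
  dropped <- setdiff(unique(demyel_grid$axon_id), dem$axon_id)
  if (length(dropped)) {
    warn(paste("axons dropped for missing demyelination cells:",
               paste(dropped, collapse = ", ")))
  }
  if (is.null(remyel_grid)) return(dem)
  rem <- remyel_grid %>%
    filter(.data$remyel_fraction == 1, .data$restore_fraction == 0.75,
           .data$demyel_fraction %in% segment_fractions,
           .data$initial == "complete", .data$complete) %>%
    group_by(.data$axon_id) %>%
    summarise(remyel_response = mean(.data$cv_recovery), .groups = "drop")
  dplyr::left_join(dem, rem, by = "axon_id")
}

#' Lasso regression of a perturbation response on axon parameters
#'
#' Fits `y ~ x` under an L1 penalty, minimizing the residual sum of
#' squares plus `lambda * sum(|beta_j|)`. All 12 predictors and the
#' response are z-scored first; `lambda` is chosen to minimize the
#' 10-fold cross-validation error (folds seeded and stratified by
#' response quantile), and the reported coefficients come from refitting
#' on all data at the selected `lambda`.
#'
#' @param predictors tibble from [axon_predictors()] (12 columns).
#' @param response numeric response vector (one per row).
#' @param nfolds cross-validation folds.
#' @param seed fold-assignment seed.
#' @return Object of class `wm_lasso`: coefficients (original and
#'   z-scored), the selected `lambda`, the cross-validation curve, and the
#'   scaling parameters needed to predict on new axons.
#' @export
fit_importance_lasso <- function(predictors, response, nfolds = 10,
                                 seed = 1) {
  x <- as.matrix(predictors)
  stopifnot(nrow(x) == length(response))
  if (sd(response) == 0) {
    warn("constant response; all coefficients zero")
    beta <- setNames(rep(0, ncol(x)), colnames(x))
    return(structure(list(beta_z = beta, lambda = Inf,
                          center = colMeans(x), scale = apply(x, 2, sd),
                          y_center = mean(response), y_scale = 0,
                          cv = NULL, r2 = 0),
                     class = "wm_lasso"))
  }
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  xz <- scale(x, ctr, scl)
  yz <- as.vector(scale(response))
  # stratified, seeded folds by response quantile
  foldid <- withr::with_seed(seed, {
    strata <- dplyr::ntile(yz, max(2, floor(length(yz) / nfolds)))
    f <- integer(length(yz))
    for (s in unique(strata)) {
      idx <- which(strata == s)
      f[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
    }
    f
  })
  cvfit <- glmnet::cv.glmnet(xz, yz, alpha = 1, foldid = foldid,
                             standardize = FALSE)
  fit <- glmnet::glmnet(xz, yz, alpha = 1, lambda = cvfit$lambda,
                        standardize = FALSE)
  bz <- as.vector(coef(fit, s = cvfit$lambda.min))[-1]
  names(bz) <- colnames(x)
  pred <- as.vector(predict(fit, newx = xz, s = cvfit$lambda.min))
  structure(list(
    beta_z = bz, lambda = cvfit$lambda.min,
    intercept_z = as.vector(coef(fit, s = cvfit$lambda.min))[1],
    center = ctr, scale = scl,
    y_center = mean(response), y_scale = sd(response),
    cv = tibble(lambda = cvfit$lambda, cvm = cvfit$cvm, cvsd = cvfit$cvsd),
    glmnet_fit = fit,
    r2 = 1 - mean((pred - yz)^2) / mean((yz - mean(yz))^2)),
    class = "wm_lasso")
}

#' @export
print.wm_lasso <- function(x, ...) {
  nz <- sum(x$beta_z != 0)
  cat(sprintf("<wm_lasso> lambda = %.4g, %d of %d predictors selected, R^2 = %.3f\n",
              x$lambda, nz, length(x$beta_z), x$r2))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.wm_lasso <- function(x, ...) {
  tibble(term = names(x$beta_z), estimate = unname(x$beta_z),
         selected = x$beta_z != 0)
}

#' @export
glance.wm_lasso <- function(x, ...) {
  tibble(lambda = x$lambda, n_selected = sum(x$beta_z != 0),
         r.squared = x$r2)
}

#' Predict perturbation responses for new axons
#'
#' @param object a [fit_importance_lasso()] result.
#' @param new_predictors tibble from [axon_predictors()].
#' @param z return predictions on the z-scored scale (default) or the
#'   original response scale.
#' @param ... unused.
#' @return Numeric vector.
#' @export
predict.wm_lasso <- function(object, new_predictors, z = TRUE, ...) {
  xz <- scale(as.matrix(new_predictors), object$center, object$scale)
  yz <- object$intercept_z + as.vector(xz %*% object$beta_z)
  if (z) yz else object$y_center + yz * object$y_scale
}

#' Held-out validation of a lasso fit
#'
#' Pearson correlation between z-scored predicted and observed responses
#' on a held-out cohort.
#'
#' @param fit a `wm_lasso`.
#' @param new_predictors predictors of the held-out axons.
#' @param new_response their measured responses.
#' @return A list: `pearson_r`, `n`, `flag` (set when either side has zero
#'   variance, leaving r undefined).
#' @export
validate_predictions <- function(fit, new_predictors, new_response) {
  pred <- predict(fit, new_predictors)
  obs <- as.vector(scale(new_response))
  if (sd(pred) == 0 || sd(new_response) == 0) {
    return(list(pearson_r = NA_real_, n = length(obs),
                flag = "degenerate variance"))
  }
  list(pearson_r = cor(pred, obs), n = length(obs), flag = NA_character_)
}
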