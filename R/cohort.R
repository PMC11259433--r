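#' Latin hypercube sample of axon parameter sets
#'
#' Space-filling sample of the eight axon parameters within their plausible
#' ranges ([axon_parameter_ranges()]). Uses a maximin Latin hypercube: the
#' best of `n_candidates` random Latin hypercube draws by minimum pairwise
#' distance (in the unit cube), so exactly one sample falls in each of the
#' `n` equal-probability strata of every dimension. Lamella counts are
#' rounded to integers after sampling.
#'
#' @param n number of parameter sets (>= 2).
#' @param seed RNG seed (the design is fully reproducible).
#' @param ranges tibble of parameter ranges, as [axon_parameter_ranges()].
#' @param n_candidates random Latin hypercube draws the maximin criterion
#'   picks from.
#' @return A tibble with one row per candidate: `candidate_id` plus the
#'   eight parameter columns.
#' @export
#' @examples
#' sample_axon_lhs(4, seed = 1)
sample_axon_lhs <- function(n, seed = 1, ranges = axon_parameter_ranges(),
                            n_candidates = 25) {
  if (n < 2) abort("n must be >= 2 for a Latin hypercube design")
  k <- nrow(ranges)
  u <- withr::with_seed(seed, {
    best <- NULL
    best_d <- -Inf
    for (i in seq_len(n_candidates)) {
      cand <- lhs::randomLHS(n, k)
      d <- min(stats::dist(cand))
      if (d > best_d) {
        best_d <- d
        best <- cand
      }
    }
    best
  })
  out <- as_tibble(setNames(as.data.frame(
    sweep(sweep(u, 2, ranges$max - ranges$min, "*"), 2, ranges$min, "+")
  ), ranges$parameter))
  out$n_lamellae <- pmax(1L, as.integer(floor(out$n_lamellae + 0.5)))
  dplyr::bind_cols(tibble(candidate_id = seq_len(n)), out)
}

spec_from_row <- function(row, constants = axon_constants(),
                          n_segments = 100) {
  axon_spec(row$axon_diameter, row$node_length, row$segment_length,
            row$n_lamellae, row$lamella_thickness,
            row$scale_leak, row$scale_naf, row$scale_kdr,
            n_segments = n_segments, constants = constants)
}

#' Screen candidate axon models against the selection criteria
#'
#' Simulates every candidate under the standard protocol and applies the
#' four selection criteria for a biologically plausible ("young control")
#' model: somatic firing 13-16 Hz at +380 pA, silence at 0 pA, conduction
#' velocity within 0.3-0.8 m/s, and saltatory conduction (suprathreshold
#' nodes, subthreshold juxtaparanodes/internodes).
#'
#' @param candidates tibble from [sample_axon_lhs()].
#' @param protocol an [axon_protocol()].
#' @param constants an [axon_constants()] object.
#' @param n_segments segments per axon (default 100).
#' @param rate_range,cv_range acceptance bands.
#' @param prescreen run a short (0.4 s) conduction pre-check first and
#'   give the full protocol only to candidates that conduct, are
#'   saltatory, and fall in a widened CV band (0.25-0.9 m/s). The
#'   pre-check can only reject candidates the full protocol would also
#'   reject (peak depolarizations only grow with protocol length and the
#'   CV estimate is stationary), so acceptance is unchanged while the
#'   screening cost drops severalfold.
#' @param progress print one line per candidate.
#' @return The candidate tibble augmented with the measured quantities
#'   (`firing_rate_hz`, `cv_m_per_s`, ...), per-criterion pass flags and the
#'   overall `accepted` flag, plus derived quantities `g_ratio` and
#'   `axon_length_cm`.
#' @export
screen_axon_candidates <- function(candidates, protocol = axon_protocol(),
                                   constants = axon_constants(),
                                   n_segments = 100,
                                   rate_range = c(13, 16),
                                   cv_range = c(0.3, 0.8),
                                   prescreen = TRUE,
                                   progress = FALSE) {
  pre_protocol <- protocol
  pre_protocol$step_s <- 0.4
  res <- purrr::map_dfr(seq_len(nrow(candidates)), function(i) {
    row <- candidates[i, ]
    sp <- spec_from_row(row, constants, n_segments)
    gr <- build_axon(sp)
    ev <- NULL
    if (prescreen) {
      pe <- evaluate_axon(gr, pre_protocol, check_silence = FALSE)
      if (!pe$saltatory || is.na(pe$cv_m_per_s) ||
          pe$cv_m_per_s < cv_range[1] - 0.05 ||
          pe$cv_m_per_s > cv_range[2] + 0.1) {
        ev <- pe  # rejected at the pre-check; stats from the short run
      }
    }
    if (is.null(ev)) ev <- evaluate_axon(gr, protocol)
    ev$g_ratio <- g_ratio(sp)
    ev$axon_length_cm <- gr$axon_length_um * 1e-4
    if (progress) {
      cat(sprintf("candidate %d: %.1f Hz, cv %.3f, salt %s\n", i,
                  ev$firing_rate_hz, ev$cv_m_per_s, ev$saltatory))
    }
    ev
  })
  out <- dplyr::bind_cols(candidates, res)
  out$pass_rate <- out$firing_rate_hz >= rate_range[1] &
    out$firing_rate_hz <= rate_range[2]
  out$pass_silent <- out$silent_0pA %in% TRUE
  out$pass_cv <- !is.na(out$cv_m_per_s) & out$cv_m_per_s >= cv_range[1] &
    out$cv_m_per_s <= cv_range[2]
  out$pass_saltatory <- out$saltatory %in% TRUE
  out$accepted <- out$pass_rate & out$pass_silent & out$pass_cv &
    out$pass_saltatory
  out
}

#' Select the control cohort from screened candidates
#'
#' Returns the accepted models; when more than `n` candidates pass, a
#' seeded random subset of `n` is drawn. With zero accepted models an empty
#' cohort is returned with per-criterion rejection counts attached (and a
#' warning).
#'
#' @param screened result of [screen_axon_candidates()].
#' @param n cohort size (the reference design uses 50).
#' @param seed seed for the random subset.
#' @return Tibble of accepted models (`axon_id` renumbered 1..n), with a
#'   `rejections` attribute counting failures per criterion.
#' @export
select_models <- function(screened, n = 50, seed = 1) {
  rej <- c(rate = sum(!screened$pass_rate),
           silent = sum(!screened$pass_silent),
           cv = sum(!screened$pass_cv),
           saltatory = sum(!screened$pass_saltatory))
  acc <- dplyr::filter(screened, .data$accepted)
  if (nrow(acc) == 0) {
    warn(paste0("no candidates met the selection criteria (rejections: ",
                paste(names(rej), rej, sep = "=", collapse = ", "), ")"))
  } else if (nrow(acc) > n) {
    keep <- withr::with_seed(seed, sample(nrow(acc), n))
    acc <- acc[sort(keep), ]
  }
  acc <- dplyr::bind_cols(tibble(axon_id = seq_len(nrow(acc))), acc)
  attr(acc, "rejections") <- rej
  acc
}

#' Build a control cohort of accepted axon models
#'
#' Convenience wrapper: Latin hypercube sampling, screening, and selection
#' in one call. Candidates are screened in batches until `n_accept` models
#' pass (or `max_candidates` is exhausted), which keeps the simulation cost
#' proportional to the cohort size actually requested.
#'
#' @param n_accept cohort size.
#' @param n_candidates LHS design size (all sampled up front to preserve the
#'   Latin property; screening stops early once enough models pass).
#' @param seed seed for design, screening order, and subset selection.
#' @inheritParams screen_axon_candidates
#' @param progress print progress lines.
#' @return A cohort tibble as from [select_models()], with the screened
#'   candidate table attached as attribute `screened`.
#' @export
build_cohort <- function(n_accept = 50, n_candidates = 1600, seed = 1,
                         protocol = axon_protocol(),
                         constants = axon_constants(), n_segments = 100,
                         progress = FALSE) {
  cand <- sample_axon_lhs(n_candidates, seed = seed)
  scr <- NULL
  done <- 0L
  batch <- max(8L, ceiling(n_accept * 2))
  while (done < nrow(cand)) {
    take <- seq(done + 1L, min(done + batch, nrow(cand)))
    scr <- dplyr::bind_rows(
      scr, screen_axon_candidates(cand[take, ], protocol, constants,
                                  n_segments, progress = progress))
    done <- max(take)
    if (sum(scr$accepted) >= n_accept) break
  }
  cohort <- select_models(scr, n = n_accept, seed = seed + 1L)
  attr(cohort, "screened") <- scr
  cohort
}

#' Summary statistics of a cohort
#'
#' @param cohort tibble from [select_models()] / [build_cohort()].
#' @return One-row tibble: cohort size, mean and sd of g-ratio, total axon
#'   length (cm), and baseline conduction velocity.
#' @export
cohort_summary <- function(cohort) {
  tibble(n = nrow(cohort),
         g_ratio_mean = mean(cohort$g_ratio),
         g_ratio_sd = sd(cohort$g_ratio),
         length_cm_mean = mean(cohort$axon_length_cm),
         length_cm_sd = sd(cohort$axon_length_cm),
         cv_mean = mean(cohort$cv_m_per_s),
         cv_sd = sd(cohort$cv_m_per_s))
}
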