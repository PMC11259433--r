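round_half_up <- function(x) floor(x + 0.5)

#' All-normal perturbation plan for an axon
#'
#' @param spec an [axon_spec()].
#' @return Tibble with one row per segment: `segment`, `state` ("normal"),
#'   `n_lam` (the spec's lamella count).
#' @export
perturbation_plan <- function(spec) {
  tibble(segment = seq_len(spec$n_segments), state = "normal",
         n_lam = spec$n_lamellae)
}

#' Randomized segment lists for perturbation trials
#'
#' Draws `n_trials` independent lists of segments to perturb, each a
#' uniform sample without replacement of `round(fraction * n_segments)`
#' segments. The same lists are reused across lamellae-removal levels
#' within a trial, and (by seeding on the fraction and trial only) across
#' axons.
#'
#' @param n_segments segments in the axon.
#' @param fraction fraction of segments to perturb.
#' @param n_trials number of randomized lists.
#' @param seed base seed.
#' @return List of sorted integer vectors.
#' @export
draw_segment_lists <- function(n_segments, fraction, n_trials = 30,
                               seed = 1) {
  k <- round_half_up(fraction * n_segments)
  withr::with_seed(seed + round(1e4 * fraction), {
    lapply(seq_len(n_trials), function(i) sort(sample.int(n_segments, k)))
  })
}

#' Demyelinate segments of an axon plan
#'
#' Removes a fraction of the myelin lamellae from the selected segments:
#' each keeps `round(n_lamellae * (1 - removal_fraction))` lamellae
#' (half-up rounding), bare (0 lamellae, sheath and periaxonal layer gone)
#' only under 100% removal.
#'
#' @param plan a [perturbation_plan()] (or the plan of a previous
#'   perturbation).
#' @param segments integer vector of segments to demyelinate.
#' @param removal_fraction fraction of lamellae removed, in (0, 1].
#' @return The updated plan tibble.
#' @export
#' @examples
#' sp <- axon_spec(0.76, 1.1, 120, 12, 0.016, 0.5, 0.5, 0.5, n_segments = 8)
#' demyelinate(perturbation_plan(sp), c(2, 5), 0.5)   # 6 lamellae remain
demyelinate <- function(plan, segments, removal_fraction) {
  if (removal_fraction <= 0 || removal_fraction > 1) {
    abort("removal_fraction must lie in (0, 1]")
  }
  if (any(segments < 1 | segments > nrow(plan))) abort("segment out of range")
  keep <- round_half_up(plan$n_lam[segments] * (1 - removal_fraction))
  plan$n_lam[segments] <- pmax(0L, as.integer(keep))
  plan$state[segments] <- "demyelinated"
  plan
}

#' Select which demyelinated segments to remyelinate
#'
#' Evenly spaced (stride) selection through the ordered list of
#' demyelinated segments, generalizing the every-alternate rule of the 50%
#' case: the k-th selected segment is at position `floor((k - 1) /
#' fraction) + 1`.
#'
#' @param demyelinated sorted integer vector of demyelinated segments.
#' @param fraction fraction to remyelinate, in (0, 1].
#' @return Integer vector of segments selected for remyelination.
#' @export
#' @examples
#' stride_select(c(2, 3, 5, 8), 0.5)    # every alternate: 2, 5
stride_select <- function(demyelinated, fraction) {
  if (fraction <= 0 || fraction > 1) abort("fraction must lie in (0, 1]")
  m <- length(demyelinated)
  k <- round_half_up(fraction * m)
  if (k == 0) return(integer(0))
  pos <- floor((seq_len(k) - 1) / fraction) + 1
  demyelinated[pos[pos <= m]]
}

#' Remyelinate previously demyelinated segments
#'
#' Replaces each selected segment by two half-length myelinated segments
#' (full paranode/juxtaparanode/internode structure at half the parent
#' lengths) separated by a new node identical to existing nodes. Each
#' child carries `round(n_lamellae_original * restore_fraction)` lamellae.
#' Non-selected demyelinated segments remain in their demyelinated state.
#'
#' @param plan plan tibble containing demyelinated segments.
#' @param n_lam_original the unperturbed lamella count (restoration is
#'   relative to it).
#' @param remyelination_fraction fraction of the demyelinated segments to
#'   remyelinate (stride selection), in (0, 1].
#' @param restore_fraction fraction of lamellae restored, in (0, 1];
#'   rejected if it would restore zero lamellae.
#' @return The updated plan tibble.
#' @export
remyelinate <- function(plan, n_lam_original, remyelination_fraction,
                        restore_fraction) {
  if (restore_fraction <= 0 || restore_fraction > 1) {
    abort("restore_fraction must lie in (0, 1]")
  }
  nl <- as.integer(round_half_up(n_lam_original * restore_fraction))
  if (nl < 1) abort("remyelination must add at least one lamella")
  dem <- plan$segment[plan$state == "demyelinated"]
  sel <- stride_select(sort(dem), remyelination_fraction)
  plan$state[sel] <- "remyelinated"
  plan$n_lam[sel] <- nl
  plan
}
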