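#' Detector parameters for TF-IDF based transfer detection
#'
#' Bundles the tunable knobs of the k-mer detector. The k-mer size and the
#' significance level follow the published optimum for class-grouped MAG
#' communities (`k = 25`, `alpha = 0.05`); the remaining knobs control how
#' "common in the donor group" and "rare in the recipient group" are
#' operationalised and how flagged k-mer starts are assembled into regions.
#'
#' @param k odd k-mer size in bp (default 25). Values below 11 carry almost
#'   no taxonomic signal and are refused unless `allow_small_k = TRUE`
#'   (useful only for hand-checkable toy corpora in tests).
#' @param alpha significance level in (0,1) applied to the per-region
#'   run-length p-value (default 0.05).
#' @param donor_prevalence minimum fraction of donor-group MAGs that must
#'   contain a k-mer for it to count as "common in the donor group"
#'   (default 0.5). The implied MAG count is `ceiling(donor_prevalence * |G|)`,
#'   so a singleton group requires presence in its single MAG.
#' @param recipient_rarity maximum number of recipient-group MAGs *other than
#'   the recipient itself* allowed to contain the k-mer (default 0, i.e. the
#'   k-mer must be recipient-exclusive within its own group).
#' @param max_group_df maximum number of groups a k-mer may occur in and
#'   still be considered group-specific (default 2: the donor group plus,
#'   via the transfer itself, the recipient's group).
#' @param merge_gap maximum difference between consecutive flagged k-mer
#'   start positions merged into one region (default `4 * k`). A cluster of
#'   donor-lineage-private substitutions spanning `s` bp inside a
#'   transferred fragment suppresses every window touching it and opens a
#'   flagged-start gap of `s + k + 1`; `4k` bridges all clusters spanning
#'   less than `3k` bp, which at percent-level divergence covers all but
#'   rare runs of four or more tightly packed substitutions, while staying
#'   at the scale of the smallest reportable event (~100 bp) so unrelated
#'   regions are not joined.
#' @param allow_small_k logical; permit `k < 11` (toy/testing only).
#' @return object of class `detector_params`.
#' @export
detector_params <- function(k = 25L, alpha = 0.05, donor_prevalence = 0.5,
                            recipient_rarity = 0L, max_group_df = 2L,
                            merge_gap = NULL, allow_small_k = FALSE) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k %% 2L == 0L) stop("k must be an odd positive integer", call. = FALSE)
  if (k < 11L && !allow_small_k) {
    stop("k < 11 degrades k-mer specificity to noise; pass allow_small_k = TRUE to override", call. = FALSE)
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  if (!is.numeric(donor_prevalence) || donor_prevalence <= 0 || donor_prevalence > 1) {
    stop("donor_prevalence must be in (0,1]", call. = FALSE)
  }
  recipient_rarity <- as.integer(recipient_rarity)
  if (is.na(recipient_rarity) || recipient_rarity < 0L) stop("recipient_rarity must be a non-negative integer", call. = FALSE)
  max_group_df <- as.integer(max_group_df)
  if (is.na(max_group_df) || max_group_df < 1L) stop("max_group_df must be a positive integer", call. = FALSE)
  if (is.null(merge_gap)) merge_gap <- 4L * k
  merge_gap <- as.integer(merge_gap)
  if (is.na(merge_gap) || merge_gap < 0L) stop("merge_gap must be a non-negative integer", call. = FALSE)
  structure(
    list(k = k, alpha = alpha, donor_prevalence = donor_prevalence,
         recipient_rarity = recipient_rarity, max_group_df = max_group_df,
         merge_gap = merge_gap),
    class = "detector_params"
  )
}

#' Validation-funnel parameters
#'
#' Thresholds of the candidate validation funnel. Boundary semantics follow
#' the strict inequalities of the published protocol: events `< 100` bp are
#' discarded (100 bp passes); regions covering `> 95%` of their scaffold are
#' discarded (95.0% passes); scaffolds that are `> 50%` simple repeat or
#' `> 50%` N are discarded (50.0% passes); scaffolds with coverage outside
#' one standard deviation of their MAG's mean in `> 2` samples are discarded
#' (1-2 aberrant samples pass with a flag).
#'
#' @param min_length_bp minimum candidate length in bp (default 100).
#' @param max_scaffold_fraction maximum fraction of the scaffold a candidate
#'   may cover (default 0.95).
#' @param max_repeat_fraction maximum simple-repeat fraction of the whole
#'   scaffold (default 0.50).
#' @param max_n_fraction maximum N fraction of the whole scaffold (default 0.50).
#' @param sd_multiplier width of the coverage-congruence band in MAG
#'   standard deviations (default 1).
#' @param max_aberrant_samples maximum number of samples in which a
#'   candidate's scaffold may fall outside the coverage band (default 2).
#' @return object of class `pipeline_params`.
#' @export
pipeline_params <- function(min_length_bp = 100L, max_scaffold_fraction = 0.95,
                            max_repeat_fraction = 0.50, max_n_fraction = 0.50,
                            sd_multiplier = 1.0, max_aberrant_samples = 2L) {
  stopifnot(min_length_bp >= 1L,
            max_scaffold_fraction > 0, max_scaffold_fraction <= 1,
            max_repeat_fraction > 0, max_repeat_fraction <= 1,
            max_n_fraction > 0, max_n_fraction <= 1,
            sd_multiplier > 0, max_aberrant_samples >= 0L)
  structure(
    list(min_length_bp = as.integer(min_length_bp),
         max_scaffold_fraction = max_scaffold_fraction,
         max_repeat_fraction = max_repeat_fraction,
         max_n_fraction = max_n_fraction,
         sd_multiplier = sd_multiplier,
         max_aberrant_samples = as.integer(max_aberrant_samples)),
    class = "pipeline_params"
  )
}
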