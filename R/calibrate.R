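#' Calibrate the bit-score threshold for one profile HMM
#'
#' Chooses a per-profile noise cutoff the way gathering thresholds are set
#' for marker-gene libraries: among the distinct observed bit scores, pick
#' the threshold that maximises the number of reference genomes carrying
#' exactly one hit at or above it. A high cutoff removes weak paralog and
#' shared-domain matches; an over-high one starts to drop the true single
#' copy, so the single-hit count peaks at the cutoff that best separates
#' orthologs from paralogs. Ties are broken toward the largest score (the
#' most stringent threshold attaining the maximum).
#'
#' Only distinct observed scores are candidates: any value strictly between
#' two observed scores classifies every hit identically to one of them.
#'
#' @param hits Hit tibble for a single profile (columns `genome_id`,
#'   `bit_score`; other columns ignored).
#' @return The calibrated threshold, a single bit score.
#' @examples
#' hits <- tibble::tibble(
#'   genome_id = c("A", "A", "B", "C", "C"),
#'   bit_score = c(50, 30, 45, 40, 35)
#' )
#' calibrate_threshold(hits) # 40: genomes A, B, C all single-copy
#' @export
calibrate_threshold <- function(hits) {
  if (nrow(hits) == 0L) {
    abort("no hits for profile")
  }
  if (any(!is.finite(hits$bit_score))) {
    abort("hit table contains non-finite bit scores")
  }
  candidates <- sort(unique(hits$bit_score), decreasing = TRUE)
  n_single <- vapply(candidates, function(t) {
    sum(table(hits$genome_id[hits$bit_score >= t]) == 1L)
  }, integer(1))
  # decreasing order: which.max lands on the largest score among ties
  candidates[which.max(n_single)]
}

#' Calibrate thresholds for every profile in a hit table
#'
#' Applies [calibrate_threshold()] per profile.
#'
#' @param hits Hit tibble (`genome_id`, `protein_id`, `profile_id`,
#'   `bit_score`).
#' @return A threshold table: tibble with columns `profile_id`, `threshold`,
#'   one row per profile, sorted by `profile_id`.
#' @export
calibrate_thresholds <- function(hits) {
  hits <- validate_hits(hits)
  if (nrow(hits) == 0L) {
    abort("no hits for profile")
  }
  hits |>
    group_by(.data$profile_id) |>
    summarise(threshold = calibrate_threshold(
      dplyr::pick("genome_id", "bit_score"))) |>
    arrange(.data$profile_id)
}
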