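#' Build the genome-by-profile marker copy-count matrix
#'
#' Applies the calibrated thresholds to a hit table and counts, for every
#' genome and profile, the number of distinct proteins with a bit score at
#' or above the profile's threshold (the comparison is inclusive). A protein
#' matched several times by the same profile — e.g. at domain level — counts
#' once. This matrix is the substrate for single-copy prevalence, clade set
#' mining, and quality scoring.
#'
#' @param hits Hit tibble (`genome_id`, `protein_id`, `profile_id`,
#'   `bit_score`).
#' @param thresholds Threshold table (`profile_id`, `threshold`), e.g. from
#'   [calibrate_thresholds()]. Every profile occurring in `hits` must have a
#'   threshold.
#' @param genomes,profiles Optional identifier vectors fixing the matrix
#'   shape (rows/columns); defaults to the identifiers observed in `hits`.
#'   Genomes or profiles with no above-threshold hit get zero rows/columns.
#' @return An integer matrix with genomes as rows and profiles as columns
#'   (both in sorted order), class `"marker_counts"`. Use [tidy()] for a
#'   long tibble view.
#' @export
build_count_matrix <- function(hits, thresholds, genomes = NULL,
                               profiles = NULL) {
  hits <- validate_hits(hits)
  unknown <- setdiff(unique(hits$profile_id), thresholds$profile_id)
  if (length(unknown) > 0L) {
    abort(paste0("no threshold for profile(s): ",
                 paste(sort(unknown), collapse = ", ")))
  }
  genomes <- sort(unique(c(genomes, hits$genome_id)))
  profiles <- sort(unique(c(profiles, hits$profile_id)))
  counts <- matrix(0L, nrow = length(genomes), ncol = length(profiles),
                   dimnames = list(genomes, profiles))
  if (nrow(hits) > 0L) {
    passed <- hits |>
      left_join(thresholds, by = "profile_id") |>
      filter(.data$bit_score >= .data$threshold) |>
      distinct(.data$genome_id, .data$profile_id, .data$protein_id) |>
      count(.data$genome_id, .data$profile_id)
    counts[cbind(passed$genome_id, passed$profile_id)] <-
      as.integer(passed$n)
  }
  structure(counts, class = c("marker_counts", class(counts)))
}

#' @export
print.marker_counts <- function(x, ...) {
  cat(sprintf("marker copy-count matrix: %d genome(s) x %d profile(s)\n",
              nrow(x), ncol(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' Tidy a marker copy-count matrix
#'
#' @param x A `"marker_counts"` matrix from [build_count_matrix()].
#' @param ... Unused.
#' @return A long tibble (`genome_id`, `profile_id`, `n_copies`).
#' @export
tidy.marker_counts <- function(x, ...) {
  tibble(
    genome_id = rep(rownames(x), times = ncol(x)),
    profile_id = rep(colnames(x), each = nrow(x)),
    n_copies = as.integer(x)
  ) |>
    arrange(.data$genome_id, .data$profile_id)
}

#' Single-copy prevalence of a profile within a clade
#'
#' Fraction of the clade's genomes carrying exactly one copy of the profile.
#' A genome with zero or with two or more copies does not count: the
#' quantity gates which profiles qualify as single copy markers for a
#' clade, so only the exactly-once state is evidence in favour.
#'
#' @param counts Copy-count matrix from [build_count_matrix()].
#' @param clade_genomes Genome identifiers of the clade (all must be rows of
#'   `counts`).
#' @param profile_id A single profile (column of `counts`).
#' @return Prevalence in `[0, 1]`.
#' @export
single_copy_prevalence <- function(counts, clade_genomes, profile_id) {
  if (length(clade_genomes) == 0L) {
    abort("clade_genomes is empty")
  }
  missing_g <- setdiff(clade_genomes, rownames(counts))
  if (length(missing_g) > 0L) {
    abort(paste0("genome(s) not in count matrix: ",
                 paste(missing_g, collapse = ", ")))
  }
  if (!profile_id %in% colnames(counts)) {
    abort(paste0("profile not in count matrix: ", profile_id))
  }
  mean(counts[clade_genomes, profile_id] == 1L)
}
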