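#' Read a profile-vs-protein hit table
#'
#' Reads the raw evidence for marker-gene analysis: one row per match of a
#' profile HMM against a predicted protein, with the full-sequence bit score.
#' Two dialects are supported: HMMER3 per-target tabular output
#' (`--tblout`), where the protein is the target and the profile the query,
#' and a plain four-column TSV (`genome_id`, `protein_id`, `profile_id`,
#' `bit_score`).
#'
#' In the HMMER dialect the genome identifier is not part of the format;
#' it is taken from `genome_id`, so one tblout file corresponds to one
#' genome's proteome scan.
#'
#' @param path Path to the hit table.
#' @param dialect `"tsv4"` (default) or `"hmmer-tblout"`.
#' @param genome_id Genome identifier for `"hmmer-tblout"` input (the format
#'   itself does not carry one).
#' @return A tibble with columns `genome_id`, `protein_id`, `profile_id`,
#'   `bit_score`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("# comment", "g1\tp1\tPTHR1\t52.3"), tf)
#' read_hit_table(tf)
#' @export
read_hit_table <- function(path, dialect = c("tsv4", "hmmer-tblout"),
                           genome_id = NULL) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(empty_hits())
  }
  if (dialect == "tsv4") {
    parts <- strsplit(lines[idx], "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 4L)
    if (length(bad) > 0L) {
      abort(sprintf("line %d: expected 4 tab-separated fields", idx[bad[1]]))
    }
    hits <- tibble(
      genome_id  = vapply(parts, `[[`, "", 1L),
      protein_id = vapply(parts, `[[`, "", 2L),
      profile_id = vapply(parts, `[[`, "", 3L),
      bit_score  = suppressWarnings(as.numeric(vapply(parts, `[[`, "", 4L)))
    )
  } else {
    if (is.null(genome_id)) {
      abort("genome_id is required for hmmer-tblout input")
    }
    # tblout: whitespace-separated; col 1 target (protein), col 3 query
    # (profile), col 6 full-sequence bit score
    parts <- strsplit(trimws(lines[idx]), "\\s+")
    bad <- which(lengths(parts) < 6L)
    if (length(bad) > 0L) {
      abort(sprintf("line %d: expected >= 6 whitespace-separated fields",
                    idx[bad[1]]))
    }
    hits <- tibble(
      genome_id  = genome_id,
      protein_id = vapply(parts, `[[`, "", 1L),
      profile_id = vapply(parts, `[[`, "", 3L),
      bit_score  = suppressWarnings(as.numeric(vapply(parts, `[[`, "", 6L)))
    )
  }
  nonnum <- which(is.na(hits$bit_score))
  if (length(nonnum) > 0L) {
    abort(sprintf("line %d: bit score is not numeric", idx[nonnum[1]]))
  }
  validate_hits(hits)
}

#' Write a hit table as four-column TSV
#'
#' The tsv4 dialect round-trips losslessly through [read_hit_table()].
#'
#' @param hits Hit tibble (`genome_id`, `protein_id`, `profile_id`,
#'   `bit_score`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  hits <- validate_hits(hits)
  readr::write_tsv(hits, path, col_names = FALSE)
  invisible(path)
}

empty_hits <- function() {
  tibble(genome_id = character(), protein_id = character(),
         profile_id = character(), bit_score = numeric())
}

# Contract shared by everything downstream: identifiers non-empty, scores
# finite.
validate_hits <- function(hits) {
  hits <- as_tibble(hits)
  need <- c("genome_id", "protein_id", "profile_id", "bit_score")
  missing_cols <- setdiff(need, names(hits))
  if (length(missing_cols) > 0L) {
    abort(paste0("hit table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  hits <- hits[need]
  if (nrow(hits) > 0L) {
    ids <- c(hits$genome_id, hits$protein_id, hits$profile_id)
    if (anyNA(ids) || any(!nzchar(ids))) {
      abort("hit table contains empty or missing identifiers")
    }
    if (any(!is.finite(hits$bit_score))) {
      abort("hit table contains non-finite bit scores")
    }
  }
  hits
}
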