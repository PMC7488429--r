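#' Build a marker database from input files
#'
#' File-level front end for [build_marker_db()]: reads the hit table, the
#' Newick reference tree and the lineage TSV, builds the database, and
#' writes it to `out_dir` with [write_marker_db()]. Building twice from
#' the same inputs — or from a database's own `counts.tsv`-consistent
#' inputs — produces byte-identical output directories.
#'
#' @param hit_path Hit table path (tsv4 dialect).
#' @param tree_path Newick tree over reference genome identifiers.
#' @param lineage_path Two-column lineage TSV.
#' @param out_dir Output database directory.
#' @param config [db_config()].
#' @return The `marker_db`, invisibly.
#' @export
run_build_db <- function(hit_path, tree_path, lineage_path, out_dir,
                         config = db_config()) {
  hits <- read_hit_table(hit_path)
  tree <- read_reference_tree(tree_path, lineage_path)
  db <- build_marker_db(hits, tree, config)
  write_marker_db(db, out_dir)
  inform(sprintf(
    "database written to %s: %d genomes, %d profiles, %d sets, config %s",
    out_dir, nrow(db$counts), ncol(db$counts), nrow(db$sets),
    paste(names(unclass(config)), unlist(config), sep = "=",
          collapse = " ")))
  invisible(db)
}

#' Estimate the quality of a query genome
#'
#' The full two-stage scoring pipeline. Stage one selects the marker set:
#' the query's hits against the reference-set profiles are placed on the
#' reference tree — from a supplied jplace file when phylogenetic
#' placements are available, otherwise with the built-in fallback
#' ([naive_place()]) — the best placement per protein is resolved, and the
#' set encapsulating the largest fraction of placements is chosen
#' ([choose_marker_set()]). Stage two scores the query's per-profile copy
#' counts against the chosen set ([estimate_quality()]) and reports the
#' consensus lineage of the set's species, plus the unassessed genome
#' fraction when contig information is given.
#'
#' Gene prediction and profile-HMM scanning are delegated to external
#' tools (e.g. GeneMark-ES and hmmer): the query arrives as a precomputed
#' hit table of its predicted proteins against the database's profile
#' HMMs, in either supported dialect of [read_hit_table()].
#'
#' @param query_hits Query hit tibble (`genome_id`, `protein_id`,
#'   `profile_id`, `bit_score`) or a path to one (tsv4).
#' @param db A `marker_db` from [build_marker_db()] or [read_marker_db()],
#'   or a database directory path.
#' @param placements Optional jplace path (or placement tibble) with
#'   placements of the reference-set hits; when `NULL` the fallback
#'   placement engine is used.
#' @param contig_lengths Optional named vector of query contig lengths
#'   (bp), enabling the unassessed-fraction output.
#' @param protein_contigs Optional tibble (`protein_id`, `contig`) mapping
#'   query proteins to contigs (required with `contig_lengths`).
#' @param min_evidence Warn loudly when fewer than this fraction of
#'   reference-set profiles produced a placement (default 0.2); a choice
#'   is still returned.
#' @param out_dir Optional directory for artifact files (`report.tsv`,
#'   `profile_counts.tsv`, `placements.tsv`).
#' @return A `magqc_report` object; see [tidy.magqc_report()] and
#'   [glance.magqc_report()].
#' @export
run_estimate <- function(query_hits, db, placements = NULL,
                         contig_lengths = NULL, protein_contigs = NULL,
                         min_evidence = 0.2, out_dir = NULL) {
  if (is.character(db)) db <- read_marker_db(db)
  if (is.character(query_hits)) query_hits <- read_hit_table(query_hits)
  query_hits <- validate_hits(query_hits)
  warnings <- character(0)

  known <- query_hits$profile_id %in% db$thresholds$profile_id
  if (any(!known)) {
    msg <- sprintf("dropping %d hit(s) to profiles unknown to the database",
                   sum(!known))
    warn(msg)
    warnings <- c(warnings, msg)
    query_hits <- query_hits[known, , drop = FALSE]
  }
  passed <- query_hits |>
    inner_join(db$thresholds, by = "profile_id") |>
    filter(.data$bit_score >= .data$threshold)
  if (nrow(passed) == 0L) {
    abort("too few markers: no above-threshold hits in the query",
          class = "magqc_too_few_markers")
  }
  query_counts <- passed |>
    distinct(.data$profile_id, .data$protein_id) |>
    count(.data$profile_id, name = "n_copies") |>
    mutate(n_copies = as.integer(.data$n_copies))

  ref_profiles <- db$reference$profiles
  ref_hits <- passed |>
    filter(.data$profile_id %in% ref_profiles) |>
    select("protein_id", "profile_id", "bit_score")
  if (is.null(placements)) {
    placements <- naive_place(ref_hits, db$reference_map)
  } else if (is.character(placements)) {
    placements <- parse_placements(placements)
  }
  if (nrow(placements) == 0L) {
    abort("too few markers: no reference-set placements for the query",
          class = "magqc_too_few_markers")
  }
  evidence <- length(unique(ref_hits$profile_id)) /
    max(length(ref_profiles), 1L)
  if (evidence < min_evidence) {
    msg <- sprintf(
      paste0("only %.0f%% of reference-set profiles produced placements ",
             "(below %.0f%%): the set choice is weakly supported and the ",
             "genome deserves closer inspection"),
      100 * evidence, 100 * min_evidence)
    warn(msg)
    warnings <- c(warnings, msg)
  }
  best <- resolve_best_placements(placements, db$tree)
  choice <- choose_marker_set(best, db$tree, db$sets)
  warnings <- c(warnings, choice$warnings)

  set_row <- db$sets[db$sets$set_id == choice$set_id, ]
  set_profiles <- set_row$profile_ids[[1]]
  quality <- estimate_quality(
    query_counts |> filter(.data$profile_id %in% set_profiles),
    set_profiles)
  species <- set_row$species_ids[[1]]
  lineage <- consensus_lineage(
    db$tree$lineages$lineage[match(species, db$tree$lineages$genome_id)])

  unassessed <- NA_real_
  if (!is.null(contig_lengths)) {
    if (is.null(protein_contigs)) {
      abort("protein_contigs is required with contig_lengths")
    }
    hit_contigs <- protein_contigs |>
      filter(.data$protein_id %in% unique(passed$protein_id)) |>
      pull("contig") |>
      unique()
    unassessed <- unassessed_fraction(contig_lengths, hit_contigs)
  }

  profile_counts <- tibble(profile_id = sort(set_profiles)) |>
    left_join(query_counts, by = "profile_id") |>
    mutate(n_copies = as.integer(dplyr::coalesce(.data$n_copies, 0L)),
           in_set = TRUE)
  report <- structure(list(
    summary = tibble(
      query_id = query_hits$genome_id[1],
      completeness = quality$completeness,
      contamination = quality$contamination,
      set_id = choice$set_id,
      n_profiles_in_set = quality$n_profiles_in_set,
      coverage_fraction = choice$coverage_fraction,
      lineage = paste(lineage, collapse = ";"),
      unassessed_fraction = unassessed
    ),
    profile_counts = profile_counts,
    placements = best,
    choice = choice,
    reference_evidence = evidence,
    warnings = warnings,
    db_hash = attr(db, "hash") %||% NA_character_
  ), class = "magqc_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(
      report$summary |> mutate(db_hash = report$db_hash),
      file.path(out_dir, "report.tsv"))
    readr::write_tsv(report$profile_counts,
                     file.path(out_dir, "profile_counts.tsv"))
    write_placements(best, file.path(out_dir, "placements.tsv"))
  }
  report
}

#' @export
print.magqc_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("genome quality report for '%s'\n",
           "  completeness:      %6.2f %%\n",
           "  contamination:     %6.2f %%\n",
           "  marker set:        %s (%d profiles, %.1f%% of placements)\n",
           "  lineage:           %s\n"),
    s$query_id, s$completeness, s$contamination, s$set_id,
    s$n_profiles_in_set, 100 * s$coverage_fraction,
    ifelse(nzchar(s$lineage), s$lineage, "<none>")))
  if (!is.na(s$unassessed_fraction)) {
    cat(sprintf("  unassessed:        %6.2f %% of genome length\n",
                100 * s$unassessed_fraction))
  }
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Tidy and summarise quality reports
#'
#' `tidy()` returns the per-profile copy counts of the chosen set
#' (`profile_id`, `n_copies`, `status` in found/duplicated/missing);
#' `glance()` returns the one-row summary used in the report TSV.
#'
#' @param x A `magqc_report`.
#' @param ... Unused.
#' @export
tidy.magqc_report <- function(x, ...) {
  x$profile_counts |>
    mutate(status = dplyr::case_when(
      .data$n_copies >= 2L ~ "duplicated",
      .data$n_copies == 1L ~ "found",
      TRUE ~ "missing"
    )) |>
    select("profile_id", "n_copies", "status")
}

#' @rdname tidy.magqc_report
#' @export
glance.magqc_report <- function(x, ...) {
  x$summary
}

#' @rdname tidy.magqc_report
#' @param object A `magqc_report`.
#' @export
autoplot.magqc_report <- function(object, ...) {
  counts <- tidy(object) |>
    mutate(status = factor(.data$status,
                           levels = c("found", "duplicated", "missing")))
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$status,
                                       fill = .data$status)) +
    ggplot2::geom_bar() +
    ggplot2::labs(
      x = NULL, y = "profiles in chosen set",
      title = sprintf("%s: %.1f%% complete, %.1f%% contaminated",
                      object$summary$query_id,
                      object$summary$completeness,
                      object$summary$contamination)
    ) +
    ggplot2::guides(fill = "none")
}
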