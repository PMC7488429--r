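#' Build a marker-gene database from annotated reference proteomes
#'
#' Runs the full database construction over a reference corpus: calibrates
#' per-profile bit-score thresholds ([calibrate_thresholds()]), builds the
#' genome-by-profile copy-count matrix ([build_count_matrix()]), grows the
#' greedy overlapping reference set used for initial placement
#' ([build_reference_set()]) together with its per-profile best reference
#' genome map (for the fallback placement engine), and mines the
#' clade-specific marker sets over the reference tree
#' ([define_clade_sets()]).
#'
#' @param hits Hit tibble for all reference genomes (`genome_id`,
#'   `protein_id`, `profile_id`, `bit_score`).
#' @param tree A [reference_tree()] over the reference genome identifiers.
#'   Every tip must occur in `hits`.
#' @param config [db_config()].
#' @return A `marker_db` object: list with `config`, `thresholds`,
#'   `counts`, `reference` (greedy set result), `reference_map`, `sets`,
#'   `tree`.
#' @export
build_marker_db <- function(hits, tree, config = db_config()) {
  hits <- validate_hits(hits)
  tips <- tree$phy$tip.label
  missing_t <- setdiff(tips, unique(hits$genome_id))
  extra_g <- setdiff(unique(hits$genome_id), tips)
  if (length(missing_t) > 0L || length(extra_g) > 0L) {
    abort(paste0(
      "tree/hit-table genome mismatch",
      if (length(missing_t) > 0L)
        paste0("; tips without hits: ", paste(missing_t, collapse = ", ")),
      if (length(extra_g) > 0L)
        paste0("; hit genomes not in tree: ",
               paste(extra_g, collapse = ", "))))
  }
  thresholds <- calibrate_thresholds(hits)
  counts <- build_count_matrix(hits, thresholds, genomes = tips)
  reference <- build_reference_set(counts, config)
  reference_map <- reference_genome_map(hits, thresholds, counts,
                                        reference$profiles)
  sets <- define_clade_sets(tree, counts, config)
  structure(list(config = config, thresholds = thresholds, counts = counts,
                 reference = reference, reference_map = reference_map,
                 sets = sets, tree = tree),
            class = "marker_db")
}

# Per reference-set profile, the genome whose single-copy marker protein
# scores highest above threshold: the anchor leaf for naive placement.
reference_genome_map <- function(hits, thresholds, counts, ref_profiles) {
  if (length(ref_profiles) == 0L) {
    return(tibble(profile_id = character(), genome_id = character()))
  }
  single <- tidy(counts) |>
    filter(.data$n_copies == 1L, .data$profile_id %in% ref_profiles)
  hits |>
    inner_join(thresholds, by = "profile_id") |>
    filter(.data$bit_score >= .data$threshold) |>
    inner_join(single, by = c("genome_id", "profile_id")) |>
    group_by(.data$profile_id) |>
    arrange(dplyr::desc(.data$bit_score), .data$genome_id,
            .by_group = TRUE) |>
    slice(1L) |>
    ungroup() |>
    select("profile_id", "genome_id") |>
    arrange(.data$profile_id)
}

#' @export
print.marker_db <- function(x, ...) {
  cat(sprintf(paste0("marker-gene database: %d genomes, %d profiles, ",
                     "%d clade sets, %d-profile reference set\n"),
              nrow(x$counts), ncol(x$counts), nrow(x$sets),
              length(x$reference$profiles)))
  invisible(x)
}

#' Write a marker database to a directory
#'
#' Lays the database out as plain text: `manifest.json` (configuration,
#' reference set in selection order, format version), `thresholds.tsv`,
#' `sets.tsv` (one row per set/profile with the stored prevalence),
#' `reference_map.tsv`, `counts.tsv` (long form), `tree.nwk` and
#' `lineages.tsv`. Writing contains no timestamps, so identical databases
#' produce byte-identical directories.
#'
#' @param db A `marker_db`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_marker_db <- function(db, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    format = "magqc-db-1",
    config = unclass(db$config),
    reference_profiles = db$reference$profiles,
    under_covered = db$reference$under_covered
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  readr::write_tsv(db$thresholds, file.path(dir, "thresholds.tsv"))
  sets_long <- db$sets |>
    select("set_id", "node_id", "profile_ids", "prevalence") |>
    tidyr::unnest_longer("profile_ids", values_to = "profile_id") |>
    group_by(.data$set_id) |>
    mutate(prevalence = purrr::map2_dbl(
      .data$prevalence, .data$profile_id, ~ unname(.x[[.y]]))) |>
    ungroup() |>
    select("set_id", "node_id", "profile_id", "prevalence")
  readr::write_tsv(sets_long, file.path(dir, "sets.tsv"))
  readr::write_tsv(db$reference_map, file.path(dir, "reference_map.tsv"))
  readr::write_tsv(tidy(db$counts), file.path(dir, "counts.tsv"))
  write_reference_tree(db$tree, file.path(dir, "tree.nwk"),
                       file.path(dir, "lineages.tsv"))
  invisible(dir)
}

#' Read a marker database from a directory
#'
#' @param dir Directory written by [write_marker_db()].
#' @return A `marker_db` object; `attr(db, "hash")` carries an MD5 digest
#'   over the database files for provenance reporting.
#' @export
read_marker_db <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    abort(paste0("not a marker database (no manifest.json): ", dir))
  }
  manifest <- jsonlite::fromJSON(manifest_path, simplifyVector = TRUE)
  if (!identical(manifest$format, "magqc-db-1")) {
    abort(paste0("unsupported database format: ", manifest$format))
  }
  cfg <- manifest$config
  config <- db_config(prevalence_cutoff = cfg$prevalence_cutoff,
                      min_species = cfg$min_species,
                      min_profiles = cfg$min_profiles,
                      min_cover = cfg$min_cover,
                      max_per_clade = cfg$max_per_clade,
                      seed = cfg$seed)
  thresholds <- readr::read_tsv(file.path(dir, "thresholds.tsv"),
                                col_types = "cd", progress = FALSE)
  tree <- read_reference_tree(file.path(dir, "tree.nwk"),
                              file.path(dir, "lineages.tsv"))
  counts_long <- readr::read_tsv(file.path(dir, "counts.tsv"),
                                 col_types = "cci", progress = FALSE)
  genomes <- sort(unique(counts_long$genome_id))
  profiles <- sort(unique(counts_long$profile_id))
  counts <- matrix(0L, length(genomes), length(profiles),
                   dimnames = list(genomes, profiles))
  counts[cbind(counts_long$genome_id, counts_long$profile_id)] <-
    counts_long$n_copies
  counts <- structure(counts, class = c("marker_counts", class(counts)))
  reference_map <- readr::read_tsv(file.path(dir, "reference_map.tsv"),
                                   col_types = "cc", progress = FALSE)
  sets_long <- readr::read_tsv(file.path(dir, "sets.tsv"),
                               col_types = "cccd", progress = FALSE)
  tips_under <- descendant_tips(tree$phy)
  ids <- node_ids(tree$phy)
  sets <- sets_long |>
    group_by(.data$set_id, .data$node_id) |>
    summarise(profile_ids = list(.data$profile_id),
              prevalence = list(setNames(.data$prevalence,
                                         .data$profile_id)),
              .groups = "drop") |>
    mutate(
      species_ids = purrr::map(.data$node_id, function(nid) {
        sort(tree$phy$tip.label[tips_under[[node_number(tree$phy, nid)]]])
      }),
      n_species = lengths(.data$species_ids),
      n_profiles = lengths(.data$profile_ids)
    ) |>
    select("set_id", "node_id", "n_species", "n_profiles", "species_ids",
           "profile_ids", "prevalence") |>
    arrange(.data$node_id)
  ref_profiles <- as.character(manifest$reference_profiles)
  single <- unclass(counts) == 1L
  coverage <- setNames(
    as.integer(rowSums(single[, intersect(ref_profiles, colnames(counts)),
                              drop = FALSE])),
    rownames(counts))
  db <- structure(list(
    config = config, thresholds = thresholds, counts = counts,
    reference = list(profiles = ref_profiles, coverage = coverage,
                     under_covered = as.character(manifest$under_covered %||%
                                                    character(0))),
    reference_map = reference_map, sets = sets, tree = tree
  ), class = "marker_db")
  attr(db, "hash") <- db_hash(dir)
  db
}

# digest over the database files (order-stable), for report provenance
db_hash <- function(dir) {
  files <- sort(list.files(dir, full.names = TRUE))
  sums <- tools::md5sum(files)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(basename(files), unname(sums), sep = "  "), tmp)
  unname(tools::md5sum(tmp))
}
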