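#' Database configuration
#'
#' Bundles the constants that govern marker-set mining. The defaults encode
#' the published calibration: clade sets require a single-copy prevalence of
#' at least 98% in a clade of at least 3 species and at least 20 qualifying
#' profile HMMs; the taxonomically balanced calibration subset takes at most
#' 30 genomes per major sub-clade; the greedy reference set covers every
#' genome as a single-copy marker at least 3 times.
#'
#' @param prevalence_cutoff Minimum single-copy prevalence for a profile to
#'   join a clade set, in `(0, 1]`.
#' @param min_species Minimum clade size (tips) for a set to be defined.
#' @param min_profiles Minimum number of qualifying profiles for a set to be
#'   emitted.
#' @param min_cover Target number of reference-set profiles covering each
#'   genome as a single copy.
#' @param max_per_clade Cap on genomes per major sub-clade in the balanced
#'   calibration subset.
#' @param seed Integer seed used wherever the database build samples.
#' @return A list of class `db_config`.
#' @export
db_config <- function(prevalence_cutoff = 0.98, min_species = 3L,
                      min_profiles = 20L, min_cover = 3L,
                      max_per_clade = 30L, seed = 1L) {
  stopifnot(prevalence_cutoff > 0, prevalence_cutoff <= 1,
            min_species >= 2, min_profiles >= 1, min_cover >= 1,
            max_per_clade >= 1)
  structure(list(
    prevalence_cutoff = prevalence_cutoff,
    min_species = as.integer(min_species),
    min_profiles = as.integer(min_profiles),
    min_cover = as.integer(min_cover),
    max_per_clade = as.integer(max_per_clade),
    seed = as.integer(seed)
  ), class = "db_config")
}

#' Mine clade-specific single copy marker gene sets over the reference tree
#'
#' Visits every internal node of the reference tree whose clade holds at
#' least `min_species` genomes, computes each profile's single-copy
#' prevalence over the clade, and emits a marker set when at least
#' `min_profiles` profiles reach `prevalence_cutoff`. Set identifiers are
#' derived from the node label, so the same tree always yields the same
#' sets.
#'
#' @param tree A [reference_tree()]; every tip must be a row of `counts`.
#' @param counts Copy-count matrix from [build_count_matrix()].
#' @param config [db_config()].
#' @return A nested tibble, one row per emitted set: `set_id`, `node_id`,
#'   `n_species`, `n_profiles`, plus list-columns `species_ids`,
#'   `profile_ids` and `prevalence` (named numeric, parallel to
#'   `profile_ids`).
#' @export
define_clade_sets <- function(tree, counts, config = db_config()) {
  phy <- tree$phy
  missing_g <- setdiff(phy$tip.label, rownames(counts))
  if (length(missing_g) > 0L) {
    abort(paste0("tree tip(s) absent from count matrix: ",
                 paste(missing_g, collapse = ", ")))
  }
  n_tip <- length(phy$tip.label)
  tips_under <- descendant_tips(phy)
  ids <- node_ids(phy)
  rows <- list()
  for (v in (n_tip + 1L):(n_tip + phy$Nnode)) {
    clade <- phy$tip.label[tips_under[[v]]]
    if (length(clade) < config$min_species) next
    prev <- colMeans(counts[clade, , drop = FALSE] == 1L)
    ok <- prev >= config$prevalence_cutoff
    if (sum(ok) < config$min_profiles) next
    profiles <- sort(colnames(counts)[ok])
    rows[[length(rows) + 1L]] <- tibble(
      set_id = paste0("set_", ids[v]),
      node_id = ids[v],
      n_species = length(clade),
      n_profiles = length(profiles),
      species_ids = list(sort(clade)),
      profile_ids = list(profiles),
      prevalence = list(prev[profiles])
    )
  }
  if (length(rows) == 0L) {
    return(tibble(set_id = character(), node_id = character(),
                  n_species = integer(), n_profiles = integer(),
                  species_ids = list(), profile_ids = list(),
                  prevalence = list()))
  }
  bind_rows(rows) |> arrange(.data$node_id)
}

#' Build the overlapping greedy reference marker set
#'
#' No single profile is single copy in every reference genome, so the
#' initial placement stage relies on a small set of overlapping single copy
#' markers that jointly cover every genome several times. The set is grown
#' greedily: at each step add the profile that is single copy in the
#' largest number of genomes still covered fewer than `min_cover` times
#' (ties broken by lexicographic profile identifier), until every genome
#' reaches `min_cover` or no remaining profile helps. When some genome can
#' never reach `min_cover`, the best-effort set is returned together with
#' the list of under-covered genomes.
#'
#' @param counts Copy-count matrix from [build_count_matrix()].
#' @param config [db_config()]; uses `min_cover`.
#' @return A list with `profiles` (selection order), `coverage` (named
#'   integer: times each genome is covered as a single copy by the chosen
#'   profiles) and `under_covered` (genomes below `min_cover`; empty when
#'   the instance was feasible).
#' @export
build_reference_set <- function(counts, config = db_config()) {
  if (nrow(counts) == 0L || ncol(counts) == 0L) {
    abort("count matrix is empty")
  }
  single <- unclass(counts) == 1L
  cover <- setNames(integer(nrow(counts)), rownames(counts))
  chosen <- character(0)
  available <- sort(colnames(counts))
  repeat {
    need <- cover < config$min_cover
    if (!any(need) || length(available) == 0L) break
    gain <- colSums(single[need, available, drop = FALSE])
    if (max(gain) == 0L) break
    best <- available[which.max(gain)] # available sorted: first max is lexicographic
    chosen <- c(chosen, best)
    cover <- cover + as.integer(single[, best])
    available <- setdiff(available, best)
  }
  under <- names(cover)[cover < config$min_cover]
  if (length(under) > 0L) {
    warn(paste0("reference set is best-effort; under-covered genome(s): ",
                paste(under, collapse = ", ")))
  }
  list(profiles = chosen, coverage = cover, under_covered = under)
}
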