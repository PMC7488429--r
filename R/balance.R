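#' Select a taxonomically balanced subset of reference genomes
#'
#' Threshold calibration should not be dominated by the deeply sequenced
#' clades, so at most `max_per_clade` genomes are taken per major sub-clade
#' (Opisthokonta, Amoebozoa, Alveolata, ...), sampled evenly across the
#' phyla below each: genomes are drawn round-robin over the phyla, one at a
#' time, skipping exhausted phyla, so any two phyla that still have
#' unselected genomes differ by at most one pick. Both the order of phyla
#' and the order within a phylum are a seeded shuffle, making the selection
#' deterministic for a given seed.
#'
#' @param genomes A tibble with columns `genome_id`, `clade` (major
#'   sub-clade label) and `phylum`.
#' @param config Database configuration from [db_config()]; uses
#'   `max_per_clade` and `seed`.
#' @return Character vector of selected genome identifiers.
#' @export
select_balanced_subset <- function(genomes, config = db_config()) {
  genomes <- as_tibble(genomes)
  if (nrow(genomes) == 0L) {
    abort("no genomes")
  }
  need <- c("genome_id", "clade", "phylum")
  if (!all(need %in% names(genomes))) {
    abort("genomes must have columns genome_id, clade, phylum")
  }
  withr::local_seed(config$seed)
  picked <- lapply(split(genomes, genomes$clade), function(cl) {
    pools <- split(cl$genome_id, cl$phylum)
    pools <- lapply(pools, function(x) sample(x, length(x)))
    pools <- pools[sample(length(pools))]
    out <- character(0)
    while (length(out) < config$max_per_clade && length(pools) > 0L) {
      for (i in seq_along(pools)) {
        if (length(out) >= config$max_per_clade) break
        out <- c(out, pools[[i]][1L])
        pools[[i]] <- pools[[i]][-1L]
      }
      pools <- pools[lengths(pools) > 0L]
    }
    out
  })
  unname(unlist(picked))
}
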