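#' Synthesize a reference corpus fixture
#'
#' Generates, from scratch, everything a database build needs: a random
#' rooted reference tree over `n_species` genomes, per-genome lineages
#' derived from the tree itself (the ancestor path down to `tree_depth`
#' ranks), a genome-by-profile copy-count matrix, per-profile bit-score
#' thresholds, a hit table consistent with the matrix, and short synthetic
#' protein sequences. Each (genome, profile) cell is single copy with
#' probability `1 - per_profile_dropout`, absent with probability
#' `per_profile_dropout * (1 - duplication_rate)` and duplicated (two
#' copies) otherwise — the idealised picture of a marker family across a
#' clade, with dropout standing in for gene loss and annotation failure.
#'
#' Above-threshold hit scores are drawn uniformly from
#' `threshold + [5, 60]` bits; roughly a third of genome-profile pairs
#' additionally receive a sub-threshold noise hit on a separate protein,
#' so threshold application is exercised without changing the counts.
#' Rebuilding the count matrix from the emitted hit table with the emitted
#' thresholds reproduces the matrix exactly.
#'
#' @param n_species Number of reference genomes (>= 4).
#' @param tree_depth Number of lineage ranks to derive (>= 2).
#' @param n_profiles Number of profile HMMs.
#' @param per_profile_dropout Per-cell probability that a profile is not
#'   single copy.
#' @param duplication_rate Among non-single-copy cells, probability of
#'   duplication rather than absence.
#' @param seed Integer seed; the fixture is deterministic given it.
#' @return A list: `tree` ([reference_tree()]), `counts`
#'   (`marker_counts` matrix), `thresholds` (tibble), `hits` (tibble),
#'   `proteins` (`AAStringSet`), `genomes`, `profiles`.
#' @export
synthesize_reference_fixture <- function(n_species = 16, tree_depth = 4,
                                         n_profiles = 30,
                                         per_profile_dropout = 0.05,
                                         duplication_rate = 0.1,
                                         seed = 1L) {
  if (n_species < 4) abort("n_species must be >= 4")
  if (tree_depth < 2) abort("tree_depth must be >= 2")
  if (n_profiles < 1) abort("n_profiles must be >= 1")
  if (per_profile_dropout < 0 || per_profile_dropout > 1) {
    abort("per_profile_dropout must be in [0, 1]")
  }
  if (duplication_rate < 0 || duplication_rate > 1) {
    abort("duplication_rate must be in [0, 1]")
  }
  withr::local_seed(seed)
  genomes <- sprintf("G%03d", seq_len(n_species))
  profiles <- sprintf("PF%04d", seq_len(n_profiles))

  phy <- ape::rtree(n_species, rooted = TRUE, tip.label = sample(genomes))
  phy <- ensure_node_labels(phy)
  lineages <- fixture_lineages(phy, tree_depth)
  tree <- reference_tree(phy, lineages)

  state <- matrix(
    sample(c(1L, 0L, 2L), n_species * n_profiles, replace = TRUE,
           prob = c(1 - per_profile_dropout,
                    per_profile_dropout * (1 - duplication_rate),
                    per_profile_dropout * duplication_rate)),
    nrow = n_species, dimnames = list(genomes, profiles))
  counts <- structure(state, class = c("marker_counts", class(state)))

  thresholds <- tibble(
    profile_id = profiles,
    threshold = round(runif(n_profiles, 50, 250), 1)
  )

  hits <- fixture_hits(counts, thresholds)
  proteins <- Biostrings::AAStringSet(
    setNames(vapply(seq_len(nrow(hits)), function(i) {
      paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 60,
                   replace = TRUE), collapse = "")
    }, ""), hits$protein_id))
  proteins <- proteins[!duplicated(names(proteins))]

  list(tree = tree, counts = counts, thresholds = thresholds, hits = hits,
       proteins = proteins, genomes = genomes, profiles = profiles)
}

# lineage of each tip = its ancestor path from the root, mapped onto the
# first `depth` standard ranks
fixture_lineages <- function(phy, depth) {
  ranks <- c("domain", "clade", "phylum", "class", "order", "family",
             "genus", "species")
  ranks <- ranks[seq_len(min(depth, length(ranks)))]
  par <- parent_vector(phy)
  ids <- node_ids(phy)
  lineage_of <- function(tip) {
    path <- tip
    v <- tip
    while (par[v] != 0L) {
      v <- par[v]
      path <- c(v, path)
    }
    labels <- ids[path]
    # pad/truncate the path to the rank count; the tip label always last
    if (length(labels) >= length(ranks)) {
      labels <- c(labels[seq_len(length(ranks) - 1L)],
                  labels[length(labels)])
    } else {
      labels <- c(labels,
                  rep(labels[length(labels)],
                      length(ranks) - length(labels)))
    }
    paste(paste0(ranks, ":", labels), collapse = ";")
  }
  tibble(
    genome_id = phy$tip.label,
    lineage = vapply(seq_along(phy$tip.label), lineage_of, "")
  )
}

# hit table consistent with a copy-count matrix under the thresholds
fixture_hits <- function(counts, thresholds) {
  thr <- setNames(thresholds$threshold, thresholds$profile_id)
  cells <- tidy(counts)
  rows <- purrr::pmap(cells, function(genome_id, profile_id, n_copies) {
    t <- thr[[profile_id]]
    above <- if (n_copies > 0L) {
      tibble(
        genome_id = genome_id,
        protein_id = sprintf("%s|%s|p%d", genome_id, profile_id,
                             seq_len(n_copies)),
        profile_id = profile_id,
        bit_score = round(t + runif(n_copies, 5, 60), 1)
      )
    }
    noise <- if (runif(1) < 0.3) {
      tibble(
        genome_id = genome_id,
        protein_id = sprintf("%s|%s|noise", genome_id, profile_id),
        profile_id = profile_id,
        bit_score = round(t - runif(1, 10, 40), 1)
      )
    }
    bind_rows(above, noise)
  })
  bind_rows(rows) |> arrange(.data$genome_id, .data$profile_id,
                             .data$protein_id)
}

#' Synthesize a genome with point marker loci
#'
#' Builds the substrate for parameter-recovery experiments: a genome of
#' `n_contigs` contigs totalling `genome_size` bp, with one 1-bp marker
#' locus per profile placed uniformly at random. Point loci make the
#' annotation exact under fragmentation — a marker survives if and only if
#' the fragment containing its position survives — so recovery experiments
#' have a clean binomial truth model.
#'
#' @param profiles Character vector of profile identifiers (one locus each).
#' @param genome_size Total genome length in bp.
#' @param n_contigs Number of contigs (lengths split evenly).
#' @param seed Integer seed.
#' @param with_sequence If `TRUE`, also generate random DNA text (slower);
#'   coordinates alone suffice for most experiments.
#' @return A list: `contig_lengths` (named), `markers` (tibble
#'   `profile_id`, `contig`, `pos`, 1-based), and optionally `sequences`.
#' @export
synthesize_marker_genome <- function(profiles, genome_size = 1e7,
                                     n_contigs = 10, seed = 1L,
                                     with_sequence = FALSE) {
  stopifnot(length(profiles) >= 1, genome_size >= n_contigs)
  withr::local_seed(seed)
  base_len <- floor(genome_size / n_contigs)
  lens <- rep(base_len, n_contigs)
  lens[n_contigs] <- genome_size - base_len * (n_contigs - 1L)
  names(lens) <- sprintf("contig%02d", seq_len(n_contigs))
  pos_global <- sort(sample.int(genome_size, length(profiles)))
  offsets <- cumsum(c(0, lens[-n_contigs]))
  idx <- findInterval(pos_global - 1, offsets) # contig index per locus
  markers <- tibble(
    profile_id = sample(profiles), # decouple id order from position order
    contig = names(lens)[idx],
    pos = as.integer(pos_global - offsets[idx])
  )
  out <- list(contig_lengths = lens, markers = markers)
  if (with_sequence) {
    out$sequences <- setNames(
      vapply(lens, function(l) random_dna(l, 0.5), ""), names(lens))
  }
  out
}

#' Count surviving marker loci per profile in a set of kept fragments
#'
#' The exact-annotation counterpart of a profile-HMM scan: a marker locus
#' is recovered by a fragment when its position falls inside the
#' fragment's half-open source interval, and the per-profile copy count is
#' the number of recovered loci (target and contaminant fragments both
#' contribute, so in-clade contamination shows up as duplicated profiles).
#'
#' @param fragments Fragment tibble with `source_seq`, `start`, `end` (and
#'   optionally `label`).
#' @param markers Marker tibble (`profile_id`, `contig`, `pos`) for the
#'   genome the fragments were cut from; when target and contaminant come
#'   from different genomes, call once per genome on the matching fragment
#'   subset and add the results.
#' @return Tibble (`profile_id`, `n_copies`) over all profiles in
#'   `markers`, including zero rows.
#' @export
count_markers_in_fragments <- function(fragments, markers) {
  hits <- markers |>
    inner_join(fragments, by = c(contig = "source_seq"),
               relationship = "many-to-many") |>
    filter(.data$pos > .data$start, .data$pos <= .data$end) |>
    count(.data$profile_id, name = "n_copies")
  tibble(profile_id = sort(unique(markers$profile_id))) |>
    left_join(hits, by = "profile_id") |>
    mutate(n_copies = as.integer(dplyr::coalesce(.data$n_copies, 0L)))
}
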