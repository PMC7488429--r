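# Shared fixture builders and independent oracles. Everything is generated
# in code; no data files.

# reference tree from a newick string, with simple per-tip lineages derived
# from the tip name unless supplied
toy_tree <- function(newick, lineages = NULL) {
  phy <- ape::read.tree(text = newick)
  if (is.null(lineages)) {
    lineages <- tibble::tibble(
      genome_id = phy$tip.label,
      lineage = paste0("domain:Eukaryota;species:", phy$tip.label)
    )
  }
  reference_tree(phy, lineages)
}

# random hit table for threshold fuzzing: integer-ish scores force ties
random_hit_table <- function(n_genomes, max_hits_per_genome = 10,
                             score_levels = 20) {
  rows <- lapply(seq_len(n_genomes), function(g) {
    k <- sample.int(max_hits_per_genome, 1)
    tibble::tibble(
      genome_id = sprintf("g%02d", g),
      protein_id = sprintf("g%02d_p%d", g, seq_len(k)),
      profile_id = "P1",
      bit_score = sample.int(score_levels, k, replace = TRUE) * 5
    )
  })
  dplyr::bind_rows(rows)
}

# independent exhaustive-scan oracle for threshold calibration: try every
# distinct observed score, count genomes with exactly one surviving hit,
# keep the largest score attaining the maximum
oracle_threshold <- function(hits) {
  cands <- unique(hits$bit_score)
  singles <- vapply(cands, function(t) {
    per_genome <- vapply(split(hits$bit_score, hits$genome_id),
                         function(s) sum(s >= t), integer(1))
    sum(per_genome == 1L)
  }, integer(1))
  max(cands[singles == max(singles)])
}

# round-robin even-allocation oracle: how many genomes each phylum should
# contribute when `cap` are drawn one-per-phylum in rotation
oracle_allocation <- function(pool_sizes, cap) {
  taken <- rep(0L, length(pool_sizes))
  while (sum(taken) < min(cap, sum(pool_sizes))) {
    for (i in seq_along(pool_sizes)) {
      if (sum(taken) >= cap) break
      if (taken[i] < pool_sizes[i]) taken[i] <- taken[i] + 1L
    }
  }
  taken
}

# marker-count matrix from explicit per-genome counts (profiles x genomes
# given as a named list of named vectors)
counts_matrix <- function(genomes, profiles, fill = 0L) {
  m <- matrix(as.integer(fill), length(genomes), length(profiles),
              dimnames = list(genomes, profiles))
  structure(m, class = c("marker_counts", class(m)))
}

# random tree with marker sets on a random subset of internal nodes and
# random placements, for set-choice fuzzing
random_choice_instance <- function(n_tips = NULL) {
  if (is.null(n_tips)) n_tips <- sample(5:12, 1)
  phy <- ape::rtree(n_tips)
  rt <- toy_tree(ape::write.tree(phy))
  phy <- rt$phy
  internal <- seq_len(phy$Nnode) + n_tips
  set_nodes <- sample(internal, max(1L, rbinom(1, length(internal), 0.5)))
  ids <- c(phy$tip.label, phy$node.label)
  sets <- tibble::tibble(
    set_id = paste0("set_", ids[set_nodes]),
    node_id = ids[set_nodes],
    n_species = NA_integer_, n_profiles = NA_integer_,
    species_ids = list(character(0)),
    profile_ids = replicate(length(set_nodes),
                            sprintf("PF%02d", 1:20), simplify = FALSE),
    prevalence = list(numeric(0))
  )
  n_place <- sample(2:10, 1)
  place_nodes <- sample(seq_len(n_tips + phy$Nnode), n_place, replace = TRUE)
  placements <- tibble::tibble(
    protein_id = sprintf("q%02d", seq_len(n_place)),
    node_id = ids[place_nodes],
    support = runif(n_place)
  )
  list(tree = rt, sets = sets, placements = placements)
}

# independent oracle for set choice: score EVERY set-bearing node by walking
# each placement's root path (a placement is inside clade v iff v lies on
# its path to the root); pick max count, deepest, then set_id; NULL when no
# set contains a placement and no ancestor of the placements' LCA has one
oracle_choose <- function(tree, sets, placements) {
  phy <- tree$phy
  ids <- c(phy$tip.label, phy$node.label)
  par <- integer(length(ids))
  par[phy$edge[, 2]] <- phy$edge[, 1]
  root_path <- function(v) {
    p <- v
    while (par[v] != 0L) {
      v <- par[v]
      p <- c(p, v)
    }
    p
  }
  depth <- vapply(seq_along(ids), function(v) length(root_path(v)) - 1L,
                  integer(1))
  place_nodes <- match(placements$node_id, ids)
  paths <- lapply(place_nodes, root_path)
  set_nodes <- match(sets$node_id, ids)
  n_in <- vapply(set_nodes, function(v) {
    sum(vapply(paths, function(p) v %in% p, logical(1)))
  }, integer(1))
  cand <- which(n_in > 0L)
  lca_path <- Reduce(intersect, paths)
  hpa <- lca_path[lca_path %in% set_nodes][1]
  if (!is.na(hpa)) cand <- union(cand, which(set_nodes == hpa))
  if (length(cand) == 0L) return(NULL)
  ord <- order(-n_in[cand], -depth[set_nodes[cand]], sets$set_id[cand])
  best <- cand[ord[1]]
  list(set_id = sets$set_id[best], n_covered = n_in[best])
}

# exhaustive minimum-cover oracle for small instances: smallest subset of
# profiles giving every genome single-copy coverage >= min_cover
oracle_min_cover <- function(counts, min_cover) {
  single <- unclass(counts) == 1L
  profiles <- colnames(counts)
  for (k in seq_along(profiles)) {
    combs <- utils::combn(profiles, k, simplify = FALSE)
    for (s in combs) {
      if (all(rowSums(single[, s, drop = FALSE]) >= min_cover)) {
        return(k)
      }
    }
  }
  Inf
}

# parameter-recovery harness: fragment + subsample a marker genome and
# count surviving point loci per profile (exact annotation)
recover_counts <- function(marker_genome, target_fraction, seed,
                           config = sim_config()) {
  withr::local_seed(seed)
  frags <- fragment_genome(marker_genome$contig_lengths, config, seed = NULL)
  kept <- subsample_to_fraction(frags, target_fraction, seed = NULL)
  count_markers_in_fragments(kept, marker_genome$markers)
}
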