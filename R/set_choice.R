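#' Choose the marker set whose clade encapsulates the most placements
#'
#' Given the best placement of each query protein on the reference tree,
#' selects the single copy marker gene set to score the genome with.
#' Candidate sets are every set whose clade contains at least one
#' placement, plus — for the lowest common ancestor (LCA) of all
#' placements — the nearest ancestor that owns a set (the "highest
#' possible ancestor" ascent, for when the LCA itself has none). Among
#' candidates the set containing the largest number of placements wins;
#' ties go to the deeper, more specific node, then to the set identifier.
#'
#' When placements land in inconsistent, distantly related clades no set
#' contains them all; the chosen set then covers only a fraction of the
#' placements, which is reported as `coverage_fraction` with a warning, so
#' that low-coverage choices can be flagged for closer inspection.
#'
#' @param best_placements Tibble with one placement per protein
#'   (`protein_id`, `node_id`, `support`), e.g. from
#'   [resolve_best_placements()].
#' @param tree A [reference_tree()].
#' @param sets Nested set tibble from [define_clade_sets()].
#' @return A list of class `set_choice`: `set_id`, `node_id`,
#'   `n_placements`, `n_covered`, `coverage_fraction`, `warnings`.
#' @export
choose_marker_set <- function(best_placements, tree, sets) {
  if (nrow(best_placements) == 0L) {
    abort("no placements")
  }
  if (nrow(sets) == 0L) {
    abort("no applicable marker set", class = "magqc_no_set")
  }
  phy <- tree$phy
  tips_under <- descendant_tips(phy)
  depth <- node_depths(phy)
  par <- parent_vector(phy)
  place_nodes <- node_number(phy, best_placements$node_id)
  set_nodes <- node_number(phy, sets$node_id)

  # placements inside a set's clade: placement node is the set node itself
  # or lies in its subtree (tip placements are tips; internal placements
  # count when the internal node is within the clade)
  in_clade <- function(v) {
    clade_nodes <- c(v, subtree_nodes(phy, v, tips_under))
    sum(place_nodes %in% clade_nodes)
  }
  n_in <- vapply(set_nodes, in_clade, integer(1))

  candidates <- which(n_in > 0L)
  # HPA ascent: nearest set-bearing ancestor of the LCA of all placements
  lca <- lca_node(phy, place_nodes)
  v <- lca
  repeat {
    hit <- which(set_nodes == v)
    if (length(hit) > 0L) {
      candidates <- union(candidates, hit)
      break
    }
    if (par[v] == 0L) break
    v <- par[v]
  }
  if (length(candidates) == 0L) {
    abort("no applicable marker set", class = "magqc_no_set")
  }
  cand <- tibble(
    idx = candidates,
    set_id = sets$set_id[candidates],
    n_covered = n_in[candidates],
    depth = depth[set_nodes[candidates]]
  ) |>
    arrange(dplyr::desc(.data$n_covered), dplyr::desc(.data$depth),
            .data$set_id)
  top <- cand[1L, ]
  n_place <- nrow(best_placements)
  warnings <- character(0)
  coverage <- top$n_covered / n_place
  if (coverage < 1) {
    warnings <- c(warnings, sprintf(
      "chosen set '%s' contains only %d of %d placements (%.1f%%)",
      top$set_id, top$n_covered, n_place, 100 * coverage))
    warn(warnings[length(warnings)])
  }
  structure(list(
    set_id = top$set_id,
    node_id = sets$node_id[top$idx],
    n_placements = n_place,
    n_covered = as.integer(top$n_covered),
    coverage_fraction = coverage,
    warnings = warnings
  ), class = "set_choice")
}

#' @export
print.set_choice <- function(x, ...) {
  cat(sprintf("marker set choice: %s at node %s (%d/%d placements, %.1f%%)\n",
              x$set_id, x$node_id, x$n_covered, x$n_placements,
              100 * x$coverage_fraction))
  invisible(x)
}

# all node numbers strictly inside the subtree of v (tips and internals)
subtree_nodes <- function(phy, v, tips_under) {
  n_tip <- length(phy$tip.label)
  if (v <= n_tip) {
    return(integer(0))
  }
  tips <- tips_under[[v]]
  par <- parent_vector(phy)
  # subtree members are exactly the nodes on tip-to-v paths (excluding v)
  seen <- integer(0)
  for (t in tips) {
    u <- t
    while (u != v && !(u %in% seen)) {
      seen <- c(seen, u)
      u <- par[u]
    }
  }
  unique(seen)
}
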