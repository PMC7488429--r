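#' Parse a jplace (version 3) placement document
#'
#' Reads phylogenetic placements of query proteins on the reference tree,
#' as produced by placement tools such as pplacer. Each query may have
#' several candidate locations; one row is returned per (query, location)
#' pair. The support value is read from the posterior-probability field
#' when the document declares one, otherwise from the likelihood weight
#' ratio. Edge numbers in the embedded tree (the `{N}` annotations) are
#' resolved to the label of the node the edge leads to, so placements can
#' be traced on the reference tree by name.
#'
#' @param path Path to a jplace file, or an already-parsed list (as from
#'   `jsonlite::fromJSON(..., simplifyVector = FALSE)`).
#' @return A tibble with columns `protein_id`, `edge_num`, `node_id`,
#'   `support`.
#' @export
parse_placements <- function(path) {
  doc <- if (is.character(path)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    path
  }
  if (is.null(doc$fields) || is.null(doc$tree)) {
    abort("not a jplace document: missing 'fields' or 'tree'")
  }
  fields <- unlist(doc$fields)
  edge_i <- match("edge_num", fields)
  if (is.na(edge_i)) {
    abort(paste0("jplace fields lack 'edge_num'; available: ",
                 paste(fields, collapse = ", ")))
  }
  support_field <- if ("post_prob" %in% fields) {
    "post_prob"
  } else if ("like_weight_ratio" %in% fields) {
    "like_weight_ratio"
  } else {
    abort(paste0("no support field (post_prob or like_weight_ratio); ",
                 "available: ", paste(fields, collapse = ", ")))
  }
  support_i <- match(support_field, fields)
  edge_map <- jplace_edge_map(doc$tree)
  rows <- purrr::map(doc$placements, function(pl) {
    names_field <- pl$n %||% pl$nm
    if (is.null(names_field)) {
      abort("placement entry lacks 'n'/'nm' query names")
    }
    qnames <- vapply(names_field, function(x) as.character(unlist(x)[1]), "")
    purrr::map(pl$p, function(p) {
      p <- unlist(p)
      tibble(
        protein_id = qnames,
        edge_num = as.integer(p[edge_i]),
        support = as.numeric(p[support_i])
      )
    }) |> bind_rows()
  }) |> bind_rows()
  if (nrow(rows) == 0L) {
    return(tibble(protein_id = character(), edge_num = integer(),
                  node_id = character(), support = numeric()))
  }
  unknown <- setdiff(rows$edge_num, edge_map$edge_num)
  if (length(unknown) > 0L) {
    abort(paste0("edge number(s) not in jplace tree: ",
                 paste(unknown, collapse = ", ")))
  }
  rows |>
    left_join(edge_map, by = "edge_num") |>
    select("protein_id", "edge_num", "node_id", "support")
}

# Map jplace {N} edge numbers to the label of the node each edge leads to.
# The {N} annotation follows the branch length of the edge above a node; we
# splice it into the node label, parse with ape, and read it back out.
jplace_edge_map <- function(tree_string) {
  tagged <- gsub("([^,():{}]*)((?::[^,(){}]*)?)\\{([0-9]+)\\}",
                 "\\1@@\\3\\2", tree_string, perl = TRUE)
  phy <- ape::read.tree(text = tagged)
  if (is.null(phy)) {
    abort("could not parse jplace tree")
  }
  labels <- c(phy$tip.label,
              if (is.null(phy$node.label)) rep("", phy$Nnode) else phy$node.label)
  has_tag <- grepl("@@", labels)
  edge_num <- rep(NA_integer_, length(labels))
  edge_num[has_tag] <- as.integer(sub(".*@@", "", labels[has_tag]))
  clean <- sub("@@[0-9]+$", "", labels)
  phy$tip.label <- clean[seq_along(phy$tip.label)]
  phy$node.label <- clean[-seq_along(phy$tip.label)]
  phy <- ensure_node_labels(phy)
  tibble(edge_num = edge_num, node_id = node_ids(phy))[has_tag, ]
}

#' Resolve the best placement per query protein
#'
#' Keeps, for every protein, the candidate location with the highest
#' support ("the best placement"). Support ties are broken toward the
#' location closer to the root — the conservative choice, since a rootward
#' node makes a weaker claim about the query's clade — and any remaining
#' tie by node identifier.
#'
#' @param placements Tibble from [parse_placements()] or [naive_place()].
#' @param tree A [reference_tree()] (or `phylo`) used for node depths.
#' @return One row per `protein_id`, same columns as the input.
#' @export
resolve_best_placements <- function(placements, tree) {
  phy <- if (inherits(tree, "reference_tree")) tree$phy else tree
  if (nrow(placements) == 0L) {
    return(placements)
  }
  depth <- node_depths(phy)
  placements |>
    mutate(.depth = depth[node_number(phy, .data$node_id)]) |>
    group_by(.data$protein_id) |>
    arrange(dplyr::desc(.data$support), .data$.depth, .data$node_id,
            .by_group = TRUE) |>
    slice(1L) |>
    ungroup() |>
    select(-".depth") |>
    arrange(.data$protein_id)
}

#' Place query proteins on reference-genome leaves without a placement tool
#'
#' Fallback placement engine used when no jplace file is supplied: each
#' query protein hitting a reference-set profile is placed on the leaf of
#' the reference genome whose marker protein for that profile scores
#' highest, with support 1.0. This is a coarse nearest-reference heuristic,
#' not a phylogenetic placement; it keeps the pipeline runnable when
#' pplacer output is unavailable.
#'
#' @param query_hits Hit tibble for the query restricted to reference-set
#'   profiles (`protein_id`, `profile_id`, `bit_score`).
#' @param reference_map Tibble (`profile_id`, `genome_id`) naming, per
#'   reference-set profile, the reference genome with the top-scoring
#'   single-copy marker (stored in the database manifest at build time).
#' @return A placement tibble (`protein_id`, `edge_num` = `NA`, `node_id`,
#'   `support`); proteins whose best profile has no reference mapping are
#'   skipped with a warning.
#' @export
naive_place <- function(query_hits, reference_map) {
  if (nrow(query_hits) == 0L) {
    return(tibble(protein_id = character(), edge_num = integer(),
                  node_id = character(), support = numeric()))
  }
  best <- query_hits |>
    group_by(.data$protein_id) |>
    arrange(dplyr::desc(.data$bit_score), .data$profile_id,
            .by_group = TRUE) |>
    slice(1L) |>
    ungroup()
  unmapped <- setdiff(unique(best$profile_id), reference_map$profile_id)
  if (length(unmapped) > 0L) {
    skipped <- best |> filter(.data$profile_id %in% unmapped)
    warn(paste0("no reference genome for profile(s) ",
                paste(sort(unmapped), collapse = ", "), "; skipping ",
                nrow(skipped), " protein(s)"))
  }
  best |>
    inner_join(reference_map, by = "profile_id") |>
    mutate(edge_num = NA_integer_, node_id = .data$genome_id,
           support = 1.0) |>
    select("protein_id", "edge_num", "node_id", "support") |>
    arrange(.data$protein_id)
}

#' Write placements as TSV
#'
#' Per-placement node assignments (`protein_id`, `node_id`, `support`),
#' the tabular counterpart of a placement plot.
#'
#' @param placements Placement tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_placements <- function(placements, path) {
  readr::write_tsv(placements[, c("protein_id", "node_id", "support")], path)
  invisible(path)
}
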