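#' Construct a reference tree with per-genome lineages
#'
#' The reference tree is a rooted `ape::phylo` tree whose tips are reference
#' genome identifiers; internal nodes are the anchors to which clade marker
#' sets are attached, and each tip carries an NCBI-style taxonomic lineage
#' used for consensus lineage reporting. Internal nodes without a label get
#' a deterministic `N<node-number>` label so that sets and placements can
#' refer to them by name.
#'
#' @param phy A rooted `phylo` object with unique tip labels.
#' @param lineages Tibble with columns `genome_id` and `lineage`
#'   (semicolon-separated `rank:name` entries, most inclusive rank first).
#'   Every tip must have a lineage.
#' @return A `reference_tree` object (list with `$phy` and `$lineages`).
#' @export
reference_tree <- function(phy, lineages) {
  if (!inherits(phy, "phylo")) {
    abort("phy must be an ape phylo object")
  }
  if (!ape::is.rooted(phy)) {
    abort("reference tree must be rooted")
  }
  if (anyDuplicated(phy$tip.label)) {
    abort("tip labels must be unique")
  }
  phy <- ensure_node_labels(phy)
  lineages <- as_tibble(lineages)
  if (!all(c("genome_id", "lineage") %in% names(lineages))) {
    abort("lineages must have columns genome_id, lineage")
  }
  missing_l <- setdiff(phy$tip.label, lineages$genome_id)
  if (length(missing_l) > 0L) {
    abort(paste0("no lineage for tip(s): ", paste(missing_l, collapse = ", ")))
  }
  structure(list(phy = phy, lineages = lineages), class = "reference_tree")
}

#' @export
print.reference_tree <- function(x, ...) {
  cat(sprintf("reference tree: %d genomes, %d internal nodes\n",
              length(x$phy$tip.label), x$phy$Nnode))
  invisible(x)
}

#' Read a reference tree from Newick plus a lineage TSV
#'
#' @param tree_path Newick file; tip labels are genome identifiers.
#' @param lineage_path Two-column TSV (`genome_id`, `lineage`), no header,
#'   lineage as semicolon-separated `rank:name` entries.
#' @return A [reference_tree()] object.
#' @export
read_reference_tree <- function(tree_path, lineage_path) {
  txt <- paste(readLines(tree_path, warn = FALSE), collapse = "\n")
  check_newick(txt, tree_path)
  phy <- tryCatch(ape::read.tree(text = txt),
                  error = function(e) NULL)
  if (is.null(phy) || !inherits(phy, "phylo")) {
    abort(paste0(tree_path, ": not parseable as Newick"))
  }
  lineages <- readr::read_tsv(lineage_path,
                              col_names = c("genome_id", "lineage"),
                              col_types = "cc", progress = FALSE)
  reference_tree(phy, lineages)
}

#' Write a reference tree and its lineage table
#'
#' @param rt A [reference_tree()] object.
#' @param tree_path,lineage_path Output paths (Newick, TSV).
#' @return `tree_path`, invisibly.
#' @export
write_reference_tree <- function(rt, tree_path, lineage_path) {
  ape::write.tree(rt$phy, file = tree_path)
  readr::write_tsv(rt$lineages[, c("genome_id", "lineage")], lineage_path,
                   col_names = FALSE)
  invisible(tree_path)
}

# Rudimentary structural check so malformed input is reported with a
# position (ape's own errors carry none).
check_newick <- function(txt, path = "<text>") {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) {
      loc <- char_location(txt, i)
      abort(sprintf("%s: unbalanced ')' at line %d, column %d",
                    path, loc[1], loc[2]))
    }
  }
  if (depth != 0L) {
    loc <- char_location(txt, length(chars))
    abort(sprintf("%s: %d unclosed '(' by line %d, column %d",
                  path, depth, loc[1], loc[2]))
  }
  if (!grepl(";", txt, fixed = TRUE)) {
    abort(paste0(path, ": missing terminating ';' in Newick"))
  }
  invisible(TRUE)
}

char_location <- function(txt, i) {
  prefix <- strsplit(substr(txt, 1, i), "")[[1]]
  nl <- which(prefix == "\n")
  line <- length(nl) + 1L
  col <- i - if (length(nl) == 0L) 0L else max(nl)
  c(line, col)
}

ensure_node_labels <- function(phy) {
  n_tip <- length(phy$tip.label)
  lab <- phy$node.label
  if (is.null(lab)) lab <- rep("", phy$Nnode)
  blank <- is.na(lab) | !nzchar(lab)
  lab[blank] <- paste0("N", which(blank) + n_tip)
  phy$node.label <- lab
  phy
}

# node number (ape convention: tips 1..n, internal n+1..n+Nnode) -> label
node_ids <- function(phy) {
  c(phy$tip.label, phy$node.label)
}

node_number <- function(phy, node_id) {
  ids <- node_ids(phy)
  num <- match(node_id, ids)
  if (anyNA(num)) {
    abort(paste0("unknown tree node(s): ",
                 paste(node_id[is.na(num)], collapse = ", ")))
  }
  num
}

# parent of every node (0 for the root), indexed by node number
parent_vector <- function(phy) {
  n <- length(phy$tip.label) + phy$Nnode
  par <- integer(n)
  par[phy$edge[, 2]] <- phy$edge[, 1]
  par
}

# depth = number of edges from the root, indexed by node number
node_depths <- function(phy) {
  par <- parent_vector(phy)
  n <- length(par)
  depth <- rep(NA_integer_, n)
  root <- which(par == 0L)
  depth[root] <- 0L
  # edges in ape preorder guarantee parents appear before children, but be
  # safe and iterate until fixed point
  repeat {
    todo <- which(is.na(depth))
    if (length(todo) == 0L) break
    depth[todo] <- depth[par[todo]] + 1L
  }
  depth
}

# tip numbers under each node (a tip is under itself), as a list indexed by
# node number; computed by accumulating over edges child-first
descendant_tips <- function(phy) {
  n_tip <- length(phy$tip.label)
  n <- n_tip + phy$Nnode
  tips <- vector("list", n)
  for (i in seq_len(n_tip)) tips[[i]] <- i
  # postorder over edges: children complete before their parent edge
  for (e in ape::postorder(phy)) {
    par <- phy$edge[e, 1]
    child <- phy$edge[e, 2]
    tips[[par]] <- c(tips[[par]], tips[[child]])
  }
  tips
}

# most recent common ancestor of a set of node numbers (itself if one node)
lca_node <- function(phy, nodes) {
  nodes <- unique(nodes)
  if (length(nodes) == 1L) {
    return(nodes)
  }
  par <- parent_vector(phy)
  path_to_root <- function(v) {
    p <- v
    while (par[v] != 0L) {
      v <- par[v]
      p <- c(p, v)
    }
    p
  }
  common <- Reduce(intersect, lapply(nodes, path_to_root))
  common[1L] # paths are ordered node -> root, first shared is deepest
}

# Split "rank:name;rank:name;..." into a character vector of entries.
split_lineage <- function(lineage) {
  if (is.na(lineage) || !nzchar(lineage)) {
    return(character(0))
  }
  trimws(strsplit(lineage, ";", fixed = TRUE)[[1]])
}
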