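#' Completeness and contamination from marker copy counts
#'
#' The core quality statistic: against the chosen clade's single copy
#' marker gene set, the fraction of profiles found at least once is the
#' completeness, and the fraction found in two or more copies is the
#' contamination — both as percentages of the set size. A duplicated
#' profile is also a found profile, so contamination can never exceed
#' completeness. A profile's copy number beyond two does not increase the
#' estimate further (fraction-of-profiles semantics); per-profile counts
#' are kept in the report for inspection.
#'
#' @param query_counts Tibble (`profile_id`, `n_copies`) of marker copy
#'   counts observed in the query genome. Profiles outside the set are
#'   ignored with a warning; set profiles absent from the table count as
#'   zero copies.
#' @param set_profiles Character vector of the chosen set's profile
#'   identifiers.
#' @return A one-row tibble: `completeness`, `contamination` (percent),
#'   `n_profiles_in_set`, `n_found`, `n_duplicated`.
#' @examples
#' counts <- tibble::tibble(
#'   profile_id = paste0("PF", 1:15),
#'   n_copies = c(rep(1, 13), 2, 2)
#' )
#' estimate_quality(counts, paste0("PF", 1:20)) # 75% complete, 10% contaminated
#' @export
estimate_quality <- function(query_counts, set_profiles) {
  if (length(set_profiles) == 0L) {
    abort("marker set is empty")
  }
  query_counts <- as_tibble(query_counts)
  extra <- setdiff(query_counts$profile_id, set_profiles)
  if (length(extra) > 0L) {
    warn(sprintf("ignoring %d profile(s) outside the chosen set",
                 length(extra)))
    query_counts <- query_counts |>
      filter(.data$profile_id %in% set_profiles)
  }
  n <- length(set_profiles)
  n_found <- sum(query_counts$n_copies >= 1L)
  n_dup <- sum(query_counts$n_copies >= 2L)
  tibble(
    completeness = 100 * n_found / n,
    contamination = 100 * n_dup / n,
    n_profiles_in_set = n,
    n_found = as.integer(n_found),
    n_duplicated = as.integer(n_dup)
  )
}

#' Fraction of the genome invisible to marker-based scoring
#'
#' Contigs carrying no marker hit contribute nothing to the completeness
#' and contamination estimates; this reports the fraction of total genome
#' length on such contigs, so that a genome padded with short marker-free
#' contigs is not silently over-trusted.
#'
#' @param contig_lengths Named numeric vector of contig lengths (bp).
#' @param marker_hit_contigs Character vector of contigs with at least one
#'   marker hit (must be a subset of `names(contig_lengths)`).
#' @return Fraction in `[0, 1]`.
#' @export
unassessed_fraction <- function(contig_lengths, marker_hit_contigs) {
  if (length(contig_lengths) == 0L || sum(contig_lengths) == 0) {
    abort("empty genome")
  }
  stray <- setdiff(marker_hit_contigs, names(contig_lengths))
  if (length(stray) > 0L) {
    abort(paste0("hit contig(s) not in genome: ",
                 paste(stray, collapse = ", ")))
  }
  unassessed <- setdiff(names(contig_lengths), marker_hit_contigs)
  sum(contig_lengths[unassessed]) / sum(contig_lengths)
}

#' Strict consensus lineage of the chosen set's species
#'
#' The taxonomic lineage reported for a query is the longest rank prefix on
#' which every species used to build the chosen marker set agrees; the
#' lineage stops at the first rank where any species disagrees. Strict
#' (100%) agreement is the conservative reading of a consensus taxonomy.
#'
#' @param species_lineages Character vector of semicolon-separated
#'   `rank:name` lineages, or a list of already-split character vectors.
#' @return Character vector of agreed `rank:name` entries (possibly empty,
#'   with a warning).
#' @export
consensus_lineage <- function(species_lineages) {
  if (length(species_lineages) == 0L) {
    abort("no lineages")
  }
  parts <- if (is.list(species_lineages)) {
    species_lineages
  } else {
    lapply(species_lineages, split_lineage)
  }
  depth_max <- min(lengths(parts))
  agreed <- character(0)
  for (i in seq_len(depth_max)) {
    entry <- unique(vapply(parts, `[[`, "", i))
    if (length(entry) != 1L) break
    agreed <- c(agreed, entry)
  }
  if (length(agreed) == 0L) {
    warn("species lineages disagree at the first rank; empty consensus")
  }
  agreed
}

#' Marker-uniformity diagnostic
#'
#' Marker-based quality estimates are only trustworthy when the markers are
#' spread evenly along the genome, so that any subset of contigs carries a
#' proportional share of them. This diagnostic accumulates non-overlapping
#' random fragments (default 5 kb) and, after each draw, records the
#' cumulative sampled length and the number of distinct markers recovered
#' so far; the Pearson correlation of the two series approaches 1 for
#' uniformly distributed markers and drops when markers are clustered.
#'
#' Fragments are drawn without replacement from the non-overlapping
#' `fragment_size` windows tiling each contig (a tail shorter than one
#' fragment is never sampled); overlapping draws would recover the same
#' markers twice and inflate the correlation.
#'
#' @param contig_lengths Named numeric vector of contig lengths (bp).
#' @param marker_positions Tibble (`profile_id`, `contig`, `pos`) of marker
#'   locus positions (1-based) on the contigs.
#' @param fragment_size Fragment length in bp (default 5000).
#' @param n_steps Number of fragments to accumulate; default all available
#'   windows.
#' @param seed Integer seed; the sampled windows are deterministic given it.
#' @return A list of class `marker_uniformity`: `r` (Pearson correlation),
#'   `series` (tibble `step`, `cum_bp`, `n_markers`), `n_fragments`.
#' @export
marker_uniformity <- function(contig_lengths, marker_positions,
                              fragment_size = 5000, n_steps = NULL,
                              seed = 1L) {
  if (nrow(marker_positions) < 2L) {
    abort("need at least 2 markers")
  }
  if (sum(contig_lengths) < fragment_size) {
    abort("genome shorter than one fragment")
  }
  windows <- purrr::imap(contig_lengths, function(len, contig) {
    k <- floor(len / fragment_size)
    if (k == 0L) return(NULL)
    tibble(contig = contig,
           start = (seq_len(k) - 1) * fragment_size, # 0-based half-open
           end = seq_len(k) * fragment_size)
  }) |> bind_rows()
  if (nrow(windows) == 0L) {
    abort("no contig holds a full fragment")
  }
  withr::local_seed(seed)
  ord <- sample(nrow(windows))
  if (!is.null(n_steps)) {
    ord <- ord[seq_len(min(n_steps, length(ord)))]
  }
  drawn <- windows[ord, ]
  # windows tile the contigs, so each marker lies in exactly one window;
  # it is recovered at the step where that window is drawn (if it is)
  marker_key <- paste(marker_positions$contig,
                      floor((marker_positions$pos - 1) / fragment_size))
  drawn_key <- paste(drawn$contig, drawn$start / fragment_size)
  hit_step <- match(marker_key, drawn_key)
  # a marker (profile) counts once, at the first step recovering any locus
  first_step <- tapply(hit_step, marker_positions$profile_id,
                       function(s) suppressWarnings(min(s, na.rm = TRUE)))
  first_step <- first_step[is.finite(first_step)]
  n_new <- tabulate(first_step, nbins = nrow(drawn))
  series <- tibble(
    step = seq_len(nrow(drawn)),
    cum_bp = seq_len(nrow(drawn)) * fragment_size,
    n_markers = cumsum(n_new)
  )
  r <- stats::cor(series$cum_bp, series$n_markers, method = "pearson")
  structure(list(r = r, series = series, n_fragments = nrow(drawn)),
            class = "marker_uniformity")
}

#' @export
print.marker_uniformity <- function(x, ...) {
  cat(sprintf("marker uniformity: Pearson r = %.4f over %d fragments\n",
              x$r, x$n_fragments))
  invisible(x)
}

#' @rdname marker_uniformity
#' @param x A `marker_uniformity` object.
#' @param ... Unused.
#' @export
tidy.marker_uniformity <- function(x, ...) {
  x$series
}

#' @rdname marker_uniformity
#' @export
glance.marker_uniformity <- function(x, ...) {
  tibble(pearson_r = x$r, n_fragments = x$n_fragments,
         n_markers_recovered = max(x$series$n_markers))
}

#' @rdname marker_uniformity
#' @param object A `marker_uniformity` object.
#' @export
autoplot.marker_uniformity <- function(object, ...) {
  ggplot2::ggplot(object$series,
                  ggplot2::aes(x = .data$cum_bp / 1e6, y = .data$n_markers)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "cumulative sampled length (Mb)",
      y = "distinct markers recovered",
      title = sprintf("Marker uniformity (Pearson r = %.3f)", object$r)
    )
}
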