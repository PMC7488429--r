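#' Simulation configuration
#'
#' Parameters for benchmark genome simulation. Fragment lengths are drawn
#' as `max(min_step, step_unit * Poisson(poisson_lambda))`: with the
#' defaults (lambda 100, unit 100 bp, floor 2000 bp) fragments are roughly
#' 2-20 kb, the size range of metagenome-assembled contigs. Setting
#' `step_unit = 1` recovers a literal base-pair Poisson step (which the
#' 2000 bp floor then dominates).
#'
#' @param poisson_lambda Mean of the Poisson step draw.
#' @param step_unit Multiplier (bp) applied to each Poisson draw.
#' @param min_step Minimum fragment length in bp.
#' @param target_fraction Probability of keeping each target fragment, in
#'   `(0, 1]` — the simulated completeness level.
#' @param contamination_fraction Fraction of the contaminant genome's
#'   length to add, in `[0, 1)`.
#' @param contaminant_mode `"same_clade"`, `"out_clade"` (contaminant is a
#'   supplied genome) or `"random_dna"` (i.i.d. random bases).
#' @param gc_content GC content of random-DNA contamination, in `(0, 1)`.
#' @param seed Integer seed; all draws are deterministic given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(poisson_lambda = 100, step_unit = 100,
                       min_step = 2000, target_fraction = 1,
                       contamination_fraction = 0,
                       contaminant_mode = c("same_clade", "out_clade",
                                            "random_dna"),
                       gc_content = 0.5, seed = 1L) {
  contaminant_mode <- match.arg(contaminant_mode)
  stopifnot(poisson_lambda > 0, step_unit >= 1, min_step >= 1,
            target_fraction > 0, target_fraction <= 1,
            contamination_fraction >= 0, contamination_fraction < 1,
            gc_content > 0, gc_content < 1)
  structure(list(
    poisson_lambda = poisson_lambda, step_unit = step_unit,
    min_step = min_step, target_fraction = target_fraction,
    contamination_fraction = contamination_fraction,
    contaminant_mode = contaminant_mode, gc_content = gc_content,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Accept sequences as a named character vector, a Biostrings XStringSet, or
# (for coordinate-only work) a named numeric vector of lengths.
seq_lengths <- function(sequences) {
  if (inherits(sequences, "XStringSet")) {
    setNames(Biostrings::width(sequences), names(sequences))
  } else if (is.character(sequences)) {
    setNames(nchar(sequences), names(sequences))
  } else if (is.numeric(sequences)) {
    sequences
  } else {
    abort("sequences must be a named character/numeric vector or XStringSet")
  }
}

#' Fragment genome sequences with Poisson-distributed step sizes
#'
#' Partitions each chromosome left to right into fragments whose lengths
#' are `max(min_step, step_unit * Poisson(poisson_lambda))` draws; the
#' terminal fragment of a chromosome may be shorter. The fragments tile
#' each chromosome exactly (no gaps, no overlaps), emulating assembly
#' breakage into contigs. Coordinates are 0-based, half-open.
#'
#' @param sequences Named character vector, `XStringSet`, or named numeric
#'   vector of chromosome lengths when only coordinates are needed.
#' @param config [sim_config()].
#' @param seed Integer seed; `NULL` leaves the RNG state alone (for use
#'   inside an outer seeded context).
#' @return Tibble with columns `fragment_id`, `source_seq`, `start`, `end`,
#'   `length`.
#' @export
fragment_genome <- function(sequences, config = sim_config(), seed = config$seed) {
  lens <- seq_lengths(sequences)
  if (length(lens) == 0L) {
    abort("no sequences")
  }
  if (is.null(names(lens)) || any(!nzchar(names(lens)))) {
    abort("sequences must be named")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  frags <- purrr::imap(lens, function(len, nm) {
    starts <- integer(0)
    ends <- integer(0)
    at <- 0
    while (at < len) {
      step <- max(config$min_step,
                  config$step_unit * stats::rpois(1L, config$poisson_lambda))
      starts <- c(starts, at)
      ends <- c(ends, min(at + step, len))
      at <- at + step
    }
    tibble(source_seq = nm, start = starts, end = ends)
  }) |> bind_rows()
  frags |>
    mutate(
      fragment_id = sprintf("%s_%d_%d", .data$source_seq, .data$start,
                            .data$end),
      length = .data$end - .data$start
    ) |>
    select("fragment_id", "source_seq", "start", "end", "length")
}

#' Randomly keep fragments to reach a target genome fraction
#'
#' Each fragment is kept independently with probability `target_fraction`,
#' simulating the loss of contigs during assembly and binning; the realized
#' kept fraction therefore scatters binomially around the target.
#'
#' @param fragments Fragment tibble from [fragment_genome()].
#' @param target_fraction Keep probability in `[0, 1]`.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return The kept subset of `fragments`.
#' @export
subsample_to_fraction <- function(fragments, target_fraction, seed = NULL) {
  stopifnot(target_fraction >= 0, target_fraction <= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  keep <- stats::runif(nrow(fragments)) < target_fraction
  fragments[keep, , drop = FALSE]
}

# i.i.d. random DNA at a given GC content
random_dna <- function(length, gc_content) {
  paste(sample(c("A", "T", "G", "C"), length, replace = TRUE,
               prob = c((1 - gc_content) / 2, (1 - gc_content) / 2,
                        gc_content / 2, gc_content / 2)),
        collapse = "")
}

#' Simulate a fragmented, contaminated benchmark genome
#'
#' Builds a test genome with known truth: the target genome is fragmented
#' ([fragment_genome()]) and subsampled to `target_fraction`
#' ([subsample_to_fraction()]); the contaminant — a genome from the same
#' clade, a genome from a different clade, or random DNA, depending on
#' `contaminant_mode` — is fragmented identically, subsampled to
#' `contamination_fraction` of the contaminant genome's length, and
#' appended. Every fragment carries a source label and source coordinates,
#' and the realized kept fractions are recorded as the truth.
#'
#' In `random_dna` mode the contaminant is an i.i.d. random sequence at
#' `gc_content`, generated with total length equal to the target genome's
#' length and then treated exactly like a genomic contaminant.
#'
#' @param target_genome Named character vector or `XStringSet` of target
#'   chromosomes (or named lengths, when sequence text is not needed).
#' @param contaminant_source Contaminant genome in the clade modes; must be
#'   `NULL` in `random_dna` mode.
#' @param config [sim_config()].
#' @return A list of class `simulated_genome`: `fragments` (tibble
#'   `fragment_id`, `source_genome`, `source_seq`, `start`, `end`, `length`,
#'   `label`), `truth` (realized and requested fractions plus bp
#'   bookkeeping), `config`, and `sequences` (named character vector of
#'   fragment sequences, when sequence text was supplied).
#' @export
make_contaminated_genome <- function(target_genome, contaminant_source = NULL,
                                     config = sim_config()) {
  withr::local_seed(config$seed)
  has_seq_t <- !is.numeric(target_genome)
  if (config$contaminant_mode == "random_dna") {
    if (!is.null(contaminant_source)) {
      abort("contaminant_source must be NULL in random_dna mode")
    }
    if (config$contamination_fraction > 0) {
      contaminant_source <- c(
        random_contig = random_dna(sum(seq_lengths(target_genome)),
                                   config$gc_content))
    }
  } else if (config$contamination_fraction > 0 &&
             is.null(contaminant_source)) {
    abort(paste0("contaminant_source is required in ",
                 config$contaminant_mode, " mode"))
  }

  tf <- fragment_genome(target_genome, config, seed = NULL)
  tf <- tf |> mutate(label = "target", source_genome = "target")
  kept_t <- subsample_to_fraction(tf, config$target_fraction, seed = NULL)

  if (config$contamination_fraction > 0) {
    cf <- fragment_genome(contaminant_source, config, seed = NULL) |>
      mutate(label = "contaminant", source_genome = "contaminant")
    kept_c <- subsample_to_fraction(cf, config$contamination_fraction,
                                    seed = NULL)
    contaminant_bp <- sum(seq_lengths(contaminant_source))
  } else {
    kept_c <- NULL
    contaminant_bp <- 0
  }

  fragments <- bind_rows(kept_t, kept_c) |>
    mutate(fragment_id = sprintf("%s|%s|%d-%d", .data$label,
                                 .data$source_seq, .data$start, .data$end)) |>
    select("fragment_id", "source_genome", "source_seq", "start", "end",
           "length", "label")
  target_bp <- sum(seq_lengths(target_genome))
  kept_target_bp <- sum(fragments$length[fragments$label == "target"])
  kept_contaminant_bp <- sum(fragments$length[fragments$label == "contaminant"])
  truth <- list(
    target_fraction = config$target_fraction,
    contamination_fraction = config$contamination_fraction,
    target_fraction_realized = kept_target_bp / target_bp,
    contamination_fraction_realized =
      if (contaminant_bp > 0) kept_contaminant_bp / contaminant_bp else 0,
    target_bp = target_bp,
    contaminant_bp = contaminant_bp,
    kept_target_bp = kept_target_bp,
    kept_contaminant_bp = kept_contaminant_bp
  )

  sequences <- NULL
  if (has_seq_t) {
    src <- list(target = as_char_seqs(target_genome),
                contaminant = if (!is.null(contaminant_source))
                  as_char_seqs(contaminant_source))
    sequences <- vapply(seq_len(nrow(fragments)), function(i) {
      s <- src[[fragments$source_genome[i]]][[fragments$source_seq[i]]]
      substr(s, fragments$start[i] + 1L, fragments$end[i])
    }, "")
    names(sequences) <- fragments$fragment_id
  }

  structure(list(fragments = fragments, truth = truth, config = config,
                 sequences = sequences),
            class = "simulated_genome")
}

as_char_seqs <- function(x) {
  if (inherits(x, "XStringSet")) {
    setNames(as.character(x), names(x))
  } else if (is.character(x)) {
    x
  } else if (is.numeric(x)) {
    abort("sequence text required but only lengths were supplied")
  } else {
    abort("unsupported sequence container")
  }
}

#' @export
print.simulated_genome <- function(x, ...) {
  cat(sprintf(paste0("simulated genome: %d fragments (%d target, %d ",
                     "contaminant)\n  realized target fraction %.3f, ",
                     "realized contamination fraction %.3f\n"),
              nrow(x$fragments), sum(x$fragments$label == "target"),
              sum(x$fragments$label == "contaminant"),
              x$truth$target_fraction_realized,
              x$truth$contamination_fraction_realized))
  invisible(x)
}

#' @rdname make_contaminated_genome
#' @param x,object A `simulated_genome`.
#' @param ... Unused.
#' @export
tidy.simulated_genome <- function(x, ...) {
  x$fragments
}

#' @rdname make_contaminated_genome
#' @export
glance.simulated_genome <- function(x, ...) {
  as_tibble(x$truth)
}

#' @rdname make_contaminated_genome
#' @export
autoplot.simulated_genome <- function(object, ...) {
  ggplot2::ggplot(object$fragments,
                  ggplot2::aes(x = .data$length / 1000, fill = .data$label)) +
    ggplot2::geom_histogram(bins = 40, position = "stack") +
    ggplot2::labs(x = "fragment length (kb)", y = "fragments",
                  fill = "source")
}

#' Write a simulated genome as FASTA plus a truth ledger
#'
#' FASTA headers encode the source, 0-based half-open coordinates, and the
#' target/contaminant label so every base is auditable; the ledger TSV
#' carries the same per-fragment records plus the realized fractions as
#' comment lines.
#'
#' @param sim A `simulated_genome` with sequence text.
#' @param fasta_path,truth_path Output paths.
#' @return `fasta_path`, invisibly.
#' @export
write_simulated_genome <- function(sim, fasta_path, truth_path) {
  if (is.null(sim$sequences)) {
    abort("simulated genome carries no sequence text")
  }
  dna <- Biostrings::DNAStringSet(sim$sequences)
  Biostrings::writeXStringSet(dna, fasta_path)
  header <- c(
    sprintf("# target_fraction_realized\t%.6f",
            sim$truth$target_fraction_realized),
    sprintf("# contamination_fraction_realized\t%.6f",
            sim$truth$contamination_fraction_realized)
  )
  body <- sim$fragments |>
    mutate(row = sprintf("%s\t%s\t%d\t%d\t%s", .data$fragment_id,
                         .data$source_seq, .data$start, .data$end,
                         .data$label)) |>
    pull(row)
  writeLines(c(header,
               "fragment_id\tsource_seq\tstart\tend\tlabel", body),
             truth_path)
  invisible(fasta_path)
}

#' Read or write a flat key-value simulation config
#'
#' @param path Config file path (`key<TAB>value` lines).
#' @return For `read_sim_config`, a [sim_config()].
#' @export
read_sim_config <- function(path) {
  kv <- readr::read_tsv(path, col_names = c("key", "value"),
                        col_types = "cc", progress = FALSE)
  vals <- setNames(as.list(kv$value), kv$key)
  num <- function(k, default) if (k %in% names(vals)) as.numeric(vals[[k]]) else default
  chr <- function(k, default) if (k %in% names(vals)) vals[[k]] else default
  sim_config(
    poisson_lambda = num("poisson_lambda", 100),
    step_unit = num("step_unit", 100),
    min_step = num("min_step", 2000),
    target_fraction = num("target_fraction", 1),
    contamination_fraction = num("contamination_fraction", 0),
    contaminant_mode = chr("contaminant_mode", "same_clade"),
    gc_content = num("gc_content", 0.5),
    seed = num("seed", 1)
  )
}

#' @rdname read_sim_config
#' @param config A [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  flat <- unlist(config)
  writeLines(paste(names(flat), flat, sep = "\t"), path)
  invisible(path)
}
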