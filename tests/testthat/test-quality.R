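test_that("completeness and contamination are fractions of the set", {
  set20 <- sprintf("PF%02d", 1:20)
  counts <- tibble::tibble(
    profile_id = sprintf("PF%02d", 1:15),
    n_copies = c(rep(1L, 13), 2L, 2L)
  )
  q <- estimate_quality(counts, set20)
  expect_equal(q$completeness, 75.0)
  expect_equal(q$contamination, 10.0)

  all_single <- tibble::tibble(profile_id = set20, n_copies = 1L)
  q2 <- estimate_quality(all_single, set20)
  expect_equal(c(q2$completeness, q2$contamination), c(100, 0))
})

test_that("self-merging a genome forces contamination equal to completeness", {
  set20 <- sprintf("PF%02d", 1:20)
  counts <- tibble::tibble(profile_id = sprintf("PF%02d", 1:12),
                           n_copies = 1L)
  merged <- counts |> dplyr::mutate(n_copies = n_copies * 2L)
  q <- estimate_quality(merged, set20)
  expect_equal(q$contamination, q$completeness)
})

test_that("profiles outside the set are ignored with a warning; empty sets
          are an error", {
  counts <- tibble::tibble(profile_id = c("PF01", "XX"), n_copies = 1L)
  expect_warning(q <- estimate_quality(counts, c("PF01", "PF02")),
                 "outside the chosen set")
  expect_equal(q$completeness, 50)
  expect_error(estimate_quality(counts, character(0)), "empty")
})

test_that("contamination never exceeds completeness on random inputs", {
  withr::local_seed(99)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    set <- sprintf("PF%02d", seq_len(n))
    counts <- tibble::tibble(
      profile_id = set,
      n_copies = sample(0:4, n, replace = TRUE))
    q <- estimate_quality(counts, set)
    expect_lte(q$contamination, q$completeness)
    expect_gte(q$completeness, 0); expect_lte(q$completeness, 100)
  }
})

test_that("unassessed fraction is the marker-free share of genome length", {
  lens <- c(big = 10000, small = 5000)
  expect_equal(unassessed_fraction(lens, "big"), 5000 / 15000)
  expect_equal(unassessed_fraction(lens, c("big", "small")), 0)
  expect_equal(unassessed_fraction(lens, character(0)), 1)
  expect_error(unassessed_fraction(numeric(0), character(0)), "empty genome")
  expect_error(unassessed_fraction(lens, "other"), "other")
})

split_lin <- function(x) trimws(strsplit(x, ";", fixed = TRUE)[[1]])

test_that("consensus lineage stops at the first disagreement", {
  full <- c("domain:Euk;phylum:Asco;family:Sacch;genus:Sacch",
            "domain:Euk;phylum:Asco;family:Sacch;genus:Sacch")
  expect_equal(consensus_lineage(full), split_lin(full[1]))

  split_g <- c("domain:Euk;phylum:Asco;family:Sacch;genus:A",
               "domain:Euk;phylum:Asco;family:Sacch;genus:B")
  expect_equal(consensus_lineage(split_g),
               c("domain:Euk", "phylum:Asco", "family:Sacch"))

  expect_warning(empty <- consensus_lineage(c("domain:Euk", "domain:Bac")),
                 "disagree")
  expect_length(empty, 0)
  expect_error(consensus_lineage(character(0)), "no lineages")
})

test_that("uniformly placed markers give a near-perfect cumulative
          correlation", {
  g <- synthesize_marker_genome(sprintf("PF%03d", 1:100),
                                genome_size = 4e6, seed = 5)
  u <- marker_uniformity(g$contig_lengths, g$markers, seed = 5)
  expect_gte(u$r, 0.95)
  # deterministic given the seed
  u2 <- marker_uniformity(g$contig_lengths, g$markers, seed = 5)
  expect_identical(u$series, u2$series)
})

test_that("clustered markers score strictly below uniform markers on the
          same seeds", {
  lens <- c(chr = 4e6)
  uniform <- tibble::tibble(
    profile_id = sprintf("PF%03d", 1:100), contig = "chr",
    pos = as.integer(seq(20000, 3.98e6, length.out = 100)))
  clustered <- uniform |>
    dplyr::mutate(pos = as.integer(seq(1000, 40000, length.out = 100)))
  for (s in 1:3) {
    ru <- marker_uniformity(lens, uniform, seed = s)$r
    rc <- marker_uniformity(lens, clustered, seed = s)$r
    expect_lt(rc, ru)
  }
})

test_that("evenly spaced markers under full tiling approach perfect
          linearity", {
  lens <- c(chr = 1e6)
  markers <- tibble::tibble(
    profile_id = sprintf("PF%03d", 1:200), contig = "chr",
    pos = as.integer(seq(2500, 997500, length.out = 200)))
  u <- marker_uniformity(lens, markers, seed = 1) # all 200 windows drawn
  expect_gt(u$r, 0.99)
})

test_that("degenerate uniformity inputs are rejected", {
  expect_error(
    marker_uniformity(c(chr = 1e6),
                      tibble::tibble(profile_id = "P", contig = "chr",
                                     pos = 1L)),
    "at least 2 markers")
  expect_error(
    marker_uniformity(c(chr = 2000),
                      tibble::tibble(profile_id = c("P", "Q"),
                                     contig = "chr", pos = c(1L, 2L))),
    "shorter than one fragment")
})
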