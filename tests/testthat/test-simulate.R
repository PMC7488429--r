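random_dna_fixture <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_that("fragments tile each chromosome exactly and respect the floor", {
  cfg <- sim_config(seed = 9)
  fr <- fragment_genome(c(chrA = 10000, chrB = 25000), cfg)
  for (chr in c("chrA", "chrB")) {
    f <- fr[fr$source_seq == chr, ]
    f <- f[order(f$start), ]
    expect_equal(f$start[1], 0)
    expect_equal(f$end[nrow(f)], unname(c(chrA = 10000, chrB = 25000)[chr]))
    if (nrow(f) > 1) {
      expect_equal(f$start[-1], f$end[-nrow(f)]) # no gaps, no overlaps
      expect_true(all(f$length[-nrow(f)] >= cfg$min_step))
    }
    expect_equal(sum(f$length), unname(c(chrA = 10000, chrB = 25000)[chr]))
  }
  # pigeonhole: a 10 kb chromosome cannot hold more than 5 fragments of
  # at least 2 kb (plus at most a shorter terminal one)
  expect_lte(sum(fr$source_seq == "chrA"), 5)
})

test_that("fragmentation is deterministic given the seed", {
  cfg <- sim_config(seed = 42)
  expect_identical(fragment_genome(c(c1 = 50000), cfg),
                   fragment_genome(c(c1 = 50000), cfg))
})

test_that("the literal step reading is recoverable via step_unit = 1", {
  cfg <- sim_config(step_unit = 1, seed = 1)
  fr <- fragment_genome(c(c1 = 20000), cfg)
  # Poisson(100) draws are all far below the 2000 bp floor
  expect_true(all(fr$length[-nrow(fr)] == 2000))
})

test_that("subsampling keeps everything at 1 and nothing at 0", {
  fr <- fragment_genome(c(c1 = 50000), sim_config(seed = 2))
  expect_equal(nrow(subsample_to_fraction(fr, 1, seed = 1)), nrow(fr))
  expect_equal(nrow(subsample_to_fraction(fr, 0, seed = 1)), 0L)
})

test_that("kept-bp fraction matches the binomial expectation over seeds", {
  fr <- tibble::tibble(
    fragment_id = sprintf("f%04d", 1:1000),
    source_seq = "c1",
    start = (0:999) * 2000, end = (1:1000) * 2000,
    length = 2000
  )
  kept_frac <- vapply(1:100, function(s) {
    sum(subsample_to_fraction(fr, 0.5, seed = s)$length) / sum(fr$length)
  }, numeric(1))
  # 3 sigma of a single Binomial(1000, 0.5) draw: 3*sqrt(0.25/1000) ~ 0.047
  expect_lt(abs(mean(kept_frac) - 0.5), 0.05)
})

test_that("zero contamination reproduces the subsampled target exactly", {
  genome <- c(c1 = 60000, c2 = 40000)
  cfg <- sim_config(target_fraction = 0.7, contamination_fraction = 0,
                    seed = 7)
  sim <- make_contaminated_genome(genome, NULL, cfg)
  expect_true(all(sim$fragments$label == "target"))
  # same seed, manual pipeline
  withr::with_seed(7L, {
    fr <- fragment_genome(genome, cfg, seed = NULL)
    kept <- subsample_to_fraction(fr, 0.7, seed = NULL)
  })
  expect_equal(sim$fragments$start, kept$start)
  expect_equal(sim$truth$target_fraction_realized,
               sum(kept$length) / sum(genome))
})

test_that("contaminant fragments are labelled and counted correctly", {
  cfg <- sim_config(target_fraction = 0.8, contamination_fraction = 0.5,
                    contaminant_mode = "same_clade", seed = 3)
  sim <- make_contaminated_genome(c(t1 = 50000), c(x1 = 80000), cfg)
  expect_gt(sum(sim$fragments$label == "target"), 0)
  expect_gt(sum(sim$fragments$label == "contaminant"), 0)
  contam <- sim$fragments[sim$fragments$label == "contaminant", ]
  expect_true(all(contam$source_genome == "contaminant"))
  expect_equal(sum(contam$length), sim$truth$kept_contaminant_bp)
  expect_equal(sim$truth$contamination_fraction_realized,
               sim$truth$kept_contaminant_bp / 80000)
  expect_error(
    make_contaminated_genome(c(t1 = 50000), NULL,
                             sim_config(contamination_fraction = 0.5)),
    "contaminant_source is required")
})

test_that("random-DNA contamination hits the configured GC content", {
  cfg <- sim_config(target_fraction = 1, contamination_fraction = 0.5,
                    contaminant_mode = "random_dna", gc_content = 0.5,
                    seed = 11)
  target <- withr::with_seed(12L, c(t1 = random_dna_fixture(1e6)))
  sim <- make_contaminated_genome(target, NULL, cfg)
  contam_seq <- paste(
    sim$sequences[sim$fragments$label == "contaminant"], collapse = "")
  gc <- sum(strsplit(contam_seq, "")[[1]] %in% c("G", "C")) /
    nchar(contam_seq)
  # binomial 3 sigma at n ~ 5e5: ~0.002; allow 0.01
  expect_lt(abs(gc - 0.5), 0.01)
  expect_error(
    make_contaminated_genome(c(t1 = 1000), c(x = 1000),
                             sim_config(contamination_fraction = 0.1,
                                        contaminant_mode = "random_dna")),
    "must be NULL")
})

test_that("FASTA and truth-ledger output round-trip", {
  withr::local_seed(1)
  genome <- c(c1 = random_dna_fixture(30000))
  cfg <- sim_config(target_fraction = 0.9, seed = 5)
  sim <- make_contaminated_genome(genome, NULL, cfg)
  fa <- withr::local_tempfile(fileext = ".fa")
  tr <- withr::local_tempfile(fileext = ".tsv")
  write_simulated_genome(sim, fa, tr)
  seqs <- Biostrings::readDNAStringSet(fa)
  expect_equal(length(seqs), nrow(sim$fragments))
  expect_equal(sum(Biostrings::width(seqs)), sum(sim$fragments$length))
  ledger <- readLines(tr)
  expect_match(ledger[1], "target_fraction_realized")
  expect_equal(length(ledger) - 3, nrow(sim$fragments))
})

test_that("sim configs round-trip through the flat key-value format", {
  cfg <- sim_config(target_fraction = 0.6, contamination_fraction = 0.05,
                    contaminant_mode = "out_clade", seed = 77)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  expect_equal(cfg2, cfg)
})
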