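test_that("zero dropout makes every profile universally single copy and a
          set at every eligible node", {
  fx <- synthesize_reference_fixture(n_species = 10, n_profiles = 25,
                                     per_profile_dropout = 0,
                                     duplication_rate = 0, seed = 4)
  expect_true(all(unclass(fx$counts) == 1L))
  cfg <- db_config(min_profiles = 20)
  sets <- define_clade_sets(fx$tree, fx$counts, cfg)
  n_tip <- length(fx$tree$phy$tip.label)
  tips_under <- magqc:::descendant_tips(fx$tree$phy)
  eligible <- sum(lengths(tips_under[(n_tip + 1):(n_tip + fx$tree$phy$Nnode)])
                  >= cfg$min_species)
  expect_equal(nrow(sets), eligible)
  expect_true(all(vapply(sets$prevalence, function(p) all(p == 1), TRUE)))
})

test_that("heavy dropout drives prevalence toward 0.5 and suppresses sets at
          the 98% cutoff", {
  fx <- synthesize_reference_fixture(n_species = 20, n_profiles = 40,
                                     per_profile_dropout = 0.5,
                                     duplication_rate = 0, seed = 8)
  prev <- colMeans(unclass(fx$counts) == 1L)
  expect_lt(abs(mean(prev) - 0.5), 3 * sqrt(0.25 / (20 * 40)) * 5)
  sets <- define_clade_sets(fx$tree, fx$counts, db_config())
  expect_equal(nrow(sets), 0L)
})

test_that("the fixture's hit table rebuilds its count matrix exactly", {
  fx <- synthesize_reference_fixture(n_species = 8, n_profiles = 15,
                                     per_profile_dropout = 0.1,
                                     duplication_rate = 0.3, seed = 21)
  rebuilt <- build_count_matrix(fx$hits, fx$thresholds,
                                genomes = fx$genomes,
                                profiles = fx$profiles)
  expect_identical(unclass(rebuilt)[fx$genomes, fx$profiles],
                   unclass(fx$counts)[fx$genomes, fx$profiles])
})

test_that("fixtures are deterministic given the seed and validate inputs", {
  f1 <- synthesize_reference_fixture(seed = 30)
  f2 <- synthesize_reference_fixture(seed = 30)
  expect_identical(f1$hits, f2$hits)
  expect_identical(ape::write.tree(f1$tree$phy), ape::write.tree(f2$tree$phy))
  expect_error(synthesize_reference_fixture(n_species = 3), "n_species")
  expect_error(synthesize_reference_fixture(per_profile_dropout = 1.2),
               "dropout")
})

test_that("marker genomes place one in-bounds point locus per profile", {
  profiles <- sprintf("PF%03d", 1:50)
  g <- synthesize_marker_genome(profiles, genome_size = 1e6, n_contigs = 5,
                                seed = 2)
  expect_equal(sum(g$contig_lengths), 1e6)
  expect_setequal(g$markers$profile_id, profiles)
  expect_true(all(g$markers$pos >= 1))
  expect_true(all(g$markers$pos <= g$contig_lengths[g$markers$contig]))
})

test_that("counting loci over the untouched fragmentation recovers every
          marker exactly once", {
  profiles <- sprintf("PF%03d", 1:50)
  g <- synthesize_marker_genome(profiles, genome_size = 1e6, seed = 3)
  frags <- fragment_genome(g$contig_lengths, sim_config(seed = 3))
  counts <- count_markers_in_fragments(frags, g$markers)
  expect_true(all(counts$n_copies == 1L))
  # dropping every fragment loses every marker
  none <- count_markers_in_fragments(frags[0, ], g$markers)
  expect_true(all(none$n_copies == 0L))
})
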