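make_sets <- function(rt, node_ids) {
  tibble::tibble(
    set_id = paste0("set_", node_ids),
    node_id = node_ids,
    n_species = NA_integer_, n_profiles = NA_integer_,
    species_ids = list(character(0)),
    profile_ids = replicate(length(node_ids), sprintf("PF%02d", 1:20),
                            simplify = FALSE),
    prevalence = list(numeric(0))
  )
}

place_at <- function(nodes, support = 1) {
  tibble::tibble(protein_id = sprintf("q%02d", seq_along(nodes)),
                 node_id = nodes, support = support)
}

rt8 <- toy_tree("(((A,B)nAB,(C,D)nCD)nABCD,((E,F)nEF,(G,H)nGH)nEFGH)root;")

test_that("placements all inside one set-bearing clade choose it with full
          coverage", {
  sets <- make_sets(rt8, c("nABCD", "nEFGH"))
  ch <- choose_marker_set(place_at(rep(c("A", "B", "C", "D"), length.out = 10)),
                          rt8, sets)
  expect_equal(ch$set_id, "set_nABCD")
  expect_equal(ch$coverage_fraction, 1.0)
  expect_length(ch$warnings, 0)
})

test_that("an 8/2 split between disjoint clades picks the majority set and
          warns about partial coverage", {
  sets <- make_sets(rt8, c("nABCD", "nEFGH"))
  pl <- place_at(c(rep("A", 4), rep("C", 4), "E", "G"))
  expect_warning(ch <- choose_marker_set(pl, rt8, sets), "8 of 10")
  expect_equal(ch$set_id, "set_nABCD")
  expect_equal(ch$coverage_fraction, 0.8)
})

test_that("when the placements' LCA owns no set the nearest set-bearing
          ancestor is used, matching the exhaustive oracle", {
  sets <- make_sets(rt8, "root") # only the root owns a set
  pl <- place_at(c("A", "B", "C"))  # LCA nABCD has none
  ch <- choose_marker_set(pl, rt8, sets)
  expect_equal(ch$set_id, "set_root")
  expect_equal(ch$coverage_fraction, 1.0)
  orc <- oracle_choose(rt8, sets, pl)
  expect_equal(ch$set_id, orc$set_id)
  expect_equal(ch$n_covered, orc$n_covered)
})

test_that("equal coverage ties break toward the deeper, more specific node", {
  sets <- make_sets(rt8, c("nABCD", "nAB"))
  pl <- place_at(c("A", "B"))  # both sets contain both placements
  ch <- choose_marker_set(pl, rt8, sets)
  expect_equal(ch$set_id, "set_nAB")
})

test_that("no applicable set is a typed error", {
  sets <- make_sets(rt8, "nAB")
  pl <- place_at(c("E", "G"))  # LCA nEFGH; no ancestor owns a set
  expect_error(choose_marker_set(pl, rt8, sets),
               class = "magqc_no_set")
  expect_error(choose_marker_set(pl[0, ], rt8, sets), "no placements")
})

test_that("the choice is invariant under permutation of placements and
          stable when adding a placement inside the chosen clade", {
  withr::local_seed(303)
  for (i in 1:10) {
    inst <- random_choice_instance()
    orc <- oracle_choose(inst$tree, inst$sets, inst$placements)
    if (is.null(orc)) next
    ch1 <- suppressWarnings(
      choose_marker_set(inst$placements, inst$tree, inst$sets))
    perm <- inst$placements[sample(nrow(inst$placements)), ]
    ch2 <- suppressWarnings(choose_marker_set(perm, inst$tree, inst$sets))
    expect_equal(ch1$set_id, ch2$set_id)
    # add a placement at the chosen node itself: inside its clade
    extra <- tibble::tibble(protein_id = "qx", node_id = ch1$node_id,
                            support = 1)
    ch3 <- suppressWarnings(choose_marker_set(
      dplyr::bind_rows(inst$placements, extra), inst$tree, inst$sets))
    expect_equal(ch3$set_id, ch1$set_id)
  }
})

test_that("the chosen node has maximal coverage and maximal depth among
          maxima on random instances (exhaustive node scoring)", {
  withr::local_seed(304)
  n_checked <- 0
  for (i in 1:30) {
    inst <- random_choice_instance()
    orc <- oracle_choose(inst$tree, inst$sets, inst$placements)
    if (is.null(orc)) {
      expect_error(
        suppressWarnings(
          choose_marker_set(inst$placements, inst$tree, inst$sets)),
        class = "magqc_no_set")
      next
    }
    ch <- suppressWarnings(
      choose_marker_set(inst$placements, inst$tree, inst$sets))
    expect_equal(ch$set_id, orc$set_id)
    expect_equal(ch$n_covered, orc$n_covered)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 15)
})
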