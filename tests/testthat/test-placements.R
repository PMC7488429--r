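jplace_doc <- function(placements,
                       fields = c("edge_num", "likelihood",
                                  "like_weight_ratio", "post_prob"),
                       tree = paste0("((A:1{0},B:1{1})nAB:1{4},",
                                     "(C:1{2},D:1{3})nCD:1{5})root;")) {
  list(version = 3, tree = tree, fields = as.list(fields),
       placements = placements)
}

write_jplace <- function(doc) {
  path <- withr::local_tempfile(fileext = ".jplace",
                                .local_envir = parent.frame())
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  path
}

test_that("one query with two candidate edges yields two placements with
          node identifiers resolved from edge numbers", {
  doc <- jplace_doc(list(list(
    p = list(list(0L, -100, 0.1, 0.9), list(4L, -101, 0.9, 0.1)),
    n = list("q1"))))
  pl <- parse_placements(write_jplace(doc))
  expect_equal(nrow(pl), 2L)
  expect_setequal(pl$node_id, c("A", "nAB"))
  # post_prob preferred over like_weight_ratio
  expect_equal(pl$support[pl$node_id == "A"], 0.9)
})

test_that("an empty placements list is empty, not an error", {
  pl <- parse_placements(write_jplace(jplace_doc(list())))
  expect_equal(nrow(pl), 0L)
})

test_that("missing support fields are reported with what is available", {
  doc <- jplace_doc(
    list(list(p = list(list(0L, -100)), n = list("q1"))),
    fields = c("edge_num", "likelihood"))
  expect_error(parse_placements(write_jplace(doc)),
               "no support field.*edge_num, likelihood")
})

test_that("like_weight_ratio is the fallback support field", {
  doc <- jplace_doc(
    list(list(p = list(list(2L, -100, 0.7)), n = list("q1"))),
    fields = c("edge_num", "likelihood", "like_weight_ratio"))
  pl <- parse_placements(write_jplace(doc))
  expect_equal(pl$support, 0.7)
  expect_equal(pl$node_id, "C")
})

test_that("best-placement resolution keeps the top support and breaks ties
          rootward", {
  rt <- toy_tree("((A,B)nAB,(C,D)nCD)root;")
  pl <- tibble::tibble(
    protein_id = c("q1", "q1", "q2", "q3", "q3"),
    node_id = c("A", "nAB", "C", "nAB", "A"),
    support = c(0.9, 0.1, 1.0, 0.5, 0.5)
  )
  best <- resolve_best_placements(pl, rt)
  expect_equal(nrow(best), 3L)
  expect_equal(best$node_id[best$protein_id == "q1"], "A")    # max support
  expect_equal(best$node_id[best$protein_id == "q2"], "C")    # identity
  expect_equal(best$node_id[best$protein_id == "q3"], "nAB")  # rootward tie
})

test_that("naive placement lands each protein on its best profile's
          reference leaf with support 1", {
  ref_map <- tibble::tibble(profile_id = c("P1", "P2"),
                            genome_id = c("A", "C"))
  hits <- tibble::tibble(
    protein_id = c("q1", "q1", "q2"),
    profile_id = c("P1", "P2", "P2"),
    bit_score = c(90, 50, 70)
  )
  pl <- naive_place(hits, ref_map)
  expect_equal(pl$node_id[pl$protein_id == "q1"], "A")
  expect_equal(pl$node_id[pl$protein_id == "q2"], "C")
  expect_true(all(pl$support == 1.0))
})

test_that("naive placement skips unmapped profiles with a warning and is
          empty on empty input", {
  ref_map <- tibble::tibble(profile_id = "P1", genome_id = "A")
  hits <- tibble::tibble(protein_id = "q9", profile_id = "P9",
                         bit_score = 10)
  expect_warning(pl <- naive_place(hits, ref_map), "P9")
  expect_equal(nrow(pl), 0L)
  expect_equal(nrow(naive_place(hits[0, ], ref_map)), 0L)
})
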