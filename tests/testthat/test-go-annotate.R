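# OBO parsing, term levels, best-hit annotation transfer, annotation rates.

obo_stanza <- function(id, ns = "biological_process", isa = character(),
                       obsolete = FALSE) {
  c("[Term]", paste0("id: ", id), paste0("name: term ", id),
    paste0("namespace: ", ns),
    if (length(isa)) paste0("is_a: ", isa, " ! parent"),
    if (obsolete) "is_obsolete: true", "")
}

test_that("parse_obo builds the DAG, drops obsoletes, flags errors", {
  dag <- parse_obo_text(c("format-version: 1.2", "",
                          obo_stanza("GO:0000001"),
                          obo_stanza("GO:0000002", isa = "GO:0000001"),
                          obo_stanza("GO:0000003", isa = "GO:0000001",
                                     obsolete = TRUE)))
  expect_equal(nrow(dag$terms), 2L)
  expect_equal(dag$roots, "GO:0000001")
  expect_equal(term_level(dag, c("GO:0000001", "GO:0000002")), c(1L, 2L))
  expect_error(term_level(dag, "GO:9999999"), "unknown term")

  expect_error(parse_obo_text(c(obo_stanza("GO:0000001", isa = "GO:0000009"))),
               "not defined")
  expect_error(parse_obo_text(c(obo_stanza("GO:0000001"),
                                obo_stanza("GO:0000002", isa = "GO:0000003"),
                                obo_stanza("GO:0000003", isa = "GO:0000002"))),
               "cycle")
})

test_that("term_level is the shortest is_a path (diamond oracle)", {
  # root -> A -> C, root -> B -> C; C also direct child of B
  dag <- parse_obo_text(c(
    obo_stanza("GO:0000001"),
    obo_stanza("GO:0000002", isa = "GO:0000001"),          # A
    obo_stanza("GO:0000003", isa = "GO:0000001"),          # B
    c("[Term]", "id: GO:0000004", "name: C",
      "namespace: biological_process",
      "is_a: GO:0000002 ! A", "is_a: GO:0000003 ! B", "")))
  # independent oracle: enumerate every is_a path to the root
  all_path_lengths <- function(term, parents) {
    if (length(parents[[term]]) == 0L) return(1L)
    unlist(lapply(parents[[term]], function(p) {
      1L + all_path_lengths(p, parents)
    }))
  }
  for (t in dag$terms$term_id) {
    expect_equal(term_level(dag, t), min(all_path_lengths(t, dag$parents)))
  }
  expect_equal(term_level(dag, "GO:0000004"), 3L)
  # monotone along is_a: level(child) <= level(parent) + 1 and >= 2
  for (t in setdiff(dag$terms$term_id, dag$roots)) {
    for (p in dag$parents[[t]]) {
      expect_lte(term_level(dag, t), term_level(dag, p) + 1L)
    }
    expect_gte(term_level(dag, t), 2L)
  }
})

test_that("make_obo produces the promised tree shape and round-trips", {
  one <- parse_obo_text(make_obo(1, 2))
  expect_equal(nrow(one$terms), 1L)
  expect_equal(one$terms$level, 1L)

  dag <- parse_obo_text(make_obo(6, 2))
  expect_equal(nrow(dag$terms), 63L)                 # full binary tree
  expect_equal(sum(dag$terms$level == 6L), 32L)
  expect_equal(sum(lengths(dag$parents)), 62L)       # every non-root: 1 edge

  # three namespaces, unique ids
  dag3 <- parse_obo_text(make_obo(3, 3, c("bp", "cc", "mf")))
  expect_equal(nrow(dag3$terms), 3L * 13L)
  expect_false(anyDuplicated(dag3$terms$term_id) > 0)
  expect_equal(length(dag3$roots), 3L)
})

test_that("transfer_annotations keeps all GO-bearing hits tied at minimum E", {
  go_map <- list(r1 = "T1", r2 = "T2", r3 = "T3", r0 = character())
  hits <- data.table::rbindlist(list(
    make_hit("q1", "r1", evalue = 1e-50),
    make_hit("q1", "r2", evalue = 1e-50),
    make_hit("q1", "r3", evalue = 1e-20)))
  ann <- transfer_annotations(hits, go_map)
  expect_equal(ann$q1, c("T1", "T2"))
  expect_equal(attr(ann, "provenance")$q1, c("r1", "r2"))

  # GO-less best hit is ignored before taking the minimum
  hits2 <- data.table::rbindlist(list(
    make_hit("q1", "r0", evalue = 1e-50),
    make_hit("q1", "r3", evalue = 1e-30)))
  expect_equal(transfer_annotations(hits2, go_map)$q1, "T3")

  # strict E-value threshold
  expect_equal(length(transfer_annotations(
    make_hit("q1", "r1", evalue = 1e-10), go_map)), 0L)
  expect_equal(transfer_annotations(
    make_hit("q1", "r1", evalue = 1e-11), go_map)$q1, "T1")

  # invariant to hit-row order
  set.seed(9)
  hits3 <- data.table::rbindlist(list(hits, hits2))
  perm <- hits3[sample(nrow(hits3)), ]
  expect_equal(transfer_annotations(hits3, go_map),
               transfer_annotations(perm, go_map),
               ignore_attr = TRUE)
})

test_that("annotation rates use half-up rounding and flag empty groups", {
  # the printed worked example: 41,532 of 66,491 -> 62.46%
  ann <- stats::setNames(as.list(rep("T", 41532)),
                         paste0("p", seq_len(41532)))
  pg <- data.frame(protein_id = paste0("p", seq_len(66491)),
                   group = "Cha+Emb")
  rates <- annotation_rates(ann, pg)
  row <- rates[rates$group == "Cha+Emb", ]
  expect_equal(row$annotated, 41532L)
  expect_equal(row$percent, 62.46)
  empty <- rates[rates$group == "KCM", ]
  expect_true(empty$undefined)
  expect_equal(empty$percent, 0)
})

test_that("go maps round-trip through write_go_map/read_go_map", {
  gm <- list(r1 = c("GO:0000001", "GO:0000002"), r2 = "GO:0000003")
  path <- tempfile()
  write_go_map(gm, path)
  expect_equal(read_go_map(path), gm)
})
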