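# Synthetic cohort generator: panel, families, hit table, ontology, GO map.

test_that("make_species_panel mints the configured panel", {
  tax <- default_panel()
  expect_equal(nrow(tax), 14L)
  expect_equal(as.vector(table(tax$clade)[c("Chl", "KCM", "ZCC", "Emb")]),
               c(2L, 2L, 5L, 5L))

  tiny <- make_species_panel(sim_config(
    n_species_per_clade = c(Chl = 1L, KCM = 1L, ZCC = 1L, Emb = 1L),
    group_mixture = c("Chl+Cha+Emb" = 1)))
  expect_equal(nrow(tiny), 4L)

  expect_error(make_species_panel(sim_config(
    n_species_per_clade = c(Chl = 0L, KCM = 2L, ZCC = 5L, Emb = 5L),
    group_mixture = c("Chl" = 0.5, "Emb" = 0.5))), "Chl")
})

test_that("sampled families satisfy their intended group rule (all groups)", {
  # force every group to appear
  mix <- stats::setNames(rep(1 / 9, 9), group_labels())
  cfg <- sim_config(n_families = 90, group_mixture = mix, seed = 33)
  tax <- make_species_panel(cfg)
  truth <- sample_families(tax, cfg)
  expect_setequal(unique(truth$families$group), group_labels())
  for (i in seq_len(nrow(truth$families))) {
    sp <- truth$families$species[[i]]
    expect_gte(length(sp), 2L)
    expect_equal(classify_ogc(sp, tax), truth$families$group[i],
                 label = paste("family", i))
  }
  # every protein maps to exactly one family
  expect_false(anyDuplicated(truth$proteins$protein_id) > 0)
  # Cha+Emb families contain no chlorophyte, >=1 charophyte, >=1 embryophyte
  ce <- truth$families$species[truth$families$group == "Cha+Emb"]
  for (sp in ce) {
    cl <- tax$clade[match(sp, tax$species_id)]
    expect_false("Chl" %in% cl)
    expect_true(any(cl %in% c("KCM", "ZCC")) && "Emb" %in% cl)
  }
  # KCM families: >=2 KCM species, nothing else
  km <- truth$families$species[truth$families$group == "KCM"]
  for (sp in km) {
    cl <- tax$clade[match(sp, tax$species_id)]
    expect_true(all(cl == "KCM") && length(sp) >= 2L)
  }
  empty <- sample_families(tax, sim_config(n_families = 0, seed = 1))
  expect_equal(nrow(empty$proteins), 0L)
})

test_that("hit tables carry reciprocal intra-family hits plus self-hits", {
  cfg <- sim_config(n_families = 1,
                    group_mixture = c("Cha" = 1),
                    proteins_per_family_per_species = c(1L, 1L),
                    n_decoys_per_family = 0,
                    seed = 5)
  tax <- make_species_panel(cfg)
  truth <- sample_families(tax, cfg)
  n <- nrow(truth$proteins)
  hits <- emit_hit_table(truth, cfg)
  expect_equal(nrow(hits), n * n)                       # ordered pairs + selfs
  expect_equal(sum(hits$qseqid == hits$sseqid), n)
  nonself <- hits[hits$qseqid != hits$sseqid, ]
  expect_true(all(nonself$evalue < 1e-5))
  expect_true(all(query_coverage(nonself) > 0.5))
})

test_that("decoys never survive the default filters; round-trip recovers families", {
  cfg <- sim_config(n_families = 20, n_decoys_per_family = 3, seed = 77)
  sim <- simulate_cohort(cfg)
  map <- stats::setNames(sim$truth$proteins$species_id,
                         sim$truth$proteins$protein_id)
  path <- hit_tsv(sim$hits)
  hits <- parse_hit_table(path)
  kept <- filter_hits(hits)
  fam_of <- stats::setNames(sim$truth$proteins$family_id,
                            sim$truth$proteins$protein_id)
  expect_true(all(fam_of[kept$qseqid] == fam_of[kept$sseqid]))  # zero decoys
  cl <- mcl(build_similarity_graph(kept, map))
  truth_part <- split(sim$truth$proteins$protein_id,
                      sim$truth$proteins$family_id)
  expect_equal(partition_signature(cl), partition_signature(truth_part))
})

test_that("hit tables are byte-identical across runs with equal seeds", {
  cfg <- sim_config(n_families = 10, seed = 123)
  tax <- make_species_panel(cfg)
  t1 <- sample_families(tax, cfg)
  t2 <- sample_families(tax, cfg)
  p1 <- hit_tsv(emit_hit_table(t1, cfg))
  p2 <- hit_tsv(emit_hit_table(t2, cfg))
  expect_identical(readLines(p1), readLines(p2))
  cfg2 <- sim_config(n_families = 10, seed = 124)
  p3 <- hit_tsv(emit_hit_table(sample_families(tax, cfg2), cfg2))
  expect_false(identical(readLines(p1), readLines(p3)))
})

test_that("planted GO signal reaches deterministic limits at p = 1 / 0", {
  cfg <- sim_config(n_families = 30, p_planted = 1, p_background = 0,
                    seed = 11)
  sim <- simulate_cohort(cfg)
  ann <- transfer_annotations(sim$ref_hits, sim$go_map)
  expect_equal(length(ann), nrow(sim$truth$proteins))   # every query annotated
  fam_group <- stats::setNames(sim$truth$families$group,
                               sim$truth$families$family_id)
  grp <- fam_group[sim$truth$proteins$family_id]
  carries <- vapply(sim$truth$proteins$protein_id, function(p) {
    sim$planted_term %in% ann[[p]]
  }, logical(1L))
  expect_true(all(carries[grp == "Cha+Emb"]))
  expect_false(any(carries[grp != "Cha+Emb"]))
  # the planted term sits at level 6 of the generated ontology
  expect_equal(term_level(sim$dag, sim$planted_term), 6L)
})

test_that("GO transfer respects the strict 1e-10 boundary on reference hits", {
  go_map <- list(r1 = "GO:0000001")
  at_boundary <- make_hit("q1", "r1", evalue = 1e-10)
  below <- make_hit("q2", "r1", evalue = 1e-9)  # still >= 1e-10 -> excluded
  inside <- make_hit("q3", "r1", evalue = 1e-11)
  ann <- transfer_annotations(data.table::rbindlist(
    list(at_boundary, below, inside)), go_map)
  expect_equal(names(ann), "q3")
})
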