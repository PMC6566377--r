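# End-to-end orchestration: simulate -> filter -> cluster -> classify ->
# annotate -> enrich, with a validated configuration, per-stage row counts
# and a JSON run manifest. Identical (config, seed) gives byte-identical
# artifacts.

pipeline_defaults <- function() {
  list(
    max_evalue_cluster = 1e-5,
    min_qcov = 0.5,
    max_evalue_go = 1e-10,
    max_evalue_domain = 1e-15,
    min_hmm_cov = 0.8,
    inflation = 1.5,
    go_level = 6L,
    alpha = 0.05,
    adjust_method = "holm",
    alternative = "greater",
    top_n = 20L,
    control_group = "Chl+Cha+Emb",
    seed = 1L,
    simulate = TRUE,
    n_families = 300L,
    hits = NULL,          # input paths when simulate = FALSE
    species = NULL,
    obo = NULL,
    go_map = NULL,
    ref_hits = NULL
  )
}

#' Validate a pipeline configuration
#'
#' Accepts a named list or a path to a JSON file. Unknown keys are errors
#' (with a nearest-key suggestion); thresholds are range-checked; the control
#' group must be one of the nine phyletic labels. Missing keys take the
#' defaults listed in the package vignette.
#'
#' @param config Named list of overrides, or a JSON file path.
#' @return A complete, validated `pipeline_config` list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a named list or a JSON path")
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    sugg <- vapply(unknown, function(k) {
      d <- utils::adist(k, names(defaults))
      names(defaults)[which.min(d)]
    }, character(1L))
    stop("unknown config key(s): ",
         paste(sprintf("'%s' (did you mean '%s'?)", unknown, sugg),
               collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  chk <- function(cond, msg) if (!cond) stop("config: ", msg)
  chk(cfg$max_evalue_cluster > 0, "max_evalue_cluster must be positive")
  chk(cfg$max_evalue_go > 0, "max_evalue_go must be positive")
  chk(cfg$max_evalue_domain > 0, "max_evalue_domain must be positive")
  chk(cfg$min_qcov >= 0 && cfg$min_qcov < 1, "min_qcov must lie in [0, 1)")
  chk(cfg$min_hmm_cov >= 0 && cfg$min_hmm_cov < 1,
      "min_hmm_cov must lie in [0, 1)")
  chk(cfg$inflation > 1, "inflation must exceed 1")
  chk(cfg$go_level >= 1, "go_level must be a positive integer")
  chk(cfg$alpha > 0 && cfg$alpha <= 1, "alpha must lie in (0, 1]")
  chk(cfg$adjust_method %in% c("holm", "BH"),
      "adjust_method must be 'holm' or 'BH'")
  chk(cfg$alternative %in% c("greater", "two_sided"),
      "alternative must be 'greater' or 'two_sided'")
  chk(cfg$top_n >= 0, "top_n must be non-negative")
  chk(cfg$control_group %in% group_labels(),
      "control_group must be one of the nine phyletic group labels")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1L, "seed must be a scalar")
  cfg$seed <- as.integer(cfg$seed)
  cfg$go_level <- as.integer(cfg$go_level)
  cfg$top_n <- as.integer(cfg$top_n)
  if (!isTRUE(cfg$simulate)) {
    for (key in c("hits", "species", "obo", "go_map", "ref_hits")) {
      if (is.null(cfg[[key]])) {
        stop("config: simulate is disabled and input '", key, "' is missing")
      }
      if (!file.exists(cfg[[key]])) {
        stop("config: input file for '", key, "' not found: ", cfg[[key]])
      }
    }
  }
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or input loading), hit filtering, similarity-graph
#' construction, MCL clustering, multi-species retention, phyletic
#' classification (group table, Venn regions, per-species occupancy), GO
#' annotation transfer, per-group annotation rates, and control-group
#' binomial enrichment with top-N reports, writing every intermediate
#' artifact plus a `manifest.json` under `outdir`.
#'
#' @param config A [validate_config()] result, or a list/path accepted by it.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results of every stage and
#'   the manifest.
#' @export
run_pipeline <- function(config = list(), outdir = tempfile("ogcpipe_run")) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(config), stages = list())
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(force(expr), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(seconds =
                                       round(proc.time()[["elapsed"]] - t0, 3))
    val
  }

  # --- simulate / load ---
  if (isTRUE(config$simulate)) {
    sim <- t_stage("simulate", {
      simulate_cohort(sim_config(n_families = config$n_families,
                                 seed = config$seed),
                      outdir = file.path(outdir, "simulated"))
    })
    taxonomy <- sim$taxonomy
    hits <- sim$hits
    dag <- sim$dag
    go_map <- sim$go_map
    ref_hits <- sim$ref_hits
  } else {
    sim <- NULL
    taxonomy <- t_stage("load_species", read_taxonomy(config$species))
    hits <- t_stage("load_hits", parse_hit_table(config$hits))
    dag <- t_stage("load_obo", parse_obo(config$obo))
    go_map <- t_stage("load_go_map", read_go_map(config$go_map))
    ref_hits <- t_stage("load_ref_hits", parse_hit_table(config$ref_hits))
  }
  manifest$stages$input <- list(n_hits = nrow(hits),
                                n_species = nrow(taxonomy))

  # --- filter ---
  filtered <- t_stage("filter", {
    filter_hits(hits, config$max_evalue_cluster, config$min_qcov)
  })
  write_hit_table(filtered, file.path(outdir, "hits.filtered.tsv"))
  manifest$stages$filter$n_kept <- nrow(filtered)

  # --- cluster ---
  protein_species_map <- if (!is.null(sim)) {
    stats::setNames(sim$truth$proteins$species_id,
                    sim$truth$proteins$protein_id)
  } else {
    ids <- unique(c(hits$qseqid, hits$sseqid))
    sp <- sub("\\|.*$", "", ids)
    missing <- setdiff(sp, taxonomy$species_id)
    if (length(missing)) {
      stop("cannot derive species for protein ids; prefix before '|' must ",
           "be a species id (unknown: ", paste(missing, collapse = ", "), ")")
    }
    stats::setNames(sp, ids)
  }
  clusters <- t_stage("cluster", {
    graph <- build_similarity_graph(filtered, protein_species_map)
    mcl(graph, inflation = config$inflation)
  })
  retained <- t_stage("retain", retain_multispecies(clusters,
                                                    protein_species_map))
  ogcs <- retained$ogcs
  write_groups(ogcs, file.path(outdir, "groups.txt"))
  manifest$stages$cluster <- list(
    n_clusters = length(clusters),
    n_ogcs = length(ogcs),
    n_excluded_proteins = retained$n_excluded_proteins,
    n_clustered_proteins = sum(lengths(ogcs)))

  # --- classify ---
  group_table <- t_stage("classify", {
    tabulate_groups(ogcs, protein_species_map, taxonomy)
  })
  fwrite(as.data.table(group_table), file.path(outdir, "group_table.tsv"),
         sep = "\t")
  venn <- venn_counts(group_table)
  fwrite(data.table(region = names(venn), n_ogcs = as.integer(venn)),
         file.path(outdir, "venn.tsv"), sep = "\t")
  occ <- species_occupancy(ogcs, protein_species_map, taxonomy)
  fwrite(data.table(species_id = rownames(occ), as.data.table(occ)),
         file.path(outdir, "occupancy.tsv"), sep = "\t")

  # --- annotate ---
  ann <- t_stage("annotate", {
    transfer_annotations(ref_hits, go_map, config$max_evalue_go)
  })
  write_annotations(ann, file.path(outdir, "annotations.tsv"))
  ogc_grp <- classify_ogcs(ogcs, protein_species_map, taxonomy)
  protein_groups <- data.frame(
    protein_id = unlist(ogcs, use.names = FALSE),
    group = rep(ogc_grp, lengths(ogcs)), stringsAsFactors = FALSE)
  rates <- annotation_rates(ann, protein_groups)
  fwrite(as.data.table(rates), file.path(outdir, "annotation_rates.tsv"),
         sep = "\t")
  manifest$stages$annotate$n_annotated <- length(ann)

  # --- enrich ---
  enrich <- t_stage("enrich", {
    control_prot <- protein_groups$protein_id[
      protein_groups$group == config$control_group]
    if (length(control_prot) == 0L) {
      stop("control group '", config$control_group, "' has no proteins")
    }
    control <- count_terms(ann, control_prot, dag, config$go_level)
    tested_groups <- setdiff(unique(protein_groups$group),
                             config$control_group)
    res <- list()
    for (g in sort(tested_groups)) {
      gp <- protein_groups$protein_id[protein_groups$group == g]
      tested <- count_terms(ann, gp, dag, config$go_level)
      if (tested$n == 0L || length(tested$k) == 0L) next
      res[[g]] <- enrich_group(tested, control, alpha = config$alpha,
                               method = config$adjust_method,
                               alternative = config$alternative)
    }
    res
  })
  enrich_dir <- file.path(outdir, "enrichment")
  dir.create(enrich_dir, showWarnings = FALSE)
  top_reports <- list()
  for (g in names(enrich)) {
    safe <- gsub("[^A-Za-z]+", "_", g)
    fwrite(as.data.table(enrich[[g]]),
           file.path(enrich_dir, paste0(safe, ".tsv")), sep = "\t")
    top_reports[[g]] <- top_report(enrich[[g]], config$top_n)
    fwrite(as.data.table(top_reports[[g]]),
           file.path(enrich_dir, paste0(safe, ".top", config$top_n, ".tsv")),
           sep = "\t")
  }
  manifest$stages$enrich$n_significant <- vapply(enrich, function(r) {
    sum(r$significant)
  }, integer(1L))

  # row-count conservation check
  n_graph <- length(protein_species_map)
  stopifnot(retained$n_excluded_proteins + sum(lengths(ogcs)) == n_graph)

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               null = "null")
  tf <- tempfile(); writeLines(cfg_json, tf)
  manifest$config_hash <- unname(tools::md5sum(tf)); unlink(tf)
  manifest$seed <- config$seed
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)

  invisible(list(config = config, taxonomy = taxonomy, sim = sim,
                 filtered = filtered, clusters = clusters, ogcs = ogcs,
                 group_table = group_table, venn = venn, occupancy = occ,
                 annotations = ann, rates = rates, enrichment = enrich,
                 top_reports = top_reports, manifest = manifest,
                 outdir = outdir))
}
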