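# Synthetic comparative-genomics cohort with known ground truth: a species
# panel over the four clades, gene families with clade-structured
# presence/absence drawn from the nine phyletic-group rules, an all-vs-all
# hit table (within-family high-confidence hits plus decoys that fail the
# filters), a tree-shaped ontology, and a reference GO map with a planted
# over-represented term in a chosen group.
#
# Every output artifact draws from its own RNG stream derived from the
# master seed, so artifacts are individually reproducible.

#' Simulation configuration
#'
#' Defaults state the emulated world: a 14-species panel (2 Chl, 2 KCM,
#' 5 ZCC, 5 Emb), group mixture proportional to the nine observed OGC-group
#' sizes of the study panel, within-family E-values of 1e-180..1e-20 with
#' query coverage above 0.55, decoy hits violating the E-value or coverage
#' filter, and a planted level-6 term carried with probability 0.4 in the
#' Cha+Emb group versus 0.05 elsewhere.
#'
#' @param n_species_per_clade Named integer vector over Chl, KCM, ZCC, Emb.
#' @param n_families Number of gene families to simulate.
#' @param group_mixture Named probabilities over the nine group labels
#'   (must sum to 1).
#' @param proteins_per_family_per_species Integer range (min, max) of
#'   proteins contributed by each present species.
#' @param within_family_evalue_range E-value range of intra-family hits.
#' @param within_family_coverage_range Query-coverage range of intra-family
#'   hits (must stay above 0.5).
#' @param decoy_evalue_range E-value range of E-value-violating decoys.
#' @param decoy_coverage_range Coverage range of coverage-violating decoys.
#' @param n_decoys_per_family Expected decoy hit pairs per family.
#' @param planted_term Ontology term id carrying the planted signal
#'   (`NULL`: chosen as the first level-6 term at simulation time).
#' @param planted_group Group label whose families carry the signal.
#' @param p_planted Probability that a planted-group protein's reference
#'   carries `planted_term`.
#' @param p_background Baseline probability elsewhere.
#' @param n_background_terms Range of extra level-6 terms per reference.
#' @param obo_depth,obo_branching Shape of each namespace tree.
#' @param obo_namespaces Namespace names for the generated ontology.
#' @param seed Master seed (integer).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_species_per_clade = c(Chl = 2L, KCM = 2L,
                                               ZCC = 5L, Emb = 5L),
                       n_families = 300L,
                       group_mixture = default_group_mixture(),
                       proteins_per_family_per_species = c(1L, 3L),
                       within_family_evalue_range = c(1e-180, 1e-20),
                       within_family_coverage_range = c(0.55, 0.95),
                       decoy_evalue_range = c(1e-4, 1),
                       decoy_coverage_range = c(0.05, 0.45),
                       n_decoys_per_family = 1,
                       planted_term = NULL,
                       planted_group = "Cha+Emb",
                       p_planted = 0.4,
                       p_background = 0.05,
                       n_background_terms = c(1L, 3L),
                       obo_depth = 6L,
                       obo_branching = 2L,
                       obo_namespaces = c("biological_process",
                                          "cellular_component",
                                          "molecular_function"),
                       seed = 1L) {
  cfg <- list(n_species_per_clade = n_species_per_clade,
              n_families = as.integer(n_families),
              group_mixture = group_mixture,
              proteins_per_family_per_species =
                as.integer(proteins_per_family_per_species),
              within_family_evalue_range = within_family_evalue_range,
              within_family_coverage_range = within_family_coverage_range,
              decoy_evalue_range = decoy_evalue_range,
              decoy_coverage_range = decoy_coverage_range,
              n_decoys_per_family = n_decoys_per_family,
              planted_term = planted_term,
              planted_group = planted_group,
              p_planted = p_planted,
              p_background = p_background,
              n_background_terms = as.integer(n_background_terms),
              obo_depth = as.integer(obo_depth),
              obo_branching = as.integer(obo_branching),
              obo_namespaces = obo_namespaces,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' Default group mixture: the observed nine-group OGC proportions
#'
#' Proportional to 5031, 4174, 1221, 140, 4849, 3600, 3807, 66, 2597 over
#' the nine groups (total 25,485).
#' @return Named numeric vector summing to 1.
#' @export
default_group_mixture <- function() {
  counts <- c("Chl+Cha+Emb" = 5031, "Cha+Emb" = 4174, "Chl+Cha" = 1221,
              "Chl+Emb" = 140, "Emb" = 4849, "Cha" = 3600, "ZCC" = 3807,
              "KCM" = 66, "Chl" = 2597)
  counts / sum(counts)
}

validate_sim_config <- function(cfg) {
  stopifnot(all(names(cfg$n_species_per_clade) %in% CLADES))
  if (abs(sum(cfg$group_mixture) - 1) > 1e-9) {
    stop("group_mixture must sum to 1 (within 1e-9)")
  }
  if (!all(names(cfg$group_mixture) %in% group_labels())) {
    stop("group_mixture references unknown group(s): ",
         paste(setdiff(names(cfg$group_mixture), group_labels()),
               collapse = ", "))
  }
  probs <- c(cfg$group_mixture, cfg$p_planted, cfg$p_background)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$p_planted < cfg$p_background) {
    stop("p_planted must be >= p_background")
  }
  if (cfg$n_families < 0) stop("n_families must be non-negative")
  if (cfg$within_family_coverage_range[1] <= 0.5) {
    stop("within-family coverage must stay above the 0.5 filter threshold")
  }
  invisible(cfg)
}

# Species a family of a given group is allowed to contain. Conditioning
# independent Bernoulli(0.5) presence draws on a rule that forbids a clade is
# equivalent to drawing only within the allowed clades.
allowed_clades <- function(group) {
  switch(group,
         "Chl+Cha+Emb" = c("Chl", "KCM", "ZCC", "Emb"),
         "Cha+Emb"     = c("KCM", "ZCC", "Emb"),
         "Chl+Cha"     = c("Chl", "KCM", "ZCC"),
         "Chl+Emb"     = c("Chl", "Emb"),
         "Emb"         = "Emb",
         "Cha"         = c("KCM", "ZCC"),
         "ZCC"         = "ZCC",
         "KCM"         = "KCM",
         "Chl"         = "Chl",
         stop("unknown group: ", group))
}

#' Generate the species panel
#'
#' Mints species identifiers per clade (`Chl1`, `KCM2`, ...) according to
#' the configured clade sizes. It is an error to request a clade size that
#' makes a group of the mixture unsatisfiable (for example, a single-clade
#' group over a clade with fewer than two species).
#'
#' @param config A [sim_config()].
#' @return A [species_taxonomy()].
#' @export
make_species_panel <- function(config) {
  counts <- config$n_species_per_clade
  mix_groups <- names(config$group_mixture)[config$group_mixture > 0]
  for (g in mix_groups) {
    need <- allowed_clades(g)
    avail <- sum(counts[need], na.rm = TRUE)
    required_nonzero <- switch(g,
      "Chl+Cha+Emb" = c("Chl", "Emb"),
      "Cha+Emb" = "Emb", "Chl+Cha" = "Chl", "Chl+Emb" = c("Chl", "Emb"),
      "Cha" = c("KCM", "ZCC"), character())
    if (any(counts[required_nonzero] < 1, na.rm = FALSE) ||
        anyNA(counts[required_nonzero])) {
      stop("group '", g, "' in mixture needs >=1 species in clade(s) ",
           paste(required_nonzero, collapse = ", "))
    }
    if (g %in% c("Chl+Cha+Emb", "Cha+Emb", "Chl+Cha")) {
      if (sum(counts[c("KCM", "ZCC")], na.rm = TRUE) < 1) {
        stop("group '", g, "' in mixture needs >=1 charophyte species")
      }
    }
    if (avail < 2) {
      stop("group '", g, "' in mixture needs >=2 species among clades ",
           paste(need, collapse = ", "))
    }
  }
  clades <- rep(names(counts), counts)
  ids <- unlist(lapply(names(counts), function(cl) {
    if (counts[[cl]] == 0L) character() else paste0(cl, seq_len(counts[[cl]]))
  }))
  species_taxonomy(ids, clades)
}

#' Sample gene families with clade-structured presence/absence
#'
#' Each family draws its intended group label from the mixture, then a
#' species presence set uniform over the sets satisfying that group's rule
#' (rejection sampling of independent Bernoulli(0.5) presence draws within
#' the clades the rule allows). Protein ids are minted for every present
#' species.
#'
#' @param taxonomy A [species_taxonomy()] from [make_species_panel()].
#' @param config A [sim_config()].
#' @return A `ground_truth` list: `families` (data.table `family_id`,
#'   `group`, `species` list-column), `proteins` (data.table `protein_id`,
#'   `family_id`, `species_id`), `planted_term`, `planted_group`.
#' @export
sample_families <- function(taxonomy, config) {
  with_stream(config$seed, "families", {
    labels <- names(config$group_mixture)
    n <- config$n_families
    fam_group <- if (n > 0) {
      sample(labels, n, replace = TRUE, prob = config$group_mixture)
    } else character()
    by_clade <- split(taxonomy$species_id, taxonomy$clade)
    species_sets <- vector("list", n)
    for (i in seq_len(n)) {
      species_sets[[i]] <- sample_presence(fam_group[i], by_clade)
    }
    prange <- config$proteins_per_family_per_species
    fam_id <- sprintf("F%04d", seq_len(n))
    prot <- list()
    for (i in seq_len(n)) {
      sp <- species_sets[[i]]
      counts <- sample(seq(prange[1], prange[2]), length(sp), replace = TRUE)
      pid <- unlist(lapply(seq_along(sp), function(j) {
        paste0(sp[j], "|", fam_id[i], "p", seq_len(counts[j]))
      }))
      prot[[i]] <- data.table(protein_id = pid,
                              family_id = fam_id[i],
                              species_id = rep(sp, counts))
    }
    proteins <- if (n > 0) data.table::rbindlist(prot) else
      data.table(protein_id = character(), family_id = character(),
                 species_id = character())
    truth <- list(families = data.table(family_id = fam_id,
                                        group = fam_group,
                                        species = species_sets),
                  proteins = proteins,
                  planted_term = config$planted_term,
                  planted_group = config$planted_group)
    class(truth) <- "ground_truth"
    truth
  })
}

sample_presence <- function(group, by_clade) {
  allowed_cl <- allowed_clades(group)
  allowed <- unlist(by_clade[allowed_cl], use.names = FALSE)
  clade_of <- rep(allowed_cl, lengths(by_clade[allowed_cl]))
  repeat {
    sel <- runif(length(allowed)) < 0.5
    if (sum(sel) < 2L) next
    cl <- clade_of[sel]
    ok <- tryCatch(classify_flags("Chl" %in% cl, "KCM" %in% cl,
                                  "ZCC" %in% cl, "Emb" %in% cl) == group,
                   error = function(e) FALSE)
    if (ok) return(sort(allowed[sel]))
  }
}

#' Emit the synthetic all-vs-all similarity hit table
#'
#' Every ordered intra-family protein pair receives a hit with E-value in
#' the within-family range and query coverage realised exactly in the
#' within-family coverage range (all survive the default filters); self-hits
#' are emitted as real search output would contain them. Decoy inter-family
#' hits are added whose E-value or coverage violates the default filters, so
#' none survives filtering.
#'
#' @param truth A `ground_truth` from [sample_families()].
#' @param config A [sim_config()].
#' @return A 14-column hit `data.table` parseable by [parse_hit_table()]
#'   after a round-trip through [write_hit_table()].
#' @export
emit_hit_table <- function(truth, config) {
  with_stream(config$seed, "hits", {
    prot <- truth$proteins
    if (nrow(prot) == 0L) stop("ground truth contains no proteins")
    qlen <- stats::setNames(sample(200:1200, nrow(prot), replace = TRUE),
                            prot$protein_id)
    fams <- split(prot$protein_id, prot$family_id)
    rows <- vector("list", length(fams) + 1L)
    fi <- 0L
    for (members in fams) {
      fi <- fi + 1L
      pairs <- expand.grid(q = members, s = members,
                           stringsAsFactors = FALSE)
      np <- nrow(pairs)
      is_self <- pairs$q == pairs$s
      ev <- rloguniform(np, config$within_family_evalue_range[1],
                        config$within_family_evalue_range[2])
      cov <- runif(np, config$within_family_coverage_range[1],
                   config$within_family_coverage_range[2])
      ev[is_self] <- 0
      cov[is_self] <- 1
      ql <- qlen[pairs$q]
      alen <- pmin(ceiling(cov * ql), ql)
      rows[[fi]] <- data.table(
        qseqid = pairs$q, sseqid = pairs$s,
        pident = round(runif(np, 30, 95), 1),
        length = alen, mismatch = 0L, gapopen = 0L,
        qstart = 1L, qend = alen,
        sstart = 1L, send = pmin(alen, qlen[pairs$s]),
        evalue = ev,
        bitscore = round(2 * -log10(pmax(ev, 1e-200)) + 30, 1),
        qlen = ql, slen = qlen[pairs$s])
    }
    n_decoys <- stats::rpois(1L, config$n_decoys_per_family *
                               length(fams))
    if (n_decoys > 0 && length(fams) >= 2L) {
      q <- character(n_decoys); s <- character(n_decoys)
      for (d in seq_len(n_decoys)) {
        f2 <- sample(length(fams), 2L)
        q[d] <- sample(fams[[f2[1L]]], 1L)
        s[d] <- sample(fams[[f2[2L]]], 1L)
      }
      bad_e <- runif(n_decoys) < 0.5
      ev <- ifelse(bad_e,
                   rloguniform(n_decoys, config$decoy_evalue_range[1],
                               config$decoy_evalue_range[2]),
                   rloguniform(n_decoys, 1e-60, 1e-10))
      cov <- ifelse(bad_e,
                    runif(n_decoys, 0.55, 0.95),
                    runif(n_decoys, config$decoy_coverage_range[1],
                          config$decoy_coverage_range[2]))
      ql <- qlen[q]
      alen <- pmax(pmin(ceiling(cov * ql), ql), 1L)
      rows[[length(fams) + 1L]] <- data.table(
        qseqid = q, sseqid = s,
        pident = round(runif(n_decoys, 20, 40), 1),
        length = alen, mismatch = 0L, gapopen = 0L,
        qstart = 1L, qend = alen,
        sstart = 1L, send = pmin(alen, qlen[s]),
        evalue = ev,
        bitscore = round(2 * -log10(pmax(ev, 1e-200)) + 30, 1),
        qlen = ql, slen = qlen[s])
    }
    out <- data.table::rbindlist(rows[!vapply(rows, is.null, logical(1L))])
    validate_hits(out)
    out
  })
}

#' Generate a tree-shaped OBO 1.2 ontology
#'
#' One rooted `branching`-ary tree of depth `depth` per namespace; a term at
#' tree depth d has level d (root = level 1). Term ids are unique across
#' namespaces.
#'
#' @param depth Tree depth (>= 1).
#' @param branching Children per internal term (>= 1).
#' @param namespaces Character vector of namespace names.
#' @return The OBO text as a single character scalar.
#' @export
make_obo <- function(depth, branching,
                     namespaces = "biological_process") {
  stopifnot(depth >= 1, branching >= 1)
  out <- c("format-version: 1.2", "")
  counter <- 0L
  for (ns in namespaces) {
    # breadth-first construction; parent of term i (>1) at index (i-2)%/%b + 1
    n_terms <- if (branching == 1L) depth else
      as.integer((branching^depth - 1) / (branching - 1))
    ids <- sprintf("GO:%07d", counter + seq_len(n_terms))
    levels <- integer(n_terms)
    levels[1L] <- 1L
    for (i in seq_len(n_terms)[-1L]) {
      parent <- (i - 2L) %/% branching + 1L
      levels[i] <- levels[parent] + 1L
    }
    for (i in seq_len(n_terms)) {
      stanza <- c("[Term]",
                  paste0("id: ", ids[i]),
                  paste0("name: ", ns, " term ", i, " level ", levels[i]),
                  paste0("namespace: ", ns))
      if (i > 1L) {
        parent <- (i - 2L) %/% branching + 1L
        stanza <- c(stanza, paste0("is_a: ", ids[parent], " ! parent"))
      }
      out <- c(out, stanza, "")
    }
    counter <- counter + n_terms
  }
  paste(out, collapse = "\n")
}

#' Generate the reference GO map and query-to-reference hits
#'
#' Every query protein receives one reference hit with E-value below 1e-10.
#' The reference of a planted-group protein carries the planted term with
#' probability `p_planted`, others with `p_background`; every reference also
#' carries 1..3 background level-6 terms drawn uniformly from the remaining
#' level-6 terms.
#'
#' @param truth A `ground_truth`.
#' @param dag A `go_dag` (the planted term must exist at level 6).
#' @param config A [sim_config()]; a `NULL` `planted_term` is resolved to
#'   the first level-6 term of `dag`.
#' @return List with `go_map` (named list reference -> terms), `hits`
#'   (14-column query->reference hit table), `planted_term`, and
#'   `planted_counts` (planted-term carriers per group).
#' @export
make_go_reference <- function(truth, dag, config) {
  lvl6 <- dag$terms$term_id[dag$terms$level == 6L]
  planted <- config$planted_term %||% lvl6[1L]
  if (!planted %in% dag$terms$term_id) {
    stop("planted term ", planted, " absent from ontology")
  }
  if (term_level(dag, planted) != 6L) {
    stop("planted term ", planted, " is not at level 6")
  }
  background_pool <- setdiff(lvl6, planted)
  with_stream(config$seed, "go_reference", {
    prot <- truth$proteins
    fam_group <- stats::setNames(truth$families$group,
                                 truth$families$family_id)
    in_planted <- fam_group[prot$family_id] == truth$planted_group
    p <- ifelse(in_planted, config$p_planted, config$p_background)
    carries <- runif(nrow(prot)) < p
    nbg <- sample(seq(config$n_background_terms[1],
                      config$n_background_terms[2]),
                  nrow(prot), replace = TRUE)
    refs <- paste0("REF|", prot$protein_id)
    go_map <- vector("list", nrow(prot))
    for (i in seq_len(nrow(prot))) {
      terms <- sample(background_pool, min(nbg[i], length(background_pool)))
      if (carries[i]) terms <- c(terms, planted)
      go_map[[i]] <- sort(terms)
    }
    names(go_map) <- refs
    ev <- rloguniform(nrow(prot), 1e-180, 1e-20)
    hits <- data.table(
      qseqid = prot$protein_id, sseqid = refs,
      pident = 90, length = 360L, mismatch = 0L, gapopen = 0L,
      qstart = 1L, qend = 360L, sstart = 1L, send = 360L,
      evalue = ev, bitscore = round(2 * -log10(pmax(ev, 1e-200)), 1),
      qlen = 400L, slen = 400L)
    planted_counts <- tapply(carries, fam_group[prot$family_id], sum)
    list(go_map = go_map, hits = hits, planted_term = planted,
         planted_counts = planted_counts)
  })
}

#' Simulate a full synthetic cohort
#'
#' Runs the generator end to end (species panel, families, hit table,
#' ontology, reference GO map) and optionally writes every artifact to
#' `outdir`: `species.tsv`, `hits.tsv`, `go.obo`, `go_map.tsv`,
#' `ref_hits.tsv`, `truth.json`.
#'
#' @param config A [sim_config()].
#' @param outdir Optional output directory.
#' @return List with `config`, `taxonomy`, `truth`, `hits`, `obo_text`,
#'   `dag`, `go_map`, `ref_hits`, `planted_term`.
#' @export
simulate_cohort <- function(config = sim_config(), outdir = NULL) {
  taxonomy <- make_species_panel(config)
  truth <- sample_families(taxonomy, config)
  hits <- emit_hit_table(truth, config)
  obo_text <- make_obo(config$obo_depth, config$obo_branching,
                       config$obo_namespaces)
  obo_path <- tempfile(fileext = ".obo")
  writeLines(obo_text, obo_path)
  dag <- parse_obo(obo_path)
  unlink(obo_path)
  ref <- make_go_reference(truth, dag, config)
  truth$planted_term <- ref$planted_term
  res <- list(config = config, taxonomy = taxonomy, truth = truth,
              hits = hits, obo_text = obo_text, dag = dag,
              go_map = ref$go_map, ref_hits = ref$hits,
              planted_term = ref$planted_term)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_taxonomy(taxonomy, file.path(outdir, "species.tsv"))
    write_hit_table(hits, file.path(outdir, "hits.tsv"))
    writeLines(obo_text, file.path(outdir, "go.obo"))
    write_go_map(ref$go_map, file.path(outdir, "go_map.tsv"))
    write_hit_table(ref$hits, file.path(outdir, "ref_hits.tsv"))
    jsonlite::write_json(
      list(planted_term = ref$planted_term,
           planted_group = truth$planted_group,
           families = lapply(split(truth$families$species,
                                   truth$families$family_id), `[[`, 1L),
           groups = as.list(stats::setNames(truth$families$group,
                                            truth$families$family_id))),
      file.path(outdir, "truth.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  res
}
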