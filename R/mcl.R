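# Similarity-graph construction and a from-scratch Markov cluster (MCL)
# implementation, plus the multi-species cluster-retention rule that defines
# orthologous gene clusters (OGCs).
#
# Weighting follows the OrthoMCL convention: an unordered protein pair is
# weighted by the mean of -log10(E) over its surviving directed best hits.

#' Build a weighted similarity graph from filtered hits
#'
#' For every ordered query-subject pair the best surviving row (lowest
#' E-value, ties by highest bitscore) is taken; each unordered pair is then
#' weighted by the mean of `-log10(max(E, evalue_floor))` over its one or two
#' directed best rows. E-values of zero are floored at `evalue_floor`
#' (default weight cap 200). Every protein in `protein_species_map` is a
#' node; proteins with no surviving edges are isolated. Each node carries a
#' self-loop equal to its maximum incident weight (1.0 if isolated).
#'
#' @param hits Hit table that already passed [filter_hits()].
#' @param protein_species_map Named character vector, protein id -> species id.
#' @param evalue_floor Smallest E-value used in weighting (default `1e-200`).
#' @return A `similarity_graph`: list with `nodes`, `species`, `edges`
#'   (data.table `u`, `v`, `weight`), `self_loop` (named numeric).
#' @export
build_similarity_graph <- function(hits, protein_species_map,
                                   evalue_floor = 1e-200) {
  nodes <- names(protein_species_map)
  if (is.null(nodes)) stop("protein_species_map must be a named vector")
  in_hits <- unique(c(hits$qseqid, hits$sseqid))
  missing <- setdiff(in_hits, nodes)
  if (length(missing)) {
    stop("protein(s) in hits absent from species map: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  edges <- data.table(u = character(), v = character(), weight = numeric())
  if (nrow(hits)) {
    dt <- as.data.table(hits)[qseqid != sseqid,
                              .(qseqid, sseqid, evalue, bitscore)]
    # best directed row per ordered pair
    setorder(dt, qseqid, sseqid, evalue, -bitscore)
    best <- dt[, .SD[1L], by = .(qseqid, sseqid)]
    best[, w := -log10(pmax(evalue, evalue_floor))]
    best[, `:=`(u = pmin(qseqid, sseqid), v = pmax(qseqid, sseqid))]
    edges <- best[, .(weight = mean(w)), by = .(u, v)]
  }
  self_loop <- stats::setNames(rep(1.0, length(nodes)), nodes)
  if (nrow(edges)) {
    mx <- tapply(c(edges$weight, edges$weight), c(edges$u, edges$v), max)
    self_loop[names(mx)] <- as.numeric(mx)
  }
  structure(list(nodes = nodes,
                 species = protein_species_map,
                 edges = edges,
                 self_loop = self_loop),
            class = "similarity_graph")
}

#' Markov clustering of a similarity graph
#'
#' From-scratch MCL: the weighted adjacency matrix (with self-loops) is made
#' column-stochastic and then iterated by expansion (matrix squaring) and
#' inflation (element-wise power `inflation`, column renormalisation),
#' pruning entries below `prune` after each inflation, until the maximum
#' absolute change falls below `tol` or `max_iter` is reached
#' (non-convergence gives a warning, not an error). Clusters are the
#' connected components of the attractor support; a node attracted to more
#' than one attractor system is assigned to the attractor with the largest
#' matrix entry, ties broken by lexicographically smallest attractor id.
#' Disconnected components of the input graph are clustered independently
#' (they are invariant under MCL).
#'
#' @param graph A `similarity_graph` from [build_similarity_graph()].
#' @param inflation Inflation exponent, must exceed 1 (default 1.5).
#' @param max_iter Maximum expansion/inflation iterations.
#' @param tol Convergence tolerance on the matrix change.
#' @param prune Per-column pruning threshold.
#' @return List of clusters (character vectors of protein ids), each node in
#'   exactly one cluster; deterministic ordering.
#' @export
mcl <- function(graph, inflation = 1.5, max_iter = 100L, tol = 1e-6,
                prune = 1e-8) {
  stopifnot(inherits(graph, "similarity_graph"))
  if (inflation <= 1) stop("inflation must exceed 1")
  comps <- graph_components(graph)
  edge_split <- if (nrow(graph$edges)) {
    split(graph$edges, comps$membership[graph$edges$u])
  } else list()
  clusters <- list()
  for (cid in names(comps$members)) {
    comp_edges <- edge_split[[cid]] %||%
      data.table(u = character(), v = character(), weight = numeric())
    clusters <- c(clusters,
                  mcl_component(comps$members[[cid]], comp_edges,
                                graph$self_loop, inflation, max_iter,
                                tol, prune))
  }
  # deterministic ordering: sort members, order clusters by first member
  clusters <- lapply(clusters, sort)
  clusters[order(vapply(clusters, `[[`, character(1L), 1L))]
}

graph_components <- function(graph) {
  if (nrow(graph$edges) == 0L) {
    membership <- stats::setNames(seq_along(graph$nodes), graph$nodes)
  } else {
    g <- igraph::graph_from_data_frame(
      graph$edges[, c("u", "v")], directed = FALSE,
      vertices = data.frame(name = graph$nodes))
    membership <- igraph::components(g)$membership
  }
  membership <- stats::setNames(as.character(membership), names(membership))
  list(membership = membership,
       members = split(names(membership), membership))
}

mcl_component <- function(members, e, self_loop, inflation, max_iter, tol,
                          prune) {
  members <- sort(members)
  n <- length(members)
  if (n == 1L) return(list(members))
  idx <- stats::setNames(seq_len(n), members)
  M <- matrix(0, n, n, dimnames = list(members, members))
  M[cbind(idx[e$u], idx[e$v])] <- e$weight
  M[cbind(idx[e$v], idx[e$u])] <- e$weight
  diag(M) <- self_loop[members]
  M <- normalize_cols(M)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    prev <- M
    M <- M %*% M                       # expansion
    M <- normalize_cols(M^inflation)   # inflation
    M[M < prune] <- 0                  # per-column pruning
    M <- normalize_cols(M)
    if (max(abs(M - prev)) < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("MCL did not converge in ", max_iter,
            " iterations; interpreting current matrix")
  }
  interpret_mcl(M, members)
}

normalize_cols <- function(M) {
  cs <- colSums(M)
  cs[cs == 0] <- 1
  sweep(M, 2L, cs, "/")
}

# Attractors are rows with positive diagonal mass. Attractor systems are
# connected components of the support restricted to attractors; every other
# node joins the system of its strongest attractor (ties: smallest id).
interpret_mcl <- function(M, members) {
  n <- length(members)
  attractors <- which(diag(M) > 0)
  if (length(attractors) == 0L) attractors <- seq_len(n)  # degenerate guard
  sup <- (M[attractors, attractors, drop = FALSE] > 0) |
    t(M[attractors, attractors, drop = FALSE] > 0)
  g <- igraph::graph_from_adjacency_matrix(sup, mode = "undirected",
                                           diag = FALSE)
  sys_id <- igraph::components(g)$membership  # per attractor
  assign <- integer(n)
  assign[attractors] <- sys_id
  for (j in setdiff(seq_len(n), attractors)) {
    scores <- M[attractors, j]
    mx <- max(scores)
    if (mx <= 0) {
      # no attractor mass (should not happen at convergence): own singleton
      assign[j] <- max(sys_id) + j
      next
    }
    cand <- attractors[scores == mx]
    assign[j] <- sys_id[match(min(members[cand]), members[attractors])]
  }
  unname(split(members, assign))
}

#' Retain multi-species clusters (the OGC rule)
#'
#' Keeps clusters with at least two member proteins from at least two
#' distinct species; singletons and single-species clusters are excluded.
#'
#' @param clusters List of clusters from [mcl()].
#' @param protein_species_map Named character vector, protein id -> species id.
#' @return List with `ogcs` (the retained clusters, renamed `OGC1..`),
#'   `n_excluded_proteins`, and `excluded` (the dropped clusters).
#' @export
retain_multispecies <- function(clusters, protein_species_map) {
  keep <- vapply(clusters, function(cl) {
    length(cl) >= 2L &&
      length(unique(protein_species_map[cl])) >= 2L
  }, logical(1L))
  ogcs <- clusters[keep]
  names(ogcs) <- if (length(ogcs)) paste0("OGC", seq_along(ogcs)) else character()
  list(ogcs = ogcs,
       n_excluded_proteins = sum(lengths(clusters[!keep])),
       excluded = clusters[!keep])
}

#' Write clusters in OrthoMCL groups format
#'
#' One cluster per line: `OGC<k>: prot1 prot2 ...`.
#'
#' @param ogcs Named list of clusters.
#' @param path Output path.
#' @export
write_groups <- function(ogcs, path) {
  lines <- vapply(seq_along(ogcs), function(i) {
    paste0(names(ogcs)[i], ": ", paste(ogcs[[i]], collapse = " "))
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read an OrthoMCL-style groups file
#' @param path Path to a groups text file (`name: member member ...`).
#' @return Named list of character vectors.
#' @export
read_groups <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, ":", fixed = TRUE)
  nm <- vapply(parts, `[[`, character(1L), 1L)
  members <- lapply(parts, function(p) {
    strsplit(trimws(p[[2L]]), " +")[[1L]]
  })
  stats::setNames(members, trimws(nm))
}
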