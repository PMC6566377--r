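# Gene Ontology handling: OBO 1.2 parsing into an is_a DAG, term level
# computation (shortest is_a path from the namespace root, root = level 1),
# best-hit GO-term transfer to query proteins, and per-group annotation
# rates.

#' Parse an OBO 1.2 ontology into an is_a DAG
#'
#' Reads `[Term]` stanzas (`id:`, `name:`, `namespace:`, `is_a:`), drops
#' stanzas marked `is_obsolete: true`, and builds the DAG from `is_a` edges
#' only. Dangling `is_a` targets and cycles are errors. Term levels (shortest
#' is_a path to the namespace root, root = 1) are computed eagerly.
#'
#' @param path Path to an OBO 1.2 file.
#' @return A `go_dag`: list with `terms` (data.table `term_id`, `name`,
#'   `namespace`, `level`), `parents` (named list), `roots`.
#' @export
parse_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  term_starts <- which(lines == "[Term]")
  ids <- character(); nms <- character(); ns <- character()
  parents <- list(); obsolete <- logical()
  block_ends <- c(which(grepl("^\\[", lines)), length(lines) + 1L)
  for (s in term_starts) {
    e <- min(block_ends[block_ends > s]) - 1L
    block <- lines[s:e]
    getv <- function(key) sub(paste0("^", key, ": *"), "", grep(
      paste0("^", key, ":"), block, value = TRUE))
    id <- getv("id")
    if (length(id) != 1L) stop("OBO term stanza without a single id (line ", s, ")")
    obs <- any(grepl("^is_obsolete: *true", block))
    isa <- sub(" *!.*$", "", getv("is_a"))
    ids <- c(ids, id)
    nms <- c(nms, if (length(getv("name"))) getv("name")[1L] else id)
    ns <- c(ns, if (length(getv("namespace"))) getv("namespace")[1L] else "default")
    parents[[length(parents) + 1L]] <- isa
    obsolete <- c(obsolete, obs)
  }
  keep <- !obsolete
  ids <- ids[keep]; nms <- nms[keep]; ns <- ns[keep]; parents <- parents[keep]
  names(parents) <- ids
  # obsolete terms may be is_a targets of nothing here; drop edges into them
  dangling <- setdiff(unique(unlist(parents)), ids)
  if (length(dangling)) {
    stop("is_a target(s) not defined in ontology: ",
         paste(dangling, collapse = ", "))
  }
  build_go_dag(ids, nms, ns, parents)
}

build_go_dag <- function(ids, nms, ns, parents) {
  if (anyDuplicated(ids)) stop("duplicate term ids in ontology")
  roots <- ids[lengths(parents) == 0L]
  if (length(roots) == 0L && length(ids) > 0L) {
    stop("ontology has no root term (cycle?)")
  }
  assert_acyclic(ids, parents)
  # children lists for the downward BFS
  children <- lapply(stats::setNames(vector("list", length(ids)), ids), identity)
  for (id in ids) for (p in parents[[id]]) {
    children[[p]] <- c(children[[p]], id)
  }
  level <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  level[roots] <- 1L
  frontier <- roots
  while (length(frontier)) {
    nxt <- character()
    for (t in frontier) {
      for (ch in children[[t]]) {
        cand <- level[t] + 1L
        if (is.na(level[ch]) || cand < level[ch]) {
          level[ch] <- cand
          nxt <- c(nxt, ch)
        }
      }
    }
    frontier <- unique(nxt)
  }
  if (anyNA(level)) {
    stop("cycle detected: term(s) unreachable from any root: ",
         paste(ids[is.na(level)], collapse = ", "))
  }
  structure(list(
    terms = data.table(term_id = ids, name = nms, namespace = ns,
                       level = as.integer(unname(level[ids]))),
    parents = parents,
    roots = roots), class = "go_dag")
}

# Kahn topological elimination on child->parent edges; leftovers mean a cycle.
assert_acyclic <- function(ids, parents) {
  outdeg <- lengths(parents)  # edges child -> parent
  rev_children <- lapply(stats::setNames(vector("list", length(ids)), ids),
                         identity)
  for (id in ids) for (p in parents[[id]]) {
    rev_children[[p]] <- c(rev_children[[p]], id)
  }
  queue <- ids[outdeg == 0L]
  done <- 0L
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]
    done <- done + 1L
    for (ch in rev_children[[t]]) {
      outdeg[ch] <- outdeg[ch] - 1L
      if (outdeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (done != length(ids)) {
    stop("cycle detected in is_a edges involving: ",
         paste(ids[outdeg > 0L], collapse = ", "))
  }
  invisible(TRUE)
}

#' Level of an ontology term
#'
#' `1 +` the length of the shortest is_a path from the term to its namespace
#' root; the root itself has level 1.
#'
#' @param dag A `go_dag` from [parse_obo()].
#' @param term_id Term identifier(s).
#' @return Integer vector of levels.
#' @export
term_level <- function(dag, term_id) {
  i <- match(term_id, dag$terms$term_id)
  if (anyNA(i)) {
    stop("unknown term(s): ", paste(term_id[is.na(i)], collapse = ", "))
  }
  dag$terms$level[i]
}

#' Read a reference-to-GO ID-mapping TSV
#'
#' Two columns, no header: `reference_id<TAB>GO:NNNNNNN;GO:NNNNNNN`.
#'
#' @param path Path to the mapping file.
#' @return Named list, reference id -> character vector of term ids.
#' @export
read_go_map <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t", colClasses = "character")
  if (ncol(dt) != 2L) stop("GO map TSV must have 2 columns")
  stats::setNames(strsplit(dt[[2L]], ";", fixed = TRUE), dt[[1L]])
}

#' Write a reference-to-GO ID-mapping TSV
#' @param go_map Named list, reference id -> term ids.
#' @param path Output path.
#' @export
write_go_map <- function(go_map, path) {
  dt <- data.table(reference_id = names(go_map),
                   terms = vapply(go_map, paste, character(1L), collapse = ";"))
  fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Transfer GO terms from best reference hits to queries
#'
#' Per query protein: restrict its hits to those with `evalue < max_evalue`
#' whose reference carries at least one GO term; among those, all hits tied
#' at the minimum E-value contribute, and the query is annotated with the
#' union of their terms. Queries with no qualifying hits are absent from the
#' result (GO-unannotated).
#'
#' @param query_hits Hit table (only `qseqid`, `sseqid`, `evalue` are used).
#' @param reference_go_map Named list, reference id -> term ids (see
#'   [read_go_map()]).
#' @param max_evalue E-value cutoff, strict (default `1e-10`).
#' @return Named list, query protein -> sorted character vector of term ids;
#'   attribute `provenance` holds the contributing reference ids per query.
#' @export
transfer_annotations <- function(query_hits, reference_go_map,
                                 max_evalue = 1e-10) {
  has_terms <- names(reference_go_map)[lengths(reference_go_map) > 0L]
  dt <- as.data.table(query_hits)[, .(qseqid, sseqid, evalue)]
  dt <- dt[evalue < max_evalue & sseqid %in% has_terms]
  if (nrow(dt) == 0L) {
    out <- stats::setNames(list(), character())
    attr(out, "provenance") <- stats::setNames(list(), character())
    return(out)
  }
  best <- dt[, .(sseqid = sseqid[evalue == min(evalue)]), by = qseqid]
  refs <- split(best$sseqid, best$qseqid)
  ann <- lapply(refs, function(rs) {
    sort(unique(unlist(reference_go_map[unique(rs)], use.names = FALSE)))
  })
  attr(ann, "provenance") <- lapply(refs, function(rs) sort(unique(rs)))
  ann
}

#' Write an annotation map TSV (`protein_id<TAB>GO:...;GO:...`)
#' @param annotation_map Named list from [transfer_annotations()].
#' @param path Output path.
#' @export
write_annotations <- function(annotation_map, path) {
  write_go_map(annotation_map, path)
}

#' Per-group GO annotation rates
#'
#' For every phyletic group: the number of member proteins that carry at
#' least one transferred GO term, the group's total protein count, and the
#' percentage (half-up rounding to two decimals). A group with zero proteins
#' reports 0 with `undefined = TRUE`.
#'
#' @param annotation_map Named list from [transfer_annotations()].
#' @param protein_groups data.frame with columns `protein_id`, `group`.
#' @return data.frame `group`, `annotated`, `total`, `percent`, `undefined`.
#' @export
annotation_rates <- function(annotation_map, protein_groups) {
  labels <- group_labels()
  annotated_ids <- names(annotation_map)
  out <- data.frame(group = labels, annotated = 0L, total = 0L,
                    percent = 0, undefined = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(labels)) {
    prot <- protein_groups$protein_id[protein_groups$group == labels[i]]
    out$total[i] <- length(prot)
    out$annotated[i] <- sum(prot %in% annotated_ids)
    if (out$total[i] == 0L) {
      out$undefined[i] <- TRUE
    } else {
      out$percent[i] <- round_half_up(100 * out$annotated[i] / out$total[i], 2)
    }
  }
  out
}
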