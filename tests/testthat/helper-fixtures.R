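# Shared fixtures, built in code.

# A minimal 14-species panel mirroring the default clade sizes.
default_panel <- function() make_species_panel(sim_config())

# One hit row in the 14-column dialect, with overridable fields.
make_hit <- function(qseqid = "A", sseqid = "B", pident = 90, length = 100,
                     mismatch = 0, gapopen = 0, qstart = 1, qend = 100,
                     sstart = 1, send = 100, evalue = 1e-50, bitscore = 300,
                     qlen = 200, slen = 200) {
  data.table::data.table(qseqid = qseqid, sseqid = sseqid, pident = pident,
                         length = length, mismatch = mismatch,
                         gapopen = gapopen, qstart = qstart, qend = qend,
                         sstart = sstart, send = send, evalue = evalue,
                         bitscore = bitscore, qlen = qlen, slen = slen)
}

# Write hit rows to a temp TSV and return the path.
hit_tsv <- function(hits) {
  path <- tempfile(fileext = ".tsv")
  write_hit_table(hits, path)
  path
}

# Parse OBO text (string) via a temp file.
parse_obo_text <- function(text) {
  path <- tempfile(fileext = ".obo")
  writeLines(text, path)
  on.exit(unlink(path))
  parse_obo(path)
}

# Partition comparison that ignores cluster names/order.
partition_signature <- function(parts) {
  unname(sort(vapply(parts, function(x) paste(sort(x), collapse = ","),
                     character(1L))))
}

# Build a similarity graph directly from an edge list (equal reciprocal
# E-values), for clique-style MCL tests.
graph_from_edges <- function(edges_df, species = NULL) {
  nodes <- sort(unique(c(edges_df$u, edges_df$v)))
  if (is.null(species)) {
    species <- stats::setNames(rep("sp1", length(nodes)), nodes)
  }
  hits <- data.table::rbindlist(list(
    make_hit(qseqid = edges_df$u, sseqid = edges_df$v,
             evalue = edges_df$evalue),
    make_hit(qseqid = edges_df$v, sseqid = edges_df$u,
             evalue = edges_df$evalue)))
  build_similarity_graph(hits, species)
}

# Independent brute-force binomial p-values (direct pmf summation).
brute_binom_greater <- function(k, n, p0) {
  j <- k:n
  sum(choose(n, j) * p0^j * (1 - p0)^(n - j))
}
brute_binom_two_sided <- function(k, n, p0) {
  j <- 0:n
  pmf <- choose(n, j) * p0^j * (1 - p0)^(n - j)
  sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)])
}
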