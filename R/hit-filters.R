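# Parsing and filtering of tabular homology and HMM domain hits.
#
# Similarity hits use the 14-column BLAST tabular dialect
#   qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#   evalue bitscore qlen slen
# (outfmt "6 std qlen slen"). Domain hits use a reduced 6-column domtblout:
#   query hmm_name hmm_length hmm_from hmm_to evalue

HIT_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
              "qstart", "qend", "sstart", "send", "evalue", "bitscore",
              "qlen", "slen")

DOMAIN_COLS <- c("query", "hmm_name", "hmm_length", "hmm_from", "hmm_to", "evalue")

#' Read a 14-column similarity-hit table
#'
#' Parses a headerless, tab-separated all-vs-all protein homology table in the
#' BLAST tabular format extended with query and subject lengths. Every row is
#' validated against the coordinate invariants (`1 <= qstart <= qend <= qlen`,
#' `evalue >= 0`, `qlen > 0`); a violating row aborts the parse with its row
#' number.
#'
#' @param path Path to the TSV file (no header, 14 columns).
#' @return A `data.table` with columns `r paste(HIT_COLS, collapse = ", ")`.
#' @export
parse_hit_table <- function(path) {
  if (!file.exists(path)) stop("hit table not found: ", path)
  if (file.size(path) == 0L) return(empty_hit_table())
  dt <- fread(path, header = FALSE, sep = "\t", colClasses = list(
    character = c(1L, 2L)))
  if (nrow(dt) == 0L) return(empty_hit_table())
  if (ncol(dt) != 14L) {
    stop("expected 14 tab-separated columns, found ", ncol(dt))
  }
  setnames(dt, HIT_COLS)
  num_cols <- setdiff(HIT_COLS, c("qseqid", "sseqid"))
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(dt[[cl]]))
    if (anyNA(v) && !anyNA(dt[[cl]])) {
      stop("non-numeric value in column '", cl, "' at row ",
           which(is.na(v) & !is.na(dt[[cl]]))[1L])
    }
    data.table::set(dt, j = cl, value = v)
  }
  validate_hits(dt)
  dt[]
}

empty_hit_table <- function() {
  dt <- data.table(qseqid = character(), sseqid = character(),
                   pident = numeric(), length = numeric(),
                   mismatch = numeric(), gapopen = numeric(),
                   qstart = numeric(), qend = numeric(),
                   sstart = numeric(), send = numeric(),
                   evalue = numeric(), bitscore = numeric(),
                   qlen = numeric(), slen = numeric())
  dt
}

validate_hits <- function(dt) {
  bad <- which(!(dt$qstart >= 1 & dt$qstart <= dt$qend & dt$qend <= dt$qlen &
                   dt$evalue >= 0 & dt$qlen > 0))
  if (length(bad)) {
    stop("invalid hit row ", bad[1L],
         ": requires 1 <= qstart <= qend <= qlen, evalue >= 0, qlen > 0")
  }
  invisible(dt)
}

#' Query coverage of an alignment
#'
#' Fraction of the query protein spanned by the aligned region,
#' `(qend - qstart + 1) / qlen`.
#'
#' @param hits A hit `data.table` (or data.frame) with `qstart`, `qend`, `qlen`.
#' @return Numeric vector of coverages in (0, 1].
#' @export
query_coverage <- function(hits) {
  (hits$qend - hits$qstart + 1) / hits$qlen
}

#' Filter similarity hits for orthology analysis
#'
#' Keeps hits with `evalue < max_evalue` and query coverage strictly greater
#' than `min_query_cov` (both comparisons strict, so boundary values are
#' excluded). Self-hits (`qseqid == sseqid`) are dropped. Row order is
#' preserved and no record is mutated.
#'
#' @param hits Hit table from [parse_hit_table()].
#' @param max_evalue E-value cutoff (default `1e-5`).
#' @param min_query_cov Query-coverage cutoff (default `0.5`).
#' @return The surviving subset of `hits`.
#' @export
filter_hits <- function(hits, max_evalue = 1e-5, min_query_cov = 0.5) {
  keep <- hits$evalue < max_evalue &
    query_coverage(hits) > min_query_cov &
    hits$qseqid != hits$sseqid
  hits[keep, ]
}

#' Read a reduced 6-column HMM domain-hit table
#'
#' Columns: `query hmm_name hmm_length hmm_from hmm_to evalue` (no header).
#'
#' @param path Path to the TSV file.
#' @return A `data.table` of domain hits.
#' @export
parse_domain_table <- function(path) {
  if (!file.exists(path)) stop("domain table not found: ", path)
  empty <- data.table(query = character(), hmm_name = character(),
                      hmm_length = numeric(), hmm_from = numeric(),
                      hmm_to = numeric(), evalue = numeric())
  if (file.size(path) == 0L) return(empty)
  dt <- fread(path, header = FALSE, sep = "\t",
              colClasses = list(character = c(1L, 2L)))
  if (nrow(dt) == 0L) return(empty)
  if (ncol(dt) != 6L) stop("expected 6 tab-separated columns, found ", ncol(dt))
  setnames(dt, DOMAIN_COLS)
  bad <- which(!(dt$hmm_from >= 1 & dt$hmm_from <= dt$hmm_to &
                   dt$hmm_to <= dt$hmm_length & dt$evalue >= 0))
  if (length(bad)) {
    stop("invalid domain row ", bad[1L],
         ": requires 1 <= hmm_from <= hmm_to <= hmm_length, evalue >= 0")
  }
  dt[]
}

#' Filter HMM domain hits (CAZyme-style rule)
#'
#' Keeps domains with `evalue < max_evalue` and HMM coverage
#' `(hmm_to - hmm_from + 1)/hmm_length` strictly greater than `min_hmm_cov`.
#'
#' @param hits Domain-hit table from [parse_domain_table()].
#' @param max_evalue E-value cutoff (default `1e-15`).
#' @param min_hmm_cov HMM-coverage cutoff (default `0.8`).
#' @return The surviving subset.
#' @export
filter_domain_hits <- function(hits, max_evalue = 1e-15, min_hmm_cov = 0.8) {
  cov <- (hits$hmm_to - hits$hmm_from + 1) / hits$hmm_length
  hits[hits$evalue < max_evalue & cov > min_hmm_cov, ]
}

#' Write a similarity-hit table
#'
#' Headerless tab-separated output matching [parse_hit_table()]'s contract.
#'
#' @param hits Hit table.
#' @param path Output path.
#' @export
write_hit_table <- function(hits, path) {
  fwrite(hits[, HIT_COLS, with = FALSE], path, sep = "\t",
         col.names = FALSE, quote = FALSE, scipen = 0)
  invisible(path)
}
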