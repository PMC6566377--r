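# Internal helpers shared across modules.

#' @importFrom data.table data.table as.data.table fread fwrite setnames setorder := .N .SD
#' @importFrom stats runif
NULL

.datatable.aware <- TRUE

# data.table non-standard-evaluation column names
utils::globalVariables(c("qseqid", "sseqid", "evalue", "bitscore", "u", "v",
                         "w", "weight", ".", ".SD", ".N"))

# Half-up rounding (round() in R rounds half to even; printed tables use half-up).
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

# log(sum(exp(x))) without overflow; x may contain -Inf.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Derive a reproducible sub-seed (< 2^31) from a master seed and a stream label,
# so each simulated artifact has its own RNG stream: adding one artifact does
# not perturb the others.
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- sum(utf8ToInt(label) * seq_len(nchar(label)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483647)
}

with_stream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(derive_seed(seed, label))
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(expr)
}

# Log-uniform draw between two positive bounds (used for E-values).
rloguniform <- function(n, lo, hi) {
  stopifnot(lo > 0, hi >= lo)
  exp(runif(n, log(lo), log(hi)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
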