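# Control-group binomial GO enrichment.
#
# For a tested phyletic group, each level-restricted GO term's protein count
# k_T out of n_T GO-annotated proteins is compared against the control
# group's fraction p0 = k_C/n_C with an exact one-sample binomial test
# (upper tail by default), followed by multiple-testing adjustment across all
# terms tested in that group. A term is called over-represented when its
# adjusted p-value is below alpha and its observed fraction exceeds p0.

#' Count level-restricted GO terms in a protein group
#'
#' `n` is the number of group proteins present in the annotation map; for
#' every term whose level equals `level` (any namespace), `k` is the number
#' of annotated group proteins carrying it. Terms with `k = 0` are omitted.
#'
#' @param annotation_map Named list from [transfer_annotations()].
#' @param group_proteins Character vector of the group's protein ids.
#' @param dag A `go_dag`.
#' @param level GO level to test (default 6).
#' @return List with `n` (annotated proteins) and `k` (named integer vector).
#' @export
count_terms <- function(annotation_map, group_proteins, dag, level = 6L) {
  ann <- annotation_map[intersect(group_proteins, names(annotation_map))]
  n <- length(ann)
  if (n == 0L) return(list(n = 0L, k = stats::setNames(integer(), character())))
  lvl_terms <- dag$terms$term_id[dag$terms$level == level]
  terms <- unlist(ann, use.names = FALSE)
  # one count per (protein, term): terms within a protein are already unique
  terms <- terms[terms %in% lvl_terms]
  k <- table(terms)
  list(n = n, k = stats::setNames(as.integer(k), names(k)))
}

#' Exact one-sample binomial test
#'
#' Upper-tail (`"greater"`) p-value
#' \eqn{\sum_{j=k}^{n} \binom{n}{j} p_0^j (1-p_0)^{n-j}}, computed in
#' log-space for stability; `"two_sided"` sums the probabilities of all
#' outcomes whose point probability does not exceed that of `k` (times
#' `1 + 1e-7`), the point-probability method.
#'
#' @param k Observed successes, `0 <= k <= n`.
#' @param n Number of trials.
#' @param p0 Null success probability in `[0, 1]`.
#' @param alternative `"greater"` (default) or `"two_sided"`.
#' @return The p-value.
#' @export
binomial_test <- function(k, n, p0, alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  if (!is.finite(k) || !is.finite(n) || k < 0 || n < 0 || k > n ||
      k != round(k) || n != round(n)) {
    stop("invalid counts: need integers 0 <= k <= n")
  }
  if (!is.finite(p0) || p0 < 0 || p0 > 1) stop("invalid p0: need 0 <= p0 <= 1")
  if (p0 == 0) return(if (k == 0) 1 else 0)
  if (p0 == 1) return(if (alternative == "greater") 1 else if (k == n) 1 else 0)
  j <- 0:n
  lpmf <- lchoose(n, j) + j * log(p0) + (n - j) * log1p(-p0)
  if (alternative == "greater") {
    p <- exp(logsumexp(lpmf[j >= k]))
  } else {
    cut <- lpmf[k + 1L] + log1p(1e-7)
    p <- exp(logsumexp(lpmf[lpmf <= cut]))
  }
  min(p, 1)
}

#' Multiple-testing adjustment (from-scratch Holm and BH)
#'
#' Holm step-down: sort p ascending, `adj_(i) = max_{j<=i} min(1, (m-j+1)
#' p_(j))`; Benjamini-Hochberg step-up: `adj_(i) = min_{j>=i} min(1,
#' m p_(j) / j)`. Values are returned in the original order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method `"holm"` (default) or `"BH"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("holm", "BH")) {
  method <- match.arg(method)
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric())
  o <- order(p)
  ps <- p[o]
  adj <- if (method == "holm") {
    cummax(pmin(1, (m - seq_len(m) + 1) * ps))
  } else {
    rev(cummin(rev(pmin(1, m * ps / seq_len(m)))))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Enrichment of a tested group against the control group
#'
#' For every term counted in the tested group: the control fraction
#' `p0 = k_C / n_C` (terms absent from the control get `k_C = 0`) is used as
#' the null proportion of an exact binomial test on `(k_T, n_T)`; the
#' adjustment spans all terms tested in this group. A term is significant
#' when `p_adj < alpha` and its direction is `over` (observed fraction above
#' `p0`). Degenerate null proportions (`p0` of 0 or 1) are computed and
#' flagged, never dropped.
#'
#' @param tested,control Term-count tables from [count_terms()].
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @param method Adjustment method, `"holm"` (default) or `"BH"`.
#' @param alternative Test sidedness (see [binomial_test()]).
#' @return data.frame `term_id`, `k_T`, `n_T`, `k_C`, `n_C`, `p0`, `p_raw`,
#'   `p_adj`, `direction`, `significant`, `degenerate`.
#' @export
enrich_group <- function(tested, control, alpha = 0.05,
                         method = c("holm", "BH"),
                         alternative = c("greater", "two_sided")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  if (control$n == 0L) stop("control group has no annotated proteins")
  terms <- names(tested$k)
  k_T <- unname(tested$k)
  k_C <- unname(ifelse(terms %in% names(control$k),
                       control$k[terms], 0L))
  p0 <- k_C / control$n
  p_raw <- vapply(seq_along(terms), function(i) {
    binomial_test(k_T[i], tested$n, p0[i], alternative)
  }, numeric(1L))
  p_adj <- adjust_pvalues(p_raw, method)
  direction <- ifelse(k_T / tested$n > p0, "over", "under")
  data.frame(term_id = terms, k_T = k_T, n_T = tested$n,
             k_C = as.integer(k_C), n_C = control$n, p0 = p0,
             p_raw = p_raw, p_adj = p_adj, direction = direction,
             significant = p_adj < alpha & direction == "over",
             degenerate = p0 %in% c(0, 1),
             stringsAsFactors = FALSE)
}

#' Top-N report of over-represented terms
#'
#' Significant results sorted ascending by adjusted p-value (ties broken by
#' descending tested fraction, then term id), truncated to `top_n`, with a
#' `-log10(p_adj)` column.
#'
#' @param results data.frame from [enrich_group()].
#' @param top_n Number of rows to keep (default 20).
#' @return The truncated, sorted data.frame with `neg_log10_padj` added.
#' @export
top_report <- function(results, top_n = 20L) {
  sig <- results[results$significant, , drop = FALSE]
  if (nrow(sig)) {
    frac <- sig$k_T / sig$n_T
    sig <- sig[order(sig$p_adj, -frac, sig$term_id), , drop = FALSE]
    sig <- utils::head(sig, top_n)
  }
  sig$neg_log10_padj <- if (nrow(sig)) -log10(sig$p_adj) else numeric()
  rownames(sig) <- NULL
  sig
}
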