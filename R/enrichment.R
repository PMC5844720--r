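#' Hypergeometric over-representation test
#'
#' For each annotation term, tests whether the selected gene set is
#' enriched for the term's members relative to the universe:
#' `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)` with `N` universe
#' genes, `K` term members, `n` selected genes and `k` the overlap
#' (upper tail inclusive of the observed `k`). The enrichment factor is
#' `(k/n) / (K/N)`; q-values are Benjamini-Hochberg adjusted over the
#' tested terms.
#'
#' @param selected Character vector of selected gene ids (e.g. DE genes or
#'   lncRNA target genes); must be a subset of `universe`.
#' @param annotation data.frame with columns `term_id`, `term_name`,
#'   `category`, `gene_id` (one row per term/gene membership). Members
#'   outside the universe are dropped before testing.
#' @param universe Character vector of all genes eligible for selection.
#'   Defaults to all genes with at least one annotation.
#' @param alpha Significance level on the adjusted p (default 0.05;
#'   significance uses `q < alpha`).
#' @return data.frame of class `enrichment_result` with columns `term_id`,
#'   `term_name`, `category`, `k`, `n`, `K`, `N`, `enrichment_factor`,
#'   `p`, `q`, `significant`.
#' @export
hypergeom_enrich <- function(selected, annotation, universe = NULL,
                             alpha = 0.05) {
  need <- c("term_id", "term_name", "category", "gene_id")
  miss <- setdiff(need, names(annotation))
  if (length(miss)) stop("missing annotation columns: ", paste(miss, collapse = ", "))
  universe <- unique(universe %||% annotation$gene_id)
  if (length(universe) == 0) stop("empty universe")
  selected <- unique(selected)
  if (!all(selected %in% universe))
    stop("selected genes must be a subset of the universe")
  ann <- annotation[annotation$gene_id %in% universe, , drop = FALSE]
  ann <- unique(ann[, need])
  N <- length(universe)
  n <- length(selected)
  terms <- unique(ann[, c("term_id", "term_name", "category")])
  members <- split(ann$gene_id, ann$term_id)
  K <- vapply(members[terms$term_id], length, integer(1))
  k <- vapply(members[terms$term_id],
              function(m) sum(m %in% selected), integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  factor <- ifelse(n > 0, (k / n) / (K / N), NA_real_)
  q <- bh_adjust(p)
  out <- data.frame(
    term_id = terms$term_id, term_name = terms$term_name,
    category = terms$category,
    k = k, n = n, K = K, N = N,
    enrichment_factor = factor, p = p, q = q,
    significant = q < alpha,
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Top enriched terms by enrichment factor
#'
#' Retains terms with at least `min_genes` selected members, sorts by
#' enrichment factor (descending, ties broken by ascending p then term
#' id) and returns the first `top_n`.
#'
#' @param results An [hypergeom_enrich()] result.
#' @param top_n Number of terms to return (default 20).
#' @param min_genes Minimum overlap `k` (default 4).
#' @return The filtered, ranked subset of `results`.
#' @export
top_terms <- function(results, top_n = 20, min_genes = 4) {
  keep <- results[results$k >= min_genes, , drop = FALSE]
  ord <- order(-keep$enrichment_factor, keep$p, keep$term_id)
  keep <- keep[ord, , drop = FALSE]
  utils::head(keep, top_n)
}
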