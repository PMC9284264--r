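# Hypergeometric over-representation of annotation terms in a gene set.

#' Hypergeometric term enrichment
#'
#' For each term, tests over-representation of the study set within the
#' population by the upper-tail hypergeometric probability
#' `P(X >= k | N, K, n)`, where N is the population size, K the number of
#' population genes carrying the term, n the study-set size, and k the
#' study genes carrying the term. P-values are BH-adjusted across the
#' tested terms. Terms annotating no population gene are skipped.
#'
#' @param study character vector of study gene ids (subset of `population`).
#' @param population character vector of background gene ids.
#' @param annotation data frame with columns `gene_id`, `term_id` and
#'   optionally `term_name`.
#' @param rich_factor `"k_over_K"` (default; study genes in term over
#'   population genes in term) or `"k_over_n"`.
#' @return data frame with one row per term: `term_id`, `term_name`, `k`,
#'   `n`, `K`, `N`, `rich_factor`, `p`, `padj`, sorted by `p`.
#' @export
hypergeom_enrich <- function(study, population, annotation,
                             rich_factor = c("k_over_K", "k_over_n")) {
  rich_factor <- match.arg(rich_factor)
  study <- unique(as.character(study))
  population <- unique(as.character(population))
  extra <- setdiff(study, population)
  if (length(extra) > 0L) {
    stop_hybex(paste("study genes absent from population:",
                     paste(utils::head(extra, 5), collapse = ", ")),
               "invalid_input")
  }
  ann <- annotation[annotation$gene_id %in% population, , drop = FALSE]
  ann <- unique(ann[, intersect(c("gene_id", "term_id", "term_name"),
                                names(ann)), drop = FALSE])
  if (nrow(ann) == 0L) {
    return(data.frame(term_id = character(), term_name = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), rich_factor = numeric(),
                      p = numeric(), padj = numeric()))
  }
  N <- length(population)
  n <- length(study)
  Ktab <- table(ann$term_id)
  ktab <- table(ann$term_id[ann$gene_id %in% study])
  terms <- names(Ktab)
  K <- as.integer(Ktab[terms])
  k <- as.integer(ktab[terms]); k[is.na(k)] <- 0L
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  nm <- if ("term_name" %in% names(ann)) {
    ann$term_name[match(terms, ann$term_id)]
  } else terms
  rf <- if (rich_factor == "k_over_K") k / K else k / n
  out <- data.frame(term_id = terms, term_name = nm, k = k, n = n, K = K,
                    N = N, rich_factor = rf, p = p,
                    padj = bh_adjust(p), stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the top enriched terms
#'
#' Restricts to the `pool` terms with the smallest adjusted p-values, then
#' orders by adjusted p ascending and rich factor descending (ties broken
#' by term id) and returns the first `k` rows -- the convention of taking
#' the top 15 of the top 50 by FDR and rich factor.
#'
#' @param rows enrichment table from [hypergeom_enrich()].
#' @param k number of terms to return (default 15).
#' @param pool size of the preliminary FDR-ranked pool (default 50).
#' @return ordered subset of `rows` with at most `k` rows.
#' @export
top_terms <- function(rows, k = 15, pool = 50) {
  if (nrow(rows) == 0L) return(rows)
  ord0 <- order(rows$padj, rows$term_id)
  pooled <- rows[ord0[seq_len(min(pool, nrow(rows)))], , drop = FALSE]
  ord <- order(pooled$padj, -pooled$rich_factor, pooled$term_id)
  out <- pooled[ord[seq_len(min(k, nrow(pooled)))], , drop = FALSE]
  rownames(out) <- NULL
  out
}
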