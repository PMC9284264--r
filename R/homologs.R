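# Reciprocal-best-hit homolog pairing from tabular alignment hit tables.

.blast_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Read a 12-column tabular alignment hit file
#'
#' Parses the standard BLAST tabular (outfmt 6) dialect: twelve
#' tab-separated fields per row, no header. `pident`, `evalue` (scientific
#' notation accepted) and `bitscore` are parsed as numerics; row order is
#' preserved. An empty file yields an empty table.
#'
#' @param path path to the hit file.
#' @return data frame with the twelve standard columns.
#' @export
read_blast_tab <- function(path) {
  if (!file.exists(path)) {
    stop_hybex(paste("hit file not found:", path), "invalid_input")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- as.data.frame(setNames(
    c(rep(list(character()), 2), rep(list(numeric()), 10)), .blast_cols))
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    stop_hybex(sprintf("malformed hit row at line %d: %d field(s), need 12",
                       which(nf < 12L)[1], nf[which(nf < 12L)[1]]),
               "parse_error")
  }
  mat <- t(vapply(fields, function(f) f[1:12], character(12)))
  out <- data.frame(mat, stringsAsFactors = FALSE)
  names(out) <- .blast_cols
  num_cols <- setdiff(.blast_cols, c("qseqid", "sseqid"))
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(out[[cc]]))
    if (anyNA(v)) {
      stop_hybex(sprintf("non-numeric value in column %s at line %d", cc,
                         which(is.na(v))[1]), "parse_error")
    }
    out[[cc]] <- v
  }
  out
}

# Best hit per query: highest bitscore, ties by lower evalue, then higher
# identity, then lexicographic subject id. Only the top row per
# (query, subject) pair is considered.
.best_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$qseqid, -hits$bitscore, hits$evalue, -hits$pident,
               hits$sseqid)
  h <- hits[ord, , drop = FALSE]
  h <- h[!duplicated(paste(h$qseqid, h$sseqid, sep = "\r")), , drop = FALSE]
  h[!duplicated(h$qseqid), , drop = FALSE]
}

#' Screen one-to-one homolog pairs by reciprocal best hits
#'
#' Retains a pair (h, b) when b is h's best forward hit, h is b's best
#' reverse hit, and both best-hit rows pass the E-value and identity
#' filters (defaults: E-value below 1e-5, identity at least 90 percent).
#' "Best" means highest bitscore over the full hit table, ties broken by
#' lower E-value, then higher identity, then lexicographic subject id;
#' only the top-scoring row per (query, subject) combination is
#' considered. Filters apply to the winning rows, not before the best-hit
#' search, so tightening a threshold can only remove pairs, never create
#' new ones. The result is a one-to-one matching: no gene id occurs twice.
#'
#' @param forward hit table, genome H queries against genome B.
#' @param reverse hit table, genome B queries against genome H.
#' @param max_evalue maximum E-value (exclusive), default `1e-5`.
#' @param min_identity minimum percent identity (inclusive), default 90.
#' @param min_coverage optional minimum alignment length as a fraction of
#'   the shorter reported alignment span; `NULL` (default) disables the
#'   coverage filter.
#' @param verbose print per-filter drop counts.
#' @return data frame with `gene_h`, `gene_b`, `identity`, `evalue`,
#'   `bitscore` (identity/evalue/bitscore from the forward direction).
#' @export
reciprocal_best_hits <- function(forward, reverse, max_evalue = 1e-5,
                                 min_identity = 90, min_coverage = NULL,
                                 verbose = FALSE) {
  fwd <- .best_hits(forward)
  rev <- .best_hits(reverse)
  if (nrow(fwd) == 0L || nrow(rev) == 0L) {
    return(data.frame(gene_h = character(), gene_b = character(),
                      identity = numeric(), evalue = numeric(),
                      bitscore = numeric(), stringsAsFactors = FALSE))
  }
  back <- rev$sseqid[match(fwd$sseqid, rev$qseqid)]
  recip <- !is.na(back) & back == fwd$qseqid
  fwd <- fwd[recip, , drop = FALSE]
  rev <- rev[match(fwd$sseqid, rev$qseqid), , drop = FALSE]
  passes <- function(h) {
    ok_e <- h$evalue < max_evalue
    ok_i <- h$pident >= min_identity
    ok_c <- rep(TRUE, nrow(h))
    if (!is.null(min_coverage)) {
      span <- pmin(abs(h$qend - h$qstart), abs(h$send - h$sstart)) + 1
      ok_c <- h$length >= min_coverage * span
    }
    list(keep = ok_e & ok_i & ok_c, n_e = sum(!ok_e),
         n_i = sum(ok_e & !ok_i), n_c = sum(ok_e & ok_i & !ok_c))
  }
  pf <- passes(fwd)
  pr <- passes(rev)
  keep <- pf$keep & pr$keep
  if (verbose) {
    message(sprintf("%d reciprocal best-hit pairs; dropped %d by evalue, %d by identity, %d by coverage; retained %d",
                    nrow(fwd), pf$n_e + pr$n_e, pf$n_i + pr$n_i,
                    pf$n_c + pr$n_c, sum(keep)))
  }
  out <- data.frame(gene_h = fwd$qseqid[keep], gene_b = fwd$sseqid[keep],
                    identity = fwd$pident[keep], evalue = fwd$evalue[keep],
                    bitscore = fwd$bitscore[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$gene_h), , drop = FALSE]
}
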