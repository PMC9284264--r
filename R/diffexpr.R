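# Count-based differential expression for homolog pairs.
#
# The engine is deliberately closed-form: median-of-ratios size factors,
# method-of-moments dispersion shrunk toward a lowess mean-dispersion
# trend, and a negative-binomial Wald test on normalized group means with
# a delta-method standard error. This keeps every step checkable against a
# hand computation while reproducing the conventions of mainstream
# count-based DE tools.

#' Median-of-ratios library size factors
#'
#' For each library j, the factor is the median over genes i (restricted to
#' genes with all-positive counts) of `count[i, j]` divided by the row's
#' geometric mean. Identical libraries get factors of 1; a library with
#' elementwise doubled counts gets a factor twice as large.
#'
#' @param counts numeric matrix of raw counts, genes x libraries.
#' @return numeric vector of positive size factors, one per library.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 1L || nrow(counts) < 1L) {
    stop_hybex("counts matrix must be non-empty", "invalid_input")
  }
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (!any(allpos)) {
    warning("no gene has all-positive counts; falling back to total-count ratios")
    totals <- colSums(counts)
    return(totals / exp(mean(log(totals))))
  }
  sub <- counts[allpos, , drop = FALSE]
  geo <- exp(rowMeans(log(sub)))
  apply(sub, 2L, function(col) stats::median(col / geo))
}

#' Fragments per kilobase per million mapped reads
#'
#' `fpkm = count * 1e9 / (gene_length * mapped_total)`.
#'
#' @param counts numeric matrix, genes x libraries.
#' @param gene_length positive gene lengths in bp, one per row.
#' @param mapped_total positive mapped-read totals, one per library.
#' @return matrix of FPKM values with the dimensions of `counts`.
#' @export
fpkm <- function(counts, gene_length, mapped_total) {
  counts <- as.matrix(counts)
  if (any(gene_length <= 0) || any(mapped_total <= 0)) {
    stop_hybex("gene lengths and mapped totals must be positive", "invalid_input")
  }
  if (length(gene_length) != nrow(counts) || length(mapped_total) != ncol(counts)) {
    stop_hybex("length/total dimensions do not match the count matrix",
               "invalid_input")
  }
  sweep(sweep(counts, 1L, gene_length, "/"), 2L, mapped_total, "/") * 1e9
}

#' Per-gene dispersion estimates with trend shrinkage
#'
#' Method-of-moments raw estimate per gene, `max(0, (var - mean) / mean^2)`,
#' pooled across the supplied groups (each group contributes its own mean
#' and variance of normalized counts, weighted by residual degrees of
#' freedom), then shrunk 50/50 toward a lowess trend of log10 dispersion
#' over log10 mean. Estimates are floored at 1e-8.
#'
#' @param norm_counts matrix of normalized counts, genes x libraries.
#' @param groups factor/character of group labels, one per library.
#' @param prior dispersion returned (with a warning) when no group has
#'   replication.
#' @return numeric vector of dispersions, one per gene.
#' @export
estimate_dispersion <- function(norm_counts, groups, prior = 0.1) {
  norm_counts <- as.matrix(norm_counts)
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(norm_counts))
  split_idx <- split(seq_along(groups), groups)
  n_rep <- lengths(split_idx)
  if (all(n_rep < 2L)) {
    warning("no replicated group; using prior dispersion ", prior)
    return(rep(prior, nrow(norm_counts)))
  }
  num <- rep(0, nrow(norm_counts))
  den <- 0
  overall_mean <- rep(0, nrow(norm_counts))
  for (idx in split_idx) {
    sub <- norm_counts[, idx, drop = FALSE]
    m <- rowMeans(sub)
    overall_mean <- overall_mean + m * length(idx)
    if (length(idx) >= 2L) {
      v <- apply(sub, 1L, stats::var)
      w <- length(idx) - 1L
      d_g <- ifelse(m > 0, (v - m) / m^2, 0)
      num <- num + w * d_g
      den <- den + w
    }
  }
  overall_mean <- overall_mean / ncol(norm_counts)
  d_raw <- pmax(0, num / den)
  # Trend fit over genes with usable mean; shrink raw halfway toward it.
  usable <- overall_mean > 0
  d_trend <- rep(NA_real_, length(d_raw))
  if (sum(usable) >= 10L) {
    lx <- log10(overall_mean[usable])
    ly <- log10(d_raw[usable] + 1e-8)
    fit <- stats::lowess(lx, ly, f = 0.5)
    d_trend[usable] <- 10^stats::approx(fit$x, fit$y, xout = lx, rule = 2,
                                        ties = mean)$y
  } else {
    d_trend[usable] <- stats::median(d_raw[usable])
  }
  d <- ifelse(is.na(d_trend), d_raw, 0.5 * d_raw + 0.5 * d_trend)
  pmax(d, 1e-8)
}

#' Negative-binomial Wald test between two groups
#'
#' Normalized group means are compared on the log2 scale with a pseudo-count
#' for stability at zero: `log2fc = log2((mean_b + c) / (mean_a + c))`. The
#' standard error comes from the NB variance function `mu + d * mu^2` via
#' the delta method, the Wald statistic is `log2fc / se`, and the two-sided
#' p-value is taken from the standard normal. Vectorized over genes.
#'
#' @param counts_a,counts_b raw count matrices (genes x libraries) for the
#'   two groups; vectors are treated as single-gene matrices.
#' @param sf_a,sf_b size factors for the libraries of each group.
#' @param dispersion per-gene dispersion (recycled if scalar).
#' @param pseudo pseudo-count added to normalized means (default 0.5).
#' @return data frame with `mean_a`, `mean_b`, `log2fc`, `se`, `p`.
#' @export
nb_wald_test <- function(counts_a, counts_b, sf_a, sf_b, dispersion,
                         pseudo = 0.5) {
  if (is.null(dim(counts_a))) counts_a <- matrix(counts_a, nrow = 1L)
  if (is.null(dim(counts_b))) counts_b <- matrix(counts_b, nrow = 1L)
  stopifnot(nrow(counts_a) == nrow(counts_b),
            ncol(counts_a) == length(sf_a), ncol(counts_b) == length(sf_b))
  n_gene <- nrow(counts_a)
  d <- rep_len(dispersion, n_gene)
  norm_a <- sweep(as.matrix(counts_a), 2L, sf_a, "/")
  norm_b <- sweep(as.matrix(counts_b), 2L, sf_b, "/")
  mean_a <- rowMeans(norm_a)
  mean_b <- rowMeans(norm_b)
  log2fc <- log2((mean_b + pseudo) / (mean_a + pseudo))
  # Var of a group mean under NB(mu, d): (mu + d mu^2) / n; delta method
  # through log2(x + pseudo).
  var_a <- (mean_a + d * mean_a^2) / ncol(norm_a)
  var_b <- (mean_b + d * mean_b^2) / ncol(norm_b)
  ln2 <- log(2)
  se <- sqrt(var_a / (ln2 * (mean_a + pseudo))^2 +
             var_b / (ln2 * (mean_b + pseudo))^2)
  both_zero <- mean_a == 0 & mean_b == 0
  se[both_zero] <- NA_real_
  z <- ifelse(both_zero | se == 0, 0, log2fc / se)
  p <- 2 * stats::pnorm(-abs(z))
  p[both_zero] <- 1
  p <- pmin(p, 1)
  data.frame(mean_a = mean_a, mean_b = mean_b, log2fc = log2fc,
             se = se, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1, after input validation.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values of the same length.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop_hybex("p-values must be finite and within [0, 1]", "invalid_input")
  }
  stats::p.adjust(p, method = "BH")
}

#' Ternary differential-expression call
#'
#' `"up"` if `log2fc > lfc_threshold` and `padj < alpha`; `"down"` if
#' `log2fc < -lfc_threshold` and `padj < alpha`; otherwise `"ns"`.
#' Defaults are the conventional `|log2 fold change| > 1` with adjusted
#' p-value below 0.05.
#'
#' @param log2fc numeric vector of log2 fold changes.
#' @param padj adjusted p-values.
#' @param lfc_threshold fold-change gate (default 1).
#' @param alpha significance gate on `padj` (default 0.05).
#' @return character vector in `{"up", "down", "ns"}`.
#' @export
de_call <- function(log2fc, padj, lfc_threshold = 1, alpha = 0.05) {
  out <- rep("ns", length(log2fc))
  sig <- !is.na(padj) & padj < alpha
  out[sig & log2fc > lfc_threshold] <- "up"
  out[sig & log2fc < -lfc_threshold] <- "down"
  out
}

#' Full two-group differential-expression table
#'
#' Convenience wrapper running size-factor normalization (computed across
#' both groups jointly), dispersion estimation, the NB Wald test, BH
#' adjustment and the ternary call.
#'
#' @param counts raw count matrix, genes x libraries, with rownames as pair
#'   ids.
#' @param groups two-level factor/character, one label per library; the
#'   first level (alphabetically, or the factor's first level) is group a.
#' @param lfc_threshold,alpha call thresholds, see [de_call()].
#' @param sf optional precomputed size factors (one per library).
#' @param dispersion optional precomputed per-gene dispersion.
#' @return data frame with `pair_id`, `mean_a`, `mean_b`, `log2fc`, `se`,
#'   `p`, `padj`, `call`.
#' @export
de_table <- function(counts, groups, lfc_threshold = 1, alpha = 0.05,
                     sf = NULL, dispersion = NULL) {
  counts <- as.matrix(counts)
  groups <- if (is.factor(groups)) groups else factor(groups)
  if (nlevels(groups) != 2L) {
    stop_hybex("exactly two group levels are required", "invalid_input")
  }
  if (any(table(groups) < 2L)) {
    warning("a group has fewer than 2 replicates; power is very low")
  }
  sf <- sf %||% size_factors(counts)
  norm <- sweep(counts, 2L, sf, "/")
  if (is.null(dispersion)) {
    dispersion <- estimate_dispersion(norm, groups)
  }
  ia <- groups == levels(groups)[1]
  res <- nb_wald_test(counts[, ia, drop = FALSE], counts[, !ia, drop = FALSE],
                      sf[ia], sf[!ia], dispersion)
  res$padj <- bh_adjust(res$p)
  res$call <- de_call(res$log2fc, res$padj, lfc_threshold, alpha)
  data.frame(pair_id = rownames(counts) %||% as.character(seq_len(nrow(res))),
             res, stringsAsFactors = FALSE)
}

#' Expressed-gene filter
#'
#' A gene counts as expressed in a material-stage group when its FPKM
#' reaches `threshold` in at least one replicate.
#'
#' @param fpkm_mat FPKM matrix, genes x libraries.
#' @param threshold FPKM cutoff (default 1).
#' @return logical vector, one per gene.
#' @export
is_expressed <- function(fpkm_mat, threshold = 1) {
  apply(as.matrix(fpkm_mat) >= threshold, 1L, any)
}
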