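# Independent brute-force oracles. These deliberately share no code with
# the implementation: plain loops and textbook definitions only.

# Step-up BH from the definition: sort p ascending, q_i = p_i * m / i,
# enforce monotonicity from the largest rank down, cap at 1.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# Median-of-ratios from the definition, one explicit loop per library.
oracle_size_factors <- function(counts) {
  allpos <- apply(counts, 1, function(r) all(r > 0))
  sub <- counts[allpos, , drop = FALSE]
  geo <- apply(sub, 1, function(r) prod(r)^(1 / length(r)))
  vapply(seq_len(ncol(sub)), function(j) median(sub[, j] / geo), numeric(1))
}

# Exhaustive reciprocal-best-hit computation over a pair of hit tables:
# best hit per query over the full table, reciprocity, then both winning
# rows must pass the filters.
oracle_rbh <- function(forward, reverse, max_evalue = 1e-5,
                       min_identity = 90) {
  best_of <- function(h, q) {
    cand <- h[h$qseqid == q, , drop = FALSE]
    if (nrow(cand) == 0) return(NULL)
    # keep top row per subject first
    cand <- do.call(rbind, lapply(split(cand, cand$sseqid), function(g) {
      g[order(-g$bitscore, g$evalue, -g$pident)[1], , drop = FALSE]
    }))
    cand[order(-cand$bitscore, cand$evalue, -cand$pident, cand$sseqid)[1], ,
         drop = FALSE]
  }
  pass <- function(row) row$evalue < max_evalue & row$pident >= min_identity
  out <- list()
  for (q in unique(forward$qseqid)) {
    bf <- best_of(forward, q)
    if (is.null(bf)) next
    br <- best_of(reverse, bf$sseqid)
    if (!is.null(br) && br$sseqid == q && pass(bf) && pass(br)) {
      out[[length(out) + 1]] <- data.frame(
        gene_h = q, gene_b = bf$sseqid, identity = bf$pident,
        evalue = bf$evalue, bitscore = bf$bitscore, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(gene_h = character(), gene_b = character(),
                      identity = numeric(), evalue = numeric(),
                      bitscore = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$gene_h), , drop = FALSE]
}

# Hypergeometric upper tail P(X >= k) as an explicit sum of point masses.
oracle_hyper_tail <- function(k, K, N, n) {
  if (k > min(n, K)) return(0)
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Venn regions by explicit per-id membership enumeration.
oracle_venn <- function(sets) {
  ids <- unique(unlist(sets))
  regions <- c("111", "110", "101", "100", "011", "010", "001")
  counts <- setNames(integer(7), regions)
  for (id in ids) {
    key <- paste(as.integer(c(id %in% sets[[1]], id %in% sets[[2]],
                              id %in% sets[[3]])), collapse = "")
    counts[key] <- counts[key] + 1L
  }
  counts
}

# Exact two-sample Poisson rate test: conditional on the total, the second
# group's total is binomial with probability proportional to its library
# count.
oracle_poisson_test <- function(a, b) {
  stats::binom.test(sum(b), sum(a) + sum(b),
                    length(b) / (length(a) + length(b)))$p.value
}

# Random well-formed hit table generator for property tests.
random_hit_table <- function(n, queries, subjects) {
  data.frame(
    qseqid = sample(queries, n, replace = TRUE),
    sseqid = sample(subjects, n, replace = TRUE),
    pident = round(runif(n, 70, 100), 2),
    length = sample(200:2000, n, replace = TRUE),
    mismatch = sample(0:50, n, replace = TRUE),
    gapopen = sample(0:5, n, replace = TRUE),
    qstart = 1L, qend = 500L, sstart = 1L, send = 500L,
    evalue = 10^-runif(n, 2, 100),
    bitscore = round(runif(n, 100, 2000), 1),
    stringsAsFactors = FALSE)
}
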