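# Synthetic-data generators emulating the reciprocal interspecific cross
# design: two parents (GH, GB), their reciprocal F1 hybrids (HB, BH),
# three seedling stages (cotyledon, one-leaf, trefoil), two biological
# replicates per material-stage. Every generator takes one integer seed
# and is bit-reproducible; planted truth tables accompany every output so
# downstream classification can be scored against known answers.

.default_materials <- c("GH", "GB", "HB", "BH")
.default_stages <- c("cot", "one", "tre")

#' Generate a full-factorial RNA-seq library design
#'
#' One library per material x stage x replicate; the default layout
#' (4 materials, 3 stages, 2 replicates) yields 24 libraries.
#'
#' @param materials character vector of material labels.
#' @param stages character vector of stage labels.
#' @param replicates number of biological replicates per material-stage.
#' @param seed accepted for interface uniformity; the design is
#'   deterministic in its arguments.
#' @return data frame with `library_id`, `material`, `stage`, `replicate`;
#'   one row per library, all (material, stage, replicate) triples unique.
#' @export
generate_design <- function(materials = .default_materials,
                            stages = .default_stages,
                            replicates = 2, seed = NULL) {
  if (length(materials) == 0L || length(stages) == 0L || replicates < 1) {
    stop_hybex("materials/stages must be non-empty and replicates >= 1",
               "invalid_design")
  }
  if (anyDuplicated(materials) || anyDuplicated(stages)) {
    stop_hybex("duplicate material or stage labels", "invalid_design")
  }
  grid <- expand.grid(replicate = seq_len(replicates), stage = stages,
                      material = materials, stringsAsFactors = FALSE)
  grid <- grid[, c("material", "stage", "replicate")]
  grid$library_id <- paste(grid$material, grid$stage,
                           paste0("r", grid$replicate), sep = "_")
  rownames(grid) <- NULL
  grid[, c("library_id", "material", "stage", "replicate")]
}

# Planted means per bin: a geometric ladder low < mid < high with
# log2(mid/low) = log2(high/mid) = effect, arranged to satisfy each bin's
# defining order relations (see classify_bins).
.bin_means <- function(bin, low, mid, high) {
  switch(bin,
    conserved = c(mid, mid, mid),
    I    = c(low,  high, mid),
    XII  = c(high, low,  mid),
    II   = c(low,  mid,  mid),
    XI   = c(mid,  low,  low),
    IV   = c(mid,  low,  mid),
    IX   = c(low,  mid,  low),
    V    = c(low,  low,  mid),
    VI   = c(low,  mid,  high),
    VIII = c(mid,  low,  high),
    VII  = c(mid,  mid,  low),
    III  = c(mid,  high, low),
    X    = c(high, mid,  low),
    stop_hybex(paste("unknown bin:", bin), "invalid_input")
  ) # (mu_GH, mu_GB, mu_F1)
}

#' Plant a per-pair, per-stage expression-pattern truth table
#'
#' Assigns each homolog pair, at each stage, a true pattern bin drawn from
#' a category mix, and derives parental and hybrid mean expression levels
#' that satisfy the bin's order relations with a configurable log2 effect
#' size between adjacent levels.
#'
#' @param pair_ids character vector of pair ids.
#' @param stages stage labels (default the three seedling stages).
#' @param category_mix named numeric of relative weights for the five
#'   categories `Additive`, `ELD-H`, `ELD-B`, `TUR`, `TDR`; bins within a
#'   category are equiprobable.
#' @param prop_conserved fraction of (pair, stage) slots planted with no
#'   expression difference.
#' @param effect planted log2 effect between adjacent expression levels
#'   (default 2).
#' @param base_range range of the low expression level, in expected counts
#'   at the reference depth; drawn log-uniformly.
#' @param dispersion negative-binomial dispersion planted for every pair.
#' @param per_stage if `TRUE` (default) each stage draws its own bin, so a
#'   pair may change patterns across development; if `FALSE` the bin is
#'   fixed across stages.
#' @param seed integer seed.
#' @return data frame with `pair_id`, `stage`, `true_bin`, `true_category`,
#'   `mu_GH`, `mu_GB`, `mu_F1`, `dispersion`.
#' @export
simulate_truth <- function(pair_ids, stages = .default_stages,
                           category_mix = c(Additive = 10, `ELD-H` = 15,
                                            `ELD-B` = 15, TUR = 35, TDR = 25),
                           prop_conserved = 0.3, effect = 2,
                           base_range = c(25, 250), dispersion = 0.05,
                           per_stage = TRUE, seed = 1) {
  stopifnot(length(pair_ids) >= 1, dispersion > 0, effect > 0,
            prop_conserved >= 0, prop_conserved < 1)
  cats <- c("Additive", "ELD-H", "ELD-B", "TUR", "TDR")
  if (!all(cats %in% names(category_mix))) {
    stop_hybex("category_mix must name all five categories", "invalid_parameter")
  }
  bins_by_cat <- split(names(.bin_category)[.bin_category != "none"],
                       .bin_category[.bin_category != "none"])
  bin_prob <- unlist(lapply(cats, function(cc) {
    b <- bins_by_cat[[cc]]
    stats::setNames(rep(category_mix[[cc]] / length(b), length(b)), b)
  }))
  bin_prob <- bin_prob / sum(bin_prob) * (1 - prop_conserved)
  bin_prob <- c(bin_prob, conserved = prop_conserved)
  with_seed(seed, {
    n <- length(pair_ids)
    draw_bins <- function(k) sample(names(bin_prob), k, replace = TRUE,
                                    prob = bin_prob)
    rows <- lapply(stages, function(st) {
      data.frame(pair_id = pair_ids, stage = st, stringsAsFactors = FALSE)
    })
    truth <- do.call(rbind, rows)
    if (per_stage) {
      truth$true_bin <- draw_bins(nrow(truth))
    } else {
      per_pair <- stats::setNames(draw_bins(n), pair_ids)
      truth$true_bin <- per_pair[truth$pair_id]
    }
    low <- exp(stats::runif(nrow(truth), log(base_range[1]), log(base_range[2])))
    mid <- low * 2^effect
    high <- low * 2^(2 * effect)
    mus <- t(mapply(.bin_means, truth$true_bin, low, mid, high))
    truth$true_category <- bin_to_category(truth$true_bin)
    truth$mu_GH <- unname(mus[, 1])
    truth$mu_GB <- unname(mus[, 2])
    truth$mu_F1 <- unname(mus[, 3])
    truth$dispersion <- dispersion
    rownames(truth) <- NULL
    truth
  })
}

#' Simulate homolog pairs and reciprocal alignment hit tables
#'
#' Emits forward (genome H queries vs genome B) and reverse hit tables in
#' the 12-column tabular dialect. True pairs are mutual best hits; a
#' requested fraction of pairs is confounded with decoys -- a competing
#' higher-scoring forward hit, a non-reciprocal reverse best hit, or a
#' degraded (low-identity) alignment -- and the truth table records which
#' pairs survive the standard reciprocal-best-hit screen (E-value below
#' 1e-5, identity at least 90 percent, one-to-one).
#'
#' @param n_pairs number of true homolog pairs.
#' @param identity_range range (in percent, within \[0, 100\]) of alignment
#'   identities for non-degraded pairs.
#' @param decoy_fraction fraction of pairs confounded by a decoy.
#' @param seed integer seed.
#' @return list with `pairs` (truth table: `gene_h`, `gene_b`, `identity`,
#'   `evalue`, `bitscore`, `decoy`, `passes`), `forward`, `reverse` (hit
#'   tables).
#' @export
simulate_pairs <- function(n_pairs, identity_range = c(95, 99),
                           decoy_fraction = 0, seed = 1) {
  stopifnot(n_pairs >= 1)
  if (identity_range[1] < 0 || identity_range[2] > 100 ||
      identity_range[1] > identity_range[2]) {
    stop_hybex("identity_range must be an interval within [0, 100]",
               "invalid_parameter")
  }
  if (decoy_fraction < 0 || decoy_fraction > 1) {
    stop_hybex("decoy_fraction must lie in [0, 1]", "invalid_parameter")
  }
  with_seed(seed, {
    gene_h <- sprintf("GH_g%05d", seq_len(n_pairs))
    gene_b <- sprintf("GB_g%05d", seq_len(n_pairs))
    pident <- round(stats::runif(n_pairs, identity_range[1], identity_range[2]), 2)
    evalue <- signif(10^-stats::runif(n_pairs, 10, 150), 3)
    alen <- round(stats::runif(n_pairs, 300, 2000))
    bitscore <- round(stats::runif(n_pairs, 500, 2500), 1)
    decoy <- rep("none", n_pairs)
    n_decoy <- round(decoy_fraction * n_pairs)
    if (n_decoy > 0) {
      idx <- sample(n_pairs, n_decoy)
      decoy[idx] <- rep_len(c("competing_best", "non_reciprocal",
                              "low_identity"), n_decoy)
      low_i <- idx[decoy[idx] == "low_identity"]
      pident[low_i] <- round(stats::runif(length(low_i), 50, 85), 2)
    }
    hit_row <- function(q, s, pid, len, ev, bs) {
      data.frame(qseqid = q, sseqid = s, pident = pid, length = len,
                 mismatch = round(len * (1 - pid / 100)), gapopen = 0,
                 qstart = 1, qend = len, sstart = 1, send = len,
                 evalue = ev, bitscore = bs, stringsAsFactors = FALSE)
    }
    forward <- hit_row(gene_h, gene_b, pident, alen, evalue, bitscore)
    reverse <- hit_row(gene_b, gene_h, pident, alen, evalue, bitscore)
    other <- function(i) (i %% n_pairs) + 1L  # a different pair's partner
    comp <- which(decoy == "competing_best")
    if (length(comp)) {
      forward <- rbind(forward,
        hit_row(gene_h[comp], gene_b[other(comp)], pident[comp], alen[comp],
                evalue[comp], bitscore[comp] + 100))
    }
    nonrec <- which(decoy == "non_reciprocal")
    if (length(nonrec)) {
      reverse <- rbind(reverse,
        hit_row(gene_b[nonrec], gene_h[other(nonrec)], pident[nonrec],
                alen[nonrec], evalue[nonrec], bitscore[nonrec] + 100))
    }
    passes <- pident >= 90 & evalue < 1e-5 &
      !decoy %in% c("competing_best", "non_reciprocal")
    rownames(forward) <- rownames(reverse) <- NULL
    list(
      pairs = data.frame(gene_h = gene_h, gene_b = gene_b, identity = pident,
                         evalue = evalue, bitscore = bitscore, decoy = decoy,
                         passes = passes, stringsAsFactors = FALSE),
      forward = forward, reverse = reverse)
  })
}

#' Write a hit table in the 12-column tabular dialect
#'
#' @param hits hit table as produced by [simulate_pairs()] or
#'   [read_blast_tab()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(hits, path) {
  utils::write.table(hits[, .blast_cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Simulate paired count matrices with planted pattern truth
#'
#' Draws negative-binomial counts for every (pair, library) cell with mean
#' equal to the planted material-stage mean scaled by the library's depth
#' factor (depth factors vary log-normally around the nominal depth, so
#' size-factor estimation is non-trivial). For hybrid libraries the
#' pair-level hybrid mean is split across the two homeolog copies
#' (default 50/50); per-homeolog counts are emitted alongside their sum,
#' and downstream analysis defaults to the sum.
#'
#' @param design library design from [generate_design()].
#' @param truth truth table from [simulate_truth()]; must cover every
#'   (pair, stage) present in the design.
#' @param depth nominal per-library depth in reads; planted means are
#'   expressed at a reference depth of 1e6, so `depth = 1e6` leaves them
#'   unscaled.
#' @param depth_sdlog log-normal sd of per-library depth multipliers.
#' @param split_ratio fraction of hybrid pair-level expression carried by
#'   the H-genome homeolog copy.
#' @param seed integer seed.
#' @return list of class `paired_counts`: `counts` (pairs x libraries sum
#'   matrix), `homeolog_h`/`homeolog_b` (per-copy counts for hybrid
#'   libraries), `design`, `truth`, `gene_length`, `depth_factors`.
#' @export
simulate_counts <- function(design, truth, depth = 1e6, depth_sdlog = 0.1,
                            split_ratio = 0.5, seed = 1) {
  stopifnot(depth > 0, split_ratio >= 0, split_ratio <= 1)
  pair_ids <- unique(truth$pair_id)
  need <- expand.grid(pair_id = pair_ids, stage = unique(design$stage),
                      stringsAsFactors = FALSE)
  have <- paste(truth$pair_id, truth$stage)
  if (!all(paste(need$pair_id, need$stage) %in% have)) {
    stop_hybex("truth table does not cover every (pair, stage) in the design",
               "inconsistent_input")
  }
  if (any(truth$dispersion <= 0)) {
    stop_hybex("dispersion must be positive", "inconsistent_input")
  }
  with_seed(seed, {
    n_pair <- length(pair_ids)
    n_lib <- nrow(design)
    mult <- stats::rlnorm(n_lib, 0, depth_sdlog)
    sfac <- (depth / 1e6) * mult
    gene_length <- stats::setNames(round(stats::runif(n_pair, 500, 5000)),
                                   pair_ids)
    counts <- matrix(0L, n_pair, n_lib,
                     dimnames = list(pair_ids, design$library_id))
    hyb <- !design$material %in% c("GH", "GB")
    hom_h <- matrix(NA_integer_, n_pair, n_lib,
                    dimnames = dimnames(counts))
    hom_b <- hom_h
    key <- paste(truth$pair_id, truth$stage)
    for (j in seq_len(n_lib)) {
      st <- design$stage[j]
      tr <- truth[match(paste(pair_ids, st), key), ]
      mu <- switch(design$material[j], GH = tr$mu_GH, GB = tr$mu_GB,
                   tr$mu_F1) * sfac[j]
      size <- 1 / tr$dispersion
      if (hyb[j]) {
        ch <- stats::rnbinom(n_pair, mu = mu * split_ratio, size = size)
        cb <- stats::rnbinom(n_pair, mu = mu * (1 - split_ratio), size = size)
        hom_h[, j] <- ch
        hom_b[, j] <- cb
        counts[, j] <- ch + cb
      } else {
        counts[, j] <- stats::rnbinom(n_pair, mu = mu, size = size)
      }
    }
    structure(list(counts = counts, homeolog_h = hom_h, homeolog_b = hom_b,
                   design = design, truth = truth,
                   gene_length = gene_length, depth_factors = sfac),
              class = "paired_counts")
  })
}

#' Simulate plant-level phenotypes with planted heterosis
#'
#' Parent means are solved so that, noise-free, the hybrids realise exactly
#' the planted mid-parent (MPH) and over-parent (OPH) heterosis: the first
#' parent (GH) is anchored at 100 trait units and the second parent (GB) is
#' the high parent. Both reciprocal hybrids share the planted hybrid mean.
#' Per-plant values add Gaussian noise.
#'
#' @param traits character vector of trait names.
#' @param n_plants plants per material per day (at least 2).
#' @param planted_mph planted mid-parent heterosis in percent.
#' @param planted_oph planted over-parent heterosis in percent; must not
#'   exceed `planted_mph` (impossible for positive trait means).
#' @param noise_sd per-plant Gaussian noise sd, in trait units.
#' @param das integer vector of measurement days after sowing.
#' @param materials material labels: two parents then the hybrids.
#' @param seed integer seed.
#' @return data frame with `material`, `trait`, `das`, `plant_id`, `value`.
#' @export
simulate_phenotypes <- function(traits = c("plant_height", "leaf_area"),
                                n_plants = 6, planted_mph = 50,
                                planted_oph = 40, noise_sd = 5,
                                das = c(11, 15, 19, 23),
                                materials = .default_materials, seed = 1) {
  if (n_plants < 2) {
    stop_hybex("at least two plants per material are required", "invalid_parameter")
  }
  if (planted_oph > planted_mph) {
    stop_hybex("planted OPH cannot exceed planted MPH for positive trait means",
               "inconsistent_heterosis")
  }
  m <- planted_mph / 100; o <- planted_oph / 100
  denom <- 2 * (1 + o) - (1 + m)
  if (denom <= 0) {
    stop_hybex("planted MPH/OPH combination admits no positive parent means",
               "inconsistent_heterosis")
  }
  p1 <- 100
  p2 <- p1 * (1 + m) / denom   # high parent; p2 >= p1 iff mph >= oph
  f1 <- p2 * (1 + o)
  mean_of <- c(stats::setNames(c(p1, p2), materials[1:2]),
               stats::setNames(rep(f1, length(materials) - 2),
                               materials[-(1:2)]))
  with_seed(seed, {
    grid <- expand.grid(plant = seq_len(n_plants), das = das,
                        trait = traits, material = materials,
                        stringsAsFactors = FALSE)
    grid$value <- mean_of[grid$material] +
      stats::rnorm(nrow(grid), 0, noise_sd)
    data.frame(material = grid$material, trait = grid$trait, das = grid$das,
               plant_id = paste0(grid$material, "_p", grid$plant),
               value = grid$value, stringsAsFactors = FALSE)
  })
}

#' Simulate a gene-to-term annotation with planted enrichment
#'
#' Every gene receives each term independently with a term-specific base
#' probability; for terms named in `enriched_terms`, genes in the
#' designated `study_genes` subset carry the term with the base probability
#' multiplied by the planted fold.
#'
#' @param n_terms number of annotation terms.
#' @param genes character vector of gene ids (the population).
#' @param enriched_terms named numeric: term index or id mapped to its
#'   planted enrichment fold (1 = no enrichment).
#' @param study_genes genes in which the enriched terms are planted; must
#'   be a subset of `genes`.
#' @param base_prob range of per-term base annotation probabilities.
#' @param seed integer seed.
#' @return data frame with `gene_id`, `term_id`, `term_name`.
#' @export
simulate_annotation <- function(n_terms, genes, enriched_terms = NULL,
                                study_genes = NULL,
                                base_prob = c(0.02, 0.08), seed = 1) {
  stopifnot(n_terms >= 1)
  term_ids <- sprintf("TERM_%04d", seq_len(n_terms))
  if (!is.null(study_genes) && length(setdiff(study_genes, genes)) > 0) {
    stop_hybex("study_genes contains ids absent from genes", "invalid_parameter")
  }
  folds <- stats::setNames(rep(1, n_terms), term_ids)
  if (!is.null(enriched_terms) && length(enriched_terms) > 0) {
    nm <- names(enriched_terms)
    if (is.null(nm)) {
      stop_hybex("enriched_terms must be a named vector", "invalid_parameter")
    }
    unknown <- setdiff(nm, term_ids)
    if (length(unknown) > 0) {
      stop_hybex(paste("unknown term id(s) in enriched_terms:",
                       paste(unknown, collapse = ", ")), "invalid_parameter")
    }
    folds[nm] <- enriched_terms
  }
  with_seed(seed, {
    p_base <- stats::runif(n_terms, base_prob[1], base_prob[2])
    in_study <- genes %in% (study_genes %||% character())
    rows <- lapply(seq_len(n_terms), function(t) {
      p <- ifelse(in_study, pmin(1, p_base[t] * folds[t]), p_base[t])
      hit <- stats::runif(length(genes)) < p
      if (!any(hit)) return(NULL)
      data.frame(gene_id = genes[hit], term_id = term_ids[t],
                 term_name = paste("synthetic term", t),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) {
      out <- data.frame(gene_id = character(), term_id = character(),
                        term_name = character(), stringsAsFactors = FALSE)
    }
    rownames(out) <- NULL
    out
  })
}
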