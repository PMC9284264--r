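# End-to-end orchestration: synthetic or file-based inputs through homolog
# pairing, per-stage differential expression (three comparisons per
# hybrid), pattern classification, proportions, cross-stage intersections,
# term enrichment and phenotype heterosis, with a run manifest for
# reproducibility.

#' Build a pipeline configuration
#'
#' All analysis thresholds are surfaced here; none are hard-coded
#' downstream. In `"real"` mode the `paths` entries point at existing
#' input files; in `"synthetic"` mode the generators are driven by the
#' `sim` block.
#'
#' @param mode `"synthetic"` or `"real"`.
#' @param outdir output directory for report tables.
#' @param seed master integer seed; every stochastic stage derives its own
#'   seed from it.
#' @param lfc_threshold,alpha differential-expression call gates.
#' @param evalue,identity homolog-screen gates.
#' @param expressed_fpkm expressed-gene FPKM cutoff.
#' @param sim named list of synthetic-mode settings (`n_pairs`, `depth`,
#'   `dispersion`, `effect`, `prop_conserved`, `category_mix`,
#'   `decoy_fraction`, `n_terms`, `planted_mph`, `planted_oph`,
#'   `noise_sd`, `n_plants`); unset entries take the defaults of the
#'   corresponding generators.
#' @param paths named list of real-mode input paths (`counts`,
#'   `sample_sheet`, `forward_hits`, `reverse_hits`, `gene_length`,
#'   `annotation`, `phenotypes`).
#' @return a `hybex_config` list.
#' @export
pipeline_config <- function(mode = c("synthetic", "real"),
                            outdir = tempfile("hybex_run_"), seed = 1,
                            lfc_threshold = 1, alpha = 0.05,
                            evalue = 1e-5, identity = 90,
                            expressed_fpkm = 1,
                            sim = list(), paths = list()) {
  mode <- match.arg(mode)
  stopifnot(alpha > 0, alpha < 1, lfc_threshold >= 0, evalue > 0,
            identity >= 0, identity <= 100)
  sim_defaults <- list(n_pairs = 6000, depth = 1e6, dispersion = 0.05,
                       effect = 2, prop_conserved = 0.3,
                       category_mix = c(Additive = 10, `ELD-H` = 15,
                                        `ELD-B` = 15, TUR = 35, TDR = 25),
                       decoy_fraction = 0.05, n_terms = 50,
                       planted_mph = 50, planted_oph = 40, noise_sd = 5,
                       n_plants = 6)
  sim <- utils::modifyList(sim_defaults, sim)
  cfg <- list(mode = mode, outdir = outdir, seed = as.integer(seed),
              lfc_threshold = lfc_threshold, alpha = alpha,
              evalue = evalue, identity = identity,
              expressed_fpkm = expressed_fpkm, sim = sim, paths = paths)
  if (mode == "real") {
    missing <- names(Filter(function(p) !file.exists(p), paths))
    if (length(paths) == 0L) {
      stop_hybex("real mode requires input paths", "invalid_config")
    }
    if (length(missing) > 0L) {
      stop_hybex(paste("missing input file(s):",
                       paste(missing, collapse = ", ")), "invalid_config")
    }
  }
  class(cfg) <- "hybex_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [pipeline_config()].
#' @return a `hybex_config` list.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim$category_mix)) {
    y$sim$category_mix <- unlist(y$sim$category_mix)
  }
  do.call(pipeline_config, y)
}

.log_line <- function(con, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
  writeLines(msg, con)
  message(msg)
}

#' Run the full analysis pipeline
#'
#' Synthetic mode: generates homolog hit tables, counts with planted
#' pattern truth, an annotation and phenotypes, then runs the complete
#' analysis. Real mode: reads the same inputs from the configured paths.
#' Either way the stages are: reciprocal-best-hit pairing, per-stage
#' differential expression (parent-vs-parent plus hybrid-vs-each-parent,
#' per hybrid), 12-bin pattern classification, pattern proportions,
#' cross-stage intersections of the transgressive sets, term enrichment of
#' the transgressive genes, and phenotype heterosis. Report tables, a JSON
#' manifest (seed, thresholds, versions) and a log are written to the
#' output directory.
#'
#' @param config a `hybex_config` from [pipeline_config()] or
#'   [read_config()].
#' @return (invisibly) a list with every intermediate and report table.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "hybex_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(config$outdir, "run.log"), open = "wt")
  on.exit(close(log_con))
  seed <- config$seed
  parents <- c("GH", "GB")
  hybrids <- c("HB", "BH")

  if (config$mode == "synthetic") {
    s <- config$sim
    .log_line(log_con, "simulating ", s$n_pairs, " homolog pairs")
    sim_pairs <- simulate_pairs(s$n_pairs, decoy_fraction = s$decoy_fraction,
                                seed = seed + 1L)
    fwd_path <- file.path(config$outdir, "forward_hits.tsv")
    rev_path <- file.path(config$outdir, "reverse_hits.tsv")
    write_blast_tab(sim_pairs$forward, fwd_path)
    write_blast_tab(sim_pairs$reverse, rev_path)
    forward <- read_blast_tab(fwd_path)
    reverse <- read_blast_tab(rev_path)
    design <- generate_design()
    pairs <- reciprocal_best_hits(forward, reverse,
                                  max_evalue = config$evalue,
                                  min_identity = config$identity)
    .log_line(log_con, nrow(pairs), " pairs pass the homolog screen (",
              sum(sim_pairs$pairs$passes), " planted to pass)")
    truth <- simulate_truth(pairs$gene_h,
                            category_mix = s$category_mix,
                            prop_conserved = s$prop_conserved,
                            effect = s$effect, dispersion = s$dispersion,
                            seed = seed + 2L)
    pc <- simulate_counts(design, truth, depth = s$depth, seed = seed + 3L)
    annotation <- simulate_annotation(s$n_terms, pairs$gene_h,
                                      seed = seed + 4L)
    phenotypes <- simulate_phenotypes(planted_mph = s$planted_mph,
                                      planted_oph = s$planted_oph,
                                      noise_sd = s$noise_sd,
                                      n_plants = s$n_plants,
                                      seed = seed + 5L)
  } else {
    p <- config$paths
    design <- read_tsv(p$sample_sheet)
    counts_df <- read_tsv(p$counts)
    counts <- as.matrix(counts_df[, -1, drop = FALSE])
    rownames(counts) <- counts_df[[1]]
    forward <- read_blast_tab(p$forward_hits)
    reverse <- read_blast_tab(p$reverse_hits)
    pairs <- reciprocal_best_hits(forward, reverse,
                                  max_evalue = config$evalue,
                                  min_identity = config$identity)
    len_df <- read_tsv(p$gene_length)
    gene_length <- stats::setNames(len_df[[2]], len_df[[1]])
    keep <- intersect(pairs$gene_h, rownames(counts))
    pc <- structure(list(counts = counts[keep, design$library_id,
                                         drop = FALSE],
                         design = design, truth = NULL,
                         gene_length = gene_length[keep]),
                    class = "paired_counts")
    annotation <- if (!is.null(p$annotation)) read_tsv(p$annotation) else NULL
    phenotypes <- if (!is.null(p$phenotypes)) read_tsv(p$phenotypes) else NULL
    truth <- NULL
  }

  counts <- pc$counts
  design <- pc$design
  stages <- unique(design$stage)
  sf <- size_factors(counts)
  .log_line(log_con, "size factors estimated for ", length(sf), " libraries")

  # Expressed-gene filter over all libraries (population for enrichment).
  fpkm_mat <- fpkm(counts, pc$gene_length[rownames(counts)], colSums(counts))
  expressed <- is_expressed(fpkm_mat, config$expressed_fpkm)
  .log_line(log_con, sum(!expressed), " pairs fail the FPKM >= ",
            config$expressed_fpkm, " expressed filter")

  calls <- list()
  for (st in stages) {
    in_stage <- design$stage == st
    disp <- estimate_dispersion(
      sweep(counts[, in_stage, drop = FALSE], 2L, sf[in_stage], "/"),
      design$material[in_stage])
    lib_of <- function(mat) design$library_id[in_stage & design$material == mat]
    run_de <- function(mat_a, mat_b) {
      la <- lib_of(mat_a); lb <- lib_of(mat_b)
      res <- nb_wald_test(counts[, la, drop = FALSE],
                          counts[, lb, drop = FALSE],
                          sf[la], sf[lb], disp)
      res$padj <- bh_adjust(res$p)
      res$call <- de_call(res$log2fc, res$padj, config$lfc_threshold,
                          config$alpha)
      data.frame(pair_id = rownames(counts), res, stringsAsFactors = FALSE)
    }
    de_hb <- run_de("GH", "GB")
    for (hy in intersect(hybrids, design$material)) {
      de_fh <- run_de("GH", hy)
      de_fb <- run_de("GB", hy)
      calls[[paste(hy, st, sep = ".")]] <-
        classify_pairs(de_hb, de_fh, de_fb, stage = st, hybrid = hy)
    }
    .log_line(log_con, "stage ", st, ": patterns classified")
  }
  calls <- do.call(rbind, c(calls, make.row.names = FALSE))

  props <- list()
  for (hy in unique(calls$hybrid)) {
    for (st in stages) {
      pp <- pattern_proportions(calls[calls$hybrid == hy & calls$stage == st, ])
      props[[paste(hy, st, sep = ".")]] <-
        data.frame(hybrid = hy, stage = st, pp$by_category,
                   stringsAsFactors = FALSE)
    }
  }
  proportions <- do.call(rbind, c(props, make.row.names = FALSE))

  inter <- list()
  for (hy in unique(calls$hybrid)) {
    for (cat in c("TUR", "TDR")) {
      sets <- lapply(stages, function(st) {
        calls$pair_id[calls$hybrid == hy & calls$stage == st &
                      calls$category == cat]
      })
      names(sets) <- stages
      vi <- stage_intersections(sets)
      inter[[paste(hy, cat, sep = ".")]] <-
        data.frame(hybrid = hy, category = cat, vi, stringsAsFactors = FALSE)
    }
  }
  intersections <- do.call(rbind, c(inter, make.row.names = FALSE))

  enrichment <- NULL
  if (!is.null(annotation) && nrow(annotation) > 0) {
    population <- rownames(counts)[expressed]
    enr <- list()
    for (hy in unique(calls$hybrid)) {
      for (cat in c("TUR", "TDR")) {
        study <- intersect(unique(
          calls$pair_id[calls$hybrid == hy & calls$category == cat]),
          population)
        if (length(study) == 0L) next
        rows <- hypergeom_enrich(study, population, annotation)
        rows <- top_terms(rows, k = 15, pool = 50)
        if (nrow(rows) > 0) {
          enr[[paste(hy, cat, sep = ".")]] <-
            data.frame(hybrid = hy, category = cat, rows,
                       stringsAsFactors = FALSE)
        }
      }
    }
    if (length(enr)) {
      enrichment <- do.call(rbind, c(enr, make.row.names = FALSE))
    }
  }

  heterosis <- NULL
  if (!is.null(phenotypes) && nrow(phenotypes) > 0) {
    heterosis <- heterosis_timecourse(phenotypes, parents = parents)
  }

  write_tsv(design, file.path(config$outdir, "design.tsv"))
  write_tsv(pairs, file.path(config$outdir, "pairs.tsv"))
  write_tsv(calls, file.path(config$outdir, "pattern_calls.tsv"))
  write_tsv(proportions, file.path(config$outdir, "proportions.tsv"))
  write_tsv(intersections, file.path(config$outdir, "intersections.tsv"))
  if (!is.null(enrichment)) {
    write_tsv(enrichment, file.path(config$outdir, "enrichment.tsv"))
  }
  if (!is.null(heterosis)) {
    write_tsv(heterosis, file.path(config$outdir, "heterosis.tsv"))
  }
  manifest <- list(
    package = "hybex",
    version = as.character(utils::packageVersion("hybex")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    mode = config$mode, seed = config$seed,
    thresholds = config[c("lfc_threshold", "alpha", "evalue", "identity",
                          "expressed_fpkm")],
    n_pairs_screened = nrow(pairs), n_libraries = nrow(design))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  .log_line(log_con, "run complete; reports in ", config$outdir)

  invisible(list(config = config, design = design, pairs = pairs,
                 counts = pc, truth = truth, calls = calls,
                 proportions = proportions, intersections = intersections,
                 enrichment = enrichment, heterosis = heterosis))
}
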