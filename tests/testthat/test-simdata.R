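# The synthetic generators: factorial design, homolog pairs, counts with
# planted truth, phenotypes and annotations.

test_that("the design is a full factorial with unique triples", {
  d <- generate_design()
  expect_equal(nrow(d), 24)
  expect_equal(anyDuplicated(d[, c("material", "stage", "replicate")]), 0)
  expect_equal(nrow(generate_design("GH", "cot", 1)), 1)
  d2 <- generate_design(c("GH", "GB"), c("cot", "one", "tre"), 3)
  expect_equal(nrow(d2), 18)
  expect_equal(anyDuplicated(d2$library_id), 0)
  expect_error(generate_design(character(), "cot", 2), class = "invalid_design")
  expect_error(generate_design("GH", "cot", 0), class = "invalid_design")
})

test_that("planted means satisfy each bin's order relations", {
  truth <- simulate_truth(sprintf("p%04d", 1:800), effect = 2,
                          prop_conserved = 0.2, seed = 5)
  eff <- 2^2
  for (i in seq_len(nrow(truth))) {
    gh <- truth$mu_GH[i]; gb <- truth$mu_GB[i]; f1 <- truth$mu_F1[i]
    bin <- truth$true_bin[i]
    hb <- if (gb >= gh * eff) "up" else if (gh >= gb * eff) "down" else "ns"
    fh <- if (f1 >= gh * eff) "up" else if (gh >= f1 * eff) "down" else "ns"
    fb <- if (f1 >= gb * eff) "up" else if (gb >= f1 * eff) "down" else "ns"
    expect_identical(classify_bins(hb, fh, fb), bin)
  }
  expect_setequal(unique(truth$true_category),
                  c("Additive", "ELD-H", "ELD-B", "TUR", "TDR", "none"))
})

test_that("simulated pairs are reproducible and respect decoys and identity filters", {
  s1 <- simulate_pairs(200, decoy_fraction = 0.2, seed = 9)
  s2 <- simulate_pairs(200, decoy_fraction = 0.2, seed = 9)
  expect_identical(s1, s2)
  s3 <- simulate_pairs(200, decoy_fraction = 0.2, seed = 10)
  expect_false(identical(s1$forward, s3$forward))

  # no confounders: every pair survives the screen
  clean <- simulate_pairs(150, identity_range = c(95, 99), seed = 4)
  expect_true(all(clean$pairs$passes))
  got <- reciprocal_best_hits(clean$forward, clean$reverse)
  expect_equal(nrow(got), 150)

  # identities all below the 90 percent gate: everything planted to fail
  low <- simulate_pairs(50, identity_range = c(80, 89), seed = 4)
  expect_false(any(low$pairs$passes))
  expect_equal(nrow(reciprocal_best_hits(low$forward, low$reverse)), 0)

  # the screen recovers exactly the planted survivors
  mixed <- simulate_pairs(300, decoy_fraction = 0.3, seed = 6)
  got <- reciprocal_best_hits(mixed$forward, mixed$reverse)
  expect_setequal(got$gene_h, mixed$pairs$gene_h[mixed$pairs$passes])

  expect_error(simulate_pairs(10, identity_range = c(-5, 50)),
               class = "invalid_parameter")
})

test_that("counts hit planted means and the NB variance relation", {
  design <- generate_design(c("GH", "GB", "HB"), "cot", 60)
  truth <- simulate_truth(sprintf("p%03d", 1:200), stages = "cot",
                          prop_conserved = 0.3, dispersion = 0.05, seed = 2)
  pc <- simulate_counts(design, truth, depth = 1e6, depth_sdlog = 0, seed = 3)
  for (mat in c("GH", "GB", "HB")) {
    libs <- design$library_id[design$material == mat]
    mu_col <- switch(mat, GH = "mu_GH", GB = "mu_GB", "mu_F1")
    emp <- rowMeans(pc$counts[, libs])
    planted <- truth[[mu_col]][match(rownames(pc$counts), truth$pair_id)]
    # mean of 60 NB replicates at dispersion 0.05: relative error small
    expect_lt(median(abs(emp - planted) / planted), 0.05)
    emp_var <- apply(pc$counts[, libs], 1, var)
    # hybrid pair-level counts are sums of two independent homeolog halves,
    # so their quadratic term carries dispersion/2
    d_eff <- if (mat == "HB") 0.05 / 2 else 0.05
    v_pred <- planted + d_eff * planted^2
    expect_lt(abs(median(emp_var / v_pred) - 1), 0.35)
  }
  # hybrid homeolog copies sum to the emitted pair-level counts
  hyb_libs <- design$library_id[design$material == "HB"]
  expect_equal(pc$homeolog_h[, hyb_libs] + pc$homeolog_b[, hyb_libs],
               pc$counts[, hyb_libs])
  expect_true(all(is.na(pc$homeolog_h[, design$material == "GH"])))
  # determinism
  pc2 <- simulate_counts(design, truth, depth = 1e6, depth_sdlog = 0, seed = 3)
  expect_identical(pc$counts, pc2$counts)
  # design/truth mismatch
  expect_error(simulate_counts(generate_design(c("GH", "GB"), "one", 2), truth),
               class = "inconsistent_input")
})

test_that("an all-conserved truth yields almost no pattern calls", {
  design <- generate_design(replicates = 2)
  ids <- sprintf("p%04d", 1:2000)
  truth <- simulate_truth(ids, prop_conserved = 1 - 1e-9, seed = 8)
  truth$true_bin <- "conserved"   # force exact null
  truth$true_category <- "none"
  truth$mu_F1 <- truth$mu_GB <- truth$mu_GH
  pc <- simulate_counts(design, truth, seed = 9)
  sf <- size_factors(pc$counts)
  st <- "one"
  libs <- function(m) design$library_id[design$stage == st & design$material == m]
  disp <- estimate_dispersion(
    sweep(pc$counts[, design$stage == st], 2, sf[design$stage == st], "/"),
    design$material[design$stage == st])
  de <- function(a, b) {
    r <- nb_wald_test(pc$counts[, libs(a)], pc$counts[, libs(b)],
                      sf[libs(a)], sf[libs(b)], disp)
    r$padj <- bh_adjust(r$p)
    r$call <- de_call(r$log2fc, r$padj)
    data.frame(pair_id = rownames(pc$counts), r)
  }
  calls <- classify_pairs(de("GH", "GB"), de("GH", "HB"), de("GB", "HB"))
  expect_gte(mean(calls$bin == "conserved"), 0.99)
})

test_that("phenotypes realise the planted heterosis and validate their inputs", {
  ph <- simulate_phenotypes(traits = "plant_height", n_plants = 4,
                            planted_mph = 50, planted_oph = 40,
                            noise_sd = 0, das = 15, seed = 1)
  mean_of <- function(m) mean(ph$value[ph$material == m])
  expect_equal(oph(mean_of("HB"), mean_of("GH"), mean_of("GB")), 40)
  expect_equal(mph(mean_of("HB"), mean_of("GH"), mean_of("GB")), 50)
  # zero planted heterosis: hybrid equals the high parent
  ph0 <- simulate_phenotypes(traits = "t", planted_mph = 0, planted_oph = 0,
                             noise_sd = 0, das = 15, seed = 1)
  m0 <- function(m) mean(ph0$value[ph0$material == m])
  expect_equal(m0("HB"), max(m0("GH"), m0("GB")))
  expect_error(simulate_phenotypes(planted_mph = 30, planted_oph = 40),
               class = "inconsistent_heterosis")
  expect_error(simulate_phenotypes(n_plants = 1), class = "invalid_parameter")
})

test_that("annotation generator plants enrichment and is reproducible", {
  genes <- sprintf("g%04d", 1:2000)
  study <- genes[1:200]
  ann <- simulate_annotation(30, genes,
                             enriched_terms = c(TERM_0001 = 5),
                             study_genes = study, seed = 12)
  ann2 <- simulate_annotation(30, genes,
                              enriched_terms = c(TERM_0001 = 5),
                              study_genes = study, seed = 12)
  expect_identical(ann, ann2)
  in_term <- unique(ann$gene_id[ann$term_id == "TERM_0001"])
  frac_study <- mean(study %in% in_term)
  frac_rest <- mean(setdiff(genes, study) %in% in_term)
  expect_gt(frac_study, 2 * frac_rest)
  expect_error(simulate_annotation(5, genes, study_genes = "nope"),
               class = "invalid_parameter")
  expect_error(simulate_annotation(5, genes,
                                   enriched_terms = c(TERM_9999 = 2)),
               class = "invalid_parameter")
})

test_that("a maximally planted term attains the minimum achievable p", {
  genes <- sprintf("g%03d", 1:50)
  study <- genes[1:10]
  ann <- data.frame(gene_id = c(study, genes[11:30]),
                    term_id = c(rep("T_study", 10), rep("T_other", 20)),
                    term_name = "x")
  rows <- hypergeom_enrich(study, genes, ann)
  expect_equal(rows$term_id[which.min(rows$p)], "T_study")
  expect_equal(rows$p[rows$term_id == "T_study"],
               oracle_hyper_tail(10, 10, 50, 10))
})
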