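# Normalization, dispersion, the NB Wald test and the ternary call.

test_that("size factors reproduce the median-of-ratios definition", {
  expect_equal(size_factors(cbind(a = c(5, 10, 20), b = c(5, 10, 20))),
               c(1, 1), ignore_attr = TRUE)
  sf <- size_factors(cbind(a = c(5, 10, 20), b = c(10, 20, 40)))
  expect_equal(sf[2] / sf[1], 2, ignore_attr = TRUE)
  set.seed(21)
  for (rep in 1:10) {
    m <- matrix(rpois(15, 50) + 1, 5, 3)
    expect_equal(unname(size_factors(m)), oracle_size_factors(m))
  }
  expect_warning(size_factors(rbind(c(0, 5), c(3, 0))), "total-count")
})

test_that("fpkm follows its defining formula and edge cases error", {
  expect_equal(fpkm(matrix(10), 1000, 1e6)[1, 1], 10)
  expect_equal(fpkm(matrix(0), 1000, 1e6)[1, 1], 0)
  m <- matrix(rpois(6, 40), 3, 2)
  f1 <- fpkm(m, c(500, 1000, 2000), c(1e6, 2e6))
  f2 <- fpkm(m, c(500, 1000, 2000), c(2e6, 4e6))
  expect_equal(f2, f1 / 2)
  expect_error(fpkm(matrix(1), 0, 1e6), class = "invalid_input")
  expect_error(fpkm(matrix(1), 100, 0), class = "invalid_input")
})

test_that("dispersion estimates recover a planted value and respect the floor", {
  set.seed(31)
  n_rep <- 50
  mu <- exp(runif(400, log(20), log(500)))
  counts <- t(vapply(mu, function(m) rnbinom(2 * n_rep, mu = m, size = 1 / 0.05),
                     numeric(2 * n_rep)))
  groups <- rep(c("a", "b"), each = n_rep)
  d <- estimate_dispersion(counts, groups)
  expect_lt(abs(median(d) - 0.05) / 0.05, 0.2)
  # constant rows have zero variance: floored
  const <- matrix(7, 5, 6)
  expect_equal(unname(estimate_dispersion(const, rep(c("a", "b"), each = 3))),
               rep(1e-8, 5))
  expect_warning(
    d1 <- estimate_dispersion(matrix(rpois(4, 20), 2, 2), c("a", "b")),
    "prior")
  expect_equal(unname(d1), c(0.1, 0.1))
})

test_that("NB Wald test is null-centred, antisymmetric, and zero-safe", {
  a <- matrix(c(20, 22, 21, 19), 2, 2)
  same <- nb_wald_test(a, a, c(1, 1), c(1, 1), 0.05)
  expect_equal(same$log2fc, c(0, 0))
  expect_true(all(same$p >= 0.99))
  b <- matrix(c(50, 55, 40, 45), 2, 2)
  fwd <- nb_wald_test(a, b, c(1, 1), c(1, 1), 0.05)
  rev <- nb_wald_test(b, a, c(1, 1), c(1, 1), 0.05)
  expect_equal(fwd$log2fc, -rev$log2fc)
  expect_equal(fwd$p, rev$p)
  zero <- nb_wald_test(matrix(0, 1, 2), matrix(0, 1, 2), c(1, 1), c(1, 1), 0.05)
  expect_equal(zero$p, 1)
  expect_equal(zero$log2fc, 0)
})

test_that("at vanishing dispersion the Wald p tracks the exact Poisson rate test", {
  set.seed(3)
  rel <- c()
  while (length(rel) < 40) {
    na <- sample(2:3, 1); nb <- sample(2:3, 1)
    a <- rpois(na, runif(1, 15, 45)); b <- rpois(nb, runif(1, 15, 45))
    if (any(c(a, b) > 50) || all(a == 0) || all(b == 0)) next
    po <- oracle_poisson_test(a, b)
    if (po < 0.1 || po > 0.9) next
    w <- nb_wald_test(matrix(a, 1), matrix(b, 1), rep(1, na), rep(1, nb),
                      1e-8)$p
    rel <- c(rel, abs(w - po) / po)
  }
  expect_lt(median(rel), 0.10)
  expect_lt(max(rel), 0.30)
})

test_that("BH adjustment matches the step-up definition and dominates p", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(41)
  p <- runif(100)
  q <- bh_adjust(p)
  expect_equal(q, oracle_bh(p))
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "invalid_input")
  expect_error(bh_adjust(c(0.5, -0.1)), class = "invalid_input")
})

test_that("ternary DE call applies both gates", {
  expect_identical(de_call(2.3, 0.001), "up")
  expect_identical(de_call(0.9, 1e-10), "ns")
  expect_identical(de_call(-1.5, 0.2), "ns")
  expect_identical(de_call(-1.5, 0.01), "down")
  expect_identical(de_call(c(2, -2, 0.5), c(0.01, 0.01, 0.01)),
                   c("up", "down", "ns"))
})

test_that("calls are invariant to pure depth rescaling of one library", {
  set.seed(51)
  mu <- exp(runif(300, log(10), log(400)))
  counts <- t(vapply(mu, function(m) {
    c(rnbinom(2, mu = m, size = 20), rnbinom(2, mu = m * sample(c(1, 4), 1),
                                             size = 20))
  }, numeric(4)))
  rownames(counts) <- sprintf("p%03d", seq_len(nrow(counts)))
  groups <- rep(c("a", "b"), each = 2)
  base <- suppressWarnings(de_table(counts, groups))
  # Median-of-ratios absorbs the depth change up to a k^(1/m) drift of the
  # geometric-mean reference; with moment-based dispersion and a fixed
  # pseudo-count the statistics are therefore equal only to within that
  # drift, and calls agree except at genes sitting on a decision boundary.
  for (k in c(2, 10)) {
    scaled <- counts
    scaled[, 3] <- scaled[, 3] * k
    got <- suppressWarnings(de_table(scaled, groups))
    expect_gte(mean(got$call == base$call), 0.95)
    flipped <- which(got$call != base$call)
    # any flip must sit on a decision boundary, not be a sign reversal
    expect_true(all(abs(abs(base$log2fc[flipped]) - 1) < 0.25 |
                      abs(base$padj[flipped] - 0.05) < 0.05))
    expect_false(any(got$call[flipped] == "up" & base$call[flipped] == "down"))
    expect_equal(got$log2fc, base$log2fc, tolerance = 0.05)
  }
})

test_that("null NB simulation keeps the significant fraction at bay", {
  set.seed(61)
  n <- 5000
  mu <- exp(runif(n, log(20), log(500)))
  counts <- t(vapply(mu, function(m) rnbinom(4, mu = m, size = 1 / 0.05),
                     numeric(4)))
  rownames(counts) <- sprintf("p%04d", 1:n)
  res <- suppressWarnings(de_table(counts, rep(c("a", "b"), each = 2)))
  frac <- mean(res$padj < 0.05)
  mc_se <- sqrt(0.05 * 0.95 / n)
  expect_lte(frac, 0.05 + 3 * mc_se)
})
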