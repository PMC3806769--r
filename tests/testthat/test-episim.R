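test_that("Hardy-Weinberg probabilities are correct and normalized", {
  expect_equal(unname(hwe_probs(0.5)), c(0.25, 0.5, 0.25))
  expect_equal(unname(hwe_probs(0.4)), c(0.36, 0.48, 0.16))
  expect_error(hwe_probs(0), "\\(0, 0.5\\]")
  expect_error(hwe_probs(0.6), "\\(0, 0.5\\]")
  for (maf in c(0.05, 0.2, 0.33, 0.5))
    expect_equal(sum(hwe_probs(maf)), 1.0)
})

test_that("prevalence matches direct summation and stays within the penetrance range", {
  m <- penetrance_model(matrix(0.1, 3, 3), 0.3)
  expect_equal(prevalence(m), 0.1)
  md <- penetrance_model(diag(3), 0.5)
  pa <- hwe_probs(0.5)
  expect_equal(prevalence(md), sum(pa^2))
  set.seed(41)
  for (rep in 1:20) {
    f <- matrix(runif(9), 3, 3)
    mm <- penetrance_model(f, runif(1, 0.1, 0.5))
    K <- prevalence(mm)
    expect_gte(K, min(f)); expect_lte(K, max(f))
    # direct 9-cell oracle
    W <- outer(hwe_probs(mm$maf_a), hwe_probs(mm$maf_b))
    expect_equal(K, sum(W * f), tolerance = 1e-14)
  }
})

test_that("heritability hits its closed-form limits and the 9-cell oracle", {
  expect_equal(heritability(penetrance_model(matrix(0.3, 3, 3), 0.4)), 0.0)
  # deterministic XOR-pattern penetrance with K = 0.5 explains all variance
  xm <- canonical_model("xor", maf = 0.5, f_low = 0, f_high = 1)
  expect_equal(prevalence(xm), 0.5)
  expect_equal(heritability(xm), 1.0)
  expect_error(heritability(penetrance_model(matrix(0, 3, 3), 0.3)), "undefined")
  set.seed(42)
  for (rep in 1:20) {
    f <- matrix(runif(9, 0.05, 0.95), 3, 3)
    m <- penetrance_model(f, runif(1, 0.1, 0.5))
    W <- outer(hwe_probs(m$maf_a), hwe_probs(m$maf_b))
    K <- sum(W * f)
    expect_equal(heritability(m), sum(W * (f - K)^2) / (K * (1 - K)),
                 tolerance = 1e-12)
  }
})

test_that("marginal penetrance obeys total probability and flags zero-marginal models", {
  m <- penetrance_model(matrix(0.2, 3, 3), 0.35)
  expect_equal(marginal_penetrance(m, "a"), rep(0.2, 3))
  set.seed(43)
  for (rep in 1:10) {
    f <- matrix(runif(9), 3, 3)
    mm <- penetrance_model(f, 0.3, 0.25)
    for (locus in c("a", "b")) {
      mp <- marginal_penetrance(mm, locus)
      pr <- hwe_probs(if (locus == "a") mm$maf_a else mm$maf_b)
      expect_equal(sum(pr * mp), prevalence(mm), tolerance = 1e-14)
    }
  }
  # XOR at maf 0.5 is exactly zero-marginal
  xm <- canonical_model("xor")
  K <- prevalence(xm)
  expect_lt(max(abs(marginal_penetrance(xm, "a") - K)), 1e-10)
  expect_lt(max(abs(marginal_penetrance(xm, "b") - K)), 1e-10)
})

test_that("zero-marginal constructor meets its postconditions deterministically", {
  for (case in list(c(0.4, 0.4), c(0.25, 0.025))) {
    m <- build_zero_marginal_model(case[1], case[2], seed = 5)
    K <- prevalence(m)
    expect_lt(max(abs(c(marginal_penetrance(m, "a") - K,
                        marginal_penetrance(m, "b") - K))), 1e-8)
    expect_lt(abs(heritability(m) - case[2]), 1e-6)
    expect_true(all(m$f >= 0 & m$f <= 1))
  }
  m1 <- build_zero_marginal_model(0.3, 0.1, seed = 9)
  m2 <- build_zero_marginal_model(0.3, 0.1, seed = 9)
  expect_identical(m1$f, m2$f)
  m3 <- build_zero_marginal_model(0.3, 0.1, seed = 10)
  expect_false(identical(m1$f, m3$f))
  expect_error(build_zero_marginal_model(0.3, 1.5), "\\(0, 1\\)")
})

test_that("penetrance CSV loading round-trips a 3x3 table", {
  f <- matrix(round(runif(9), 3), 3, 3)
  tmp <- tempfile(fileext = ".csv")
  write.table(f, tmp, sep = ",", row.names = FALSE, col.names = FALSE)
  m <- read_penetrance_csv(tmp, maf_a = 0.3)
  expect_equal(unname(m$f), f, ignore_attr = TRUE)
  writeLines(c("1,2", "3,4"), tmp)
  expect_error(read_penetrance_csv(tmp, 0.3), "3 x 3")
})

test_that("simulate_pure meets class quotas, plants the pair, and is seed-deterministic", {
  m <- canonical_model("xor")
  d <- simulate_pure(m, n_cases = 30, n_controls = 50, n_snps = 20,
                     positions = c(1, 10), seed = 7)
  expect_equal(sum(d$phenotype == 1), 30)
  expect_equal(sum(d$phenotype == 0), 50)
  expect_equal(dim(d$genotypes$values), c(80, 20))
  expect_equal(d$truth$pairs[[1]], c(1L, 10L))
  d2 <- simulate_pure(m, 30, 50, 20, positions = c(1, 10), seed = 7)
  expect_identical(d$genotypes$values, d2$genotypes$values)
  d3 <- simulate_pure(m, 30, 50, 20, positions = c(1, 10), seed = 8)
  expect_false(identical(d$genotypes$values, d3$genotypes$values))
  expect_error(simulate_pure(m, positions = c(1, 1)), "distinct")
  expect_error(simulate_pure(m, n_snps = 5, positions = c(1, 10)), "1..5")
  expect_error(simulate_pure(penetrance_model(matrix(0, 3, 3), 0.4), 10, 10, 5, c(1, 2)),
               "identically 0")
})

test_that("missingness knob plants code 3 at roughly the requested rate", {
  m <- canonical_model("xor")
  d <- simulate_pure(m, 100, 100, 50, c(1, 2), missing_rate = 0.1, seed = 3)
  rate <- mean(d$genotypes$values == 3L)
  expect_gt(rate, 0.06); expect_lt(rate, 0.14)
})

test_that("conditional genotype sampling matches the analytic distribution (chi-square GOF)", {
  m <- build_zero_marginal_model(0.4, 0.2, seed = 1)
  d <- simulate_pure(m, n_cases = 20000, n_controls = 20000, n_snps = 2,
                     positions = c(1, 2), seed = 13)
  W <- outer(hwe_probs(m$maf_a), hwe_probs(m$maf_b))
  for (cls in 0:1) {
    expected <- if (cls == 1) W * m$f else W * (1 - m$f)
    expected <- as.vector(expected / sum(expected))
    rows <- d$phenotype == cls
    cells <- d$genotypes$values[rows, 1] + 3L * d$genotypes$values[rows, 2] + 1L
    obs <- tabulate(cells, 9)
    pval <- suppressWarnings(stats::chisq.test(obs, p = expected)$p.value)
    expect_gt(pval, 0.01)
  }
})

test_that("noise SNPs are label-independent and case loci keep HWE marginals under zero-marginal models", {
  m <- build_zero_marginal_model(0.4, 0.4, seed = 2)
  d <- simulate_pure(m, 2000, 2000, 5, c(1, 2), seed = 21)
  # zero-marginal: case and control genotype marginals at disease loci are HWE
  for (col in 1:2) {
    for (cls in 0:1) {
      counts <- tabulate(d$genotypes$values[d$phenotype == cls, col] + 1L, 3)
      pval <- stats::chisq.test(counts, p = unname(hwe_probs(0.4)))$p.value
      expect_gt(pval, 0.001)
    }
  }
  # a noise SNP shows no association with the label
  tab <- table(d$genotypes$values[, 4], d$phenotype)
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("hybrid datasets plant five independent pairs at the canonical positions", {
  hm <- hybrid_model(maf = 0.4, h2 = 0.2, seed = 6)
  expect_length(hm$models, 5)
  d <- simulate_hybrid(hm, n_cases = 300, n_controls = 300, seed = 19)
  expect_equal(d$truth$pairs, hybrid_positions())
  expect_equal(ncol(d$genotypes$values), 1000)
  # disease-locus MAFs within binomial error of the model MAF
  for (pos in unlist(hybrid_positions())) {
    maf_hat <- mean(d$genotypes$values[, pos]) / 2
    expect_lt(abs(maf_hat - 0.4), 4 * sqrt(0.4 * 0.6 / (2 * 600)))
  }
  # loci of different pairs are uncorrelated
  g <- d$genotypes$values
  expect_lt(abs(stats::cor(g[, 1], g[, 201])), 0.15)
  expect_lt(abs(stats::cor(g[, 100], g[, 900])), 0.15)
  expect_error(simulate_hybrid(hm, n_snps = 500), "at least 900")
  expect_error(hybrid_model(models = hm$models[1:3]), "five")
})

test_that("planted XOR pair is detectable end to end while noise stays null", {
  m <- canonical_model("xor")
  d <- simulate_pure(m, 200, 200, 2, positions = c(1, 2), seed = 23)
  pg <- pack_genotypes(d$genotypes)
  obs <- max_statistic(pg, d$phenotype, "ii")$value
  null <- permutation_null(pg, d$phenotype, "ii", B = 99, seed = 24)
  expect_gt(obs, stats::quantile(null$maxima, 0.95))
})
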