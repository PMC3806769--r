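test_that("packing encodes the 4 codes on the expected bit planes", {
  pg <- pack_genotypes(genotype_matrix(matrix(2L, 1, 1)))
  expect_equal(as.integer(pg$hi[1, 1]), 1L)
  expect_equal(as.integer(pg$lo[1, 1]), 0L)

  pg <- pack_genotypes(genotype_matrix(matrix(c(0L, 1L, 2L, 3L), 4, 1)))
  bits <- function(r) as.integer(rawToBits(r[, 1]))[1:4]
  expect_equal(bits(pg$hi), c(0L, 0L, 1L, 1L))
  expect_equal(bits(pg$lo), c(0L, 1L, 0L, 1L))
  # padding bits beyond n_samples are zero
  expect_true(all(as.integer(rawToBits(pg$hi[, 1]))[-(1:4)] == 0L))
})

test_that("pack/unpack round-trips, including across word boundaries", {
  set.seed(101)
  for (n in c(1, 5, 20, 63, 64, 65, 130)) {
    g <- matrix(sample(0:3, n * 7, replace = TRUE), n, 7)
    gm <- genotype_matrix(g)
    expect_identical(unpack_genotypes(pack_genotypes(gm))$values, gm$values)
  }
})

test_that("invalid genotype codes are rejected with row and column", {
  g <- matrix(0L, 3, 2)
  g[2, 2] <- 4L
  expect_error(genotype_matrix(g), "sample 2, SNP 2")
  expect_error(genotype_matrix(matrix(c(0L, NA, 0L, 0L), 2, 2)), "sample 2, SNP 1")
})

test_that("genotype_matrix enforces unique, length-matched ids", {
  g <- matrix(0L, 2, 2)
  expect_error(genotype_matrix(g, snp_ids = c("a", "a")), "unique")
  expect_error(genotype_matrix(g, sample_ids = "s1"), "length")
})

test_that("pair_contingency matches the spec example and rejects i == j", {
  g <- cbind(c(0L, 1L, 2L), c(2L, 2L, 0L))
  pg <- pack_genotypes(genotype_matrix(g))
  y <- c(1L, 0L, 1L)
  tab <- pair_contingency(pg, 1, 2, y)
  expect_equal(sum(tab), 3)
  expect_equal(tab["0", "2", "1"], 1L, ignore_attr = TRUE)
  expect_equal(tab["1", "2", "0"], 1L, ignore_attr = TRUE)
  expect_equal(tab["2", "0", "1"], 1L, ignore_attr = TRUE)
  expect_error(pair_contingency(pg, 2, 2, y), "distinct")
  expect_error(pair_contingency(pg, 1, 3, y), "1..2")
})

test_that("all-missing genotypes land in the missing cell", {
  g <- matrix(3L, 6, 2)
  pg <- pack_genotypes(genotype_matrix(g))
  tab <- pair_contingency(pg, 1, 2, rep(1L, 6))
  expect_equal(tab["3", "3", "1"], 6L, ignore_attr = TRUE)
  expect_equal(sum(tab), 6)
})

test_that("bitwise pair counting equals the per-sample tally (word-boundary sweep)", {
  set.seed(202)
  for (rep in 1:200) {
    n <- sample(c(2:62, 63, 64, 65), 1)
    p <- sample(2:6, 1)
    d <- random_dataset(n, p)
    pg <- pack_genotypes(genotype_matrix(d$geno))
    i <- sample(p, 1); j <- pick_one(setdiff(seq_len(p), i))
    expect_equal(unclass(pair_contingency(pg, i, j, d$pheno)),
                 oracle_pair_counts(d$geno, i, j, d$pheno),
                 ignore_attr = TRUE)
  }
  # n = 63, 64, 65 explicitly
  for (n in 63:65) {
    d <- random_dataset(n, 3)
    pg <- pack_genotypes(genotype_matrix(d$geno))
    expect_equal(unclass(pair_contingency(pg, 1, 3, d$pheno)),
                 oracle_pair_counts(d$geno, 1, 3, d$pheno), ignore_attr = TRUE)
  }
})

test_that("single_contingency matches the tally and the pair marginal", {
  g <- cbind(c(0L, 0L, 1L), c(1L, 2L, 0L))
  pg <- pack_genotypes(genotype_matrix(g))
  y <- c(1L, 0L, 1L)
  tab <- single_contingency(pg, 1, y)
  expect_equal(tab["0", "1"], 1L, ignore_attr = TRUE)
  expect_equal(tab["0", "0"], 1L, ignore_attr = TRUE)
  expect_equal(tab["1", "1"], 1L, ignore_attr = TRUE)
  set.seed(303)
  for (rep in 1:20) {
    d <- random_dataset(sample(5:70, 1), 4)
    pg <- pack_genotypes(genotype_matrix(d$geno))
    pair <- pair_contingency(pg, 2, 4, d$pheno)
    expect_equal(unclass(single_contingency(pg, 2, d$pheno)),
                 apply(pair, c(1, 3), sum), ignore_attr = TRUE)
    # row/column sums recover class sizes and genotype counts
    single <- single_contingency(pg, 2, d$pheno)
    expect_equal(colSums(single), c(sum(d$pheno == 0), sum(d$pheno == 1)),
                 ignore_attr = TRUE)
    expect_equal(rowSums(single), tabulate(d$geno[, 2] + 1L, 4), ignore_attr = TRUE)
  }
})

test_that("constant genotype column yields a single nonzero contingency row", {
  pg <- pack_genotypes(genotype_matrix(matrix(1L, 10, 1)))
  tab <- single_contingency(pg, 1, rep(c(0L, 1L), 5))
  expect_equal(sum(tab["1", ]), 10)
  expect_equal(sum(tab[c("0", "2", "3"), ]), 0)
})

test_that("simple-tsv round-trips and maps missing tokens to code 3", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\trs1\trs2\tphenotype",
               "s1\t0\tNA\t1",
               "s2\t-9\t2\t0"), tmp)
  d <- read_dataset(tmp, "simple-tsv")
  expect_equal(d$genotypes$values, rbind(c(0L, 3L), c(3L, 2L)))
  expect_equal(d$genotypes$snp_ids, c("rs1", "rs2"))
  expect_equal(d$phenotype, c(1L, 0L))

  # write/read round trip on random data
  set.seed(404)
  dd <- random_dataset(12, 5)
  gm <- genotype_matrix(dd$geno)
  out <- tempfile(fileext = ".tsv")
  write_dataset(gm, dd$pheno, out)
  back <- read_dataset(out, "simple-tsv")
  expect_identical(back$genotypes$values, gm$values)
  expect_identical(back$genotypes$snp_ids, gm$snp_ids)
  expect_identical(back$phenotype, dd$pheno)
})

test_that("simple-tsv parse failures name the offending line", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\trs1\tphenotype", "s1\t0\t1", "s2\t0"), tmp)
  expect_error(read_dataset(tmp), ":3:")
  writeLines(c("sample_id\trs1\tphenotype", "s1\tX\t1"), tmp)
  expect_error(read_dataset(tmp), "unknown genotype token 'X'")
  writeLines(c("sample_id\trs1\tphenotype", "s1\t0\t7"), tmp)
  expect_error(read_dataset(tmp), "phenotype")
})

test_that("plink-raw parsing follows the 1/2 phenotype convention", {
  tmp <- tempfile(fileext = ".raw")
  writeLines(c("FID IID PAT MAT SEX PHENOTYPE snpA_A snpB_C",
               "f1 i1 0 0 1 2 0 NA",
               "f2 i2 0 0 2 1 2 1"), tmp)
  d <- read_dataset(tmp, "plink-raw")
  expect_equal(d$phenotype, c(1L, 0L))
  expect_equal(d$genotypes$values, rbind(c(0L, 3L), c(2L, 1L)))
  expect_equal(d$genotypes$snp_ids, c("snpA", "snpB"))

  writeLines(c("FID IID PAT MAT SEX PHENOTYPE snpA_A", "f1 i1 0 0 1 0 1"), tmp)
  expect_error(read_dataset(tmp, "plink-raw"), "1 \\(control\\) or 2 \\(case\\)")
  writeLines(c("NOT A PLINK HEADER AT ALL x", "f1 i1 0 0 1 2 0"), tmp)
  expect_error(read_dataset(tmp, "plink-raw"), "header")
})
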