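# Independent brute-force oracles used to check the bit-packed fast paths.
# These deliberately share no code with the package internals: tables are
# tallied per sample with base::table and entropies evaluated as naive
# log-sums over probabilities.

# per-sample tally of the 4 x 4 x 2 pair table
oracle_pair_counts <- function(geno, i, j, labels) {
  unclass(table(factor(geno[, i], levels = 0:3),
                factor(geno[, j], levels = 0:3),
                factor(labels, levels = 0:1)))
}

oracle_single_counts <- function(geno, i, labels) {
  unclass(table(factor(geno[, i], levels = 0:3),
                factor(labels, levels = 0:1)))
}

# naive entropy in bits from a probability-normalized count table
oracle_entropy <- function(counts) {
  p <- as.vector(counts) / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p)) / log(2)
}

# I(X;C) via direct double sum over the joint
oracle_mi <- function(tab) {
  n <- sum(tab)
  px <- rowSums(tab) / n
  pc <- colSums(tab) / n
  s <- 0
  for (a in seq_len(nrow(tab))) for (b in seq_len(ncol(tab))) {
    pxy <- tab[a, b] / n
    if (pxy > 0) s <- s + pxy * log2(pxy / (px[a] * pc[b]))
  }
  unname(s)
}

# sample() that never expands a scalar x into 1:x
pick_one <- function(x) x[sample.int(length(x), 1)]

# Î(Y;X|Z) for a (Y, X, Z) table, summing I(Y;X | Z=z) weighted by P(z)
oracle_cmi <- function(tab) {
  n <- sum(tab)
  s <- 0
  for (z in seq_len(dim(tab)[3])) {
    slice <- tab[, , z]
    nz <- sum(slice)
    if (nz > 0) s <- s + (nz / n) * oracle_mi(t(slice))  # I(Y;X) symmetric
  }
  s
}

# I(X1;X2;C) as I({X1,X2};C) - I(X1;C) - I(X2;C), built from flattened pairs
oracle_ii <- function(tab) {
  d <- dim(tab)
  joint <- matrix(aperm(tab, c(1, 2, 3)), d[1] * d[2], d[3])
  oracle_mi(joint) - oracle_mi(apply(tab, c(1, 3), sum)) -
    oracle_mi(apply(tab, c(2, 3), sum))
}

# interaction information straight from raw sample columns
oracle_ii_columns <- function(x1, x2, y) {
  oracle_ii(unclass(table(factor(x1, levels = 0:3),
                          factor(x2, levels = 0:3),
                          factor(y, levels = 0:1))))
}

# random genotype dataset with both phenotype classes present
random_dataset <- function(n, p, codes = 0:3) {
  g <- matrix(sample(codes, n * p, replace = TRUE), n, p)
  y <- sample(0:1, n, replace = TRUE)
  if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
  list(geno = g, pheno = as.integer(y))
}

# a dataset where SNPs 1 and 2 encode XOR of the label (codes 0/1, uniform,
# exactly balanced) and any remaining SNPs are constant
xor_dataset <- function(n_per_cell = 25, n_extra = 1) {
  x1 <- rep(c(0L, 0L, 1L, 1L), n_per_cell)
  x2 <- rep(c(0L, 1L, 0L, 1L), n_per_cell)
  y <- as.integer(xor(x1, x2))
  g <- cbind(x1, x2, matrix(0L, length(x1), n_extra))
  colnames(g) <- NULL
  list(geno = g, pheno = y)
}
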