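#' Genotype matrix with a 4-state code
#'
#' Container for case-control genotype data. Each cell holds the number of
#' copies of the minor allele (0, 1 or 2) or the code 3 for a missing
#' genotype. Missing genotypes are a scored fourth category throughout the
#' package: they are never dropped, so every statistic is computed on the
#' full sample and does not depend on the partner SNP's missingness pattern.
#'
#' @param values integer matrix, samples in rows, SNPs in columns, all cells
#'   in `{0, 1, 2, 3}`.
#' @param snp_ids optional character vector of unique SNP identifiers
#'   (default `"snp_1"`, ...).
#' @param sample_ids optional character vector of unique sample identifiers
#'   (default `"sample_1"`, ...).
#' @return An object of class `genotype_matrix`: a list with elements
#'   `values`, `snp_ids`, `sample_ids`.
#' @examples
#' gm <- genotype_matrix(matrix(c(0L, 1L, 2L, 3L), 2, 2))
#' dim(gm$values)
#' @export
genotype_matrix <- function(values, snp_ids = NULL, sample_ids = NULL) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  storage.mode(values) <- "integer"
  bad <- which(is.na(values) | values < 0L | values > 3L)
  if (length(bad)) {
    s <- ((bad[1] - 1L) %% nrow(values)) + 1L
    k <- ((bad[1] - 1L) %/% nrow(values)) + 1L
    stop(sprintf("invalid genotype code at sample %d, SNP %d: codes must be 0, 1, 2 or 3", s, k))
  }
  if (is.null(snp_ids)) snp_ids <- paste0("snp_", seq_len(ncol(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(nrow(values)))
  snp_ids <- as.character(snp_ids)
  sample_ids <- as.character(sample_ids)
  if (length(snp_ids) != ncol(values)) stop("length(snp_ids) must equal ncol(values)")
  if (length(sample_ids) != nrow(values)) stop("length(sample_ids) must equal nrow(values)")
  if (anyDuplicated(snp_ids)) stop("snp_ids must be unique")
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  dimnames(values) <- NULL
  structure(list(values = values, snp_ids = snp_ids, sample_ids = sample_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (codes 0/1/2, 3 = missing)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Pack genotypes into 2-bit bit planes
#'
#' Encodes each SNP column as two length-`n_samples` bit vectors (a high and
#' a low bit plane), so that the code of sample `s` is `2*high + low`. Two
#' bits suffice for the three genotype states plus the missing state, and the
#' packed form lets contingency tables be counted with bitwise AND and
#' hardware popcount. Planes are zero-padded to a multiple of 64 samples;
#' padding bits are masked out of every count.
#'
#' @param genotypes a [genotype_matrix()].
#' @return An object of class `packed_genotypes` with elements `hi`, `lo`
#'   (raw matrices, one column per SNP), `n_samples`, `n_snps`, `snp_ids`,
#'   `sample_ids`.
#' @seealso [unpack_genotypes()] for the exact inverse.
#' @examples
#' gm <- genotype_matrix(matrix(c(0L, 1L, 2L, 3L), 4, 1))
#' pg <- pack_genotypes(gm)
#' identical(unpack_genotypes(pg)$values, gm$values)
#' @export
pack_genotypes <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  planes <- cpp_pack(genotypes$values)
  structure(list(hi = planes$hi, lo = planes$lo,
                 n_samples = nrow(genotypes$values),
                 n_snps = ncol(genotypes$values),
                 snp_ids = genotypes$snp_ids,
                 sample_ids = genotypes$sample_ids),
            class = "packed_genotypes")
}

#' Unpack 2-bit bit planes back to a genotype matrix
#'
#' Exact inverse of [pack_genotypes()].
#'
#' @param packed a `packed_genotypes` object.
#' @return A [genotype_matrix()].
#' @export
unpack_genotypes <- function(packed) {
  stopifnot(inherits(packed, "packed_genotypes"))
  genotype_matrix(cpp_unpack(packed$hi, packed$lo, packed$n_samples),
                  snp_ids = packed$snp_ids, sample_ids = packed$sample_ids)
}

#' @export
print.packed_genotypes <- function(x, ...) {
  cat(sprintf("packed_genotypes: %d samples x %d SNPs, 2 bits/genotype\n",
              x$n_samples, x$n_snps))
  invisible(x)
}

# validate a 0/1 phenotype vector against a packed or unpacked matrix;
# returns an integer vector
as_phenotype <- function(labels, n_samples = NULL, require_both = TRUE) {
  labels <- as.integer(labels)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L)))
    stop("phenotype labels must be 0 (control) or 1 (case), no missing values")
  if (!is.null(n_samples) && length(labels) != n_samples)
    stop(sprintf("phenotype length %d does not match %d samples",
                 length(labels), n_samples))
  if (require_both && length(unique(labels)) < 2L)
    stop("both phenotype classes (0 and 1) must be present")
  labels
}

check_snp_index <- function(packed, i) {
  i <- as.integer(i)
  if (length(i) != 1L || is.na(i) || i < 1L || i > packed$n_snps)
    stop(sprintf("SNP index must be in 1..%d", packed$n_snps))
  i
}

#' Pairwise genotype-phenotype contingency table
#'
#' Counts the 4 x 4 x 2 table (genotype at SNP `i` x genotype at SNP `j` x
#' phenotype) using bitwise combination of the two SNPs' bit planes with the
#' phenotype mask and population counts. Identical to a per-sample tally.
#'
#' @param packed a `packed_genotypes` object.
#' @param i,j distinct 1-based SNP indices.
#' @param pheno 0/1 phenotype vector of length `n_samples`.
#' @return Integer array of dim `c(4, 4, 2)` with dimnames
#'   `g_i` (0:3), `g_j` (0:3), `pheno` (0:1); its total equals `n_samples`.
#' @export
pair_contingency <- function(packed, i, j, pheno) {
  stopifnot(inherits(packed, "packed_genotypes"))
  i <- check_snp_index(packed, i)
  j <- check_snp_index(packed, j)
  if (i == j) stop("i and j must be distinct SNP indices")
  pheno <- as_phenotype(pheno, packed$n_samples, require_both = FALSE)
  counts <- cpp_pair_counts(packed$hi, packed$lo, packed$n_samples,
                            i - 1L, j - 1L, pheno)
  array(counts, dim = c(4, 4, 2),
        dimnames = list(g_i = 0:3, g_j = 0:3, pheno = 0:1))
}

#' Single-SNP genotype-phenotype contingency table
#'
#' The 4 x 2 (genotype x phenotype) table for one SNP; equals the
#' marginalization of any [pair_contingency()] involving that SNP.
#'
#' @inheritParams pair_contingency
#' @param i 1-based SNP index.
#' @return Integer matrix of dim `c(4, 2)` with dimnames `g` (0:3),
#'   `pheno` (0:1).
#' @export
single_contingency <- function(packed, i, pheno) {
  stopifnot(inherits(packed, "packed_genotypes"))
  i <- check_snp_index(packed, i)
  pheno <- as_phenotype(pheno, packed$n_samples, require_both = FALSE)
  counts <- cpp_single_counts(packed$hi, packed$lo, packed$n_samples,
                              i - 1L, pheno)
  matrix(counts, 4, 2, dimnames = list(g = 0:3, pheno = 0:1))
}
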