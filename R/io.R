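#' Read a case-control genotype dataset
#'
#' Two text dialects are supported:
#'
#' * `"simple-tsv"`: tab-separated with a header row. First column is the
#'   sample id, last column is the phenotype in `{0, 1}`, every column in
#'   between is one SNP with genotype tokens `0`, `1`, `2` or a missing
#'   token (`NA`, `-9`, or `3`). Missing genotypes become code 3.
#' * `"plink-raw"`: PLINK additive recode text (`--recode A`), whitespace
#'   separated, header `FID IID PAT MAT SEX PHENOTYPE` followed by one
#'   column per SNP (conventionally named `<snp>_<counted allele>`).
#'   Genotypes are minor-allele counts `0/1/2` with `NA` for missing;
#'   phenotypes use the PLINK 1/2 convention and are mapped to 0/1.
#'
#' Parse failures (ragged rows, unknown tokens, bad phenotypes) are reported
#' with the offending line number.
#'
#' @param path path to the text file.
#' @param format `"simple-tsv"` or `"plink-raw"`.
#' @return A list with elements `genotypes` (a [genotype_matrix()]) and
#'   `phenotype` (integer 0/1 vector).
#' @seealso [write_dataset()]
#' @export
read_dataset <- function(path, format = c("simple-tsv", "plink-raw")) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop(sprintf("%s: need a header line and at least one sample row", path))
  if (format == "simple-tsv") {
    parse_simple_tsv(lines, path)
  } else {
    parse_plink_raw(lines, path)
  }
}

parse_simple_tsv <- function(lines, path) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  nc <- length(header)
  if (nc < 3L)
    stop(sprintf("%s:1: header must have sample id, >=1 SNP column and a phenotype column", path))
  snp_ids <- header[2:(nc - 1L)]
  n <- length(fields) - 1L
  values <- matrix(0L, n, nc - 2L)
  pheno <- integer(n)
  sample_ids <- character(n)
  missing_tokens <- c("NA", "-9", "3")
  for (r in seq_len(n)) {
    row <- fields[[r + 1L]]
    line <- r + 1L
    if (length(row) != nc)
      stop(sprintf("%s:%d: expected %d fields, found %d", path, line, nc, length(row)))
    sample_ids[r] <- row[1]
    ph <- row[nc]
    if (!ph %in% c("0", "1"))
      stop(sprintf("%s:%d: phenotype must be 0 or 1, found '%s'", path, line, ph))
    pheno[r] <- as.integer(ph)
    g <- row[2:(nc - 1L)]
    g[g %in% missing_tokens] <- "3"
    if (!all(g %in% c("0", "1", "2", "3"))) {
      bad <- g[!g %in% c("0", "1", "2", "3")][1]
      stop(sprintf("%s:%d: unknown genotype token '%s'", path, line, bad))
    }
    values[r, ] <- as.integer(g)
  }
  list(genotypes = genotype_matrix(values, snp_ids = snp_ids, sample_ids = sample_ids),
       phenotype = pheno)
}

parse_plink_raw <- function(lines, path) {
  fields <- strsplit(trimws(lines), "[ \t]+")
  header <- fields[[1]]
  fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (length(header) < 7L || !identical(header[1:6], fixed))
    stop(sprintf("%s:1: not a PLINK .raw header (expected 'FID IID PAT MAT SEX PHENOTYPE' then SNP columns)", path))
  snp_ids <- sub("_[ACGT0-9]+$", "", header[-(1:6)])
  nc <- length(header)
  n <- length(fields) - 1L
  values <- matrix(0L, n, nc - 6L)
  pheno <- integer(n)
  sample_ids <- character(n)
  for (r in seq_len(n)) {
    row <- fields[[r + 1L]]
    line <- r + 1L
    if (length(row) != nc)
      stop(sprintf("%s:%d: expected %d fields, found %d", path, line, nc, length(row)))
    sample_ids[r] <- paste(row[1], row[2], sep = "_")
    ph <- row[6]
    if (!ph %in% c("1", "2"))
      stop(sprintf("%s:%d: PLINK phenotype must be 1 (control) or 2 (case), found '%s'", path, line, ph))
    pheno[r] <- as.integer(ph) - 1L
    g <- row[-(1:6)]
    g[g == "NA"] <- "3"
    if (!all(g %in% c("0", "1", "2", "3"))) {
      bad <- g[!g %in% c("0", "1", "2", "3")][1]
      stop(sprintf("%s:%d: unknown genotype token '%s'", path, line, bad))
    }
    values[r, ] <- as.integer(g)
  }
  list(genotypes = genotype_matrix(values, snp_ids = snp_ids, sample_ids = sample_ids),
       phenotype = pheno)
}

#' Write a dataset in the simple-tsv dialect
#'
#' Writes genotypes and phenotype in the format read back exactly by
#' [read_dataset()] with `format = "simple-tsv"` (missing genotypes are
#' written as `3`).
#'
#' @param genotypes a [genotype_matrix()].
#' @param phenotype integer 0/1 vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(genotypes, phenotype, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  phenotype <- as_phenotype(phenotype, nrow(genotypes$values), require_both = FALSE)
  header <- c("sample_id", genotypes$snp_ids, "phenotype")
  body <- cbind(genotypes$sample_ids,
                matrix(as.character(genotypes$values), nrow(genotypes$values)),
                as.character(phenotype))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}
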