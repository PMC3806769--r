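# run code with a private, seeded RNG stream; the caller's .Random.seed is
# restored on exit
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  code
}

#' Permutation null distribution of the maximum scan statistic
#'
#' For `b = 1..B`, the phenotype labels are uniformly permuted (genotypes
#' untouched, so LD structure among SNPs is preserved) and the maximum scan
#' statistic — max pairwise interaction information (`kind = "ii"`) or max
#' single-SNP mutual information (`kind = "mi"`) — is recorded. The B maxima
#' form the family-wise null used for threshold selection and p-values.
#'
#' All B permutations are drawn up front from one seeded stream, so the
#' result is reproducible from `seed` and independent of how the pair space
#' is partitioned during scanning.
#'
#' @inheritParams scan_pairs
#' @param kind `"ii"` or `"mi"`.
#' @param B number of permutations (`>= 1`).
#' @param seed integer master seed.
#' @return An object of class `perm_null`: list with `kind`, `B`, `maxima`
#'   (length-B numeric, bits), `seed`, `gamma_max = max(maxima)`.
#' @export
permutation_null <- function(packed, pheno, kind = c("ii", "mi"), B, seed) {
  kind <- match.arg(kind)
  stopifnot(inherits(packed, "packed_genotypes"))
  B <- as.integer(B)
  if (is.na(B) || B < 1L) stop("B must be a positive integer")
  pheno <- as_phenotype(pheno, packed$n_samples)
  labmat <- with_seed(seed, {
    m <- matrix(0L, length(pheno), B)
    for (b in seq_len(B)) m[, b] <- sample(pheno)
    m
  })
  maxima <- if (kind == "ii") {
    cpp_perm_pair_max(packed$hi, packed$lo, packed$n_samples, labmat)
  } else {
    cpp_perm_single_max(packed$hi, packed$lo, packed$n_samples, labmat)
  }
  structure(list(kind = kind, B = B, maxima = maxima, seed = as.integer(seed),
                 gamma_max = max(maxima)),
            class = "perm_null")
}

#' @export
print.perm_null <- function(x, ...) {
  cat(sprintf("perm_null: %s statistic, B = %d permutations (seed %d)\n",
              x$kind, x$B, x$seed))
  cat(sprintf("  gamma_max = %.6g bits\n", x$gamma_max))
  invisible(x)
}

#' Select a family-wise threshold from a permutation null
#'
#' Two rules:
#' * `"strictly-above-max"`: `gamma = gamma_max`, the largest statistic seen
#'   in the B permutations. Because hits require `value > gamma`, any hit has
#'   family-wise p-value below `1/(B+1)` (with B = 1000, below 0.001).
#' * `"multiplier"`: `gamma = C * gamma_max` for a constant `C >= 1`; `C < 1`
#'   is allowed but warned as anti-conservative.
#'
#' @param null a `perm_null`.
#' @param rule `"strictly-above-max"` or `"multiplier"`.
#' @param C multiplier constant (used when `rule = "multiplier"`), default 1.
#' @return An object of class `epi_threshold`: list with `gamma`, `rule`,
#'   `C`, `gamma_max`.
#' @export
select_threshold <- function(null, rule = c("strictly-above-max", "multiplier"), C = 1) {
  stopifnot(inherits(null, "perm_null"))
  rule <- match.arg(rule)
  if (rule == "multiplier") {
    if (!is.numeric(C) || length(C) != 1L || is.na(C)) stop("C must be a number")
    if (C < 1) warning("multiplier C < 1 is anti-conservative: threshold below the permutation maximum")
    gamma <- C * null$gamma_max
  } else {
    gamma <- null$gamma_max
    C <- NA_real_
  }
  structure(list(gamma = gamma, rule = rule, C = C, gamma_max = null$gamma_max),
            class = "epi_threshold")
}

#' @export
print.epi_threshold <- function(x, ...) {
  cat(sprintf("epi_threshold: gamma = %.6g bits (rule %s%s)\n", x$gamma, x$rule,
              if (!is.na(x$C)) sprintf(", C = %g", x$C) else ""))
  invisible(x)
}

#' Family-wise permutation p-value
#'
#' Add-one estimator `(1 + #\{maxima >= observed\}) / (B + 1)`: never exactly
#' zero, conservative, and non-increasing in the observed value. An observed
#' statistic above all B = 999 permutation maxima gets p = 1/1000.
#'
#' @param observed observed statistic value(s) in bits (vectorized).
#' @param null a `perm_null`.
#' @return Numeric p-value(s) in `(0, 1]`.
#' @export
familywise_pvalue <- function(observed, null) {
  stopifnot(inherits(null, "perm_null"), is.numeric(observed))
  vapply(observed,
         function(o) (1 + sum(null$maxima >= o)) / (null$B + 1),
         numeric(1))
}
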