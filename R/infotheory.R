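#' Plug-in Shannon entropy of a count table
#'
#' Maximum-likelihood ("plug-in") entropy in bits: cell probabilities are
#' `count / total` and `0 * log2(0)` is taken as 0. No small-sample bias
#' correction is applied; downstream permutation nulls absorb estimator bias.
#'
#' @param counts non-negative numeric array (any number of axes) with a
#'   positive total.
#' @return Entropy in bits (`>= 0`).
#' @examples
#' entropy(c(1, 1))   # 1 bit
#' entropy(c(5, 0))   # 0 bits
#' @export
entropy <- function(counts) {
  counts <- check_counts(counts)
  total <- sum(counts)
  p <- counts[counts > 0] / total
  -sum(p * log2(p))
}

check_counts <- function(counts) {
  if (!is.numeric(counts)) stop("counts must be numeric")
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative and free of NA")
  if (sum(counts) <= 0) stop("count table must have a positive total")
  counts
}

n_axes <- function(counts) if (is.null(dim(counts))) 1L else length(dim(counts))

# entropy of the marginal over the given axes
marginal_entropy <- function(counts, axes) {
  entropy(apply(counts, axes, sum))
}

#' Mutual information from a two-way count table
#'
#' `I(X; C) = H(X) + H(C) - H(X, C)` in bits, with plug-in probabilities.
#' For a SNP-phenotype table this measures single-locus (marginal)
#' association with the phenotype.
#'
#' @param counts non-negative two-axis table (X in rows, C in columns).
#' @return Mutual information in bits (`>= 0` up to floating-point error).
#' @examples
#' mutual_information(matrix(c(5, 0, 0, 5), 2))  # 1 bit
#' mutual_information(matrix(2, 2, 2))           # 0 bits
#' @export
mutual_information <- function(counts) {
  counts <- check_counts(counts)
  if (n_axes(counts) != 2L) stop("mutual_information needs a 2-axis table")
  marginal_entropy(counts, 1) + marginal_entropy(counts, 2) - entropy(counts)
}

#' Conditional mutual information from a three-way count table
#'
#' `I(Y; X | Z) = H(Y, Z) + H(X, Z) - H(X, Y, Z) - H(Z)` in bits: the extra
#' information X carries about Y once Z is known. This is the score refreshed
#' by the CMIM greedy selection. Always `>= 0` up to floating-point error;
#' exactly 0 when X and Z carry the same information about Y.
#'
#' @param counts non-negative three-axis table with axes ordered (Y, X, Z).
#' @return Conditional mutual information in bits.
#' @export
conditional_mutual_information <- function(counts) {
  counts <- check_counts(counts)
  if (n_axes(counts) != 3L) stop("conditional_mutual_information needs a 3-axis table")
  marginal_entropy(counts, c(1, 3)) + marginal_entropy(counts, c(2, 3)) -
    entropy(counts) - marginal_entropy(counts, 3)
}

#' Interaction information (synergy) from a three-way count table
#'
#' `I(X1; X2; C) = I(C; X1 | X2) - I(C; X1)`: the information about the
#' phenotype bound up in the pair beyond what either SNP carries alone.
#' Positive values indicate synergy (e.g. a pure XOR pair scores +1 bit with
#' zero single-SNP information), negative values redundancy (a duplicated
#' informative SNP scores `-H(C)`). The statistic is symmetric under any
#' permutation of the three axes; it is computed here in the equivalent
#' joint-entropy form
#' `H(X1,C) + H(X2,C) + H(X1,X2) - H(X1) - H(X2) - H(C) - H(X1,X2,C)`.
#'
#' @param counts non-negative three-axis table with axes (X1, X2, C).
#' @return Interaction information in bits (may be negative).
#' @examples
#' # C = XOR(X1, X2), X1 and X2 uniform independent: +1 bit of pure synergy
#' xor_tab <- array(0, c(2, 2, 2))
#' xor_tab[1, 1, 1] <- xor_tab[1, 2, 2] <- xor_tab[2, 1, 2] <- xor_tab[2, 2, 1] <- 2
#' interaction_information(xor_tab)
#' @export
interaction_information <- function(counts) {
  counts <- check_counts(counts)
  if (n_axes(counts) != 3L) stop("interaction_information needs a 3-axis table")
  marginal_entropy(counts, c(1, 3)) + marginal_entropy(counts, c(2, 3)) +
    marginal_entropy(counts, c(1, 2)) -
    marginal_entropy(counts, 1) - marginal_entropy(counts, 2) -
    marginal_entropy(counts, 3) - entropy(counts)
}
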