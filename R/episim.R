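#' Hardy-Weinberg genotype probabilities
#'
#' Genotype prior for one biallelic locus under Hardy-Weinberg equilibrium,
#' indexed by minor-allele count: `P(0) = (1-q)^2`, `P(1) = 2q(1-q)`,
#' `P(2) = q^2` with `q = maf`.
#'
#' @param maf minor-allele frequency in `(0, 0.5]`.
#' @return Numeric vector of length 3 (names `"0"`, `"1"`, `"2"`), summing
#'   to 1.
#' @examples
#' hwe_probs(0.5)  # 0.25 0.50 0.25
#' hwe_probs(0.4)  # 0.36 0.48 0.16
#' @export
hwe_probs <- function(maf) {
  if (!is.numeric(maf) || length(maf) != 1L || is.na(maf) || maf <= 0 || maf > 0.5)
    stop("maf must be a single number in (0, 0.5]")
  q <- maf; p <- 1 - maf
  stats::setNames(c(p^2, 2 * p * q, q^2), c("0", "1", "2"))
}

#' Two-locus penetrance model
#'
#' A 3 x 3 penetrance table `f[i, j] = P(disease | g_a = i-1, g_b = j-1)`
#' (rows: minor-allele count at locus A; columns: locus B) together with the
#' two loci's minor-allele frequencies. Prevalence and heritability are
#' derived quantities under Hardy-Weinberg independence of the loci.
#'
#' @param f numeric 3 x 3 matrix with entries in `[0, 1]`.
#' @param maf_a,maf_b minor-allele frequencies in `(0, 0.5]`.
#' @return An object of class `penetrance_model`.
#' @seealso [prevalence()], [heritability()], [marginal_penetrance()],
#'   [build_zero_marginal_model()], [canonical_model()]
#' @export
penetrance_model <- function(f, maf_a, maf_b = maf_a) {
  if (!is.matrix(f) || !all(dim(f) == c(3, 3)))
    stop("f must be a 3 x 3 matrix")
  if (anyNA(f) || any(f < 0) || any(f > 1))
    stop("penetrance entries must lie in [0, 1]")
  hwe_probs(maf_a); hwe_probs(maf_b)  # range checks
  dimnames(f) <- list(g_a = 0:2, g_b = 0:2)
  structure(list(f = f, maf_a = maf_a, maf_b = maf_b), class = "penetrance_model")
}

#' @export
print.penetrance_model <- function(x, ...) {
  cat(sprintf("penetrance_model: maf_a = %g, maf_b = %g\n", x$maf_a, x$maf_b))
  print(round(x$f, 4))
  cat(sprintf("  prevalence K = %.4g, heritability h2 = %.4g\n",
              prevalence(x), heritability(x)))
  invisible(x)
}

#' Disease prevalence of a penetrance model
#'
#' `K = sum_ij P(g_a = i) P(g_b = j) f[i, j]` under HWE independence of the
#' two loci.
#'
#' @param model a [penetrance_model()].
#' @return Prevalence in `[0, 1]`.
#' @export
prevalence <- function(model) {
  stopifnot(inherits(model, "penetrance_model"))
  sum(outer(hwe_probs(model$maf_a), hwe_probs(model$maf_b)) * model$f)
}

#' Broad-sense heritability of a penetrance model
#'
#' Variance-explained convention for binary penetrance models:
#' `h2 = sum_ij P(i) P(j) (f[i,j] - K)^2 / (K (1 - K))` with `K` the
#' prevalence. A constant table gives 0; a deterministic (0/1) table with
#' `K = 0.5` gives 1.
#'
#' @param model a [penetrance_model()].
#' @return Heritability in `[0, 1]`.
#' @export
heritability <- function(model) {
  stopifnot(inherits(model, "penetrance_model"))
  K <- prevalence(model)
  if (K <= 0 || K >= 1)
    stop("heritability undefined: prevalence is 0 or 1")
  W <- outer(hwe_probs(model$maf_a), hwe_probs(model$maf_b))
  sum(W * (model$f - K)^2) / (K * (1 - K))
}

#' Marginal penetrance of one locus
#'
#' `m_a[i] = sum_j P(g_b = j) f[i, j]` (and symmetrically for locus B). A
#' model has no marginal effects exactly when all three values equal the
#' prevalence at both loci — the property the simulated disease loci are
#' built to satisfy, which makes them invisible to single-SNP scans.
#'
#' @param model a [penetrance_model()].
#' @param locus `"a"` or `"b"`.
#' @return Numeric vector of length 3.
#' @export
marginal_penetrance <- function(model, locus = c("a", "b")) {
  stopifnot(inherits(model, "penetrance_model"))
  locus <- match.arg(locus)
  if (locus == "a") as.vector(model$f %*% hwe_probs(model$maf_b))
  else as.vector(crossprod(model$f, hwe_probs(model$maf_a)))
}

# null-space basis (9 x d) of the zero-marginal constraints for deviation
# tables delta: sum_j P_b(j) delta[i,j] = 0 per row, sum_i P_a(i) delta[i,j] = 0
# per column
zero_marginal_basis <- function(pa, pb) {
  A <- matrix(0, 6, 9)  # vec(delta) column-major: cell (i,j) -> i + 3*(j-1)
  for (i in 1:3) for (j in 1:3) {
    A[i, i + 3 * (j - 1)] <- pb[j]
    A[3 + j, i + 3 * (j - 1)] <- pa[i]
  }
  s <- svd(A, nu = 0, nv = 9)
  d <- c(s$d, rep(0, 9 - length(s$d)))
  s$v[, d < 1e-10 * max(s$d), drop = FALSE]
}

#' Construct a penetrance model with no marginal effects
#'
#' Builds a 3 x 3 penetrance table whose marginal penetrances at both loci
#' are exactly the prevalence (no single-locus effect) and whose
#' heritability equals `target_h2`. The table is found by a seeded random
#' search in the exact null space of the marginal constraints: a random
#' deviation direction is normalized to unit penetrance variance, scaled to
#' the target heritability, and combined with a prevalence `K` chosen from a
#' grid so all entries stay in `[0, 1]`. Determinism: the same seed always
#' yields the same table.
#'
#' @param maf minor-allele frequency of both loci (nominal range
#'   `[0.2, 0.4]`; any value in `(0, 0.5]` is accepted).
#' @param target_h2 desired heritability in `(0, 1)`.
#' @param seed integer seed for the random search.
#' @param max_tries number of random directions before giving up.
#' @return A [penetrance_model()] satisfying
#'   `max |marginal - K| < 1e-8` at both loci and
#'   `|heritability - target_h2| < 1e-6`.
#' @export
build_zero_marginal_model <- function(maf, target_h2, seed = 1L, max_tries = 2000L) {
  if (!is.numeric(target_h2) || length(target_h2) != 1L || is.na(target_h2) ||
      target_h2 <= 0 || target_h2 >= 1)
    stop("target_h2 must be in (0, 1)")
  pa <- hwe_probs(maf); pb <- pa
  N <- zero_marginal_basis(pa, pb)
  W <- outer(pa, pb)
  Kgrid <- seq(0.02, 0.98, by = 0.005)
  eps <- 1e-6
  model <- with_seed(seed, {
    found <- NULL
    for (try in seq_len(max_tries)) {
      d0 <- matrix(N %*% rnorm(ncol(N)), 3, 3)
      nrm <- sqrt(sum(W * d0^2))
      if (nrm < 1e-12) next
      d0 <- d0 / nrm
      for (K in Kgrid) {
        tt <- sqrt(target_h2 * K * (1 - K))
        f <- K + tt * d0
        if (all(f >= eps & f <= 1 - eps)) { found <- f; break }
      }
      if (!is.null(found)) break
    }
    found
  })
  if (is.null(model))
    stop(sprintf("no feasible zero-marginal penetrance table for maf = %g, h2 = %g after %d tries",
                 maf, target_h2, max_tries))
  m <- penetrance_model(model, maf, maf)
  K <- prevalence(m)
  dev <- max(abs(c(marginal_penetrance(m, "a") - K, marginal_penetrance(m, "b") - K)))
  if (dev >= 1e-8 || abs(heritability(m) - target_h2) >= 1e-6)
    stop("internal error: constructed model violates its postconditions")
  m
}

#' Canonical two-locus epistatic penetrance patterns
#'
#' Small library of textbook interaction patterns:
#' * `"xor"`: `f[i, j] = f_high` where `i + j` is odd, else `f_low`. At
#'   `maf = 0.5` this has exactly zero marginal effects at both loci
#'   (prevalence `(f_low + f_high)/2`, heritability
#'   `((f_high - f_low)/2)^2 / (K(1-K))`).
#' * `"modulo"`: `f[i, j] = f_high` where `(i + j) %% 3 == 0`, else
#'   `f_low`; a classic epistatic pattern, not zero-marginal in general.
#'
#' @param type `"xor"` or `"modulo"`.
#' @param maf minor-allele frequency of both loci (default 0.5 so the XOR
#'   pattern is exactly zero-marginal).
#' @param f_low,f_high penetrance of the low- and high-risk cells.
#' @return A [penetrance_model()].
#' @export
canonical_model <- function(type = c("xor", "modulo"), maf = 0.5,
                            f_low = 0.1, f_high = 0.9) {
  type <- match.arg(type)
  idx <- outer(0:2, 0:2, `+`)
  f <- matrix(f_low, 3, 3)
  if (type == "xor") f[idx %% 2 == 1] <- f_high else f[idx %% 3 == 0] <- f_high
  penetrance_model(f, maf, maf)
}

#' Read a 3 x 3 penetrance table from CSV
#'
#' Allows published penetrance tables (for example the Velez model
#' collection) to be dropped in: the file must contain exactly 3 rows of 3
#' comma-separated penetrance values (no header), rows indexed by
#' minor-allele count at locus A.
#'
#' @param path CSV path.
#' @param maf_a,maf_b locus minor-allele frequencies.
#' @return A [penetrance_model()].
#' @export
read_penetrance_csv <- function(path, maf_a, maf_b = maf_a) {
  f <- as.matrix(utils::read.csv(path, header = FALSE))
  if (!all(dim(f) == c(3, 3)))
    stop(sprintf("%s: expected a 3 x 3 table, found %d x %d", path, nrow(f), ncol(f)))
  dimnames(f) <- NULL
  penetrance_model(f, maf_a, maf_b)
}

# exact conditional two-locus genotype distributions given disease status;
# cells indexed column-major as (g_a, g_b) with W = outer(pa, pb)
conditional_cell_probs <- function(model) {
  W <- outer(hwe_probs(model$maf_a), hwe_probs(model$maf_b))
  num_case <- W * model$f
  num_ctrl <- W * (1 - model$f)
  list(case = if (sum(num_case) > 0) as.vector(num_case) / sum(num_case) else NULL,
       control = if (sum(num_ctrl) > 0) as.vector(num_ctrl) / sum(num_ctrl) else NULL)
}

# draw n (g_a, g_b) pairs from a 9-cell probability vector
draw_pairs <- function(probs, n) {
  cells <- sample.int(9L, n, replace = TRUE, prob = probs)
  cbind(ga = (cells - 1L) %% 3L, gb = (cells - 1L) %/% 3L)
}

# noise genotype matrix: each SNP HWE with its own MAF, independent of labels
draw_noise <- function(n, n_snps, maf_range) {
  if (n_snps == 0L) return(matrix(integer(0), n, 0))
  mafs <- runif(n_snps, maf_range[1], maf_range[2])
  vapply(mafs, function(m) sample(0:2, n, replace = TRUE, prob = hwe_probs(m)),
         integer(n))
}

apply_missingness <- function(values, rate) {
  if (rate <= 0) return(values)
  miss <- runif(length(values)) < rate
  values[miss] <- 3L
  values
}

#' Simulate a case-control dataset with one planted epistatic pair
#'
#' Retrospective (case-control) sampling: disease-locus genotype pairs are
#' drawn from the exact conditional distributions
#' `P(g_a, g_b | case) propto P(i) P(j) f[i, j]` and
#' `P(g_a, g_b | control) propto P(i) P(j) (1 - f[i, j])` (no rejection
#' loop), so the requested class counts are met exactly. Every other SNP is
#' drawn under HWE with its own MAF sampled uniformly from
#' `noise_maf_range`, independent of the label.
#'
#' @param model a [penetrance_model()].
#' @param n_cases,n_controls class sizes (default 200/200, the layout of
#'   the simulated association-study benchmark).
#' @param n_snps total SNP count (default 1000).
#' @param positions length-2 vector of distinct 1-based positions for the
#'   disease loci (default `c(1, 10)`).
#' @param noise_maf_range MAF range for noise SNPs (default
#'   `c(0.05, 0.5)`).
#' @param missing_rate fraction of genotype cells set to missing uniformly
#'   at random (default 0).
#' @param seed integer seed; identical seeds give identical datasets.
#' @return An object of class `sim_dataset`: list with `genotypes`
#'   ([genotype_matrix()]), `phenotype` (cases first, then controls), and
#'   `truth` (list of planted `pairs`, `models`, `seed`).
#' @export
simulate_pure <- function(model, n_cases = 200, n_controls = 200, n_snps = 1000,
                          positions = c(1, 10), noise_maf_range = c(0.05, 0.5),
                          missing_rate = 0, seed = 1L) {
  stopifnot(inherits(model, "penetrance_model"))
  positions <- as.integer(positions)
  if (length(positions) != 2L || positions[1] == positions[2])
    stop("positions must be two distinct indices")
  if (any(positions < 1L | positions > n_snps))
    stop(sprintf("positions must lie in 1..%d", n_snps))
  simulate_epistatic(list(model), list(positions), n_cases, n_controls, n_snps,
                     noise_maf_range, missing_rate, seed)
}

# shared generator for pure (1 pair) and hybrid (5 pairs) layouts
simulate_epistatic <- function(models, position_pairs, n_cases, n_controls,
                               n_snps, noise_maf_range, missing_rate, seed) {
  n <- n_cases + n_controls
  disease_pos <- unlist(position_pairs)
  if (anyDuplicated(disease_pos)) stop("disease-locus positions clash")
  values <- with_seed(seed, {
    v <- matrix(0L, n, n_snps)
    case_rows <- seq_len(n_cases)
    ctrl_rows <- n_cases + seq_len(n_controls)
    for (m in seq_along(models)) {
      cp <- conditional_cell_probs(models[[m]])
      if (n_cases > 0 && is.null(cp$case))
        stop("penetrance table is identically 0 but cases were requested")
      if (n_controls > 0 && is.null(cp$control))
        stop("penetrance table is identically 1 but controls were requested")
      pos <- position_pairs[[m]]
      if (n_cases > 0) {
        g <- draw_pairs(cp$case, n_cases)
        v[case_rows, pos[1]] <- g[, "ga"]; v[case_rows, pos[2]] <- g[, "gb"]
      }
      if (n_controls > 0) {
        g <- draw_pairs(cp$control, n_controls)
        v[ctrl_rows, pos[1]] <- g[, "ga"]; v[ctrl_rows, pos[2]] <- g[, "gb"]
      }
    }
    noise_cols <- setdiff(seq_len(n_snps), disease_pos)
    v[, noise_cols] <- draw_noise(n, length(noise_cols), noise_maf_range)
    apply_missingness(v, missing_rate)
  })
  structure(list(
    genotypes = genotype_matrix(values),
    phenotype = c(rep(1L, n_cases), rep(0L, n_controls)),
    truth = list(pairs = position_pairs, models = models, seed = as.integer(seed))
  ), class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("sim_dataset: %d cases + %d controls x %d SNPs; %d planted pair(s)\n",
              sum(x$phenotype == 1L), sum(x$phenotype == 0L),
              ncol(x$genotypes$values), length(x$truth$pairs)))
  if (length(x$truth$pairs))
    cat("  planted at:", paste(vapply(x$truth$pairs, function(p)
      sprintf("(%d,%d)", p[1], p[2]), ""), collapse = " "), "\n")
  invisible(x)
}

#' Default disease-locus positions of the hybrid layout
#'
#' The five planted pairs sit at 1-based positions (1,100), (201,300),
#' (401,500), (601,700), (801,900) in a 1000-SNP dataset.
#'
#' @return List of five length-2 integer vectors.
#' @export
hybrid_positions <- function() {
  list(c(1L, 100L), c(201L, 300L), c(401L, 500L), c(601L, 700L), c(801L, 900L))
}

#' Bundle of five pure epistatic models sharing heritability and MAF
#'
#' A hybrid model mixes five pure two-locus models — all with the same
#' heritability and minor-allele frequency — planted as five independent
#' interacting pairs in one dataset. Either pass five ready models or let
#' the zero-marginal constructor build them (one sub-seed per model).
#'
#' @param models optional list of exactly five [penetrance_model()]s with
#'   equal MAFs and (within `1e-6`) equal heritabilities.
#' @param maf,h2 used with [build_zero_marginal_model()] when `models` is
#'   `NULL`.
#' @param seed seed for the constructor searches.
#' @param positions list of five distinct position pairs (default
#'   [hybrid_positions()]).
#' @return An object of class `hybrid_model`.
#' @export
hybrid_model <- function(models = NULL, maf = 0.4, h2 = 0.2, seed = 1L,
                         positions = hybrid_positions()) {
  if (is.null(models)) {
    sub <- with_seed(seed, sample.int(2^31 - 2L, 5L))
    models <- lapply(sub, function(s) build_zero_marginal_model(maf, h2, seed = s))
  }
  if (length(models) != 5L || !all(vapply(models, inherits, TRUE, "penetrance_model")))
    stop("a hybrid model needs exactly five penetrance models")
  mafs <- vapply(models, function(m) c(m$maf_a, m$maf_b), numeric(2))
  if (diff(range(mafs)) > 0)
    stop("all five models must share the same MAF")
  h2s <- vapply(models, heritability, numeric(1))
  if (diff(range(h2s)) > 1e-6)
    stop("all five models must share the same heritability (within 1e-6)")
  if (length(positions) != 5L || anyDuplicated(unlist(positions)))
    stop("positions must be five pairs of distinct indices")
  structure(list(models = models, positions = lapply(positions, as.integer)),
            class = "hybrid_model")
}

#' @export
print.hybrid_model <- function(x, ...) {
  cat(sprintf("hybrid_model: 5 models, maf = %g, h2 = %.4g\n",
              x$models[[1]]$maf_a, heritability(x$models[[1]])))
  invisible(x)
}

#' Simulate a case-control dataset with five planted epistatic pairs
#'
#' Each of the five pairs is simulated independently conditional on the
#' same per-sample disease label (exact class quotas, as in
#' [simulate_pure()]); the remaining SNPs are label-independent HWE noise.
#'
#' @param hybrid a [hybrid_model()].
#' @inheritParams simulate_pure
#' @param n_snps total SNP count, at least the largest planted position
#'   (default 1000).
#' @return A `sim_dataset` whose truth record lists all five pairs.
#' @export
simulate_hybrid <- function(hybrid, n_cases = 200, n_controls = 200,
                            n_snps = 1000, noise_maf_range = c(0.05, 0.5),
                            missing_rate = 0, seed = 1L) {
  stopifnot(inherits(hybrid, "hybrid_model"))
  if (n_snps < max(unlist(hybrid$positions)))
    stop(sprintf("n_snps must be at least %d to hold the planted positions",
                 max(unlist(hybrid$positions))))
  simulate_epistatic(hybrid$models, hybrid$positions, n_cases, n_controls,
                     n_snps, noise_maf_range, missing_rate, seed)
}

#' Simulate a null dataset (no planted interactions)
#'
#' All SNPs are label-independent HWE noise; the truth record has no pairs.
#' Used for type-I-error evaluation of the scan + permutation-threshold
#' pipeline.
#'
#' @inheritParams simulate_pure
#' @return A `sim_dataset` with an empty truth pair list.
#' @export
simulate_null <- function(n_cases = 200, n_controls = 200, n_snps = 1000,
                          noise_maf_range = c(0.05, 0.5), missing_rate = 0,
                          seed = 1L) {
  n <- n_cases + n_controls
  values <- with_seed(seed, {
    apply_missingness(draw_noise(n, n_snps, noise_maf_range), missing_rate)
  })
  structure(list(
    genotypes = genotype_matrix(values),
    phenotype = c(rep(1L, n_cases), rep(0L, n_controls)),
    truth = list(pairs = list(), models = list(), seed = as.integer(seed))
  ), class = "sim_dataset")
}
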