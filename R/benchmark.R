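#' Score one simulated replicate against its planted truth
#'
#' Runs the chosen detection method on a simulated dataset with its own
#' per-dataset permutation threshold and scores the result against the
#' truth record. A planted pair counts as detected only when exactly that
#' unordered pair is reported (strict rule); a lenient "pair-overlap"
#' indicator (some hit shares at least one SNP with the planted pair) is
#' reported alongside. Any reported hit that is not a planted pair is a
#' false positive.
#'
#' Methods:
#' * `"ii"`: pairwise interaction-information scan ([scan_pairs()]); the
#'   threshold is `C * gamma_max` from a `B`-permutation null of the max
#'   pair statistic.
#' * `"mi"`: single-SNP mutual-information scan with its own permutation
#'   threshold; a planted pair is detected when both members are single
#'   hits, and each non-truth single hit counts as one false positive.
#' * `"cmim"`: CMIM selection of `k` features (default
#'   `2 * number of planted pairs`, minimum 2); a planted pair is detected
#'   when both members are selected, and each selected non-truth SNP is a
#'   false positive.
#'
#' @param dataset a `sim_dataset` (must carry a truth record).
#' @param method `"ii"`, `"mi"` or `"cmim"`.
#' @param B permutations for the per-dataset threshold (default 10).
#' @param C threshold multiplier (default 1).
#' @param seed seed for the permutation stream.
#' @param k number of CMIM picks (method `"cmim"` only).
#' @return List with `method`, `detected` / `detected_lenient` (logical per
#'   planted pair), `n_false_positives`, `gamma`, and the raw `hits`.
#' @export
evaluate_replicate <- function(dataset, method = c("ii", "mi", "cmim"),
                               B = 10, C = 1, seed = 1L, k = NULL) {
  method <- match.arg(method)
  if (!inherits(dataset, "sim_dataset") || is.null(dataset$truth))
    stop("dataset must be a sim_dataset with a truth record")
  truth <- lapply(dataset$truth$pairs, function(p) sort(as.integer(p)))
  truth_snps <- unlist(truth)
  packed <- pack_genotypes(dataset$genotypes)
  pheno <- dataset$phenotype
  if (method == "ii") {
    null <- permutation_null(packed, pheno, "ii", B = B, seed = seed)
    thr <- select_threshold(null, "multiplier", C = C)
    scan <- scan_pairs(packed, pheno, gamma = thr$gamma)
    hit_pairs <- mapply(function(a, b) paste(a, b, sep = ":"),
                        scan$hits$position_i, scan$hits$position_j)
    truth_keys <- vapply(truth, function(p) paste(p[1], p[2], sep = ":"), "")
    detected <- truth_keys %in% hit_pairs
    lenient <- vapply(truth, function(p)
      any(scan$hits$position_i %in% p | scan$hits$position_j %in% p), TRUE)
    n_fp <- sum(!hit_pairs %in% truth_keys)
    gamma <- thr$gamma
    hits <- scan$hits
  } else if (method == "mi") {
    null <- permutation_null(packed, pheno, "mi", B = B, seed = seed)
    thr <- select_threshold(null, "multiplier", C = C)
    scan <- scan_singles(packed, pheno, gamma = thr$gamma)
    hit_snps <- scan$hits$position
    detected <- vapply(truth, function(p) all(p %in% hit_snps), TRUE)
    lenient <- vapply(truth, function(p) any(p %in% hit_snps), TRUE)
    n_fp <- sum(!hit_snps %in% truth_snps)
    gamma <- thr$gamma
    hits <- scan$hits
  } else {
    if (is.null(k)) k <- max(2L, 2L * length(truth))
    sel <- as.integer(cmim_select(packed, pheno, k = k, fast = TRUE))
    detected <- vapply(truth, function(p) all(p %in% sel), TRUE)
    lenient <- vapply(truth, function(p) any(p %in% sel), TRUE)
    n_fp <- sum(!sel %in% truth_snps)
    gamma <- NA_real_
    hits <- data.frame(position = sel)
  }
  if (length(truth) == 0L) detected <- lenient <- logical(0)
  list(method = method, detected = detected, detected_lenient = lenient,
       n_false_positives = n_fp, gamma = gamma, hits = hits)
}

#' Benchmark configuration
#'
#' @param generator list describing the simulated world: `kind` one of
#'   `"hybrid"` (five planted zero-marginal pairs at the canonical
#'   positions), `"pure"` (one planted pair at `positions`, default
#'   `c(1, 10)`), or `"null"` (no planted pairs); plus `maf`, `h2`,
#'   `n_cases`, `n_controls`, `n_snps` (defaults 0.4, 0.2, 200, 200, 1000)
#'   and optionally `model` (a ready [penetrance_model()] for
#'   `kind = "pure"`).
#' @param R number of replicate datasets.
#' @param method detection method passed to [evaluate_replicate()].
#' @param B,C per-replicate permutation threshold policy.
#' @param seed master seed; replicate and permutation sub-seeds are derived
#'   from it, so the whole report is reproducible.
#' @param k CMIM pick count (method `"cmim"`).
#' @return A `benchmark_config` list.
#' @export
benchmark_config <- function(generator = list(kind = "hybrid"), R = 10,
                             method = "ii", B = 10, C = 1, seed = 1L, k = NULL) {
  gen <- utils::modifyList(
    list(kind = "hybrid", maf = 0.4, h2 = 0.2, n_cases = 200, n_controls = 200,
         n_snps = 1000, positions = c(1, 10), model = NULL),
    generator)
  if (!gen$kind %in% c("hybrid", "pure", "null"))
    stop("generator kind must be 'hybrid', 'pure' or 'null'")
  if (R < 1) stop("R must be >= 1")
  structure(list(generator = gen, R = as.integer(R), method = method,
                 B = as.integer(B), C = C, seed = as.integer(seed), k = k),
            class = "benchmark_config")
}

#' Power / false-positive benchmark over simulated replicates
#'
#' Reproduces the artificial-data study design at configurable scale: `R`
#' replicate datasets are simulated from the configured generator, each
#' scanned with a threshold re-derived from that replicate's own
#' permutations, and scored against the planted truth. Power is reported
#' both per pair (detected pairs over all planted pairs) and per dataset
#' (replicates where every planted pair was detected), with the lenient
#' pair-overlap variant of each.
#'
#' @param config a [benchmark_config()].
#' @return An object of class `benchmark_report`: list with `config`,
#'   `power_per_pair`, `power_per_dataset`, `power_per_pair_lenient`,
#'   `power_per_dataset_lenient`, `total_false_positives`,
#'   `mean_false_positives`, `frac_replicates_with_fp`, and a per-replicate
#'   `detail` data frame.
#' @export
run_benchmark <- function(config) {
  stopifnot(inherits(config, "benchmark_config"))
  gen <- config$generator
  seeds <- with_seed(config$seed, {
    list(model = sample.int(2^31 - 2L, 1L),
         sim = sample.int(2^31 - 2L, config$R),
         perm = sample.int(2^31 - 2L, config$R))
  })
  hm <- if (gen$kind == "hybrid") {
    hybrid_model(maf = gen$maf, h2 = gen$h2, seed = seeds$model)
  } else NULL
  pure_model <- if (gen$kind == "pure") {
    if (!is.null(gen$model)) gen$model
    else build_zero_marginal_model(gen$maf, gen$h2, seed = seeds$model)
  } else NULL
  rows <- vector("list", config$R)
  n_pairs_planted <- switch(gen$kind, hybrid = 5L, pure = 1L, null = 0L)
  for (r in seq_len(config$R)) {
    dataset <- switch(gen$kind,
      hybrid = simulate_hybrid(hm, gen$n_cases, gen$n_controls, gen$n_snps,
                               seed = seeds$sim[r]),
      pure = simulate_pure(pure_model, gen$n_cases, gen$n_controls, gen$n_snps,
                           positions = gen$positions, seed = seeds$sim[r]),
      null = simulate_null(gen$n_cases, gen$n_controls, gen$n_snps,
                           seed = seeds$sim[r]))
    ev <- tryCatch(
      evaluate_replicate(dataset, config$method, B = config$B, C = config$C,
                         seed = seeds$perm[r], k = config$k),
      error = function(e) stop(sprintf("replicate %d failed: %s", r, conditionMessage(e))))
    rows[[r]] <- data.frame(replicate = r,
                            sim_seed = seeds$sim[r],
                            perm_seed = seeds$perm[r],
                            n_detected = sum(ev$detected),
                            n_detected_lenient = sum(ev$detected_lenient),
                            n_planted = n_pairs_planted,
                            n_false_positives = ev$n_false_positives,
                            gamma = ev$gamma)
  }
  detail <- do.call(rbind, rows)
  denom <- max(1L, config$R * n_pairs_planted)
  structure(list(
    config = config,
    power_per_pair = sum(detail$n_detected) / denom,
    power_per_dataset = mean(detail$n_detected == n_pairs_planted),
    power_per_pair_lenient = sum(detail$n_detected_lenient) / denom,
    power_per_dataset_lenient = mean(detail$n_detected_lenient == n_pairs_planted),
    total_false_positives = sum(detail$n_false_positives),
    mean_false_positives = mean(detail$n_false_positives),
    frac_replicates_with_fp = mean(detail$n_false_positives > 0),
    detail = detail
  ), class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  g <- x$config$generator
  cat(sprintf("benchmark_report: %s generator, method %s, R = %d, B = %d, C = %g\n",
              g$kind, x$config$method, x$config$R, x$config$B, x$config$C))
  if (g$kind != "null")
    cat(sprintf("  power per pair = %.3f (lenient %.3f); per dataset = %.3f\n",
                x$power_per_pair, x$power_per_pair_lenient, x$power_per_dataset))
  cat(sprintf("  false positives: total %d, mean %.3f/replicate, %d%% of replicates affected\n",
              x$total_false_positives, x$mean_false_positives,
              round(100 * x$frac_replicates_with_fp)))
  invisible(x)
}
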