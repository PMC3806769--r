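#' Exhaustive pairwise interaction-information scan
#'
#' Evaluates the interaction information `I(Xi; Xj; C)` for all `C(p, 2)`
#' unordered SNP pairs against the phenotype, and reports the pairs whose
#' value strictly exceeds the threshold `gamma`. The scan is exhaustive and
#' deterministic: no pre-filtering of SNPs is applied, and rerunning on the
#' same input is bit-identical. Pair values are invariant to sample order
#' and to swapping the two SNPs.
#'
#' @param packed a `packed_genotypes` object (see [pack_genotypes()]).
#' @param pheno 0/1 phenotype vector; both classes must be present.
#' @param gamma threshold in bits; hits require `value > gamma`. The default
#'   `-Inf` reports every pair. Typically derived from a permutation null
#'   via [select_threshold()].
#' @param keep_values if `TRUE`, the full vector of `C(p, 2)` values is
#'   retained in the result (element `values`, pair order
#'   (1,2), (1,3), ..., (p-1,p)).
#' @return An object of class `epi_scan`: list with `kind` (`"ii"`),
#'   `gamma`, `hits` (data frame `snp_i`, `snp_j`, `position_i`,
#'   `position_j`, `ii_bits`, `pvalue`, sorted by decreasing value),
#'   `max_pair` (1-based positions), `max_value`, `n_pairs` and optionally
#'   `values`.
#' @examples
#' d <- simulate_pure(canonical_model("xor"), n_cases = 50, n_controls = 50,
#'                    n_snps = 10, positions = c(1, 2), seed = 1)
#' s <- scan_pairs(pack_genotypes(d$genotypes), d$phenotype, gamma = 0.1)
#' s$hits
#' @export
scan_pairs <- function(packed, pheno, gamma = -Inf, keep_values = FALSE) {
  stopifnot(inherits(packed, "packed_genotypes"))
  if (packed$n_snps < 2L) stop("pair scan needs at least 2 SNPs")
  pheno <- as_phenotype(pheno, packed$n_samples)
  values <- cpp_pair_scan_values(packed$hi, packed$lo, packed$n_samples, pheno)
  p <- packed$n_snps
  idx_i <- rep.int(seq_len(p - 1L), (p - 1L):1L)
  idx_j <- sequence((p - 1L):1L) + idx_i
  best <- which.max(values)  # first maximum = lexicographically smallest pair
  sel <- which(values > gamma)
  sel <- sel[order(values[sel], idx_i[sel], idx_j[sel],
                   decreasing = c(TRUE, FALSE, FALSE), method = "radix")]
  hits <- data.frame(snp_i = packed$snp_ids[idx_i[sel]],
                     snp_j = packed$snp_ids[idx_j[sel]],
                     position_i = idx_i[sel],
                     position_j = idx_j[sel],
                     ii_bits = values[sel],
                     pvalue = rep(NA_real_, length(sel)),
                     stringsAsFactors = FALSE)
  res <- list(kind = "ii", gamma = gamma, hits = hits,
              max_pair = c(idx_i[best], idx_j[best]),
              max_value = values[best],
              n_pairs = length(values))
  if (keep_values) res$values <- values
  structure(res, class = "epi_scan")
}

#' Single-SNP mutual-information scan
#'
#' Evaluates `I(Xk; C)` for every SNP and reports those strictly above
#' `gamma`. This is the marginal-association counterpart of [scan_pairs()]:
#' SNPs in a pure (zero-marginal) epistatic pair do not appear here at any
#' threshold above the permutation null.
#'
#' @inheritParams scan_pairs
#' @return An `epi_scan` object with `kind = "mi"`, `hits` columns `snp`,
#'   `position`, `mi_bits`, `pvalue`, plus `max_snp` (position),
#'   `max_value`, and optionally `values` (per-SNP MI).
#' @export
scan_singles <- function(packed, pheno, gamma = -Inf, keep_values = FALSE) {
  stopifnot(inherits(packed, "packed_genotypes"))
  pheno <- as_phenotype(pheno, packed$n_samples)
  values <- cpp_single_scan_values(packed$hi, packed$lo, packed$n_samples, pheno)
  best <- which.max(values)
  sel <- which(values > gamma)
  sel <- sel[order(values[sel], sel, decreasing = c(TRUE, FALSE), method = "radix")]
  hits <- data.frame(snp = packed$snp_ids[sel],
                     position = sel,
                     mi_bits = values[sel],
                     pvalue = rep(NA_real_, length(sel)),
                     stringsAsFactors = FALSE)
  res <- list(kind = "mi", gamma = gamma, hits = hits,
              max_snp = best, max_value = values[best],
              n_pairs = length(values))
  if (keep_values) res$values <- values
  structure(res, class = "epi_scan")
}

#' @export
print.epi_scan <- function(x, ...) {
  what <- if (x$kind == "ii") "pairwise interaction-information" else "single-SNP mutual-information"
  cat(sprintf("epi_scan: %s scan\n", what))
  cat(sprintf("  threshold gamma = %g bits; %d hit(s); max = %.6g bits\n",
              x$gamma, nrow(x$hits), x$max_value))
  if (x$kind == "ii")
    cat(sprintf("  max pair: positions (%d, %d)\n", x$max_pair[1], x$max_pair[2]))
  invisible(x)
}

#' Maximum scan statistic
#'
#' Returns the maximum interaction information over all pairs
#' (`kind = "ii"`) or the maximum single-SNP mutual information
#' (`kind = "mi"`) without materializing all values; this is the statistic
#' recorded per permutation by [permutation_null()]. Ties are broken toward
#' the lexicographically smallest pair (or smallest index).
#'
#' @inheritParams scan_pairs
#' @param kind `"ii"` (pairwise) or `"mi"` (single-SNP).
#' @return A list with `value` (bits) and either `pair` (two 1-based
#'   positions) or `snp` (one position).
#' @export
max_statistic <- function(packed, pheno, kind = c("ii", "mi")) {
  kind <- match.arg(kind)
  stopifnot(inherits(packed, "packed_genotypes"))
  pheno <- as_phenotype(pheno, packed$n_samples)
  if (kind == "ii") {
    if (packed$n_snps < 2L) stop("pair scan needs at least 2 SNPs")
    m <- cpp_pair_max(packed$hi, packed$lo, packed$n_samples, pheno)
    list(pair = c(m$i, m$j), value = m$value)
  } else {
    v <- cpp_single_scan_values(packed$hi, packed$lo, packed$n_samples, pheno)
    list(snp = which.max(v), value = max(v))
  }
}

#' Attach family-wise p-values to scan hits
#'
#' Fills the `pvalue` column of an `epi_scan` using the permutation null of
#' the matching statistic (see [familywise_pvalue()]).
#'
#' @param scan an `epi_scan`.
#' @param null a `perm_null` from [permutation_null()] with the same `kind`.
#' @return The scan with `pvalue` filled in.
#' @export
attach_pvalues <- function(scan, null) {
  stopifnot(inherits(scan, "epi_scan"), inherits(null, "perm_null"))
  if (!identical(scan$kind, null$kind))
    stop(sprintf("scan kind '%s' does not match null kind '%s'", scan$kind, null$kind))
  vals <- if (scan$kind == "ii") scan$hits$ii_bits else scan$hits$mi_bits
  scan$hits$pvalue <- familywise_pvalue(vals, null)
  scan
}

#' Write scan hits as TSV
#'
#' @param scan an `epi_scan`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(scan, path) {
  stopifnot(inherits(scan, "epi_scan"))
  utils::write.table(scan$hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export hits as a gene-gene interaction graph
#'
#' Maps each SNP of each pairwise hit to its gene (falling back to the SNP
#' id when unmapped) and builds a graph with one node per gene and one edge
#' per hit; repeated gene pairs accumulate into the edge `weight`. Hits
#' whose two SNPs map to the same gene become self-loops, which are
#' retained.
#'
#' @param hits data frame with columns `snp_i` and `snp_j` (e.g.
#'   `scan$hits` from [scan_pairs()]).
#' @param snp_to_gene optional mapping: either a named character vector
#'   (names = SNP ids) or a data frame with columns `snp`, `gene`. May be
#'   partial; unmapped SNPs are reported via `message()`.
#' @return An [igraph::graph] with edge attribute `weight` (hit
#'   multiplicity).
#' @seealso [write_gene_graph()]
#' @export
export_gene_graph <- function(hits, snp_to_gene = NULL) {
  stopifnot(is.data.frame(hits), all(c("snp_i", "snp_j") %in% names(hits)))
  map <- character(0)
  if (!is.null(snp_to_gene)) {
    if (is.data.frame(snp_to_gene)) {
      stopifnot(all(c("snp", "gene") %in% names(snp_to_gene)))
      map <- stats::setNames(as.character(snp_to_gene$gene), snp_to_gene$snp)
    } else {
      map <- snp_to_gene
    }
  }
  gene_of <- function(snp) {
    g <- unname(map[snp])
    miss <- is.na(g) | !nzchar(g)
    g[miss] <- snp[miss]
    g
  }
  if (nrow(hits)) {
    unmapped <- setdiff(unique(c(hits$snp_i, hits$snp_j)), names(map))
    if (length(unmapped) && length(map))
      message(sprintf("export_gene_graph: %d SNP(s) without gene annotation kept under their SNP id: %s",
                      length(unmapped), paste(unmapped, collapse = ", ")))
    edges <- data.frame(from = gene_of(as.character(hits$snp_i)),
                        to = gene_of(as.character(hits$snp_j)),
                        stringsAsFactors = FALSE)
    key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to), sep = "\r")
    agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
    parts <- strsplit(agg$key, "\r", fixed = TRUE)
    el <- data.frame(from = vapply(parts, `[`, "", 1),
                     to = vapply(parts, `[`, "", 2),
                     weight = agg$Freq, stringsAsFactors = FALSE)
    igraph::graph_from_data_frame(el, directed = FALSE)
  } else {
    igraph::make_empty_graph(0, directed = FALSE)
  }
}

#' Write a gene graph as edge-list TSV and GraphML
#'
#' @param graph an igraph object from [export_gene_graph()].
#' @param edge_list_path path for the TSV edge list (`gene_a`, `gene_b`,
#'   `weight`); `NULL` to skip.
#' @param graphml_path path for the GraphML export; `NULL` to skip.
#' @return `invisible(NULL)`.
#' @export
write_gene_graph <- function(graph, edge_list_path = NULL, graphml_path = NULL) {
  if (!is.null(edge_list_path)) {
    el <- igraph::as_data_frame(graph, what = "edges")
    names(el)[1:2] <- c("gene_a", "gene_b")
    if (!"weight" %in% names(el)) el$weight <- rep(1L, nrow(el))
    utils::write.table(el, edge_list_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(graphml_path))
    igraph::write_graph(graph, graphml_path, format = "graphml")
  invisible(NULL)
}
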