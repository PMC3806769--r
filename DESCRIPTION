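Package: epii
Title: Epistasis Detection in Case-Control Data via Interaction Information
Version: 0.1.0
Authors@R:
    person("epii", "developers", email = "epii@example.org", role = c("aut", "cre"))
Description: Exhaustive pairwise scanning of case-control genotype data for
    epistatic (synergistic) SNP pairs using the three-way interaction
    information statistic, computed from 2-bit packed genotypes with
    popcount-based contingency counting. Includes a single-SNP mutual
    information scan, permutation-based family-wise thresholds and p-values,
    the greedy conditional-mutual-information-maximization (CMIM) feature
    selection baseline in standard and fast lazy variants, a penetrance-table
    simulator for planting pure and hybrid two-locus interactions with no
    marginal effects, and a power / false-positive benchmark harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
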