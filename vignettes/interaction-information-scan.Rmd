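---
title: "Detecting zero-marginal epistasis with an exhaustive interaction-information scan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting zero-marginal epistasis with an exhaustive interaction-information scan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epii)
```

## The problem

Genome-wide association studies overwhelmingly test one SNP at a time.
That is blind, by construction, to *pure epistasis*: two loci whose joint
genotype strongly predicts disease while each locus alone carries no
information at all. Classifiers and greedy feature-selection methods fail
on the same inputs and for the same reason — every per-feature signal they
could seed on is zero. `epii` takes the direct route: evaluate a synergy
statistic on **all** pairs, with no marginal pre-filtering, and control the
resulting multiple-testing burden with a permutation max-statistic
threshold.

## Model and statistic

Genotypes are categorical with four states: 0/1/2 copies of the minor
allele plus an explicit missing state (code 3). Missing genotypes are a
*scored category*, never dropped: pairwise-complete deletion would make a
pair's statistic depend on the partner SNP's missingness pattern, while a
fourth category keeps every estimator a function of the full sample.

For a pair $(X_1, X_2)$ and phenotype $C$, the scan statistic is the
interaction information

$$I(X_1;X_2;C) = \hat I(C;X_1\mid X_2) - I(C;X_1),$$

estimated with plug-in (maximum-likelihood) probabilities in base 2
(bits). The conditional-MI-difference form and the joint-minus-marginals
form $I(\{X_1,X_2\};C) - I(X_1;C) - I(X_2;C)$ are algebraically equal; the
package computes the equivalent seven-joint-entropy expansion and the test
suite asserts all forms agree to 1e-12 and that the statistic is symmetric
in its three arguments. Positive values are synergy (XOR with uniform
independent inputs: exactly +1 bit), negative values redundancy (a
duplicated informative SNP: exactly $-H(C)$), independence gives 0.

No small-sample bias correction (Miller–Madow, pseudocounts, ...) is
applied. The plug-in estimator is biased upward on sparse tables, but the
decision rule compares the observed statistic with a permutation null
computed by *the same estimator on the same table sizes*, which absorbs
the bias. This is why thresholds must come from permutations rather than
from an asymptotic reference.

## Thresholding and inference

For $b = 1,\dots,B$ the phenotype labels are uniformly permuted (genotypes
untouched, preserving inter-SNP structure) and the maximum pair statistic
over all $\binom p2$ pairs is recorded. Two threshold rules:

* **strictly-above-max** — $\gamma = \gamma_{\max}$, the largest permuted
  maximum; hits require value $> \gamma$, so each carries family-wise
  p-value below $1/(B+1)$ (0.001 at $B = 1000$).
* **multiplier** — $\gamma = C\,\gamma_{\max}$ with $C \ge 1$; the default
  $C = 1$ is used because the constant actually used in the original
  artificial-data experiments is not recoverable; it is exposed as a knob.

Reported p-values use the add-one estimator $(1 + \#\{m_b \ge
\text{obs}\})/(B+1)$: conservative and never zero. All $B$ permutations are
drawn up front from one seeded stream, so the null is reproducible from
its seed and independent of how the pair space is partitioned during
scanning.

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `gamma` | hit threshold, bits | from permutations | user-defined in principle; permutation-derived in practice |
| `B` | permutations | 10 (benchmarks) / 1000 (confirmatory) | $1/(B+1)$ family-wise bound; B=10 is the fast artificial-data setting |
| `C` | threshold multiplier | 1.0 | original value unrecoverable; 1.0 is the least arbitrary conservative choice |
| `maf` | minor-allele frequency of disease loci | 0.4 | benchmark grid spans 0.2–0.4 |
| `h2` | heritability of the planted model | 0.2 | benchmark grid spans 0.025–0.4 |
| `noise_maf_range` | MAF of noise SNPs | U(0.05, 0.5) | unspecified upstream; avoids monomorphic columns |
| `k` (CMIM) | features selected | — | 2 × planted pairs in benchmark scoring |

## The simulator: what it emulates, what it does not

`simulate_pure()` / `simulate_hybrid()` emulate the classic two-locus
benchmark design: 200 cases, 200 controls, 1000 SNPs, one planted pair at
positions (1, 10) or five pairs at (1,100), (201,300), (401,500),
(601,700), (801,900), each drawn from a penetrance table with **no
marginal effects**. Sampling is retrospective and exact: case genotype
pairs come from $P(g_a,g_b\mid\text{case}) \propto P(i)P(j)f_{ij}$,
controls from the complement — no rejection loop, class quotas met
exactly. Noise SNPs are Hardy–Weinberg draws independent of the label.

The original 60-model penetrance-table collection is not published in our
source, so `build_zero_marginal_model()` *constructs* a synthetic stand-in
for any (MAF, h²): it searches, under a fixed seed, the exact null space
of the marginal-penetrance constraints for a deviation direction,
normalizes it to unit penetrance variance, and scans a prevalence grid for
a scale at which all nine entries stay in [0, 1]. The result satisfies
max marginal deviation < 1e-8 and |h² − target| < 1e-6 by construction
(observed: ~1e-16). Published 3×3 tables can be dropped in via
`read_penetrance_csv()`. Heritability follows the variance-explained
convention of the MDR simulation literature, $h^2 = \sum_{ij}
P_iP_j(f_{ij}-K)^2 / K(1-K)$, stated explicitly because the source leaves
it undefined.

What the simulator deliberately does **not** model: linkage
disequilibrium, population structure, covariates, genotyping-error
structure, quantitative traits. A green benchmark therefore establishes
statistical power against *independent-noise* backgrounds only; on real
data, LD will smear hits across correlated SNPs and the per-SNP-pair
reporting (we do not deduplicate to gene pairs) will show that directly.

## Numerical choices

* Base-2 logarithms everywhere; $0\log 0 := 0$.
* Contingency counting via 2-bit planes + popcount; planes are zero-padded
  to 64-sample words and padding is masked once at mask-build time. Oracle
  equivalence with a per-sample tally is tested across word boundaries
  (n = 63, 64, 65).
* Entropies are computed from an $n\log_2 n$ lookup table per scan, so a
  pair costs 16 popcount cells plus table sums.
* Hits require **strict** inequality over γ, matching the
  strictly-above-the-permutation-maximum construction.
* `max_statistic` ties break toward the lexicographically smallest pair;
  CMIM ties toward the lowest index (both variants, so their equivalence
  is well-defined — the source is silent on ties).
* Degenerate inputs are rejected early: single-class phenotypes, empty
  count tables, `i == j` pairs, all-zero penetrance with cases requested.

## CMIM baseline

Both the standard and the lazy ("fast") CMIM of Fleuret are implemented
over the 4-category genotype variables (not Fleuret's original binarized
features — a deliberate deviation for consistency with the rest of the
package). The fast variant exploits that scores only decrease: a stale
score is an upper bound and is refreshed only while it still beats the
running best. The two variants return identical sequences (tested on 200
random datasets and on all-tied inputs), and the fast one provably
evaluates no more conditional MIs. On zero-marginal pairs the first greedy
pick lands on noise and conditioning on noise never resurrects the pair —
the acceptance suite checks that CMIM misses the planted pair in the
majority of seeded replicates while the exhaustive scan recovers it.

## Benchmark harness

`run_benchmark()` re-derives the threshold from each replicate's own
permutations, then scores hits against the truth record. Detection is
strict — exactly the planted unordered pair — because the upstream power
definition is not spelled out; a lenient pair-overlap column (any hit
sharing ≥ 1 SNP with the planted pair) is emitted alongside. Power is
reported both per pair and per dataset for the same reason. Under the
null generator, the fraction of replicates with any hit matches the
$1/(B+1)$ family-wise expectation (tested at B = 99 over 200 replicates).

## Known limitations

* Pair scans only; no triplet or higher-order search.
* No adaptive early stopping of permutations: the full $B$ scans are run.
* Plug-in estimation makes individual statistic *values* biased on sparse
  tables; only permutation-calibrated decisions are meaningful at small n.
* The zero-marginal constructor targets both loci at the same MAF, as in
  the benchmark grids; unequal-MAF zero-marginal tables would need the
  same null-space construction with asymmetric weights.
* Real-data practicalities (VCF/.bed input, QC, LD pruning) are out of
  scope; inputs are the simple TSV dialect or PLINK `.raw` text.
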