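// Bit-packed genotype kernels.
//
// Genotypes are stored as two bit planes per SNP (high bit, low bit), one
// column per SNP, padded with zero bits to a multiple of 64 samples so each
// column can be walked as uint64_t words.  Code = 2*high + low, i.e.
// 0/1/2 = minor-allele copies, 3 = missing.  All contingency counting is
// done with AND + popcount against per-genotype indicator masks; padding
// bits are masked out once when the indicator masks are built.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline int popcnt(uint64_t x) { return __builtin_popcountll(x); }
static inline int words_for(int n) { return (n + 63) / 64; }

// ---------------------------------------------------------------------------
// packing

// [[Rcpp::export]]
List cpp_pack(IntegerMatrix geno) {
  const int n = geno.nrow(), p = geno.ncol();
  const int w = words_for(n), bytes = w * 8;
  RawMatrix hi(bytes, p), lo(bytes, p);
  std::memset(RAW(hi), 0, (size_t)bytes * p);
  std::memset(RAW(lo), 0, (size_t)bytes * p);
  uint64_t* H = reinterpret_cast<uint64_t*>(RAW(hi));
  uint64_t* L = reinterpret_cast<uint64_t*>(RAW(lo));
  for (int k = 0; k < p; ++k) {
    uint64_t* hc = H + (size_t)w * k;
    uint64_t* lc = L + (size_t)w * k;
    for (int s = 0; s < n; ++s) {
      const int v = geno(s, k);
      if (v == NA_INTEGER || v < 0 || v > 3)
        stop("invalid genotype code at sample %d, SNP %d: codes must be 0, 1, 2 or 3",
             s + 1, k + 1);
      if (v & 2) hc[s >> 6] |= (uint64_t)1 << (s & 63);
      if (v & 1) lc[s >> 6] |= (uint64_t)1 << (s & 63);
    }
  }
  return List::create(_["hi"] = hi, _["lo"] = lo);
}

// [[Rcpp::export]]
IntegerMatrix cpp_unpack(RawMatrix hi, RawMatrix lo, int n) {
  const int p = hi.ncol(), w = hi.nrow() / 8;
  const uint64_t* H = reinterpret_cast<const uint64_t*>(RAW(hi));
  const uint64_t* L = reinterpret_cast<const uint64_t*>(RAW(lo));
  IntegerMatrix out(n, p);
  for (int k = 0; k < p; ++k) {
    const uint64_t* hc = H + (size_t)w * k;
    const uint64_t* lc = L + (size_t)w * k;
    for (int s = 0; s < n; ++s) {
      const int h = (hc[s >> 6] >> (s & 63)) & 1;
      const int l = (lc[s >> 6] >> (s & 63)) & 1;
      out(s, k) = 2 * h + l;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// scan context: indicator masks, xlogx table, per-SNP marginal sums

namespace {

struct ScanCtx {
  int n, p, w;
  std::vector<uint64_t> M;     // p * 4 * w genotype indicator masks
  std::vector<int> gcount;     // p * 4 genotype counts (label-independent)
  std::vector<double> T;       // T[k] = k * log2(k)
  std::vector<double> S1;      // per-SNP sum of T over the 4 genotype counts
  // label-dependent parts (refreshed per permutation):
  std::vector<uint64_t> C1;    // case mask
  std::vector<double> S1C;     // per-SNP sum of T over 4x2 genotype-class counts
  double SC;                   // sum of T over the two class counts
  double log2n;
};

void ctx_init(ScanCtx& c, RawMatrix hi, RawMatrix lo, int n) {
  c.n = n;
  c.p = hi.ncol();
  c.w = hi.nrow() / 8;
  const uint64_t* H = reinterpret_cast<const uint64_t*>(RAW(hi));
  const uint64_t* L = reinterpret_cast<const uint64_t*>(RAW(lo));
  const uint64_t pad = (n & 63) ? (((uint64_t)1 << (n & 63)) - 1) : ~(uint64_t)0;
  c.M.assign((size_t)c.p * 4 * c.w, 0);
  c.gcount.assign((size_t)c.p * 4, 0);
  for (int k = 0; k < c.p; ++k) {
    const uint64_t* hc = H + (size_t)c.w * k;
    const uint64_t* lc = L + (size_t)c.w * k;
    uint64_t* m = &c.M[(size_t)k * 4 * c.w];
    for (int j = 0; j < c.w; ++j) {
      const uint64_t h = hc[j], l = lc[j];
      const uint64_t keep = (j == c.w - 1) ? pad : ~(uint64_t)0;
      m[0 * c.w + j] = ~h & ~l & keep;
      m[1 * c.w + j] = ~h &  l & keep;
      m[2 * c.w + j] =  h & ~l & keep;
      m[3 * c.w + j] =  h &  l & keep;
    }
    for (int g = 0; g < 4; ++g) {
      int cnt = 0;
      for (int j = 0; j < c.w; ++j) cnt += popcnt(m[g * c.w + j]);
      c.gcount[(size_t)k * 4 + g] = cnt;
    }
  }
  c.T.resize(n + 1);
  c.T[0] = 0.0;
  for (int k = 1; k <= n; ++k) c.T[k] = (double)k * std::log2((double)k);
  c.S1.assign(c.p, 0.0);
  for (int k = 0; k < c.p; ++k)
    for (int g = 0; g < 4; ++g) c.S1[k] += c.T[c.gcount[(size_t)k * 4 + g]];
  c.log2n = std::log2((double)n);
}

// refresh the label-dependent sums for a given 0/1 label vector
void ctx_set_labels(ScanCtx& c, const int* lab) {
  c.C1.assign(c.w, 0);
  int ncase = 0;
  for (int s = 0; s < c.n; ++s)
    if (lab[s] == 1) { c.C1[s >> 6] |= (uint64_t)1 << (s & 63); ++ncase; }
  c.SC = c.T[ncase] + c.T[c.n - ncase];
  c.S1C.assign(c.p, 0.0);
  for (int k = 0; k < c.p; ++k) {
    const uint64_t* m = &c.M[(size_t)k * 4 * c.w];
    double s = 0.0;
    for (int g = 0; g < 4; ++g) {
      const int tot = c.gcount[(size_t)k * 4 + g];
      if (tot == 0) continue;
      int cas = 0;
      for (int j = 0; j < c.w; ++j) cas += popcnt(m[g * c.w + j] & c.C1[j]);
      s += c.T[cas] + c.T[tot - cas];
    }
    c.S1C[k] = s;
  }
}

// interaction information I(Xi; Xj; C) in bits for one SNP pair, via
// II = H(Xi,C) + H(Xj,C) + H(Xi,Xj) - H(Xi) - H(Xj) - H(C) - H(Xi,Xj,C)
double pair_ii(const ScanCtx& c, int i, int j) {
  const uint64_t* mi = &c.M[(size_t)i * 4 * c.w];
  const uint64_t* mj = &c.M[(size_t)j * 4 * c.w];
  double S12 = 0.0, S123 = 0.0;
  for (int g1 = 0; g1 < 4; ++g1) {
    if (c.gcount[(size_t)i * 4 + g1] == 0) continue;
    const uint64_t* a = mi + g1 * c.w;
    for (int g2 = 0; g2 < 4; ++g2) {
      if (c.gcount[(size_t)j * 4 + g2] == 0) continue;
      const uint64_t* b = mj + g2 * c.w;
      int tot = 0, cas = 0;
      for (int t = 0; t < c.w; ++t) {
        const uint64_t ab = a[t] & b[t];
        tot += popcnt(ab);
        cas += popcnt(ab & c.C1[t]);
      }
      S12 += c.T[tot];
      S123 += c.T[cas] + c.T[tot - cas];
    }
  }
  return (c.S1[i] + c.S1[j] + c.SC + S123 - c.S1C[i] - c.S1C[j] - S12) / c.n
         - c.log2n;
}

// mutual information I(Xk; C) in bits
double single_mi(const ScanCtx& c, int k) {
  return c.log2n + (c.S1C[k] - c.S1[k] - c.SC) / c.n;
}

}  // namespace

// ---------------------------------------------------------------------------
// contingency tables

// counts[g_i + 4*g_j + 16*c] for one pair (0-based SNP indices)
// [[Rcpp::export]]
IntegerVector cpp_pair_counts(RawMatrix hi, RawMatrix lo, int n, int i, int j,
                              IntegerVector labels) {
  ScanCtx c;
  ctx_init(c, hi, lo, n);
  ctx_set_labels(c, INTEGER(labels));
  IntegerVector out(32);
  const uint64_t* mi = &c.M[(size_t)i * 4 * c.w];
  const uint64_t* mj = &c.M[(size_t)j * 4 * c.w];
  for (int g1 = 0; g1 < 4; ++g1)
    for (int g2 = 0; g2 < 4; ++g2) {
      int tot = 0, cas = 0;
      for (int t = 0; t < c.w; ++t) {
        const uint64_t ab = mi[g1 * c.w + t] & mj[g2 * c.w + t];
        tot += popcnt(ab);
        cas += popcnt(ab & c.C1[t]);
      }
      out[g1 + 4 * g2 + 16 * 0] = tot - cas;
      out[g1 + 4 * g2 + 16 * 1] = cas;
    }
  return out;
}

// counts[g + 4*c] for one SNP
// [[Rcpp::export]]
IntegerVector cpp_single_counts(RawMatrix hi, RawMatrix lo, int n, int i,
                                IntegerVector labels) {
  ScanCtx c;
  ctx_init(c, hi, lo, n);
  ctx_set_labels(c, INTEGER(labels));
  IntegerVector out(8);
  const uint64_t* m = &c.M[(size_t)i * 4 * c.w];
  for (int g = 0; g < 4; ++g) {
    const int tot = c.gcount[(size_t)i * 4 + g];
    int cas = 0;
    for (int t = 0; t < c.w; ++t) cas += popcnt(m[g * c.w + t] & c.C1[t]);
    out[g + 4 * 0] = tot - cas;
    out[g + 4 * 1] = cas;
  }
  return out;
}

// ---------------------------------------------------------------------------
// scans

// all C(p,2) interaction-information values, pair order (1,2),(1,3),...,(p-1,p)
// [[Rcpp::export]]
NumericVector cpp_pair_scan_values(RawMatrix hi, RawMatrix lo, int n,
                                   IntegerVector labels) {
  ScanCtx c;
  ctx_init(c, hi, lo, n);
  ctx_set_labels(c, INTEGER(labels));
  const R_xlen_t npair = (R_xlen_t)c.p * (c.p - 1) / 2;
  NumericVector out(npair);
  R_xlen_t q = 0;
  for (int i = 0; i < c.p - 1; ++i)
    for (int j = i + 1; j < c.p; ++j) out[q++] = pair_ii(c, i, j);
  return out;
}

// max interaction information over all pairs; ties to lexicographically
// smallest (i, j); returns 1-based indices
// [[Rcpp::export]]
List cpp_pair_max(RawMatrix hi, RawMatrix lo, int n, IntegerVector labels) {
  ScanCtx c;
  ctx_init(c, hi, lo, n);
  ctx_set_labels(c, INTEGER(labels));
  double best = R_NegInf;
  int bi = 0, bj = 1;
  for (int i = 0; i < c.p - 1; ++i)
    for (int j = i + 1; j < c.p; ++j) {
      const double v = pair_ii(c, i, j);
      if (v > best) { best = v; bi = i; bj = j; }
    }
  return List::create(_["i"] = bi + 1, _["j"] = bj + 1, _["value"] = best);
}

// per-SNP mutual information with the phenotype
// [[Rcpp::export]]
NumericVector cpp_single_scan_values(RawMatrix hi, RawMatrix lo, int n,
                                     IntegerVector labels) {
  ScanCtx c;
  ctx_init(c, hi, lo, n);
  ctx_set_labels(c, INTEGER(labels));
  NumericVector out(c.p);
  for (int k = 0; k < c.p; ++k) out[k] = single_mi(c, k);
  return out;
}

// max pair statistic under each column of a label matrix (n x B);
// used for permutation nulls so masks are built once
// [[Rcpp::export]]
NumericVector cpp_perm_pair_max(RawMatrix hi, RawMatrix lo, int n,
                                IntegerMatrix labmat) {
  ScanCtx c;
  ctx_init(c, hi, lo, n);
  const int B = labmat.ncol();
  NumericVector out(B);
  for (int b = 0; b < B; ++b) {
    ctx_set_labels(c, &labmat(0, b));
    double best = R_NegInf;
    for (int i = 0; i < c.p - 1; ++i)
      for (int j = i + 1; j < c.p; ++j) {
        const double v = pair_ii(c, i, j);
        if (v > best) best = v;
      }
    out[b] = best;
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// max single-SNP MI under each column of a label matrix
// [[Rcpp::export]]
NumericVector cpp_perm_single_max(RawMatrix hi, RawMatrix lo, int n,
                                  IntegerMatrix labmat) {
  ScanCtx c;
  ctx_init(c, hi, lo, n);
  const int B = labmat.ncol();
  NumericVector out(B);
  for (int b = 0; b < B; ++b) {
    ctx_set_labels(c, &labmat(0, b));
    double best = R_NegInf;
    for (int k = 0; k < c.p; ++k) {
      const double v = single_mi(c, k);
      if (v > best) best = v;
    }
    out[b] = best;
  }
  return out;
}
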