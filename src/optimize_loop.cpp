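// Stochastic local search over codon multisets.
//
// State: l codons, each a 12-tuple of per-position nucleotide fractions
// (blocks T,C,A,G for the three codon positions).  Each iteration draws
// a fresh random codon from the pre-selected base-codon pool (equimolar
// in degenerate mode, flat-Dirichlet fractions over the support in
// spiked mode), replaces a uniformly chosen element of the multiset, and
// accepts the move iff the distance between the target and the encoded
// amino-acid mixture strictly decreases.  The search stops after
// rejLimit consecutive rejections.
//
// Uses R's RNG so that set.seed() in the caller makes runs bit-identical.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double norm_dist(const std::vector<double>& s,
                               const NumericVector& target,
                               double invl, int normCode) {
  double acc = 0.0;
  const int n = target.size();
  for (int k = 0; k < n; ++k) {
    double d = std::fabs(target[k] - s[k] * invl);
    if (normCode == 1) acc += d;                 // L1
    else if (normCode == 3) { if (d > acc) acc = d; }  // Linf
    else acc += d * d;                           // L2
  }
  return normCode == 2 ? std::sqrt(acc) : acc;
}

// draw fractions for pool row j into frac[12]
static inline void draw_fractions(const IntegerMatrix& poolBits, int j,
                                  bool spiked, double* frac) {
  for (int b = 0; b < 3; ++b) {
    double tot = 0.0;
    double g[4];
    for (int k = 0; k < 4; ++k) {
      int bit = poolBits(j, 4 * b + k);
      if (bit) {
        g[k] = spiked ? exp_rand() : 1.0;  // Exp(1) == Gamma(1,1)
        tot += g[k];
      } else g[k] = 0.0;
    }
    for (int k = 0; k < 4; ++k) frac[4 * b + k] = g[k] / tot;
  }
}

// amino-acid distribution of a fractional codon into out[nsym]
static inline void codon_dist(const double* frac, const IntegerVector& aaIdx,
                              int nsym, double* out) {
  for (int k = 0; k < nsym; ++k) out[k] = 0.0;
  for (int i1 = 0; i1 < 4; ++i1) {
    double f1 = frac[i1];
    if (f1 == 0.0) continue;
    for (int i2 = 0; i2 < 4; ++i2) {
      double f12 = f1 * frac[4 + i2];
      if (f12 == 0.0) continue;
      for (int i3 = 0; i3 < 4; ++i3) {
        double f = f12 * frac[8 + i3];
        if (f != 0.0) out[aaIdx[16 * i1 + 4 * i2 + i3]] += f;
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_optimize(const IntegerMatrix poolBits, const NumericMatrix poolDist,
                  const IntegerVector aaIndex, const NumericVector target,
                  const int l, const bool spiked, const int normCode,
                  const double rejLimit, const bool perturb,
                  const double perturbProb) {
  const int npool = poolBits.nrow();
  const int nsym = target.size();
  if (npool < 1) stop("empty base-codon pool");
  if (l < 1) stop("library length must be at least 1");

  std::vector<double> F((size_t)l * 12), Dm((size_t)l * nsym), s(nsym, 0.0);
  std::vector<double> frac(12), cd(nsym);
  const double invl = 1.0 / l;

  // initialize with l random proposals
  for (int i = 0; i < l; ++i) {
    int j = (int)(unif_rand() * npool); if (j == npool) j = npool - 1;
    draw_fractions(poolBits, j, spiked, &F[(size_t)i * 12]);
    if (spiked) codon_dist(&F[(size_t)i * 12], aaIndex, nsym,
                           &Dm[(size_t)i * nsym]);
    else for (int k = 0; k < nsym; ++k) Dm[(size_t)i * nsym + k] =
           poolDist(j, k);
    for (int k = 0; k < nsym; ++k) s[k] += Dm[(size_t)i * nsym + k];
  }
  double d_old = norm_dist(s, target, invl, normCode);

  std::vector<double> trace;
  trace.push_back(d_old);
  long long accepted = 0, proposals = 0;
  double streak = 0;

  std::vector<double> snew(nsym);
  while (streak < rejLimit) {
    ++proposals;
    bool local = perturb && spiked && unif_rand() < perturbProb;
    int r = (int)(unif_rand() * l); if (r == l) r = l - 1;
    if (local) {
      // re-draw one positional block of an existing codon over its support
      int src = (int)(unif_rand() * l); if (src == l) src = l - 1;
      for (int k = 0; k < 12; ++k) frac[k] = F[(size_t)src * 12 + k];
      int b = (int)(unif_rand() * 3); if (b == 3) b = 2;
      double tot = 0.0; double g[4];
      for (int k = 0; k < 4; ++k) {
        if (frac[4 * b + k] > 0.0) { g[k] = exp_rand(); tot += g[k]; }
        else g[k] = 0.0;
      }
      for (int k = 0; k < 4; ++k) frac[4 * b + k] = g[k] / tot;
      codon_dist(frac.data(), aaIndex, nsym, cd.data());
      r = src;  // a ratio shift modifies the codon in place
    } else {
      int j = (int)(unif_rand() * npool); if (j == npool) j = npool - 1;
      draw_fractions(poolBits, j, spiked, frac.data());
      if (spiked) codon_dist(frac.data(), aaIndex, nsym, cd.data());
      else for (int k = 0; k < nsym; ++k) cd[k] = poolDist(j, k);
    }
    for (int k = 0; k < nsym; ++k)
      snew[k] = s[k] - Dm[(size_t)r * nsym + k] + cd[k];
    double d_new = norm_dist(snew, target, invl, normCode);
    if (d_new < d_old) {
      for (int k = 0; k < 12; ++k) F[(size_t)r * 12 + k] = frac[k];
      for (int k = 0; k < nsym; ++k) Dm[(size_t)r * nsym + k] = cd[k];
      ++accepted;
      if (accepted % 4096 == 0) {   // control round-off drift in s
        for (int k = 0; k < nsym; ++k) {
          double t = 0.0;
          for (int i = 0; i < l; ++i) t += Dm[(size_t)i * nsym + k];
          snew[k] = t;
        }
        d_new = norm_dist(snew, target, invl, normCode);
        if (d_new > d_old) d_new = d_old;  // drift only, never uphill
      }
      s = snew;
      d_old = d_new;
      trace.push_back(d_old);
      streak = 0;
    } else {
      ++streak;
    }
    if (proposals % 65536 == 0) checkUserInterrupt();
  }

  // recompute final distance from scratch
  std::fill(s.begin(), s.end(), 0.0);
  for (int i = 0; i < l; ++i)
    for (int k = 0; k < nsym; ++k) s[k] += Dm[(size_t)i * nsym + k];
  double final_d = norm_dist(s, target, invl, normCode);

  NumericMatrix Fout(l, 12);
  for (int i = 0; i < l; ++i)
    for (int k = 0; k < 12; ++k) Fout(i, k) = F[(size_t)i * 12 + k];
  NumericVector ach(nsym);
  for (int k = 0; k < nsym; ++k) ach[k] = s[k] * invl;

  return List::create(_["fractions"] = Fout,
                      _["distance"] = final_d,
                      _["trace"] = NumericVector(trace.begin(), trace.end()),
                      _["achieved"] = ach,
                      _["accepted"] = (double)accepted,
                      _["proposals"] = (double)proposals);
}
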