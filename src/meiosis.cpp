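// Core gene-dropping machinery: Haldane-model meioses (Poisson crossover
// count, uniform positions, no interference), founder-labeled haplotype
// mosaics, and extraction of maximal shared segments between a pair of
// individuals.  Uses R's RNG throughout so set.seed() governs every draw,
// and the R-level single-meiosis wrappers consume the stream in exactly the
// same order as the bulk simulator.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// One chromosome copy: an ordered mosaic of founder-labeled intervals.
// brk holds the n-1 internal breakpoints (strictly increasing, in (0, l));
// lab holds the n interval labels.  A simplified haplotype has no two
// adjacent equal labels.
struct Hap {
  std::vector<double> brk;
  std::vector<int> lab;
};

static Hap single_label(int label) {
  Hap h;
  h.lab.push_back(label);
  return h;
}

// Crossover positions for one meiosis: count ~ Poisson(l), positions i.i.d.
// Uniform(0, l), sorted; coincident or boundary positions are resampled
// (measure-zero events, but exact duplicates would create empty intervals).
static std::vector<double> sample_positions(double l) {
  int k = (int)R::rpois(l);
  std::vector<double> x((size_t)k);
  for (int i = 0; i < k; i++) x[(size_t)i] = unif_rand() * l;
  std::sort(x.begin(), x.end());
  bool clean = false;
  while (!clean) {
    clean = true;
    for (size_t i = 0; i < x.size(); i++) {
      bool bad = (x[i] <= 0.0 || x[i] >= l) || (i > 0 && x[i] == x[i - 1]);
      if (bad) {
        x[i] = unif_rand() * l;
        std::sort(x.begin(), x.end());
        clean = false;
        break;
      }
    }
  }
  return x;
}

static int label_at(const Hap& h, double pos) {
  size_t j = (size_t)(std::upper_bound(h.brk.begin(), h.brk.end(), pos) -
                      h.brk.begin());
  return h.lab[j];
}

// Deterministic gamete: alternate source haplotype at each crossover,
// starting from A if startA; output is simplified on the fly.
static Hap gamete_fixed(const Hap& A, const Hap& B, double l,
                        const std::vector<double>& xo, bool startA) {
  const Hap* cur = startA ? &A : &B;
  const Hap* oth = startA ? &B : &A;
  Hap out;
  double lo = 0.0;
  size_t nx = xo.size();
  for (size_t i = 0; i <= nx; i++) {
    double hi = (i < nx) ? xo[i] : l;
    // copy cur's intervals overlapping (lo, hi)
    size_t j = (size_t)(std::upper_bound(cur->brk.begin(), cur->brk.end(), lo) -
                        cur->brk.begin());
    double s = lo;
    while (s < hi) {
      double e = (j < cur->brk.size()) ? cur->brk[j] : l;
      if (e > hi) e = hi;
      int lb = cur->lab[j];
      if (!out.lab.empty() && out.lab.back() == lb) {
        // adjacent equal labels merge: do not record the boundary
      } else {
        if (s > 0.0) out.brk.push_back(s);
        out.lab.push_back(lb);
      }
      s = e;
      j++;
    }
    std::swap(cur, oth);
    lo = hi;
  }
  return out;
}

// One random meiosis.  RNG order: crossover count, positions, then phase.
static Hap gamete_random(const Hap& A, const Hap& B, double l) {
  std::vector<double> xo = sample_positions(l);
  bool startA = unif_rand() < 0.5;
  return gamete_fixed(A, B, l, xo, startA);
}

// Maximal shared segments between the haplotype sets of two individuals:
// positions where some haplotype of A and some haplotype of B carry the
// same founder label; adjacent elementary intervals shared through
// different founder haplotypes merge into one segment.
struct ShareOut {
  int ns;
  int ps;
  double total;                 // proportion of l
  std::vector<double> segs;     // start,end pairs (Morgans), if requested
};

static void shared_summary(const std::vector<const Hap*>& A,
                           const std::vector<const Hap*>& B, double l,
                           bool keep_segs, ShareOut& out) {
  std::vector<double> bounds;
  bounds.push_back(0.0);
  for (size_t a = 0; a < A.size(); a++)
    bounds.insert(bounds.end(), A[a]->brk.begin(), A[a]->brk.end());
  for (size_t b = 0; b < B.size(); b++)
    bounds.insert(bounds.end(), B[b]->brk.begin(), B[b]->brk.end());
  bounds.push_back(l);
  std::sort(bounds.begin(), bounds.end());
  bounds.erase(std::unique(bounds.begin(), bounds.end()), bounds.end());

  out.ns = 0;
  out.total = 0.0;
  out.segs.clear();
  bool touch0 = false, touchl = false;
  bool in_seg = false;
  double seg_start = 0.0;
  size_t ni = bounds.size() - 1;
  for (size_t i = 0; i <= ni; i++) {
    bool shared = false;
    if (i < ni) {
      double mid = 0.5 * (bounds[i] + bounds[i + 1]);
      for (size_t a = 0; a < A.size() && !shared; a++) {
        int la = label_at(*A[a], mid);
        for (size_t b = 0; b < B.size(); b++) {
          if (label_at(*B[b], mid) == la) {
            shared = true;
            break;
          }
        }
      }
    }
    if (shared && !in_seg) {
      in_seg = true;
      seg_start = bounds[i];
    } else if (!shared && in_seg) {
      double seg_end = bounds[i];
      out.ns++;
      out.total += (seg_end - seg_start);
      if (seg_start == 0.0) touch0 = true;
      if (seg_end == l) touchl = true;
      if (keep_segs) {
        out.segs.push_back(seg_start);
        out.segs.push_back(seg_end);
      }
      in_seg = false;
    }
  }
  out.total /= l;
  out.ps = (touch0 ? 1 : 0) + (touchl ? 1 : 0);
}

// ---- R-facing converters -------------------------------------------------

static Hap hap_from_list(const List& h) {
  Hap out;
  NumericVector b = h["breakpoints"];
  IntegerVector lb = h["labels"];
  out.brk.assign(b.begin(), b.end());
  out.lab.assign(lb.begin(), lb.end());
  return out;
}

static List hap_to_list(const Hap& h) {
  return List::create(_["breakpoints"] = NumericVector(h.brk.begin(), h.brk.end()),
                      _["labels"] = IntegerVector(h.lab.begin(), h.lab.end()));
}

// [[Rcpp::export]]
NumericVector cpp_sample_crossovers(double l) {
  std::vector<double> x = sample_positions(l);
  return NumericVector(x.begin(), x.end());
}

// start: -1 random phase, 0 start from A, 1 start from B.
// [[Rcpp::export]]
List cpp_gamete(List hapA, List hapB, double l,
                Nullable<NumericVector> crossovers, int start) {
  Hap A = hap_from_list(hapA), B = hap_from_list(hapB);
  std::vector<double> xo;
  if (crossovers.isNull()) {
    xo = sample_positions(l);
  } else {
    NumericVector cx(crossovers);
    xo.assign(cx.begin(), cx.end());
    std::sort(xo.begin(), xo.end());
  }
  bool startA;
  if (start < 0)
    startA = unif_rand() < 0.5;
  else
    startA = (start == 0);
  Hap g = gamete_fixed(A, B, l, xo, startA);
  return hap_to_list(g);
}

// [[Rcpp::export]]
List cpp_shared_segments(List hapsA, List hapsB, double l) {
  std::vector<Hap> A, B;
  for (int i = 0; i < hapsA.size(); i++) A.push_back(hap_from_list(hapsA[i]));
  for (int i = 0; i < hapsB.size(); i++) B.push_back(hap_from_list(hapsB[i]));
  std::vector<const Hap*> pA, pB;
  for (size_t i = 0; i < A.size(); i++) pA.push_back(&A[i]);
  for (size_t i = 0; i < B.size(); i++) pB.push_back(&B[i]);
  ShareOut out;
  shared_summary(pA, pB, l, true, out);
  NumericMatrix segs(out.ns, 2);
  for (int i = 0; i < out.ns; i++) {
    segs(i, 0) = out.segs[(size_t)(2 * i)];
    segs(i, 1) = out.segs[(size_t)(2 * i + 1)];
  }
  return List::create(_["segments"] = segs, _["n_s"] = out.ns,
                      _["p_s"] = out.ps, _["total"] = out.total);
}

// Bulk simulator.  base: 1 = full-sib founder couple, 2 = single common
// ancestor (half-sib collateral and lineal).  pairs: m x 2 chain indices,
// index 0 denoting the diploid endpoint (the sib itself for base 1, the
// ancestor for base 2), index k >= 1 the tracked haplotype k meioses below
// the diploid endpoint's generation.  Within a replicate one pedigree
// instance is reused to score every requested pair.
//
// RNG order per replicate (identical to the R-level drop_pair wrapper):
// base 1: sib1 paternal, sib1 maternal, sib2 paternal, sib2 maternal,
//         chain1[1..d1], chain2[1..d2];
// base 2: chain1[1..d1], chain2[1..d2].
// [[Rcpp::export]]
List cpp_simulate_base(int base, double l, int N, IntegerMatrix pairs) {
  int m = pairs.nrow();
  int d1 = 0, d2 = 0;
  for (int i = 0; i < m; i++) {
    if (pairs(i, 0) > d1) d1 = pairs(i, 0);
    if (pairs(i, 1) > d2) d2 = pairs(i, 1);
  }
  std::vector<IntegerVector> ns_out, ps_out;
  std::vector<NumericVector> tot_out;
  for (int i = 0; i < m; i++) {
    ns_out.push_back(IntegerVector(N));
    ps_out.push_back(IntegerVector(N));
    tot_out.push_back(NumericVector(N));
  }

  Hap F1 = single_label(1), F2 = single_label(2);
  Hap M1 = single_label(3), M2 = single_label(4);
  Hap A1 = single_label(1), A2 = single_label(2);

  std::vector<Hap> c1((size_t)d1 + 1), c2((size_t)d2 + 1);
  Hap sib1p, sib1m, sib2p, sib2m;
  ShareOut sh;

  for (int rep = 0; rep < N; rep++) {
    int fresh = (base == 1) ? 5 : 3;
    if (base == 1) {
      sib1p = gamete_random(F1, F2, l);
      sib1m = gamete_random(M1, M2, l);
      sib2p = gamete_random(F1, F2, l);
      sib2m = gamete_random(M1, M2, l);
      if (d1 >= 1) c1[1] = gamete_random(sib1p, sib1m, l);
      for (int k = 2; k <= d1; k++) {
        Hap mate = single_label(fresh++);
        c1[(size_t)k] = gamete_random(c1[(size_t)k - 1], mate, l);
      }
      if (d2 >= 1) c2[1] = gamete_random(sib2p, sib2m, l);
      for (int k = 2; k <= d2; k++) {
        Hap mate = single_label(fresh++);
        c2[(size_t)k] = gamete_random(c2[(size_t)k - 1], mate, l);
      }
    } else {
      if (d1 >= 1) c1[1] = gamete_random(A1, A2, l);
      for (int k = 2; k <= d1; k++) {
        Hap mate = single_label(fresh++);
        c1[(size_t)k] = gamete_random(c1[(size_t)k - 1], mate, l);
      }
      if (d2 >= 1) c2[1] = gamete_random(A1, A2, l);
      for (int k = 2; k <= d2; k++) {
        Hap mate = single_label(fresh++);
        c2[(size_t)k] = gamete_random(c2[(size_t)k - 1], mate, l);
      }
    }
    for (int i = 0; i < m; i++) {
      std::vector<const Hap*> pA, pB;
      int i1 = pairs(i, 0), i2 = pairs(i, 1);
      if (i1 == 0) {
        if (base == 1) {
          pA.push_back(&sib1p);
          pA.push_back(&sib1m);
        } else {
          pA.push_back(&A1);
          pA.push_back(&A2);
        }
      } else {
        pA.push_back(&c1[(size_t)i1]);
      }
      if (i2 == 0) {
        if (base == 1) {
          pB.push_back(&sib2p);
          pB.push_back(&sib2m);
        } else {
          pB.push_back(&A1);
          pB.push_back(&A2);
        }
      } else {
        pB.push_back(&c2[(size_t)i2]);
      }
      shared_summary(pA, pB, l, false, sh);
      ns_out[(size_t)i][rep] = sh.ns;
      ps_out[(size_t)i][rep] = sh.ps;
      tot_out[(size_t)i][rep] = sh.total;
    }
  }

  List res(m);
  for (int i = 0; i < m; i++) {
    res[i] = List::create(_["n_s"] = ns_out[(size_t)i],
                          _["p_s"] = ps_out[(size_t)i],
                          _["total"] = tot_out[(size_t)i]);
  }
  return res;
}
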