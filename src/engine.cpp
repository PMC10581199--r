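// Simplified combinatorial assignment engine.
//
// Expected peaks (tuples of atom ids) are matched to measured peaks of the
// same spectrum under two hard constraints: every coordinate must lie
// within k*width of the atom's search-space center (candidate window), and
// coordinates supporting the same atom must agree within that atom's
// matching tolerance.  The score rewards matches close to the search-space
// centers and penalizes unmatched expected peaks; it is maximized by
// weighted stochastic initialization, simulated annealing over
// reassign/swap/unassign moves, and a final greedy polish.
//
// Randomness comes from a private mt19937 with explicit uniform mapping so
// replicates are bit-reproducible across platforms.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Problem {
  int nE, nM, nA;
  const int *expAtoms;      // nE x 3 column-major, -1 unused
  const int *expSpec;       // nE
  const double *coords;     // nM x 3 column-major
  const int *measSpec;      // nM
  const double *center, *halfw, *tol; // per atom; halfw = k * width
  double lambda;
};

class Rng {
 public:
  explicit Rng(unsigned int seed) : gen_(seed) {}
  double unif() { return (gen_() + 0.5) * (1.0 / 4294967296.0); }
  int below(int n) { return (int)(unif() * n) % n; }
 private:
  std::mt19937 gen_;
};

class State {
 public:
  State(const Problem &p) : p_(p), match(p.nE, -1),
                            supCount(p.nA, 0), supSum(p.nA, 0.0) {}

  int ndim(int e) const {
    int nd = 0;
    for (int d = 0; d < 3; ++d) if (p_.expAtoms[e + d * p_.nE] >= 0) ++nd;
    return nd;
  }

  // deviation of measured peak m from peak e's search-space centers,
  // normalized per dimension; bracket contribution = 1 - dev
  double dev(int e, int m) const {
    double s = 0.0; int nd = 0;
    for (int d = 0; d < 3; ++d) {
      int a = p_.expAtoms[e + d * p_.nE];
      if (a < 0) continue;
      double z = (p_.coords[m + d * p_.nM] - p_.center[a]) / p_.halfw[a];
      s += z * z; ++nd;
    }
    return s / nd;
  }

  bool inWindow(int e, int m) const {
    if (p_.measSpec[m] != p_.expSpec[e]) return false;
    for (int d = 0; d < 3; ++d) {
      int a = p_.expAtoms[e + d * p_.nE];
      if (a < 0) continue;
      if (std::fabs(p_.coords[m + d * p_.nM] - p_.center[a]) > p_.halfw[a])
        return false;
    }
    return true;
  }

  // consistency of candidate m for (currently unmatched) peak e with the
  // committed shifts of shared atoms
  bool consistent(int e, int m) const {
    for (int d = 0; d < 3; ++d) {
      int a = p_.expAtoms[e + d * p_.nE];
      if (a < 0) continue;
      if (supCount[a] > 0) {
        double mean = supSum[a] / supCount[a];
        if (std::fabs(p_.coords[m + d * p_.nM] - mean) > p_.tol[a])
          return false;
      }
    }
    return true;
  }

  double contrib(int e) const {
    int m = match[e];
    if (m < 0) return -p_.lambda / p_.nE;
    return 1.0 - dev(e, m);
  }

  void attach(int e, int m) {
    match[e] = m;
    for (int d = 0; d < 3; ++d) {
      int a = p_.expAtoms[e + d * p_.nE];
      if (a < 0) continue;
      supCount[a] += 1;
      supSum[a] += p_.coords[m + d * p_.nM];
    }
  }

  void detach(int e) {
    int m = match[e];
    if (m < 0) return;
    for (int d = 0; d < 3; ++d) {
      int a = p_.expAtoms[e + d * p_.nE];
      if (a < 0) continue;
      supCount[a] -= 1;
      supSum[a] -= p_.coords[m + d * p_.nM];
    }
    match[e] = -1;
  }

  double totalScore() const {
    double s = 0.0;
    for (int e = 0; e < p_.nE; ++e) s += contrib(e);
    return s;
  }

  const Problem &p_;
  std::vector<int> match;
  std::vector<int> supCount;
  std::vector<double> supSum;
};

Problem makeProblem(const IntegerMatrix &expAtoms,
                    const IntegerVector &expSpec,
                    const NumericMatrix &coords,
                    const IntegerVector &measSpec,
                    const NumericVector &center,
                    const NumericVector &halfw,
                    const NumericVector &tol,
                    double lambda) {
  Problem p;
  p.nE = expAtoms.nrow(); p.nM = coords.nrow(); p.nA = center.size();
  p.expAtoms = INTEGER(expAtoms); p.expSpec = INTEGER(expSpec);
  p.coords = REAL(coords); p.measSpec = INTEGER(measSpec);
  p.center = REAL(center); p.halfw = REAL(halfw); p.tol = REAL(tol);
  p.lambda = lambda;
  return p;
}

} // namespace

// [[Rcpp::export(name = ".cstCandidates")]]
List cstCandidates(IntegerMatrix expAtoms, IntegerVector expSpec,
                   NumericMatrix coords, IntegerVector measSpec,
                   NumericVector center, NumericVector halfw) {
  NumericVector tol(center.size(), 1.0);
  Problem p = makeProblem(expAtoms, expSpec, coords, measSpec, center,
                          halfw, tol, 0.0);
  State st(p);
  List out(p.nE);
  std::vector<int> buf;
  for (int e = 0; e < p.nE; ++e) {
    buf.clear();
    for (int m = 0; m < p.nM; ++m)
      if (st.inWindow(e, m)) buf.push_back(m);
    out[e] = IntegerVector(buf.begin(), buf.end());
  }
  return out;
}

// [[Rcpp::export(name = ".cstScore")]]
double cstScore(IntegerMatrix expAtoms, IntegerVector expSpec,
                NumericMatrix coords, IntegerVector measSpec,
                NumericVector center, NumericVector halfw,
                NumericVector tol, double lambda, IntegerVector match) {
  Problem p = makeProblem(expAtoms, expSpec, coords, measSpec, center,
                          halfw, tol, lambda);
  State st(p);
  for (int e = 0; e < p.nE; ++e)
    if (match[e] >= 0) st.attach(e, match[e]);
  return st.totalScore();
}

// [[Rcpp::export(name = ".cstRun")]]
List cstRun(IntegerMatrix expAtoms, IntegerVector expSpec,
            NumericMatrix coords, IntegerVector measSpec,
            NumericVector center, NumericVector halfw, NumericVector tol,
            List cand, IntegerVector initMatch, bool doInit,
            double initGreed, int iters, double t0, double coolRate,
            NumericVector moveProbs, int polishSweeps, double lambda,
            int seed) {
  Problem p = makeProblem(expAtoms, expSpec, coords, measSpec, center,
                          halfw, tol, lambda);
  State st(p);
  Rng rng((unsigned int)seed);

  std::vector<std::vector<int> > cands(p.nE);
  for (int e = 0; e < p.nE; ++e) {
    IntegerVector ce = cand[e];
    cands[e].assign(ce.begin(), ce.end());
  }

  if (doInit) {
    // visit expected peaks in random order; sample a consistent candidate
    // with weight exp(-initGreed * deviation)
    std::vector<int> order(p.nE);
    for (int e = 0; e < p.nE; ++e) order[e] = e;
    for (int i = p.nE - 1; i > 0; --i)
      std::swap(order[i], order[rng.below(i + 1)]);
    std::vector<double> w;
    std::vector<int> ok;
    for (int i = 0; i < p.nE; ++i) {
      int e = order[i];
      w.clear(); ok.clear();
      double wsum = 0.0;
      for (size_t j = 0; j < cands[e].size(); ++j) {
        int m = cands[e][j];
        if (!st.consistent(e, m)) continue;
        double wt = std::exp(-initGreed * st.dev(e, m));
        ok.push_back(m); w.push_back(wt); wsum += wt;
      }
      if (ok.empty()) continue;
      double u = rng.unif() * wsum;
      size_t j = 0;
      for (; j + 1 < ok.size(); ++j) {
        u -= w[j];
        if (u <= 0) break;
      }
      st.attach(e, ok[j]);
    }
  } else {
    for (int e = 0; e < p.nE; ++e)
      if (initMatch[e] >= 0) st.attach(e, initMatch[e]);
  }

  double score = st.totalScore();
  const double pReassign = moveProbs[0];
  const double pSwap = moveProbs[0] + moveProbs[1];

  // simulated annealing
  double temp = t0;
  for (int it = 0; it < iters; ++it, temp *= coolRate) {
    double u = rng.unif();
    if (u < pReassign || p.nE < 2) {
      int e = rng.below(p.nE);
      if (cands[e].empty()) continue;
      int oldM = st.match[e];
      double oldC = st.contrib(e);
      st.detach(e);
      int m = cands[e][rng.below((int)cands[e].size())];
      bool okMove = st.consistent(e, m);
      if (okMove) {
        st.attach(e, m);
        double delta = st.contrib(e) - oldC;
        bool accept = delta >= 0 ||
          (temp > 0 && rng.unif() < std::exp(delta / temp));
        if (accept) { score += delta; continue; }
        st.detach(e);
      }
      if (oldM >= 0) st.attach(e, oldM);
    } else if (u < pSwap) {
      int e1 = rng.below(p.nE), e2 = rng.below(p.nE);
      if (e1 == e2) continue;
      if (st.match[e1] < 0 || st.match[e2] < 0) continue;
      if (p.expSpec[e1] != p.expSpec[e2]) continue;
      int m1 = st.match[e1], m2 = st.match[e2];
      double oldC = st.contrib(e1) + st.contrib(e2);
      if (!st.inWindow(e1, m2) || !st.inWindow(e2, m1)) continue;
      st.detach(e1); st.detach(e2);
      bool okMove = st.consistent(e1, m2);
      if (okMove) {
        st.attach(e1, m2);
        okMove = st.consistent(e2, m1);
        if (okMove) st.attach(e2, m1);
        else st.detach(e1);
      }
      if (okMove) {
        double delta = st.contrib(e1) + st.contrib(e2) - oldC;
        bool accept = delta >= 0 ||
          (temp > 0 && rng.unif() < std::exp(delta / temp));
        if (accept) { score += delta; continue; }
        st.detach(e1); st.detach(e2);
      }
      st.attach(e1, m1); st.attach(e2, m2);
    } else {
      int e = rng.below(p.nE);
      if (st.match[e] < 0) continue;
      int oldM = st.match[e];
      double oldC = st.contrib(e);
      st.detach(e);
      double delta = st.contrib(e) - oldC;
      bool accept = delta >= 0 ||
        (temp > 0 && rng.unif() < std::exp(delta / temp));
      if (accept) { score += delta; continue; }
      st.attach(e, oldM);
    }
  }

  // greedy polish: best-improvement sweeps at temperature zero
  for (int sweep = 0; sweep < polishSweeps; ++sweep) {
    bool changed = false;
    for (int e = 0; e < p.nE; ++e) {
      if (cands[e].empty()) continue;
      int oldM = st.match[e];
      double oldC = st.contrib(e);
      st.detach(e);
      double bestDelta = 0.0;
      int bestM = oldM;
      double unC = st.contrib(e); // unmatched contribution
      if (oldM >= 0 && unC - oldC > bestDelta) {
        // unassigning never improves (bracket >= 0) but keep for safety
        bestDelta = unC - oldC; bestM = -1;
      }
      for (size_t j = 0; j < cands[e].size(); ++j) {
        int m = cands[e][j];
        if (!st.consistent(e, m)) continue;
        double d = 1.0 - st.dev(e, m) - oldC;
        if (d > bestDelta + 1e-12) { bestDelta = d; bestM = m; }
      }
      if (bestM >= 0) st.attach(e, bestM);
      if (bestM != oldM && bestDelta > 0) { score += bestDelta; changed = true; }
      else if (bestM != oldM) { /* restored different but equal; keep */ }
    }
    if (!changed) break;
  }

  score = st.totalScore(); // guard against incremental drift

  IntegerVector outMatch(p.nE);
  for (int e = 0; e < p.nE; ++e)
    outMatch[e] = st.match[e] < 0 ? NA_INTEGER : st.match[e] + 1;
  NumericVector atomShift(p.nA);
  for (int a = 0; a < p.nA; ++a)
    atomShift[a] = st.supCount[a] > 0 ? st.supSum[a] / st.supCount[a]
                                      : NA_REAL;
  return List::create(_["match"] = outMatch, _["atomShift"] = atomShift,
                      _["score"] = score);
}
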