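// Folding engine for the bundled nearest-neighbour energy backend.
//
// Two independent machines live here:
//  * a McCaskill-type partition function over nested secondary structures
//    (Watson-Crick + GU pairs, stacking energies, logarithmic hairpin and
//    interior-loop penalties, affine multiloops) with per-position pairing
//    constraints, used for interval "unpaired" probabilities; and
//  * an RNAduplex-style dynamic program over purely inter-molecular
//    hybridisation (stacks plus affine bulge/interior penalties) that returns
//    the optimal duplex and per-end-position sub-optimal candidate sites.
//
// Long double accumulation keeps the partition function away from overflow for
// the window sizes the screening pipeline uses (< ~1000 nt).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

const int MINHP = 3; // minimum hairpin loop length (unpaired bases)

struct EnergyPar {
  double stack[7][7];     // [outer pair type][inner pair type], kcal/mol
  double hairpin_a, hairpin_b;
  double interior_a, interior_b;
  int    interior_cap;    // max total unpaired bases in an interior loop/bulge
  double ml_a, ml_b;      // multiloop closing + per-branch (per-unpaired = 0)
  double dup_init;
  double dup_loop_a, dup_loop_b;
  int    dup_gap_cap;     // max unpaired per strand between duplex pairs
  double RT;
};

// base codes: 0=A 1=C 2=G 3=U; pair types 1..6 = AU UA CG GC GU UG, 0 = none
inline int pairType(int x, int y) {
  if (x == 0 && y == 3) return 1;
  if (x == 3 && y == 0) return 2;
  if (x == 1 && y == 2) return 3;
  if (x == 2 && y == 1) return 4;
  if (x == 2 && y == 3) return 5;
  if (x == 3 && y == 2) return 6;
  return 0;
}

EnergyPar readPar(const List& par) {
  EnergyPar P;
  NumericMatrix st = par["stack"];
  if (st.nrow() != 6 || st.ncol() != 6) stop("stack table must be 6x6");
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 6; ++j) P.stack[i + 1][j + 1] = st(i, j);
  P.hairpin_a  = as<double>(par["hairpin_a"]);
  P.hairpin_b  = as<double>(par["hairpin_b"]);
  P.interior_a = as<double>(par["interior_a"]);
  P.interior_b = as<double>(par["interior_b"]);
  P.interior_cap = as<int>(par["interior_cap"]);
  P.ml_a = as<double>(par["ml_a"]);
  P.ml_b = as<double>(par["ml_b"]);
  P.dup_init  = as<double>(par["dup_init"]);
  P.dup_loop_a = as<double>(par["dup_loop_a"]);
  P.dup_loop_b = as<double>(par["dup_loop_b"]);
  P.dup_gap_cap = as<int>(par["dup_gap_cap"]);
  P.RT = as<double>(par["RT"]);
  return P;
}

inline double hairpinE(const EnergyPar& P, int L) {
  return P.hairpin_a + P.hairpin_b * std::log((double)L / MINHP);
}
inline double interiorE(const EnergyPar& P, int s) {
  return P.interior_a + P.interior_b * std::log((double)s);
}
inline double dupLoopE(const EnergyPar& P, int g1, int g2) {
  return P.dup_loop_a + P.dup_loop_b * (g1 + g2);
}

// log of the constrained partition function.  canpair[i] = false forbids any
// intramolecular pair involving position i; maxspan <= 0 disables the span cap.
long double pfLogZ(const std::vector<int>& s, const std::vector<bool>& canpair,
                   const EnergyPar& P, int maxspan) {
  const int n = (int)s.size();
  if (n == 0) return 0.0L;
  const long double beta = 1.0L / (long double)P.RT;
  std::vector<long double> Zb((size_t)n * n, 0.0L);
  std::vector<long double> Zm((size_t)n * n, 0.0L);
  std::vector<long double> ZM1((size_t)n * n, 0.0L); // branch at k ending <= e
  auto at = [n](int i, int j) { return (size_t)i * n + j; };

  // Boltzmann lookup tables
  std::vector<long double> bhp(n + 1, 0.0L), bil(P.interior_cap + 1, 0.0L);
  for (int L = MINHP; L <= n; ++L) bhp[L] = expl(-beta * (long double)hairpinE(P, L));
  for (int sz = 1; sz <= P.interior_cap; ++sz)
    bil[sz] = expl(-beta * (long double)interiorE(P, sz));
  long double bstack[7][7];
  for (int a = 1; a <= 6; ++a)
    for (int b = 1; b <= 6; ++b)
      bstack[a][b] = expl(-beta * (long double)P.stack[a][b]);
  const long double eb  = expl(-beta * (long double)P.ml_b);
  const long double eab = expl(-beta * (long double)(P.ml_a + P.ml_b));

  for (int d = MINHP + 1; d < n; ++d) {
    for (int i = 0; i + d < n; ++i) {
      const int j = i + d;
      int pt = 0;
      bool ok = canpair[i] && canpair[j] &&
                (maxspan <= 0 || d + 1 <= maxspan) &&
                (pt = pairType(s[i], s[j])) != 0;
      if (ok) {
        long double val = bhp[d - 1]; // hairpin closed by (i,j)
        // stack / interior / bulge to inner pair (k,l)
        const int kmax = std::min(i + 1 + P.interior_cap, j - MINHP - 2);
        for (int k = i + 1; k <= kmax; ++k) {
          const int g1 = k - i - 1;
          const int lmin = std::max(k + MINHP + 1, j - 1 - (P.interior_cap - g1));
          for (int l = j - 1; l >= lmin; --l) {
            const long double zkl = Zb[at(k, l)];
            if (zkl == 0.0L) continue;
            const int g2 = j - 1 - l;
            long double w;
            if (g1 == 0 && g2 == 0)
              w = bstack[pt][pairType(s[k], s[l])];
            else
              w = bil[g1 + g2];
            val += w * zkl;
          }
        }
        // multiloop closed by (i,j): >= 2 inner branches, last starts at k
        long double ml = 0.0L;
        for (int k = i + 2; k <= j - MINHP - 2; ++k) {
          const long double zm = Zm[at(i + 1, k - 1)];
          if (zm == 0.0L) continue;
          ml += zm * ZM1[at(k, j - 1)];
        }
        val += eab * ml;
        Zb[at(i, j)] = val;
      }
      ZM1[at(i, j)] = (j > i ? ZM1[at(i, j - 1)] : 0.0L) + Zb[at(i, j)] * eb;
      // Zm(i,j): >= 1 branch, decomposed on the start k of the last branch
      long double zm = 0.0L;
      for (int k = i; k <= j - MINHP - 1; ++k) {
        const long double zm1 = ZM1[at(k, j)];
        if (zm1 == 0.0L) continue;
        const long double pre = (k > i) ? (1.0L + Zm[at(i, k - 1)]) : 1.0L;
        zm += pre * zm1;
      }
      Zm[at(i, j)] = zm;
    }
  }

  // exterior loop
  std::vector<long double> Zext(n + 1, 0.0L);
  Zext[0] = 1.0L;
  for (int j = 1; j <= n; ++j) {
    Zext[j] = Zext[j - 1];
    for (int k = 1; k + MINHP + 1 <= j; ++k)
      Zext[j] += Zext[k - 1] * Zb[at(k - 1, j - 1)];
  }
  return logl(Zext[n]);
}

struct Cell { double e; int bk_i, bk_j; bool used; };

} // namespace

// [[Rcpp::export]]
List cpp_unpaired_prob(IntegerVector seq, LogicalVector forbidden,
                       int istart, int iend, List par, int maxspan) {
  const int n = seq.size();
  if (istart < 0 || iend >= n || istart > iend) stop("invalid interval");
  EnergyPar P = readPar(par);
  std::vector<int> s(seq.begin(), seq.end());
  std::vector<bool> base(n), constr(n);
  for (int i = 0; i < n; ++i) base[i] = !forbidden[i];
  constr = base;
  for (int i = istart; i <= iend; ++i) constr[i] = false;
  long double logZ  = pfLogZ(s, base, P, maxspan);
  long double logZu = pfLogZ(s, constr, P, maxspan);
  long double lp = logZu - logZ;
  if (lp > 0.0L) lp = 0.0L; // guard against rounding
  return List::create(_["prob"] = (double)expl(lp),
                      _["log_prob"] = (double)lp,
                      _["logZ"] = (double)logZ,
                      _["logZ_unpaired"] = (double)logZu);
}

// [[Rcpp::export]]
double cpp_log_partition(IntegerVector seq, LogicalVector forbidden,
                         List par, int maxspan) {
  EnergyPar P = readPar(par);
  std::vector<int> s(seq.begin(), seq.end());
  std::vector<bool> base(s.size());
  for (size_t i = 0; i < s.size(); ++i) base[i] = !forbidden[i];
  return (double)pfLogZ(s, base, P, maxspan);
}

// Duplex DP between target t (5'->3') and query q (5'->3').  A duplex is a set
// of inter-molecular pairs (i on t, j on q), antiparallel: successive pairs
// have increasing i and decreasing j.  H(i,j) holds the best energy of a
// duplex whose 3'-most pair on the target is (i,j), including the initiation
// penalty.  Returns, per requested mode, the global optimum or the best
// candidate for every target end position i.
static List duplexCore(IntegerVector tv, IntegerVector qv, List par,
                       double cutoff, bool best_only) {
  EnergyPar P = readPar(par);
  const int n = tv.size(), m = qv.size();
  std::vector<int> t(tv.begin(), tv.end()), q(qv.begin(), qv.end());
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<Cell> H((size_t)n * m);
  auto at = [m](int i, int j) { return (size_t)i * m + j; };
  for (int i = 0; i < n; ++i) {
    for (int j = m - 1; j >= 0; --j) {
      Cell c; c.e = INF; c.bk_i = -1; c.bk_j = -1; c.used = false;
      const int pt = pairType(t[i], q[j]);
      if (pt != 0) {
        c.e = P.dup_init; // duplex of a single pair
        for (int g1 = 0; g1 <= P.dup_gap_cap; ++g1) {
          const int k = i - 1 - g1;
          if (k < 0) break;
          for (int g2 = 0; g2 <= P.dup_gap_cap; ++g2) {
            const int l = j + 1 + g2;
            if (l >= m) break;
            const Cell& pc = H[at(k, l)];
            if (!std::isfinite(pc.e)) continue;
            double step;
            if (g1 == 0 && g2 == 0)
              step = P.stack[pairType(t[k], q[l])][pt];
            else
              step = dupLoopE(P, g1, g2);
            const double cand = pc.e + step;
            if (cand < c.e) { c.e = cand; c.bk_i = k; c.bk_j = l; }
          }
        }
      }
      H[at(i, j)] = c;
    }
  }

  // traceback helper
  auto trace = [&](int i, int j) {
    std::vector<int> pi, pj;
    int ci = i, cj = j;
    while (ci >= 0) {
      pi.push_back(ci + 1); pj.push_back(cj + 1); // 1-based
      const Cell& c = H[at(ci, cj)];
      int ni = c.bk_i, nj = c.bk_j;
      ci = ni; cj = nj;
    }
    std::reverse(pi.begin(), pi.end());
    std::reverse(pj.begin(), pj.end());
    return List::create(_["pairs_t"] = wrap(pi), _["pairs_q"] = wrap(pj));
  };

  List sites;
  if (best_only) {
    double bei = INF; // best energy
    int bi = -1, bj = -1, bs = n + 1;
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < m; ++j) {
        const Cell& c = H[at(i, j)];
        if (!std::isfinite(c.e)) continue;
        // recover start for tie-breaking (5'-most on target wins)
        int si = i, sj = j;
        while (H[at(si, sj)].bk_i >= 0) {
          int ni = H[at(si, sj)].bk_i, nj = H[at(si, sj)].bk_j;
          si = ni; sj = nj;
        }
        if (c.e < bei - 1e-12 ||
            (std::abs(c.e - bei) <= 1e-12 && si < bs)) {
          bei = c.e; bi = i; bj = j; bs = si;
        }
      }
    if (bi < 0 || bei > cutoff) return List();
    List tr = trace(bi, bj);
    IntegerVector pt_ = tr["pairs_t"], pq_ = tr["pairs_q"];
    sites.push_back(List::create(
      _["energy"] = bei,
      _["t_start"] = pt_[0], _["t_end"] = pt_[pt_.size() - 1],
      _["q_start"] = pq_[pq_.size() - 1], _["q_end"] = pq_[0],
      _["pairs_t"] = pt_, _["pairs_q"] = pq_));
  } else {
    // one candidate per target end position: the best j for that i
    for (int i = 0; i < n; ++i) {
      double be = INF; int bj = -1;
      for (int j = 0; j < m; ++j) {
        const Cell& c = H[at(i, j)];
        if (std::isfinite(c.e) && c.e < be - 1e-12) { be = c.e; bj = j; }
      }
      if (bj < 0 || be > cutoff) continue;
      List tr = trace(i, bj);
      IntegerVector pt_ = tr["pairs_t"], pq_ = tr["pairs_q"];
      sites.push_back(List::create(
        _["energy"] = be,
        _["t_start"] = pt_[0], _["t_end"] = pt_[pt_.size() - 1],
        _["q_start"] = pq_[pq_.size() - 1], _["q_end"] = pq_[0],
        _["pairs_t"] = pt_, _["pairs_q"] = pq_));
    }
  }
  return sites;
}

// [[Rcpp::export]]
List cpp_duplex_best(IntegerVector target, IntegerVector query, List par,
                     double cutoff) {
  return duplexCore(target, query, par, cutoff, true);
}

// [[Rcpp::export]]
List cpp_duplex_subopt(IntegerVector target, IntegerVector query, List par,
                       double cutoff) {
  return duplexCore(target, query, par, cutoff, false);
}
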