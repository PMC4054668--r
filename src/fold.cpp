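// Simplified nearest-neighbour RNA folding engine.
//
// Energy model (kcal/mol): stacking bonuses between adjacent base pairs,
// derived from pair strengths (GC 3, AU 2, GU 1; stack = -(s1+s2)/2);
// linear loop penalties (hairpin 3.0 + 0.3*(L-3), internal/bulge
// 2.0 + 0.3*u capped at u <= 30, multiloop 3.4 + 0.4/branch + 0.1/unpaired;
// external bases free). Minimum hairpin loop 3 nt. The same parameter table
// drives the Zuker-style DP, the intermolecular duplex DP and the
// brute-force enumeration references used for validation.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
#include <algorithm>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();
static const int MIN_LOOP = 3;
static const int MAX_INTERIOR = 30;
static const double HAIRPIN_A = 3.0, HAIRPIN_B = 0.3;
static const double INTERIOR_A = 2.0, INTERIOR_B = 0.3;
static const double MULTI_A = 3.4, MULTI_BRANCH = 0.4, MULTI_UNPAIRED = 0.1;

static int encodeBase(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'U': case 'u': case 'T': case 't': return 3;
  case 'N': case 'n': return 4;
  default: return -1;
  }
}

static std::vector<int> encodeSeq(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int b = encodeBase(s[i]);
    if (b < 0) stop("invalid nucleotide character '%s'", std::string(1, s[i]));
    v[i] = b;
  }
  return v;
}

// pair strength; <0 means cannot pair
static double pairStrength(int a, int b) {
  if (a > b) std::swap(a, b);
  if (a == 0 && b == 3) return 2.0;  // A:U
  if (a == 1 && b == 2) return 3.0;  // C:G
  if (a == 2 && b == 3) return 1.0;  // G:U wobble
  return -1.0;
}

static bool canPair(int a, int b) { return pairStrength(a, b) > 0; }
static bool isWatsonCrick(int a, int b) {
  if (a > b) std::swap(a, b);
  return (a == 0 && b == 3) || (a == 1 && b == 2);
}

static double stackEnergy(double s1, double s2) { return -0.5 * (s1 + s2); }

static double hairpinEnergy(int L) {
  if (L < MIN_LOOP) return INF;
  return HAIRPIN_A + HAIRPIN_B * (L - MIN_LOOP);
}

static double interiorEnergy(int u) {
  if (u < 1 || u > MAX_INTERIOR) return INF;
  return INTERIOR_A + INTERIOR_B * u;
}

// ---------------------------------------------------------------------------
// Loop-decomposition scorer for an explicit pairing (partner[i] = j or -1).
// Used by the enumeration references and exported for dot-bracket scoring.
// ---------------------------------------------------------------------------
static double scorePairingVec(const std::vector<int>& s, const std::vector<int>& partner) {
  int n = (int)s.size();
  double e = 0.0;
  for (int i = 0; i < n; ++i) {
    int j = partner[i];
    if (j <= i) continue;  // closed pair handled at its opening position
    if (!canPair(s[i], s[j])) return INF;
    // walk the loop closed by (i, j)
    std::vector<std::pair<int,int> > children;
    int unpaired = 0;
    int k = i + 1;
    while (k < j) {
      if (partner[k] > k) {
        children.push_back(std::make_pair(k, partner[k]));
        k = partner[k] + 1;
      } else if (partner[k] == -1) {
        ++unpaired; ++k;
      } else {
        return INF;  // crossing / inconsistent
      }
    }
    if (children.empty()) {
      double h = hairpinEnergy(unpaired);
      if (h == INF) return INF;
      e += h;
    } else if (children.size() == 1) {
      if (unpaired == 0) {
        e += stackEnergy(pairStrength(s[i], s[j]),
                         pairStrength(s[children[0].first], s[children[0].second]));
      } else {
        double ie = interiorEnergy(unpaired);
        if (ie == INF) return INF;
        e += ie;
      }
    } else {
      e += MULTI_A + MULTI_BRANCH * (children.size() + 1) + MULTI_UNPAIRED * unpaired;
    }
  }
  return e;
}

// [[Rcpp::export(name = ".scorePairingCpp")]]
double scorePairingCpp(std::string seq, IntegerVector partner1based) {
  std::vector<int> s = encodeSeq(seq);
  int n = (int)s.size();
  if ((int)partner1based.size() != n) stop("partner vector length mismatch");
  std::vector<int> p(n);
  for (int i = 0; i < n; ++i) {
    int q = partner1based[i];
    p[i] = (q == NA_INTEGER || q == 0) ? -1 : q - 1;
  }
  double e = scorePairingVec(s, p);
  if (e == INF) return NA_REAL;
  return e;
}

// ---------------------------------------------------------------------------
// Zuker-style DP. V[i][j]: best energy of structure closed by pair (i,j),
// hairpin/stack/interior only. M adds multibranch segments for the
// unconstrained fold.
// ---------------------------------------------------------------------------
struct FoldTables {
  int n;
  std::vector<double> V;    // closed, no multiloop at this level decided later
  std::vector<double> VM;   // closed including multiloop option
  std::vector<double> M;    // >=1 branch inside a multiloop
  double at(const std::vector<double>& T, int i, int j) const { return T[(size_t)i * n + j]; }
};

static void foldDP(const std::vector<int>& s, bool withMulti, FoldTables& ft) {
  int n = (int)s.size();
  ft.n = n;
  ft.V.assign((size_t)n * n, INF);
  ft.VM.assign((size_t)n * n, INF);
  if (withMulti) ft.M.assign((size_t)n * n, INF);

  for (int d = MIN_LOOP + 1; d < n; ++d) {
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      if (canPair(s[i], s[j])) {
        double best = hairpinEnergy(j - i - 1);
        // interior / stack: inner pair (k, l)
        int kmax = std::min(j - 1, i + 1 + MAX_INTERIOR);
        for (int k = i + 1; k <= kmax; ++k) {
          int lmin = std::max(k + MIN_LOOP + 1, j - 1 - (MAX_INTERIOR - (k - i - 1)));
          for (int l = lmin; l < j; ++l) {
            double inner = ft.VM[(size_t)k * n + l];
            if (inner == INF) continue;
            double cost;
            if (k == i + 1 && l == j - 1)
              cost = stackEnergy(pairStrength(s[i], s[j]), pairStrength(s[k], s[l]));
            else
              cost = interiorEnergy((k - i - 1) + (j - l - 1));
            if (cost == INF) continue;
            if (inner + cost < best) best = inner + cost;
          }
        }
        ft.V[(size_t)i * n + j] = best;
        double bestVM = best;
        if (withMulti && j - i >= 2 * (MIN_LOOP + 2)) {
          // multiloop closing: a + b(closing) + two multi segments
          for (int k = i + 1; k < j - 1; ++k) {
            double m1 = ft.M[(size_t)(i + 1) * n + k];
            double m2 = ft.M[(size_t)(k + 1) * n + (j - 1)];
            if (m1 == INF || m2 == INF) continue;
            double e = MULTI_A + MULTI_BRANCH + m1 + m2;
            if (e < bestVM) bestVM = e;
          }
        }
        ft.VM[(size_t)i * n + j] = bestVM;
      }
      if (withMulti) {
        // M[i][j]
        double best = INF;
        if (j > i) {
          double prev = ft.M[(size_t)i * n + (j - 1)];
          if (prev != INF) best = prev + MULTI_UNPAIRED;
        }
        for (int k = i; k <= j - MIN_LOOP - 1; ++k) {
          double v = ft.VM[(size_t)k * n + j];
          if (v == INF) continue;
          double e = MULTI_BRANCH + MULTI_UNPAIRED * (k - i) + v;
          if (e < best) best = e;
          if (k > i) {
            double m = ft.M[(size_t)i * n + (k - 1)];
            if (m != INF && m + MULTI_BRANCH + v < best) best = m + MULTI_BRANCH + v;
          }
        }
        ft.M[(size_t)i * n + j] = best;
      }
    }
  }
}

// traceback of a closed structure (i,j) using table T (VM for unconstrained,
// V for constrained); fills partner
static void traceClosed(const std::vector<int>& s, const FoldTables& ft, bool withMulti,
                        int i, int j, std::vector<int>& partner);

static void traceM(const std::vector<int>& s, const FoldTables& ft, int i, int j,
                   std::vector<int>& partner) {
  int n = ft.n;
  double target = ft.M[(size_t)i * n + j];
  if (j > i && ft.M[(size_t)i * n + (j - 1)] != INF &&
      std::abs(ft.M[(size_t)i * n + (j - 1)] + MULTI_UNPAIRED - target) < 1e-9) {
    traceM(s, ft, i, j - 1, partner);
    return;
  }
  for (int k = i; k <= j - MIN_LOOP - 1; ++k) {
    double v = ft.VM[(size_t)k * n + j];
    if (v == INF) continue;
    if (std::abs(MULTI_BRANCH + MULTI_UNPAIRED * (k - i) + v - target) < 1e-9) {
      traceClosed(s, ft, true, k, j, partner);
      return;
    }
    if (k > i) {
      double m = ft.M[(size_t)i * n + (k - 1)];
      if (m != INF && std::abs(m + MULTI_BRANCH + v - target) < 1e-9) {
        traceM(s, ft, i, k - 1, partner);
        traceClosed(s, ft, true, k, j, partner);
        return;
      }
    }
  }
  stop("internal error: M traceback failed");
}

static void traceClosed(const std::vector<int>& s, const FoldTables& ft, bool withMulti,
                        int i, int j, std::vector<int>& partner) {
  int n = ft.n;
  partner[i] = j; partner[j] = i;
  double target = withMulti ? ft.VM[(size_t)i * n + j] : ft.V[(size_t)i * n + j];
  if (std::abs(hairpinEnergy(j - i - 1) - target) < 1e-9) return;
  int kmax = std::min(j - 1, i + 1 + MAX_INTERIOR);
  for (int k = i + 1; k <= kmax; ++k) {
    for (int l = std::max(k + MIN_LOOP + 1, j - 1 - (MAX_INTERIOR - (k - i - 1))); l < j; ++l) {
      double inner = withMulti ? ft.VM[(size_t)k * n + l] : ft.V[(size_t)k * n + l];
      if (inner == INF) continue;
      double cost = (k == i + 1 && l == j - 1)
        ? stackEnergy(pairStrength(s[i], s[j]), pairStrength(s[k], s[l]))
        : interiorEnergy((k - i - 1) + (j - l - 1));
      if (cost == INF) continue;
      if (std::abs(inner + cost - target) < 1e-9) {
        traceClosed(s, ft, withMulti, k, l, partner);
        return;
      }
    }
  }
  if (withMulti) {
    for (int k = i + 1; k < j - 1; ++k) {
      double m1 = ft.M[(size_t)(i + 1) * n + k];
      double m2 = ft.M[(size_t)(k + 1) * n + (j - 1)];
      if (m1 == INF || m2 == INF) continue;
      if (std::abs(MULTI_A + MULTI_BRANCH + m1 + m2 - target) < 1e-9) {
        traceM(s, ft, i + 1, k, partner);
        traceM(s, ft, k + 1, j - 1, partner);
        return;
      }
    }
  }
  stop("internal error: traceback failed");
}

static int countHairpinLoops(const std::vector<int>& partner) {
  int n = (int)partner.size(), cnt = 0;
  for (int i = 0; i < n; ++i) {
    int j = partner[i];
    if (j <= i) continue;
    bool leaf = true;
    for (int k = i + 1; k < j; ++k) if (partner[k] != -1) { leaf = false; break; }
    if (leaf) ++cnt;
  }
  return cnt;
}

static IntegerVector partnerOut(const std::vector<int>& partner) {
  int n = (int)partner.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = partner[i] < 0 ? NA_INTEGER : partner[i] + 1;
  return out;
}

static std::string dotBracket(const std::vector<int>& partner) {
  int n = (int)partner.size();
  std::string db(n, '.');
  for (int i = 0; i < n; ++i)
    if (partner[i] > i) { db[i] = '('; db[partner[i]] = ')'; }
  return db;
}

// [[Rcpp::export(name = ".foldCpp")]]
List foldCpp(std::string seq, bool forbidBifurcation,
             bool withUnconstrained = true) {
  std::vector<int> s = encodeSeq(seq);
  int n = (int)s.size();
  if (n < 1) stop("empty sequence");

  // constrained: single stem-loop (one closed structure, no multiloops,
  // external bases outside it unpaired)
  FoldTables ftc;
  foldDP(s, false, ftc);
  double bestC = 0.0; int bi = -1, bj = -1;
  for (int i = 0; i < n; ++i)
    for (int j = i + MIN_LOOP + 1; j < n; ++j) {
      double v = ftc.V[(size_t)i * n + j];
      if (v < bestC) { bestC = v; bi = i; bj = j; }
    }
  std::vector<int> partnerC(n, -1);
  if (bi >= 0) traceClosed(s, ftc, false, bi, bj, partnerC);

  if (!withUnconstrained && forbidBifurcation) {
    return List::create(
      _["dot_bracket"] = dotBracket(partnerC),
      _["energy"] = bestC,
      _["partner"] = partnerOut(partnerC),
      _["bifurcated"] = LogicalVector::create(NA_LOGICAL),
      _["unconstrained_energy"] = NumericVector::create(NA_REAL),
      _["unconstrained_bifurcated"] = LogicalVector::create(NA_LOGICAL),
      _["constrained_energy"] = bestC);
  }

  // unconstrained: full decomposition with multiloops + external splits
  FoldTables ftu;
  foldDP(s, true, ftu);
  std::vector<double> W(n + 1, 0.0);
  std::vector<int> Wtrace(n + 1, -1);  // -1: j unpaired; else start of closing pair
  for (int j = 1; j <= n; ++j) {
    W[j] = W[j - 1]; Wtrace[j] = -1;
    for (int i = 0; i < j - MIN_LOOP; ++i) {
      double v = ftu.VM[(size_t)i * n + (j - 1)];
      if (v == INF) continue;
      if (W[i] + v < W[j]) { W[j] = W[i] + v; Wtrace[j] = i; }
    }
  }
  std::vector<int> partnerU(n, -1);
  int j = n;
  while (j > 0) {
    if (Wtrace[j] == -1) { --j; }
    else { int i = Wtrace[j]; traceClosed(s, ftu, true, i, j - 1, partnerU); j = i; }
  }
  double bestU = W[n];
  bool bifurc = countHairpinLoops(partnerU) > 1;

  const std::vector<int>& partner = forbidBifurcation ? partnerC : partnerU;
  double energy = forbidBifurcation ? bestC : bestU;
  return List::create(
    _["dot_bracket"] = dotBracket(partner),
    _["energy"] = energy,
    _["partner"] = partnerOut(partner),
    _["bifurcated"] = forbidBifurcation ? (countHairpinLoops(partner) > 1) : bifurc,
    _["unconstrained_energy"] = bestU,
    _["unconstrained_bifurcated"] = bifurc,
    _["constrained_energy"] = bestC);
}

// ---------------------------------------------------------------------------
// Brute-force fold reference: enumerate every non-crossing pairing with
// minimum loop 3 and score each with the loop-decomposition scorer.
// Intended for short sequences only.
// ---------------------------------------------------------------------------
struct EnumState {
  const std::vector<int>* s;
  std::vector<int> partner;
  std::vector<int> limits;
  double best;
  long long count;
  long long maxStructures;
};

static void enumRec(EnumState& st, int i) {
  int n = (int)st.s->size();
  if (!st.limits.empty() && i == st.limits.back()) {
    int q = st.limits.back();
    st.limits.pop_back();
    enumRec(st, q + 1);
    st.limits.push_back(q);
    return;
  }
  if (i == n) {
    ++st.count;
    if (st.count > st.maxStructures) stop("structure enumeration limit exceeded");
    double e = scorePairingVec(*st.s, st.partner);
    if (e < st.best) st.best = e;
    return;
  }
  st.partner[i] = -1;
  enumRec(st, i + 1);
  int lim = st.limits.empty() ? n : st.limits.back();
  for (int q = i + MIN_LOOP + 1; q < lim; ++q) {
    if (canPair((*st.s)[i], (*st.s)[q])) {
      st.partner[i] = q; st.partner[q] = i;
      st.limits.push_back(q);
      enumRec(st, i + 1);
      st.limits.pop_back();
      st.partner[q] = -1;
    }
  }
  st.partner[i] = -1;
}

// [[Rcpp::export(name = ".enumFoldMFECpp")]]
double enumFoldMFECpp(std::string seq, double maxStructures = 5e7) {
  EnumState st;
  std::vector<int> s = encodeSeq(seq);
  st.s = &s;
  st.partner.assign(s.size(), -1);
  st.best = 0.0;
  st.count = 0;
  st.maxStructures = (long long)maxStructures;
  enumRec(st, 0);
  return st.best;
}

// ---------------------------------------------------------------------------
// Intermolecular duplex (hybrid-min style): strand a 5'->3' against strand b,
// no intramolecular pairs. b is internally reversed so pairs are strictly
// increasing in both indices.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".duplexCpp")]]
List duplexCpp(std::string mirna, std::string site) {
  std::vector<int> a = encodeSeq(mirna);
  std::string siteRev(site.rbegin(), site.rend());
  std::vector<int> b = encodeSeq(siteRev);
  int n = (int)a.size(), m = (int)b.size();
  std::vector<double> D((size_t)n * m, INF);
  std::vector<int> Pi((size_t)n * m, -2), Pj((size_t)n * m, -2);
  double best = 0.0; int bi = -1, bj = -1;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      if (!canPair(a[i], b[j])) continue;
      double e = 0.0;  // opening pair
      int pi = -1, pj = -1;
      int imin = std::max(0, i - 1 - MAX_INTERIOR);
      for (int i2 = imin; i2 < i; ++i2) {
        int jmin = std::max(0, j - 1 - (MAX_INTERIOR - (i - i2 - 1)));
        for (int j2 = jmin; j2 < j; ++j2) {
          double prev = D[(size_t)i2 * m + j2];
          if (prev == INF) continue;
          int u = (i - i2 - 1) + (j - j2 - 1);
          double cost = (u == 0)
            ? stackEnergy(pairStrength(a[i2], b[j2]), pairStrength(a[i], b[j]))
            : interiorEnergy(u);
          if (cost == INF) continue;
          if (prev + cost < e) { e = prev + cost; pi = i2; pj = j2; }
        }
      }
      D[(size_t)i * m + j] = e;
      Pi[(size_t)i * m + j] = pi; Pj[(size_t)i * m + j] = pj;
      if (e < best) { best = e; bi = i; bj = j; }
    }
  }
  LogicalVector mirnaPaired(n, false);
  LogicalVector mirnaWC(n, false);
  IntegerVector sitePartner(n, NA_INTEGER);  // 1-based position on site, 5'->3'
  int i = bi, j = bj;
  while (i >= 0) {
    mirnaPaired[i] = true;
    mirnaWC[i] = isWatsonCrick(a[i], b[j]);
    sitePartner[i] = (int)site.size() - j;  // reverse back to site coordinates
    int ii = Pi[(size_t)i * m + j], jj = Pj[(size_t)i * m + j];
    i = ii; j = jj;
  }
  return List::create(
    _["energy"] = best,
    _["mirna_paired"] = mirnaPaired,
    _["mirna_wc"] = mirnaWC,
    _["site_partner"] = sitePartner);
}

// Brute-force duplex reference: enumerate all co-linear pair sets.
static void enumDuplexRec(const std::vector<int>& a, const std::vector<int>& b,
                          int lastI, int lastJ, double cur, double& best) {
  int n = (int)a.size(), m = (int)b.size();
  for (int i = lastI + 1; i < n; ++i) {
    for (int j = lastJ + 1; j < m; ++j) {
      if (!canPair(a[i], b[j])) continue;
      double cost;
      if (lastI < 0) cost = 0.0;
      else {
        int u = (i - lastI - 1) + (j - lastJ - 1);
        cost = (u == 0)
          ? stackEnergy(pairStrength(a[lastI], b[lastJ]), pairStrength(a[i], b[j]))
          : interiorEnergy(u);
      }
      if (cost == INF) continue;
      double e = cur + cost;
      if (e < best) best = e;
      enumDuplexRec(a, b, i, j, e, best);
    }
  }
}

// [[Rcpp::export(name = ".enumDuplexMFECpp")]]
double enumDuplexMFECpp(std::string mirna, std::string site) {
  std::vector<int> a = encodeSeq(mirna);
  std::string siteRev(site.rbegin(), site.rend());
  std::vector<int> b = encodeSeq(siteRev);
  double best = 0.0;
  enumDuplexRec(a, b, -1, -1, 0.0, best);
  return best;
}
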