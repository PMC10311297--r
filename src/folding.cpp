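// Exact dynamic programs for the built-in nearest-pair energy model.
//
// Model: a structure's energy is the sum of one term per base pair
// (looked up in a 4x4 table over A,C,G,U; non-finite = disallowed pair)
// plus `stack` for every pair (i,j) whose inner neighbour (i+1,j-1) is
// also paired.  Hairpin loops must enclose at least `hmin` unpaired
// bases (j - i > hmin).
//
// All recursions use the unambiguous "first position unpaired, or first
// position paired to k" decomposition, so the same skeleton yields the
// partition function (sum-product), the MFE (min-plus), the count of
// co-optimal structures, and a zero-slack traceback of the full MFE set.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>
using namespace Rcpp;

static const double E_INF = 1e18;
static const double E_EPS = 1e-9;

struct Model {
  double emat[4][4];
  double stack;
  int hmin;
  double RT;
  bool allowed(int a, int b) const { return R_finite(emat[a][b]); }
};

static Model make_model(const NumericMatrix& emat, double stack, int hmin,
                        double RT) {
  Model m;
  for (int a = 0; a < 4; ++a)
    for (int b = 0; b < 4; ++b) m.emat[a][b] = emat(a, b);
  m.stack = stack;
  m.hmin = hmin;
  m.RT = RT;
  return m;
}

// Flat (n+2)^2 matrix with 1-based indexing; idx(a,b) valid for
// 0 <= a,b <= n+1 so empty-segment cells (a, a-1) exist.
struct Mat {
  int dim;
  std::vector<double> v;
  Mat(int n, double fill) : dim(n + 2), v((n + 2) * (n + 2), fill) {}
  double& operator()(int a, int b) { return v[a * dim + b]; }
  double operator()(int a, int b) const { return v[a * dim + b]; }
};

// ---------------------------------------------------------------------------
// Partition function + base-pair probabilities (inside-outside).
// Per-nucleotide rescaling keeps cells bounded for long sequences.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_partition(IntegerVector seq, NumericMatrix emat, double stack,
                   int hmin, double RT) {
  const int n = seq.size();
  const Model m = make_model(emat, stack, hmin, RT);
  const double s = std::exp(-m.stack / m.RT);

  // scale so the most favourable stacked pair has weight ~1 per nucleotide
  double wmax = 1.0;
  for (int a = 0; a < 4; ++a)
    for (int b = 0; b < 4; ++b)
      if (m.allowed(a, b)) wmax = std::max(wmax, std::exp(-m.emat[a][b] / m.RT));
  const double K = std::max(1.0, std::sqrt(wmax * std::max(s, 1.0)));
  const double logK = std::log(K);

  Mat Q(n, 0.0), Qb(n, 0.0);
  for (int a = 1; a <= n + 1; ++a) Q(a, a - 1) = 1.0;  // empty segments

  for (int len = 1; len <= n; ++len) {
    for (int i = 1; i + len - 1 <= n; ++i) {
      const int j = i + len - 1;
      if (j - i > m.hmin && m.allowed(seq[i - 1], seq[j - 1])) {
        const double w2 =
            std::exp(-m.emat[seq[i - 1]][seq[j - 1]] / m.RT) / (K * K);
        Qb(i, j) = w2 * (Q(i + 1, j - 1) + (s - 1.0) * Qb(i + 1, j - 1));
      }
      double acc = Q(i + 1, j) / K;
      for (int k = i + m.hmin + 1; k <= j; ++k)
        acc += Qb(i, k) * Q(k + 1, j);
      Q(i, j) = acc;
    }
  }

  const double Qtot = Q(1, n);
  if (!(Qtot > 0.0)) stop("partition function underflow");
  const double logQ = std::log(Qtot) + n * logK;

  // outside pass
  Mat O(n, 0.0), Ob(n, 0.0);
  O(1, n) = 1.0;
  for (int len = n; len >= 1; --len) {
    for (int i = 1; i + len - 1 <= n; ++i) {
      const int j = i + len - 1;
      const double o = O(i, j);
      if (o != 0.0) {
        if (i < j) O(i + 1, j) += o / K;
        for (int k = i + m.hmin + 1; k <= j; ++k) {
          if (Qb(i, k) == 0.0) continue;
          Ob(i, k) += o * Q(k + 1, j);
          if (k < j) O(k + 1, j) += o * Qb(i, k);
        }
      }
      const double ob = Ob(i, j);
      if (ob != 0.0 && Qb(i, j) != 0.0) {
        const double w2 =
            std::exp(-m.emat[seq[i - 1]][seq[j - 1]] / m.RT) / (K * K);
        if (i + 1 <= j - 1) {
          O(i + 1, j - 1) += ob * w2;
          Ob(i + 1, j - 1) += ob * w2 * (s - 1.0);
        }
      }
    }
  }

  NumericMatrix bpp(n, n);
  NumericVector q(n, 1.0);
  for (int i = 1; i <= n; ++i) {
    for (int j = i + 1; j <= n; ++j) {
      if (Qb(i, j) == 0.0) continue;
      double p = Qb(i, j) * Ob(i, j) / Qtot;
      if (p < 0.0) p = 0.0;
      if (p > 1.0) p = 1.0;
      bpp(i - 1, j - 1) = p;
      bpp(j - 1, i - 1) = p;
      q[i - 1] -= p;
      q[j - 1] -= p;
    }
  }
  for (int i = 0; i < n; ++i)
    if (q[i] < 0.0 && q[i] > -1e-9) q[i] = 0.0;

  return List::create(_["logQ"] = logQ, _["bpp"] = bpp, _["unpaired"] = q);
}

// ---------------------------------------------------------------------------
// MFE: minimum energy, number of co-optimal structures, full MFE set.
// ---------------------------------------------------------------------------

struct MfeTables {
  int n;
  Model m;
  const int* x;      // 0-based base codes
  Mat E, Eb, Enp;    // segment min, pair-closed min, segment min w/o (i,j) pair
  Mat N, Nb, Nnp;    // co-optimal counts for the same three states
  MfeTables(int n_, const Model& m_, const int* x_)
      : n(n_), m(m_), x(x_), E(n_, 0.0), Eb(n_, E_INF), Enp(n_, 0.0),
        N(n_, 1.0), Nb(n_, 0.0), Nnp(n_, 1.0) {}

  double pe(int i, int j) const { return m.emat[x[i - 1]][x[j - 1]]; }
  bool ok(int i, int j) const {
    return j - i > m.hmin && m.allowed(x[i - 1], x[j - 1]);
  }

  void fill() {
    for (int a = 1; a <= n + 1; ++a) {
      E(a, a - 1) = 0.0; Enp(a, a - 1) = 0.0;
      N(a, a - 1) = 1.0; Nnp(a, a - 1) = 1.0;
    }
    for (int len = 1; len <= n; ++len) {
      for (int i = 1; i + len - 1 <= n; ++i) {
        const int j = i + len - 1;
        if (ok(i, j)) {
          double best = E_INF, cnt = 0.0;
          const double e_open = Enp(i + 1, j - 1);          // inner not stacked
          const double e_stk = (Eb(i + 1, j - 1) < E_INF / 2)
                                   ? m.stack + Eb(i + 1, j - 1)
                                   : E_INF;
          best = std::min(e_open, e_stk);
          if (e_open < best + E_EPS) cnt += Nnp(i + 1, j - 1);
          if (e_stk < best + E_EPS) cnt += Nb(i + 1, j - 1);
          Eb(i, j) = pe(i, j) + best;
          Nb(i, j) = cnt;
        }
        // segment minimum, excluding then including the (i,j) pair
        double best = E(i + 1, j), cnt = 0.0;
        for (int k = i + m.hmin + 1; k < j; ++k)
          if (Eb(i, k) < E_INF / 2)
            best = std::min(best, Eb(i, k) + E(k + 1, j));
        if (E(i + 1, j) < best + E_EPS) cnt += N(i + 1, j);
        for (int k = i + m.hmin + 1; k < j; ++k)
          if (Eb(i, k) < E_INF / 2 && Eb(i, k) + E(k + 1, j) < best + E_EPS)
            cnt += Nb(i, k) * N(k + 1, j);
        Enp(i, j) = best;
        Nnp(i, j) = cnt;
        double full = best, fcnt = cnt;
        if (Eb(i, j) < E_INF / 2 && Eb(i, j) < full + E_EPS) {
          if (Eb(i, j) < full - E_EPS) { full = Eb(i, j); fcnt = 0.0; }
          fcnt += Nb(i, j);
        }
        E(i, j) = full;
        N(i, j) = fcnt;
      }
    }
  }
};

typedef std::vector<std::vector<int> > PartnerSet;  // 1-based partners, 0 = unpaired

static void cross(const PartnerSet& a, const PartnerSet& b, PartnerSet& out,
                  double cap) {
  for (size_t u = 0; u < a.size(); ++u)
    for (size_t v = 0; v < b.size(); ++v) {
      std::vector<int> merged = a[u];
      for (size_t t = 0; t < merged.size(); ++t)
        if (merged[t] == 0 && b[v][t] != 0) merged[t] = b[v][t];
      out.push_back(merged);
      if (out.size() > (size_t)cap) stop("MFE set larger than traceback cap");
    }
}

// modes: 0 = segment, 1 = pair-closed, 2 = segment without the (i,j) pair
static PartnerSet trace(const MfeTables& T, int i, int j, int mode, double cap) {
  PartnerSet out;
  if (i > j) {
    out.push_back(std::vector<int>(T.n, 0));
    return out;
  }
  if (mode == 1) {
    const double target = T.Eb(i, j) - T.pe(i, j);
    if (T.Enp(i + 1, j - 1) < target + E_EPS) {
      PartnerSet sub = trace(T, i + 1, j - 1, 2, cap);
      for (size_t u = 0; u < sub.size(); ++u) {
        sub[u][i - 1] = j; sub[u][j - 1] = i;
        out.push_back(sub[u]);
        if (out.size() > (size_t)cap) stop("MFE set larger than traceback cap");
      }
    }
    if (T.Eb(i + 1, j - 1) < E_INF / 2 &&
        T.m.stack + T.Eb(i + 1, j - 1) < target + E_EPS) {
      PartnerSet sub = trace(T, i + 1, j - 1, 1, cap);
      for (size_t u = 0; u < sub.size(); ++u) {
        sub[u][i - 1] = j; sub[u][j - 1] = i;
        out.push_back(sub[u]);
        if (out.size() > (size_t)cap) stop("MFE set larger than traceback cap");
      }
    }
    return out;
  }
  const double target = (mode == 0) ? T.E(i, j) : T.Enp(i, j);
  if (T.E(i + 1, j) < target + E_EPS) {
    PartnerSet sub = trace(T, i + 1, j, 0, cap);
    for (size_t u = 0; u < sub.size(); ++u) {
      out.push_back(sub[u]);
      if (out.size() > (size_t)cap) stop("MFE set larger than traceback cap");
    }
  }
  const int kmax = (mode == 0) ? j : j - 1;
  for (int k = i + T.m.hmin + 1; k <= kmax; ++k) {
    if (T.Eb(i, k) >= E_INF / 2) continue;
    if (T.Eb(i, k) + T.E(k + 1, j) < target + E_EPS) {
      PartnerSet left = trace(T, i, k, 1, cap);
      PartnerSet right = trace(T, k + 1, j, 0, cap);
      cross(left, right, out, cap);
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_mfe(IntegerVector seq, NumericMatrix emat, double stack, int hmin,
             double RT, bool traceback, double cap) {
  const int n = seq.size();
  const Model m = make_model(emat, stack, hmin, RT);
  std::vector<int> x(seq.begin(), seq.end());
  MfeTables T(n, m, x.data());
  T.fill();
  const double emin = T.E(1, n);
  const double count = T.N(1, n);

  CharacterVector structs;
  if (traceback) {
    PartnerSet set = trace(T, 1, n, 0, cap);
    structs = CharacterVector(set.size());
    for (size_t u = 0; u < set.size(); ++u) {
      std::string db(n, '.');
      for (int t = 0; t < n; ++t) {
        if (set[u][t] > t + 1) db[t] = '(';
        else if (set[u][t] != 0) db[t] = ')';
      }
      structs[u] = db;
    }
  }
  return List::create(_["emin"] = emin, _["n_optimal"] = count,
                      _["structures"] = structs);
}
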