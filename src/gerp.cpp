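#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <limits>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Phylogenetic likelihood machinery.
//
// Trees arrive as a postorder edge list (child before the edge leading to its
// own parent), nodes numbered 1..nnode with leaves 1..ntip, plus the root id.
// The HKY85 model arrives pre-eigendecomposed: P(t) = V1 diag(exp(lam t)) V2,
// with V1 = D^{-1/2} U, V2 = U' D^{1/2}, D = diag(stationary frequencies).
//
// Missing leaves (state -1) carry an all-ones partial vector, which under a
// reversible model marginalizes them out exactly: the likelihood equals that
// of the tree with those leaves projected out, for every rescaling r, because
// rescaling acts uniformly on all branches.  Edges whose entire subtree is
// missing are skipped (their message is identically one).
// ---------------------------------------------------------------------------

struct TreeModel {
  int ntip, nnode, root;
  const int *parent, *child;   // 1-based node ids, postorder
  const double *elen;
  int nedge;
  const double *V1, *V2;       // 4x4 column-major
  const double *lam;           // 4 eigenvalues
  const double *pi;            // 4 stationary frequencies
};

// likelihood of one column (states: length ntip, values 0..3 or -1) under the
// tree with every branch multiplied by r.  cnt[node] = number of observed
// leaves below node (precomputed by caller); npres = total observed leaves.
static double column_lik(const TreeModel &tm, const int *states,
                         const int *cnt, int npres, double r) {
  std::vector<double> part(4 * (tm.nnode + 1));
  std::vector<bool> init(tm.nnode + 1, false);
  for (int i = 1; i <= tm.ntip; ++i) {
    double *p = &part[4 * i];
    if (states[i - 1] >= 0) {
      p[0] = p[1] = p[2] = p[3] = 0.0;
      p[states[i - 1]] = 1.0;
    } else {
      p[0] = p[1] = p[2] = p[3] = 1.0;
    }
    init[i] = true;
  }
  for (int n = tm.ntip + 1; n <= tm.nnode; ++n) {
    double *p = &part[4 * n];
    p[0] = p[1] = p[2] = p[3] = 1.0;
  }
  for (int e = 0; e < tm.nedge; ++e) {
    int c = tm.child[e], pnode = tm.parent[e];
    if (cnt[c] == 0) continue;            // fully missing subtree: message = 1
    const double *pc = &part[4 * c];
    double *pp = &part[4 * pnode];
    double t = r * tm.elen[e];
    double m[4];
    if (t == 0.0) {
      m[0] = pc[0]; m[1] = pc[1]; m[2] = pc[2]; m[3] = pc[3];
    } else {
      double w[4];
      for (int k = 0; k < 4; ++k) {
        double s = 0.0;
        for (int b = 0; b < 4; ++b) s += tm.V2[k + 4 * b] * pc[b];
        w[k] = std::exp(tm.lam[k] * t) * s;
      }
      for (int a = 0; a < 4; ++a) {
        double s = 0.0;
        for (int k = 0; k < 4; ++k) s += tm.V1[a + 4 * k] * w[k];
        m[a] = s;
      }
    }
    pp[0] *= m[0]; pp[1] *= m[1]; pp[2] *= m[2]; pp[3] *= m[3];
  }
  const double *pr = &part[4 * tm.root];
  double L = 0.0;
  for (int a = 0; a < 4; ++a) L += tm.pi[a] * pr[a];
  return L;
}

// Classical Brent bounded minimization (golden section + successive parabolic
// interpolation), absolute tolerance on the argument.
template <typename F>
static double brent_min(double a, double b, F f, double tol, double &fout) {
  const double gold = 0.3819660112501051;
  double x, w, v, fx, fw, fv, d = 0.0, e = 0.0;
  x = w = v = a + gold * (b - a);
  fx = fw = fv = f(x);
  for (int it = 0; it < 200; ++it) {
    double m = 0.5 * (a + b);
    double tol1 = tol, tol2 = 2.0 * tol;
    if (std::fabs(x - m) <= tol2 - 0.5 * (b - a)) break;
    bool golden = true;
    if (std::fabs(e) > tol1) {
      double rr = (x - w) * (fx - fv);
      double q = (x - v) * (fx - fw);
      double p = (x - v) * q - (x - w) * rr;
      q = 2.0 * (q - rr);
      if (q > 0.0) p = -p;
      q = std::fabs(q);
      double etemp = e;
      e = d;
      if (!(std::fabs(p) >= std::fabs(0.5 * q * etemp) ||
            p <= q * (a - x) || p >= q * (b - x))) {
        d = p / q;
        double u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (m > x) ? tol1 : -tol1;
        golden = false;
      }
    }
    if (golden) {
      e = (x >= m) ? a - x : b - x;
      d = gold * e;
    }
    double u = (std::fabs(d) >= tol1) ? x + d : x + ((d > 0) ? tol1 : -tol1);
    double fu = f(u);
    if (fu <= fx) {
      if (u >= x) a = x; else b = x;
      v = w; fv = fw; w = x; fw = fx; x = u; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu <= fw || w == x) { v = w; fv = fw; w = u; fw = fu; }
      else if (fu <= fv || v == x || v == w) { v = u; fv = fu; }
    }
  }
  fout = fx;
  return x;
}

static TreeModel make_tm(const IntegerVector &parent, const IntegerVector &child,
                         const NumericVector &elen, int ntip, int nnode, int root,
                         const NumericMatrix &V1, const NumericMatrix &V2,
                         const NumericVector &lam, const NumericVector &pi) {
  TreeModel tm;
  tm.ntip = ntip; tm.nnode = nnode; tm.root = root;
  tm.parent = INTEGER(parent); tm.child = INTEGER(child);
  tm.elen = REAL(elen); tm.nedge = child.size();
  tm.V1 = REAL(V1); tm.V2 = REAL(V2);
  tm.lam = REAL(lam); tm.pi = REAL(pi);
  return tm;
}

// [[Rcpp::export]]
double cpp_column_likelihood(IntegerVector states, double r,
                             IntegerVector parent, IntegerVector child,
                             NumericVector elen, int ntip, int nnode, int root,
                             NumericMatrix V1, NumericMatrix V2,
                             NumericVector lam, NumericVector pi) {
  std::vector<int> cnt(nnode + 1, 0);
  int npres = 0;
  for (int i = 0; i < ntip; ++i)
    if (states[i] >= 0) { cnt[i + 1] = 1; ++npres; }
  for (int e = 0; e < child.size(); ++e) cnt[parent[e]] += cnt[child[e]];
  TreeModel tm = make_tm(parent, child, elen, ntip, nnode, root, V1, V2, lam, pi);
  return column_lik(tm, INTEGER(states), cnt.data(), npres, r);
}

// Per-column scoring: neutral rate of the induced subtree, ML rescaling rhat
// on [0, rmax] by Brent on the negative log-likelihood (endpoints compared
// explicitly so boundary optima are returned exactly), RS = n * (1 - rhat).
// Columns with fewer than 3 observed species get the unscored sentinel.
// [[Rcpp::export]]
NumericMatrix cpp_score_columns(IntegerMatrix states,
                                IntegerVector parent, IntegerVector child,
                                NumericVector elen, int ntip, int nnode, int root,
                                NumericMatrix V1, NumericMatrix V2,
                                NumericVector lam, NumericVector pi,
                                double rmax, double rtol) {
  int m = states.ncol();
  int nedge = child.size();
  NumericMatrix out(m, 4);  // n, rhat, rs, scored
  colnames(out) = CharacterVector::create("neutral_rate", "rescaling",
                                          "rs", "scored");
  TreeModel tm = make_tm(parent, child, elen, ntip, nnode, root, V1, V2, lam, pi);
  std::vector<int> cnt(nnode + 1), col(ntip);
  const double inf = std::numeric_limits<double>::infinity();
  for (int j = 0; j < m; ++j) {
    std::fill(cnt.begin(), cnt.end(), 0);
    int npres = 0;
    for (int i = 0; i < ntip; ++i) {
      col[i] = states(i, j);
      if (col[i] >= 0) { cnt[i + 1] = 1; ++npres; }
    }
    if (npres < 3) {
      out(j, 0) = 0.0; out(j, 1) = NA_REAL; out(j, 2) = 0.0; out(j, 3) = 0.0;
      continue;
    }
    for (int e = 0; e < nedge; ++e) cnt[parent[e]] += cnt[child[e]];
    double n = 0.0;
    for (int e = 0; e < nedge; ++e) {
      int cb = cnt[child[e]];
      if (cb > 0 && cb < npres) n += elen[e];
    }
    auto nll = [&](double r) {
      double L = column_lik(tm, col.data(), cnt.data(), npres, r);
      return (L > 0.0) ? -std::log(L) : inf;
    };
    double fhat;
    double rhat = brent_min(0.0, rmax, nll, rtol, fhat);
    double f0 = nll(0.0), fmax = nll(rmax);
    if (f0 <= fhat && f0 <= fmax) { rhat = 0.0; }
    else if (fmax <= fhat) { rhat = rmax; }
    out(j, 0) = n;
    out(j, 1) = rhat;
    out(j, 2) = n * (1.0 - rhat);
    out(j, 3) = 1.0;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Dynamic-programming p-values for sums of i.i.d. draws from a discretized
// score distribution.  probs[i] is the probability of score index (kmin + i)
// (score = index * tol).  The pmf of the L-fold sum is built by iterated
// convolution; bins whose probability underflows to zero are trimmed from
// both ends (they cannot affect any representable tail).  For each queried
// (L, S) the tail Pr(sum >= S) is read off a suffix cumulative sum.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_pvalue_batch(NumericVector probs, int kmin, double tol,
                               IntegerVector L, NumericVector S) {
  int nq = L.size();
  NumericVector out(nq);
  if (nq == 0) return out;
  int B = probs.size();
  std::vector<int> ord(nq);
  for (int i = 0; i < nq; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return L[a] < L[b]; });
  std::vector<double> dp(probs.begin(), probs.end());
  long base = kmin;       // score index of dp[0]
  double dropped = 0.0;   // probability mass trimmed below dp[0]
  // Trimming budget: bins far below the bulk may be dropped as long as the
  // total dropped mass stays below this; any tail probability is then exact
  // to within the budget (queried scores always sit above the trimmed
  // range, since candidates are pruned to non-negative score slopes).
  const double drop_budget = 1e-30;
  int curL = 1;
  std::vector<double> nd, suf;
  const double *pr = REAL(probs);
  int qi = 0;
  while (qi < nq) {
    int Lt = L[ord[qi]];
    if (Lt < 1) stop("element length must be >= 1");
    while (curL < Lt) {
      int len = dp.size();
      nd.assign(len + B - 1, 0.0);
      double *ndp = nd.data();
      const double *dpp = dp.data();
      for (int i = 0; i < len; ++i) {
        double di = dpp[i];
        if (di == 0.0) continue;
        double *o = ndp + i;
        for (int b = 0; b < B; ++b) o[b] += di * pr[b];
      }
      base += kmin;
      int lo = 0, hi = (int)nd.size();
      while (lo < hi && nd[lo] == 0.0) ++lo;
      while (hi > lo && nd[hi - 1] == 0.0) --hi;
      while (lo < hi && dropped + nd[lo] < drop_budget) dropped += nd[lo++];
      dp.assign(nd.begin() + lo, nd.begin() + hi);
      base += lo;
      ++curL;
    }
    int len = dp.size();
    suf.assign(len + 1, 0.0);
    for (int i = len - 1; i >= 0; --i) suf[i] = suf[i + 1] + dp[i];
    while (qi < nq && L[ord[qi]] == Lt) {
      double s = S[ord[qi]];
      long mq = (long)std::ceil(s / tol - 1e-6);
      long idx = mq - base;
      double p;
      if (idx <= 0) p = 1.0;
      else if (idx >= len) p = 0.0;
      else p = suf[idx];
      if (p > 1.0) p = 1.0;
      if (p < 0.0) p = 0.0;
      out[ord[qi]] = p;
      ++qi;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Candidate element enumeration.  Within each maximal segment of usable
// positions, candidates run from the start of any maximal non-negative run to
// the end of any (same or later) maximal non-negative run in that segment,
// with length in [minL, maxL] and score >= slope * length.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_enumerate_candidates(NumericVector eff, LogicalVector usable,
                              int minL, int maxL, double slope) {
  int n = eff.size();
  std::vector<double> pref(n + 1, 0.0);
  for (int i = 0; i < n; ++i)
    pref[i + 1] = pref[i] + (usable[i] ? eff[i] : 0.0);
  std::vector<int> starts, ends;
  std::vector<double> scores;
  int i = 0;
  while (i < n) {
    if (!usable[i]) { ++i; continue; }
    int segs = i;
    while (i < n && usable[i]) ++i;
    int sege = i;  // segment [segs, sege)
    // maximal runs of eff >= 0 within the segment
    std::vector<int> rs_, re_;
    int j = segs;
    while (j < sege) {
      if (eff[j] >= 0.0) {
        int r0 = j;
        while (j < sege && eff[j] >= 0.0) ++j;
        rs_.push_back(r0);
        re_.push_back(j);
      } else ++j;
    }
    int nr = rs_.size();
    for (int a = 0; a < nr; ++a) {
      for (int b = a; b < nr; ++b) {
        int Lab = re_[b] - rs_[a];
        if (Lab > maxL) break;  // run ends grow with b
        if (Lab < minL) continue;
        double sc = pref[re_[b]] - pref[rs_[a]];
        if (sc >= slope * Lab - 1e-12) {
          starts.push_back(rs_[a]);
          ends.push_back(re_[b]);
          scores.push_back(sc);
        }
      }
    }
  }
  return List::create(_["start"] = IntegerVector(starts.begin(), starts.end()),
                      _["end"] = IntegerVector(ends.begin(), ends.end()),
                      _["score"] = NumericVector(scores.begin(), scores.end()));
}

// Greedy non-overlapping selection.  ord gives candidate indices (0-based) in
// acceptance order (ascending p-value, ties already broken); returns logical
// acceptance flags.  span is the region length; start/end are 0-based
// half-open offsets within the region.
// [[Rcpp::export]]
LogicalVector cpp_greedy_select(IntegerVector start, IntegerVector end,
                                IntegerVector ord, int span) {
  int nc = start.size();
  LogicalVector acc(nc, false);
  std::vector<bool> covered(span, false);
  for (int k = 0; k < ord.size(); ++k) {
    int i = ord[k];
    int s = start[i], e = end[i];
    bool free = true;
    for (int j = s; j < e; ++j)
      if (covered[j]) { free = false; break; }
    if (!free) continue;
    for (int j = s; j < e; ++j) covered[j] = true;
    acc[i] = true;
  }
  return acc;
}
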