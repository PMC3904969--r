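// Core numerical engine: linear (Wagner) parsimony on a fixed rooted tree,
// least-median-of-squares (LMS) regression by elemental-subset search,
// correlation-based feature selection (CFS), and the branch-wise
// trait-association pipeline (leave-one-species-out + permutations).
//
// Everything here is deterministic given the seed passed from R.

#include <RcppArmadillo.h>
#include <random>
#include <algorithm>
#include <vector>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---------- small helpers ----------

// median with R's convention (mean of the two central order statistics
// for even n); v is modified.
static double median_destructive(std::vector<double> &v) {
  const size_t n = v.size();
  if (n == 0) return NA_REAL;
  const size_t h = n / 2;
  std::nth_element(v.begin(), v.begin() + h, v.end());
  double m = v[h];
  if (n % 2 == 0) {
    double lo = *std::max_element(v.begin(), v.begin() + h);
    m = (m + lo) / 2.0;
  }
  return m;
}

static double pearson(const std::vector<double> &a, const std::vector<double> &b) {
  const size_t n = a.size();
  double ma = 0, mb = 0;
  for (size_t i = 0; i < n; ++i) { ma += a[i]; mb += b[i]; }
  ma /= n; mb /= n;
  double sab = 0, saa = 0, sbb = 0;
  for (size_t i = 0; i < n; ++i) {
    const double da = a[i] - ma, db = b[i] - mb;
    sab += da * db; saa += da * da; sbb += db * db;
  }
  if (saa <= 0 || sbb <= 0) return 0.0;
  return sab / std::sqrt(saa * sbb);
}

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// ---------- Wagner (linear) parsimony ----------
//
// Up-pass: each node carries an interval of optimal states.  For a node
// with informative child intervals I_1..I_k, the optimal states are the
// median interval of the 2k endpoints and the added cost is the summed
// distance from that interval to the child intervals.  This is exact for
// arbitrary multifurcations because each child's cost function, after
// convolution with the |child - parent| branch penalty, equals
// cost_c + dist(x, I_c) (slopes outside the optimum are >= 1).
// Missing tips are uninformative: no constraint, no cost; they inherit
// the parent's value on the down-pass.

struct WagnerResult {
  std::vector<double> value; // per node, resolved
  double cost;
  double root_lo, root_hi;
  int n_informative;
  bool ok;
};

struct WagnerWork {
  std::vector<double> lo, hi, cst;
  std::vector<char> inf, fin;
  std::vector<std::vector<double>> clo, chi;
};

// edges: 0-based parent/child arrays in postorder (children before parents)
static void wagner_run(const int *ep, const int *ec, int n_edge,
                       int n_tip, int n_node,
                       const double *tip, WagnerWork &W, WagnerResult &out) {
  W.lo.assign(n_node, 0.0); W.hi.assign(n_node, 0.0);
  W.cst.assign(n_node, 0.0);
  W.inf.assign(n_node, 0); W.fin.assign(n_node, 0);
  if ((int)W.clo.size() != n_node) { W.clo.resize(n_node); W.chi.resize(n_node); }
  for (int i = 0; i < n_node; ++i) { W.clo[i].clear(); W.chi[i].clear(); }

  out.n_informative = 0;
  for (int i = 0; i < n_tip; ++i) {
    W.fin[i] = 1;
    if (std::isfinite(tip[i])) {
      W.lo[i] = W.hi[i] = tip[i];
      W.inf[i] = 1;
      ++out.n_informative;
    }
  }

  std::vector<double> endp;
  auto finalize = [&](int p) {
    if (W.fin[p]) return;
    W.fin[p] = 1;
    const size_t k = W.clo[p].size();
    if (k == 0) { W.inf[p] = 0; return; }
    endp.clear();
    for (size_t j = 0; j < k; ++j) { endp.push_back(W.clo[p][j]); endp.push_back(W.chi[p][j]); }
    std::sort(endp.begin(), endp.end());
    const double l = endp[k - 1], h = endp[k];
    double extra = 0;
    for (size_t j = 0; j < k; ++j) {
      if (l < W.clo[p][j]) extra += W.clo[p][j] - l;
      else if (l > W.chi[p][j]) extra += l - W.chi[p][j];
    }
    W.lo[p] = l; W.hi[p] = h;
    W.cst[p] += extra;
    W.inf[p] = 1;
  };

  for (int i = 0; i < n_edge; ++i) {
    const int p = ep[i], c = ec[i];
    finalize(c);
    W.cst[p] += W.cst[c];
    if (W.inf[c]) { W.clo[p].push_back(W.lo[c]); W.chi[p].push_back(W.hi[c]); }
  }
  const int root = ep[n_edge - 1];
  finalize(root);

  out.ok = W.inf[root] != 0;
  out.value.assign(n_node, NA_REAL);
  out.cost = NA_REAL; out.root_lo = NA_REAL; out.root_hi = NA_REAL;
  if (!out.ok) return;

  out.cost = W.cst[root];
  out.root_lo = W.lo[root]; out.root_hi = W.hi[root];
  out.value[root] = (W.lo[root] + W.hi[root]) / 2.0; // midpoint resolution
  for (int i = n_edge - 1; i >= 0; --i) {            // preorder
    const int p = ep[i], c = ec[i];
    out.value[c] = W.inf[c] ? clampd(out.value[p], W.lo[c], W.hi[c])
                            : out.value[p];
  }
}

// [[Rcpp::export]]
List cpp_wagner(IntegerVector edge_parent, IntegerVector edge_child,
                int n_tip, int n_node, NumericVector tip_values) {
  const int n_edge = edge_parent.size();
  std::vector<int> ep(n_edge), ec(n_edge);
  for (int i = 0; i < n_edge; ++i) { ep[i] = edge_parent[i] - 1; ec[i] = edge_child[i] - 1; }
  std::vector<double> tv(n_tip);
  for (int i = 0; i < n_tip; ++i)
    tv[i] = NumericVector::is_na(tip_values[i]) ? NAN : tip_values[i];
  WagnerWork W; WagnerResult res;
  wagner_run(ep.data(), ec.data(), n_edge, n_tip, n_node, tv.data(), W, res);
  return List::create(
    _["values"] = NumericVector(res.value.begin(), res.value.end()),
    _["cost"] = res.cost,
    _["root_interval"] = NumericVector::create(res.root_lo, res.root_hi),
    _["n_informative"] = res.n_informative);
}

// [[Rcpp::export]]
List cpp_wagner_matrix(IntegerVector edge_parent, IntegerVector edge_child,
                       int n_tip, int n_node, NumericMatrix tip_values) {
  const int n_edge = edge_parent.size(), n_char = tip_values.ncol();
  std::vector<int> ep(n_edge), ec(n_edge);
  for (int i = 0; i < n_edge; ++i) { ep[i] = edge_parent[i] - 1; ec[i] = edge_child[i] - 1; }
  NumericMatrix values(n_node, n_char);
  NumericVector cost(n_char), rlo(n_char), rhi(n_char);
  WagnerWork W; WagnerResult res;
  std::vector<double> tv(n_tip);
  for (int ch = 0; ch < n_char; ++ch) {
    for (int i = 0; i < n_tip; ++i) {
      const double x = tip_values(i, ch);
      tv[i] = NumericMatrix::is_na(x) ? NAN : x;
    }
    wagner_run(ep.data(), ec.data(), n_edge, n_tip, n_node, tv.data(), W, res);
    for (int i = 0; i < n_node; ++i) values(i, ch) = res.value[i];
    cost[ch] = res.cost; rlo[ch] = res.root_lo; rhi[ch] = res.root_hi;
  }
  return List::create(_["values"] = values, _["cost"] = cost,
                      _["root_lo"] = rlo, _["root_hi"] = rhi);
}

// ---------- LMS regression ----------

struct LmsFit {
  arma::vec coef; // intercept first
  double crit;
  bool ok;
};

// intercept-only LMS: midpoint of the shortest half of y
static LmsFit lms_intercept_only(const arma::vec &y) {
  LmsFit f; f.coef = arma::vec(1); f.ok = true;
  const int n = y.n_elem;
  std::vector<double> s(y.begin(), y.end());
  std::sort(s.begin(), s.end());
  const int h = n / 2 + 1;
  double best = std::numeric_limits<double>::infinity(), c = s[0];
  if (h > n) { c = s[0]; }
  else {
    for (int i = 0; i + h <= n; ++i) {
      const double w = s[i + h - 1] - s[i];
      if (w < best) { best = w; c = (s[i] + s[i + h - 1]) / 2.0; }
    }
  }
  f.coef[0] = c;
  std::vector<double> r2(n);
  for (int i = 0; i < n; ++i) { const double d = y[i] - c; r2[i] = d * d; }
  f.crit = median_destructive(r2);
  return f;
}

// reusable buffers for the subset search: the association engine calls
// LMS tens of thousands of times per permutation test
struct LmsWork {
  std::vector<double> A, As, ys, b, bbest, r2;
  std::vector<int> idx;
};

// LMS by elemental subsets: exact fits on (p+1)-point subsamples, keep the
// one minimizing the median squared residual over all rows.  Exhaustive
// when the number of subsets fits within nsamp, otherwise seeded random
// subsets (degenerate subsets are skipped and redrawn).  X is n x p,
// column-major; all hot-loop work happens on raw buffers.
static LmsFit lms_core(const double *X, int n, int p, const double *y,
                       int nsamp, std::mt19937_64 &rng, LmsWork &wk) {
  const int m = p + 1;
  if (p == 0 || n <= m) return lms_intercept_only(arma::vec(y, n));

  wk.A.resize((size_t)n * m);
  for (int i = 0; i < n; ++i) wk.A[i] = 1.0;
  std::copy(X, X + (size_t)n * p, wk.A.begin() + n);
  wk.As.resize((size_t)m * m);
  wk.ys.resize(m); wk.b.resize(m); wk.r2.resize(n); wk.idx.resize(m);
  double *A = wk.A.data(), *As = wk.As.data(), *ys = wk.ys.data(),
         *b = wk.b.data();

  double ncomb = 1.0;
  for (int i = 0; i < m; ++i) ncomb = ncomb * (n - i) / (i + 1);
  const bool exhaustive = ncomb <= (double)nsamp;

  double best_crit = std::numeric_limits<double>::infinity();
  bool any = false;
  wk.bbest.resize(m);
  std::vector<int> &idx = wk.idx;

  // in-place Gaussian elimination with partial pivoting (m x m,
  // column-major): LAPACK call overhead dwarfs the arithmetic here
  auto solve_small = [&]() -> bool {
    for (int c = 0; c < m; ++c) {
      double *col = As + (size_t)c * m;
      int piv = c;
      double mx = std::fabs(col[c]);
      for (int r = c + 1; r < m; ++r) {
        const double a2 = std::fabs(col[r]);
        if (a2 > mx) { mx = a2; piv = r; }
      }
      if (mx < 1e-10) return false;
      if (piv != c) {
        for (int c2 = c; c2 < m; ++c2) std::swap(As[c2 * m + piv], As[c2 * m + c]);
        std::swap(ys[piv], ys[c]);
      }
      const double inv = 1.0 / col[c];
      for (int r = c + 1; r < m; ++r) {
        const double f = col[r] * inv;
        if (f == 0.0) continue;
        for (int c2 = c + 1; c2 < m; ++c2) As[c2 * m + r] -= f * As[c2 * m + c];
        ys[r] -= f * ys[c];
      }
    }
    for (int c = m - 1; c >= 0; --c) {
      double s = ys[c];
      for (int c2 = c + 1; c2 < m; ++c2) s -= As[c2 * m + c] * b[c2];
      b[c] = s / As[c * m + c];
      if (!std::isfinite(b[c])) return false;
    }
    return true;
  };

  auto try_subset = [&]() -> bool {
    for (int j = 0; j < m; ++j) {
      const double *acol = A + (size_t)j * n;
      double *scol = As + (size_t)j * m;
      for (int i = 0; i < m; ++i) scol[i] = acol[idx[i]];
    }
    for (int i = 0; i < m; ++i) ys[i] = y[idx[i]];
    if (!solve_small()) return false;
    double *r2 = wk.r2.data();
    for (int i = 0; i < n; ++i) r2[i] = y[i] - b[0];
    for (int j = 1; j < m; ++j) {
      const double *acol = A + (size_t)j * n;
      const double bj = b[j];
      for (int i = 0; i < n; ++i) r2[i] -= bj * acol[i];
    }
    for (int i = 0; i < n; ++i) r2[i] *= r2[i];
    const double crit = median_destructive(wk.r2);
    if (crit < best_crit) {
      best_crit = crit;
      std::copy(b, b + m, wk.bbest.begin());
      any = true;
    }
    return true;
  };

  if (exhaustive) {
    for (int i = 0; i < m; ++i) idx[i] = i;
    while (true) {
      try_subset();
      int i = m - 1;
      while (i >= 0 && idx[i] == n - m + i) --i;
      if (i < 0) break;
      ++idx[i];
      for (int j = i + 1; j < m; ++j) idx[j] = idx[j - 1] + 1;
    }
  } else {
    std::uniform_int_distribution<int> U(0, n - 1);
    int done = 0, attempts = 0, cap = 10 * nsamp;
    while (done < nsamp && attempts < cap) {
      ++attempts;
      for (int i = 0; i < m; ++i) {
        int v;
        bool dup;
        do {
          v = U(rng);
          dup = false;
          for (int j = 0; j < i; ++j) if (idx[j] == v) { dup = true; break; }
        } while (dup);
        idx[i] = v;
      }
      if (try_subset()) ++done;
    }
  }
  if (!any) return lms_intercept_only(arma::vec(y, n));
  LmsFit best;
  best.ok = true;
  best.crit = best_crit;
  best.coef = arma::vec(wk.bbest.data(), m);
  return best;
}

// [[Rcpp::export]]
List cpp_lms(NumericMatrix X, NumericVector y, int nsamp, double seed) {
  std::mt19937_64 rng((uint64_t)seed);
  LmsWork wk;
  LmsFit f = lms_core(X.begin(), X.nrow(), X.ncol(), y.begin(), nsamp, rng, wk);
  return List::create(_["coefficients"] = NumericVector(f.coef.begin(), f.coef.end()),
                      _["crit"] = f.crit);
}

// ---------- CFS feature selection ----------
//
// merit(S) = sum|r_cf| / sqrt(k + 2 * sum_pairs|r_ff|), greedy forward
// search; the search continues past non-improving additions and stops
// after two consecutive failures to improve, returning the best subset
// seen (best-first with a patience of 2).
//
// The standardized design and feature-feature correlations do not depend
// on the target, so they can be cached and reused across permutations
// (CfsCache); rows of the |r_ff| matrix are computed lazily.

struct CfsCache {
  arma::mat Z;               // n x p standardized columns (0 if constant)
  std::vector<char> usable;
  std::map<int, arma::vec> rff_rows; // lazily filled |r_ff| rows

  void init(const arma::mat &X) {
    const int n = X.n_rows, p = X.n_cols;
    Z.set_size(n, p);
    usable.assign(p, 0);
    for (int j = 0; j < p; ++j) {
      arma::vec c = X.col(j) - arma::mean(X.col(j));
      const double nrm = arma::norm(c);
      if (nrm > 1e-12) { Z.col(j) = c / nrm; usable[j] = 1; }
      else Z.col(j).zeros();
    }
    rff_rows.clear();
  }
  const arma::vec &rff_row(int i) {
    auto it = rff_rows.find(i);
    if (it != rff_rows.end()) return it->second;
    arma::vec row = arma::abs(Z.t() * Z.col(i));
    return rff_rows.emplace(i, std::move(row)).first->second;
  }
};

static std::vector<int> cfs_select_cached(CfsCache &C, const arma::vec &y) {
  const int n = C.Z.n_rows, p = C.Z.n_cols;
  std::vector<int> empty;
  if (n < 3 || p == 0) return empty;

  arma::vec yc = y - arma::mean(y);
  const double ynrm = arma::norm(yc);
  if (ynrm <= 1e-12) return empty;
  yc /= ynrm;
  arma::vec rcf = arma::abs(C.Z.t() * yc);
  for (int j = 0; j < p; ++j) if (!C.usable[j]) rcf[j] = 0;

  std::vector<int> sel, best_sel;
  std::vector<char> in(p, 0);
  arma::vec ffsum(p, arma::fill::zeros); // sum over selected of |r_ff|
  double sum_rcf = 0, sum_rff = 0;
  double best_merit = -std::numeric_limits<double>::infinity();
  int fails = 0;

  while ((int)sel.size() < p) {
    int cand = -1;
    double cand_merit = -std::numeric_limits<double>::infinity();
    const int k1 = (int)sel.size() + 1;
    for (int j = 0; j < p; ++j) {
      if (in[j] || !C.usable[j]) continue;
      const double merit = (sum_rcf + rcf[j]) /
        std::sqrt((double)k1 + 2.0 * (sum_rff + ffsum[j]));
      if (merit > cand_merit + 1e-12) { cand_merit = merit; cand = j; }
    }
    if (cand < 0) break;
    sel.push_back(cand); in[cand] = 1;
    sum_rcf += rcf[cand]; sum_rff += ffsum[cand];
    const arma::vec &row = C.rff_row(cand);
    for (int j = 0; j < p; ++j) if (!in[j] && C.usable[j]) ffsum[j] += row[j];
    if (cand_merit > best_merit + 1e-12) {
      best_merit = cand_merit; best_sel = sel; fails = 0;
    } else if (++fails >= 2) break;
  }
  std::sort(best_sel.begin(), best_sel.end());
  return best_sel;
}

static std::vector<int> cfs_core(const arma::mat &X, const arma::vec &y) {
  CfsCache C;
  C.init(X);
  return cfs_select_cached(C, y);
}

// [[Rcpp::export]]
IntegerVector cpp_cfs(NumericMatrix X, NumericVector y) {
  arma::mat Xa(X.begin(), X.nrow(), X.ncol(), false);
  arma::vec ya(y.begin(), y.size(), false);
  std::vector<int> s = cfs_core(Xa, ya);
  IntegerVector out(s.size());
  for (size_t i = 0; i < s.size(); ++i) out[i] = s[i] + 1;
  return out;
}

// ---------- association pipeline ----------
//
// For one trait: reconstruct tip trait values over the tree by Wagner
// parsimony, take per-branch trait deltas, select predictor groups by
// CFS among the per-branch copy-number deltas, fit LMS, and score by
// leave-one-species-out prediction: drop the species' terminal branch,
// re-reconstruct the trait without that tip, re-select and re-fit, then
// predict tip trait = reconstructed parent value + predicted branch delta.

struct TreeIdx {
  std::vector<int> ep, ec;   // 0-based postorder edges
  int n_tip, n_node, n_edge;
  std::vector<int> term_edge; // per tip: index of its terminal edge
};

// per-held-out-tip design matrices and CFS caches; these depend only on
// the copy-number deltas (never on the trait) and are shared across all
// trait permutations
struct AssocCache {
  std::vector<char> built;
  std::vector<arma::mat> Xs;
  std::vector<CfsCache> cfs;
  void init(int n_tip) {
    built.assign(n_tip, 0);
    Xs.assign(n_tip, arma::mat());
    cfs.assign(n_tip, CfsCache());
  }
  void ensure(const TreeIdx &T, const arma::mat &D, int s) {
    if (built[s]) return;
    built[s] = 1;
    Xs[s].set_size(T.n_edge - 1, D.n_cols);
    int k = 0;
    for (int b = 0; b < T.n_edge; ++b) {
      if (b == T.term_edge[s]) continue;
      Xs[s].row(k++) = D.row(b);
    }
    cfs[s].init(Xs[s]);
  }
};

static double assoc_loo(const TreeIdx &T, const arma::mat &D,
                        const std::vector<double> &y_tip, int nsamp,
                        std::mt19937_64 &rng, WagnerWork &W,
                        std::vector<double> *pred_out, AssocCache &AC,
                        LmsWork &LW) {
  std::vector<int> obs;
  for (int i = 0; i < T.n_tip; ++i)
    if (std::isfinite(y_tip[i])) obs.push_back(i);

  std::vector<double> preds, truth;
  std::vector<double> y2(y_tip);
  WagnerResult res;
  arma::vec ys(T.n_edge - 1);

  if (pred_out) pred_out->assign(T.n_tip, NAN);

  for (int s : obs) {
    y2 = y_tip; y2[s] = NAN;
    wagner_run(T.ep.data(), T.ec.data(), T.n_edge, T.n_tip, T.n_node,
               y2.data(), W, res);
    if (!res.ok || res.n_informative < 2) continue;
    const int te = T.term_edge[s];
    AC.ensure(T, D, s);
    int k = 0;
    for (int b = 0; b < T.n_edge; ++b) {
      if (b == te) continue;
      ys[k++] = res.value[T.ec[b]] - res.value[T.ep[b]];
    }
    std::vector<int> sel = cfs_select_cached(AC.cfs[s], ys);
    static thread_local std::vector<double> xsel;
    xsel.resize((size_t)k * sel.size());
    for (size_t j = 0; j < sel.size(); ++j) {
      std::copy(AC.Xs[s].colptr(sel[j]), AC.Xs[s].colptr(sel[j]) + k,
                xsel.begin() + (size_t)j * k);
    }
    LmsFit fit = lms_core(xsel.data(), k, (int)sel.size(), ys.memptr(),
                          nsamp, rng, LW);
    double delta = fit.coef[0];
    if ((int)fit.coef.n_elem == (int)sel.size() + 1) {
      for (size_t j = 0; j < sel.size(); ++j) delta += fit.coef[j + 1] * D(te, sel[j]);
    }
    const double pv = res.value[T.ep[te]];
    preds.push_back(pv + delta);
    truth.push_back(y_tip[s]);
    if (pred_out) (*pred_out)[s] = pv + delta;
  }
  if (preds.size() < 3) return NA_REAL;
  return pearson(preds, truth);
}

static TreeIdx make_tree(IntegerVector edge_parent, IntegerVector edge_child,
                         int n_tip, int n_node) {
  TreeIdx T;
  T.n_edge = edge_parent.size();
  T.n_tip = n_tip; T.n_node = n_node;
  T.ep.resize(T.n_edge); T.ec.resize(T.n_edge);
  T.term_edge.assign(n_tip, -1);
  for (int i = 0; i < T.n_edge; ++i) {
    T.ep[i] = edge_parent[i] - 1;
    T.ec[i] = edge_child[i] - 1;
    if (T.ec[i] < n_tip) T.term_edge[T.ec[i]] = i;
  }
  return T;
}

// [[Rcpp::export]]
List cpp_assoc_loo(IntegerVector edge_parent, IntegerVector edge_child,
                   int n_tip, int n_node, NumericMatrix D,
                   NumericVector y_tip, int nsamp, double seed) {
  TreeIdx T = make_tree(edge_parent, edge_child, n_tip, n_node);
  arma::mat Da(D.begin(), D.nrow(), D.ncol(), false);
  std::vector<double> y(n_tip);
  for (int i = 0; i < n_tip; ++i)
    y[i] = NumericVector::is_na(y_tip[i]) ? NAN : y_tip[i];

  std::mt19937_64 rng((uint64_t)seed);
  WagnerWork W;
  AssocCache AC;
  AC.init(n_tip);
  LmsWork LW;
  std::vector<double> pred;
  const double r = assoc_loo(T, Da, y, nsamp, rng, W, &pred, AC, LW);

  // full-data reconstruction + selection, for reporting
  WagnerResult res;
  wagner_run(T.ep.data(), T.ec.data(), T.n_edge, T.n_tip, T.n_node,
             y.data(), W, res);
  arma::vec td(T.n_edge);
  for (int b = 0; b < T.n_edge; ++b)
    td[b] = res.value[T.ec[b]] - res.value[T.ep[b]];
  std::vector<int> sel = cfs_core(Da, td);
  IntegerVector selR(sel.size());
  for (size_t i = 0; i < sel.size(); ++i) selR[i] = sel[i] + 1;

  NumericVector predR(n_tip);
  for (int i = 0; i < n_tip; ++i)
    predR[i] = std::isfinite(pred[i]) ? pred[i] : NA_REAL;

  return List::create(_["r"] = r, _["predictions"] = predR,
                      _["selected"] = selR,
                      _["trait_values"] = NumericVector(res.value.begin(), res.value.end()),
                      _["trait_cost"] = res.cost,
                      _["trait_deltas"] = NumericVector(td.begin(), td.end()));
}

// [[Rcpp::export]]
List cpp_assoc_perm(IntegerVector edge_parent, IntegerVector edge_child,
                    int n_tip, int n_node, NumericMatrix D,
                    NumericVector y_tip, int n_perm, int nsamp, double seed) {
  TreeIdx T = make_tree(edge_parent, edge_child, n_tip, n_node);
  arma::mat Da(D.begin(), D.nrow(), D.ncol(), false);
  std::vector<double> y(n_tip);
  std::vector<int> obs;
  for (int i = 0; i < n_tip; ++i) {
    y[i] = NumericVector::is_na(y_tip[i]) ? NAN : y_tip[i];
    if (std::isfinite(y[i])) obs.push_back(i);
  }
  std::mt19937_64 rng((uint64_t)seed);
  WagnerWork W;
  AssocCache AC;
  AC.init(n_tip);
  LmsWork LW;
  const double r_obs = assoc_loo(T, Da, y, nsamp, rng, W, nullptr, AC, LW);

  NumericVector r_perm(n_perm);
  std::vector<double> vals(obs.size()), yp(y);
  for (int it = 0; it < n_perm; ++it) {
    for (size_t i = 0; i < obs.size(); ++i) vals[i] = y[obs[i]];
    std::shuffle(vals.begin(), vals.end(), rng);
    yp = y;
    for (size_t i = 0; i < obs.size(); ++i) yp[obs[i]] = vals[i];
    const double r = assoc_loo(T, Da, yp, nsamp, rng, W, nullptr, AC, LW);
    r_perm[it] = std::isfinite(r) ? r : 0.0;
  }
  return List::create(_["r_obs"] = r_obs, _["r_perm"] = r_perm);
}
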