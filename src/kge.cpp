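// Translational knowledge-graph embedding core: triplet scoring, margin-
// ranking gradients, filtered negative sampling and the Adam training loop.
// Four mapping variants share one residual/gradient kernel:
//   0 = nomap     : e = v_h + v_r - v_t
//   1 = planemap  : e = (v_h - (w_r.v_h) w_r) + v_r - (v_t - (w_r.v_t) w_r)
//   2 = staticmap : e = M_r v_h + v_r - M_r v_t
//   3 = dynmap    : e = (w_r w_h^T + I) v_h + v_r - (w_r w_t^T + I) v_t
// Score is ||e||_1 or ||e||_2.
//
// The R-facing layout is one row per entity/relation (relation matrices
// M_r flattened column-major into a row).  Internally everything is
// transposed so each embedding vector is a contiguous column, which keeps
// the inner loops cache-friendly.  All randomness draws from R's RNG so
// set.seed() controls everything.

#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

static NumericMatrix transpose_of(const NumericMatrix& A) {
  NumericMatrix B(A.ncol(), A.nrow());
  for (int i = 0; i < A.nrow(); ++i)
    for (int j = 0; j < A.ncol(); ++j)
      B(j, i) = A(i, j);
  return B;
}

// Columns of these matrices are embedding vectors (d x n layout).
struct Params {
  NumericMatrix E, P, R, Q, M;  // M: (d*d) x n_rel, column r = vec(M_r)
  int d;
};

static Params to_internal(const NumericMatrix& E, const NumericMatrix& P,
                          const NumericMatrix& R, const NumericMatrix& Q,
                          const NumericMatrix& M) {
  Params pa;
  pa.E = transpose_of(E); pa.P = transpose_of(P);
  pa.R = transpose_of(R); pa.Q = transpose_of(Q);
  pa.M = transpose_of(M);
  pa.d = E.ncol();
  return pa;
}

static inline double col_dot(const NumericMatrix& A, int i,
                             const NumericMatrix& B, int j, int d) {
  const double* a = &A(0, i);
  const double* b = &B(0, j);
  double s = 0.0;
  for (int k = 0; k < d; ++k) s += a[k] * b[k];
  return s;
}

// e <- mapped residual of triplet (h, r, t)
static void residual_vec(const Params& pa, int h, int r, int t,
                         int variant, std::vector<double>& e) {
  const int d = pa.d;
  const double* vh = &pa.E(0, h);
  const double* vt = &pa.E(0, t);
  const double* vr = &pa.R(0, r);
  switch (variant) {
  case 0:
    for (int k = 0; k < d; ++k) e[k] = vh[k] + vr[k] - vt[k];
    break;
  case 1: {
    const double* w = &pa.Q(0, r);
    double ah = 0.0, at = 0.0;
    for (int k = 0; k < d; ++k) { ah += w[k] * vh[k]; at += w[k] * vt[k]; }
    for (int k = 0; k < d; ++k)
      e[k] = (vh[k] - ah * w[k]) + vr[k] - (vt[k] - at * w[k]);
    break;
  }
  case 2: {
    const double* m = &pa.M(0, r);  // column-major d x d
    for (int i = 0; i < d; ++i) e[i] = vr[i];
    for (int j = 0; j < d; ++j) {
      double dv = vh[j] - vt[j];
      const double* mj = m + (std::size_t)j * d;
      for (int i = 0; i < d; ++i) e[i] += mj[i] * dv;
    }
    break;
  }
  default: { // dynmap
    const double* w = &pa.Q(0, r);
    double ah = col_dot(pa.P, h, pa.E, h, d);
    double at = col_dot(pa.P, t, pa.E, t, d);
    for (int k = 0; k < d; ++k)
      e[k] = vh[k] + w[k] * ah + vr[k] - vt[k] - w[k] * at;
  }
  }
}

static inline double score_from_residual(const std::vector<double>& e,
                                         int norm_p) {
  double s = 0.0;
  if (norm_p == 1) {
    for (double x : e) s += std::fabs(x);
  } else {
    for (double x : e) s += x * x;
    s = std::sqrt(s);
  }
  return s;
}

// g <- d score / d e  (L1 subgradient: sign, 0 at 0)
static void dscore_de(const std::vector<double>& e, int norm_p,
                      std::vector<double>& g) {
  const size_t d = e.size();
  if (norm_p == 1) {
    for (size_t k = 0; k < d; ++k)
      g[k] = (double)((e[k] > 0.0) - (e[k] < 0.0));
  } else {
    double n = 0.0;
    for (size_t k = 0; k < d; ++k) n += e[k] * e[k];
    n = std::sqrt(n);
    if (n < 1e-12) { std::fill(g.begin(), g.end(), 0.0); return; }
    for (size_t k = 0; k < d; ++k) g[k] = e[k] / n;
  }
}

// Accumulate f * d score(h,r,t) / d params into gradients (same layout
// as Params).
static void accumulate_grad(const Params& pa, int h, int r, int t,
                            int variant, const std::vector<double>& g,
                            double f, Params& gr) {
  const int d = pa.d;
  double* gR = &gr.R(0, r);
  for (int k = 0; k < d; ++k) gR[k] += f * g[k];
  switch (variant) {
  case 0: {
    double* gh = &gr.E(0, h);
    double* gt = &gr.E(0, t);
    for (int k = 0; k < d; ++k) { gh[k] += f * g[k]; gt[k] -= f * g[k]; }
    break;
  }
  case 1: {
    const double* w = &pa.Q(0, r);
    const double* vh = &pa.E(0, h);
    const double* vt = &pa.E(0, t);
    double qg = 0.0, a = 0.0;
    for (int k = 0; k < d; ++k) {
      qg += w[k] * g[k];
      a += w[k] * (vh[k] - vt[k]);
    }
    double* gh = &gr.E(0, h);
    double* gt = &gr.E(0, t);
    double* gq = &gr.Q(0, r);
    for (int k = 0; k < d; ++k) {
      double ge = g[k] - qg * w[k];   // (I - w w^T) g
      gh[k] += f * ge;
      gt[k] -= f * ge;
      gq[k] -= f * (qg * (vh[k] - vt[k]) + a * g[k]);
    }
    break;
  }
  case 2: {
    const double* m = &pa.M(0, r);
    const double* vh = &pa.E(0, h);
    const double* vt = &pa.E(0, t);
    double* gh = &gr.E(0, h);
    double* gt = &gr.E(0, t);
    double* gm = &gr.M(0, r);
    for (int j = 0; j < d; ++j) {
      const double* mj = m + (std::size_t)j * d;
      double* gmj = gm + (std::size_t)j * d;
      double mg = 0.0, dv = vh[j] - vt[j];
      for (int i = 0; i < d; ++i) {
        mg += mj[i] * g[i];
        gmj[i] += f * g[i] * dv;
      }
      gh[j] += f * mg;
      gt[j] -= f * mg;
    }
    break;
  }
  default: { // dynmap
    const double* w = &pa.Q(0, r);
    const double* vh = &pa.E(0, h);
    const double* vt = &pa.E(0, t);
    const double* ph = &pa.P(0, h);
    const double* pt = &pa.P(0, t);
    double qg = 0.0;
    for (int k = 0; k < d; ++k) qg += w[k] * g[k];
    double ah = col_dot(pa.P, h, pa.E, h, d);
    double at = col_dot(pa.P, t, pa.E, t, d);
    double* gh = &gr.E(0, h);
    double* gt = &gr.E(0, t);
    double* gph = &gr.P(0, h);
    double* gpt = &gr.P(0, t);
    double* gq = &gr.Q(0, r);
    for (int k = 0; k < d; ++k) {
      gh[k] += f * (g[k] + qg * ph[k]);
      gt[k] -= f * (g[k] + qg * pt[k]);
      gph[k] += f * qg * vh[k];
      gpt[k] -= f * qg * vt[k];
      gq[k] += f * (ah - at) * g[k];
    }
  }
  }
}

// [[Rcpp::export]]
NumericVector cpp_score_triplets(NumericMatrix E, NumericMatrix P,
                                 NumericMatrix R, NumericMatrix Q,
                                 NumericMatrix Mflat,
                                 IntegerVector h, IntegerVector r,
                                 IntegerVector t, int variant, int norm_p) {
  Params pa = to_internal(E, P, R, Q, Mflat);
  const int n = h.size();
  std::vector<double> e(pa.d);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    residual_vec(pa, h[i], r[i], t[i], variant, e);
    out[i] = score_from_residual(e, norm_p);
  }
  return out;
}

// Margin-ranking loss over paired positive/negative triplets, with
// optional dense gradients (used by the finite-difference check; the
// training loop shares the same kernels).
// [[Rcpp::export]]
List cpp_batch_loss_grad(NumericMatrix E, NumericMatrix P,
                         NumericMatrix R, NumericMatrix Q,
                         NumericMatrix Mflat,
                         IntegerVector ph, IntegerVector pr, IntegerVector pt,
                         IntegerVector nh, IntegerVector nr, IntegerVector nt,
                         double margin, int variant, int norm_p,
                         bool want_grad) {
  Params pa = to_internal(E, P, R, Q, Mflat);
  const int n = ph.size(), d = pa.d;
  std::vector<double> e(d), epos(d), g(d);
  Params gr;
  if (want_grad) {
    gr.E = NumericMatrix(d, E.nrow());
    gr.P = NumericMatrix(d, P.nrow());
    gr.R = NumericMatrix(d, R.nrow());
    gr.Q = NumericMatrix(d, Q.nrow());
    gr.M = NumericMatrix(Mflat.ncol(), Mflat.nrow());
    gr.d = d;
  }
  double loss = 0.0;
  for (int i = 0; i < n; ++i) {
    residual_vec(pa, ph[i], pr[i], pt[i], variant, epos);
    double sp = score_from_residual(epos, norm_p);
    residual_vec(pa, nh[i], nr[i], nt[i], variant, e);
    double sn = score_from_residual(e, norm_p);
    double hinge = margin + sp - sn;
    if (hinge > 0.0) {
      loss += hinge;
      if (want_grad) {
        dscore_de(epos, norm_p, g);
        accumulate_grad(pa, ph[i], pr[i], pt[i], variant, g, +1.0, gr);
        dscore_de(e, norm_p, g);
        accumulate_grad(pa, nh[i], nr[i], nt[i], variant, g, -1.0, gr);
      }
    }
  }
  if (want_grad)
    return List::create(_["loss"] = loss,
                        _["gE"] = transpose_of(gr.E),
                        _["gP"] = transpose_of(gr.P),
                        _["gR"] = transpose_of(gr.R),
                        _["gQ"] = transpose_of(gr.Q),
                        _["gM"] = transpose_of(gr.M));
  return List::create(_["loss"] = loss);
}

static inline std::uint64_t trip_key(int h, int r, int t,
                                     std::uint64_t nent, std::uint64_t nrel) {
  return ((std::uint64_t)h * nrel + (std::uint64_t)r) * nent +
         (std::uint64_t)t;
}

static std::unordered_set<std::uint64_t>
build_member_set(const IntegerMatrix& triplets, std::uint64_t nent,
                 std::uint64_t nrel) {
  std::unordered_set<std::uint64_t> s;
  s.reserve(triplets.nrow() * 2);
  for (int i = 0; i < triplets.nrow(); ++i)
    s.insert(trip_key(triplets(i, 0), triplets(i, 1), triplets(i, 2),
                      nent, nrel));
  return s;
}

static inline int runif_int(int n) {  // uniform on 0..n-1 via R's RNG
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// Corrupt one endpoint of (h, r, t): uniform side choice among feasible
// sides, candidate drawn from entities of the endpoint's kind, rejected
// if the corrupted triplet is already a graph member.  Falls back to
// exhaustive enumeration, then to the other side; fails only if no
// valid corruption exists anywhere.
static bool corrupt_one(int h, int r, int t,
                        const std::vector<std::vector<int>>& by_kind,
                        int hkind, int tkind,
                        const std::unordered_set<std::uint64_t>& members,
                        std::uint64_t nent, std::uint64_t nrel,
                        int max_tries, int& ch, int& ct) {
  const std::vector<int>& hc = by_kind[hkind];
  const std::vector<int>& tc = by_kind[tkind];
  bool head_ok = hc.size() >= 2, tail_ok = tc.size() >= 2;
  if (!head_ok && !tail_ok) return false;
  bool corrupt_head = head_ok && (!tail_ok || unif_rand() < 0.5);
  for (int attempt = 0; attempt < 2; ++attempt) {
    const std::vector<int>& cand = corrupt_head ? hc : tc;
    if (cand.size() >= 2) {
      int cur = corrupt_head ? h : t;
      for (int it = 0; it < max_tries; ++it) {
        int c = cand[runif_int((int)cand.size())];
        if (c == cur) continue;
        std::uint64_t key = corrupt_head ? trip_key(c, r, t, nent, nrel)
                                         : trip_key(h, r, c, nent, nrel);
        if (members.count(key)) continue;
        ch = corrupt_head ? c : h;
        ct = corrupt_head ? t : c;
        return true;
      }
      // exhaustive fallback for near-saturated graphs
      std::vector<int> valid;
      for (int c : cand) {
        if (c == cur) continue;
        std::uint64_t key = corrupt_head ? trip_key(c, r, t, nent, nrel)
                                         : trip_key(h, r, c, nent, nrel);
        if (!members.count(key)) valid.push_back(c);
      }
      if (!valid.empty()) {
        int c = valid[runif_int((int)valid.size())];
        ch = corrupt_head ? c : h;
        ct = corrupt_head ? t : c;
        return true;
      }
    }
    corrupt_head = !corrupt_head;  // try the other side
  }
  return false;
}

// [[Rcpp::export]]
IntegerVector cpp_negative_sample(IntegerMatrix triplets, int nent, int nrel,
                                  int h, int r, int t,
                                  IntegerVector ent_kind, int hkind,
                                  int tkind, int max_tries) {
  auto members = build_member_set(triplets, nent, nrel);
  std::vector<std::vector<int>> by_kind(4);
  for (int i = 0; i < ent_kind.size(); ++i)
    by_kind[ent_kind[i]].push_back(i);
  int ch, ct;
  if (!corrupt_one(h, r, t, by_kind, hkind, tkind, members,
                   (std::uint64_t)nent, (std::uint64_t)nrel, max_tries,
                   ch, ct))
    stop("no valid corruption exists for triplet (%d, %d, %d)", h, r, t);
  return IntegerVector::create(ch, r, ct);
}

struct AdamState {
  std::vector<double> m, v;
  AdamState(std::size_t n) : m(n, 0.0), v(n, 0.0) {}
};

static void adam_update(NumericMatrix& x, const NumericMatrix& g,
                        AdamState& st, double lr, double b1c, double b2c) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  const std::size_t n = (std::size_t)x.nrow() * x.ncol();
  double* xp = x.begin();
  const double* gp = g.begin();
  double* mp = st.m.data();
  double* vp = st.v.data();
  for (std::size_t i = 0; i < n; ++i) {
    mp[i] = b1 * mp[i] + (1.0 - b1) * gp[i];
    vp[i] = b2 * vp[i] + (1.0 - b2) * gp[i] * gp[i];
    xp[i] -= lr * (mp[i] / b1c) / (std::sqrt(vp[i] / b2c) + eps);
  }
}

// [[Rcpp::export]]
List cpp_train(NumericMatrix E0, NumericMatrix P0, NumericMatrix R0,
               NumericMatrix Q0, NumericMatrix M0,
               IntegerMatrix triplets, IntegerVector ent_kind,
               IntegerVector rel_hkind, IntegerVector rel_tkind,
               int variant, int norm_p, double margin, double lr,
               int epochs, int batch_size, int negatives, int max_tries,
               double average_tail) {
  Params pa = to_internal(E0, P0, R0, Q0, M0);
  const int n = triplets.nrow(), d = pa.d;
  const std::uint64_t nent = E0.nrow(), nrel = R0.nrow();
  auto members = build_member_set(triplets, nent, nrel);
  std::vector<std::vector<int>> by_kind(4);
  for (int i = 0; i < ent_kind.size(); ++i)
    by_kind[ent_kind[i]].push_back(i);

  Params gr;
  gr.E = NumericMatrix(d, E0.nrow());
  gr.P = NumericMatrix(d, P0.nrow());
  gr.R = NumericMatrix(d, R0.nrow());
  gr.Q = NumericMatrix(d, Q0.nrow());
  gr.M = NumericMatrix(M0.ncol(), M0.nrow());
  gr.d = d;
  AdamState sE(gr.E.size()), sP(gr.P.size()), sR(gr.R.size()),
            sQ(gr.Q.size()), sM(gr.M.size());
  const bool useP = (variant == 3), useQ = (variant == 1 || variant == 3),
             useM = (variant == 2);

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::vector<double> e(d), epos(d), g(d);
  NumericVector trace(epochs);
  long step = 0;

  // tail iterate averaging: accumulate parameters over the last
  // ceil(average_tail * epochs) epochs and return their mean, damping
  // the stochastic wobble of the final iterate
  int tail_from = epochs;
  if (average_tail > 0) {
    tail_from = epochs - (int)std::ceil(average_tail * epochs);
    if (tail_from < 0) tail_from = 0;
  }
  Params avg;
  avg.E = NumericMatrix(d, E0.nrow());
  avg.P = NumericMatrix(d, P0.nrow());
  avg.R = NumericMatrix(d, R0.nrow());
  avg.Q = NumericMatrix(d, Q0.nrow());
  avg.M = NumericMatrix(M0.ncol(), M0.nrow());
  avg.d = d;
  int n_avg = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = n - 1; i > 0; --i)  // Fisher-Yates via R RNG
      std::swap(order[i], order[runif_int(i + 1)]);
    double ep_loss = 0.0;
    for (int start = 0; start < n; start += batch_size) {
      int end = std::min(start + batch_size, n);
      std::fill(gr.E.begin(), gr.E.end(), 0.0);
      if (useP) std::fill(gr.P.begin(), gr.P.end(), 0.0);
      std::fill(gr.R.begin(), gr.R.end(), 0.0);
      if (useQ) std::fill(gr.Q.begin(), gr.Q.end(), 0.0);
      if (useM) std::fill(gr.M.begin(), gr.M.end(), 0.0);
      for (int b = start; b < end; ++b) {
        int i = order[b];
        int h = triplets(i, 0), r = triplets(i, 1), t = triplets(i, 2);
        residual_vec(pa, h, r, t, variant, epos);
        double sp = score_from_residual(epos, norm_p);
        for (int nn = 0; nn < negatives; ++nn) {
          int ch, ct;
          if (!corrupt_one(h, r, t, by_kind, rel_hkind[r], rel_tkind[r],
                           members, nent, nrel, max_tries, ch, ct))
            continue;  // saturated triplet: no contrast available
          residual_vec(pa, ch, r, ct, variant, e);
          double sn = score_from_residual(e, norm_p);
          double hinge = margin + sp - sn;
          if (hinge > 0.0) {
            ep_loss += hinge;
            dscore_de(epos, norm_p, g);
            accumulate_grad(pa, h, r, t, variant, g, +1.0, gr);
            dscore_de(e, norm_p, g);
            accumulate_grad(pa, ch, r, ct, variant, g, -1.0, gr);
          }
        }
      }
      ++step;
      double b1c = 1.0 - std::pow(0.9, (double)step);
      double b2c = 1.0 - std::pow(0.999, (double)step);
      adam_update(pa.E, gr.E, sE, lr, b1c, b2c);
      if (useP) adam_update(pa.P, gr.P, sP, lr, b1c, b2c);
      adam_update(pa.R, gr.R, sR, lr, b1c, b2c);
      if (useQ) adam_update(pa.Q, gr.Q, sQ, lr, b1c, b2c);
      if (useM) adam_update(pa.M, gr.M, sM, lr, b1c, b2c);
      // collapse guards: entities inside the unit ball, unit hyperplane
      // normals under planemap
      for (int i = 0; i < (int)nent; ++i) {
        double* v = &pa.E(0, i);
        double nrm = 0.0;
        for (int k = 0; k < d; ++k) nrm += v[k] * v[k];
        nrm = std::sqrt(nrm);
        if (nrm > 1.0)
          for (int k = 0; k < d; ++k) v[k] /= nrm;
      }
      if (variant == 1) {
        for (int r2 = 0; r2 < (int)nrel; ++r2) {
          double* w = &pa.Q(0, r2);
          double nrm = 0.0;
          for (int k = 0; k < d; ++k) nrm += w[k] * w[k];
          nrm = std::sqrt(nrm);
          if (nrm > 1e-12)
            for (int k = 0; k < d; ++k) w[k] /= nrm;
        }
      }
    }
    trace[ep] = ep_loss / (double)(n * negatives);
    if (!std::isfinite(trace[ep]))
      stop("non-finite training loss at epoch %d", ep + 1);
    if (ep >= tail_from) {
      ++n_avg;
      auto acc = [](NumericMatrix& a, const NumericMatrix& x) {
        double* ap = a.begin();
        const double* xp = x.begin();
        for (R_xlen_t i = 0; i < a.size(); ++i) ap[i] += xp[i];
      };
      acc(avg.E, pa.E); acc(avg.P, pa.P); acc(avg.R, pa.R);
      acc(avg.Q, pa.Q); acc(avg.M, pa.M);
    }
    if (ep % 16 == 0) Rcpp::checkUserInterrupt();
  }
  if (n_avg > 0) {
    auto scale = [&](NumericMatrix& a) {
      double* ap = a.begin();
      for (R_xlen_t i = 0; i < a.size(); ++i) ap[i] /= n_avg;
    };
    scale(avg.E); scale(avg.P); scale(avg.R); scale(avg.Q); scale(avg.M);
    pa = avg;
  }
  return List::create(_["E"] = transpose_of(pa.E),
                      _["P"] = transpose_of(pa.P),
                      _["R"] = transpose_of(pa.R),
                      _["Q"] = transpose_of(pa.Q),
                      _["M"] = transpose_of(pa.M),
                      _["loss_trace"] = trace);
}
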