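// Compiled core of the interval type-2 fuzzy neural network: per-sample
// forward inference, analytic gradients of the squared-error loss through the
// piecewise membership envelopes, and the stochastic training pass. All
// matrices follow the R layout: antecedent grids are n_rules x m (rule j,
// input i), V is m x n_rules, W is n_rules x p.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double EPS_GUARD = 1e-12;    // added to a degenerate denominator
static const double EPS_ZERO = 1e-300;     // "degenerate" = underflowed to ~0
static const double SIGMA_FLOOR = 1e-4;
// Per-sample gradient sup-norm cap for the SGD loop. When every rule's
// product firing strength underflows (high-dimensional inputs far from all
// footprints), the epsilon-guarded type-reduction denominators put a 1/eps
// factor into the antecedent gradients; rescaling the whole per-sample
// gradient keeps those steps bounded without biasing healthy ones.
static const double GRAD_CLIP = 10.0;

namespace {

struct Work {
  int n, m, p;
  std::vector<double> mulo, muhi;   // n*m memberships, idx j + n*i
  std::vector<int> act_lo;          // which center realises the lower MF: 0 -> c1, 1 -> c2
  std::vector<int> br_hi;           // upper-MF branch: -1 left of c1, 0 interior, +1 right of c2
  std::vector<int> amin_lo, amin_hi; // argmin input per rule (min t-norm only)
  std::vector<double> fl, fu, y;    // per-rule firing strengths and local outputs
  std::vector<double> u, ul, uu;    // crisp outputs and the lower/upper weighted means
  double Sl, Su;
  bool guarded;
  void resize(int n_, int m_, int p_) {
    n = n_; m = m_; p = p_;
    mulo.assign(n * m, 0.0); muhi.assign(n * m, 0.0);
    act_lo.assign(n * m, 0); br_hi.assign(n * m, 0);
    amin_lo.assign(n, 0); amin_hi.assign(n, 0);
    fl.assign(n, 0.0); fu.assign(n, 0.0); y.assign(n, 0.0);
    u.assign(p, 0.0); ul.assign(p, 0.0); uu.assign(p, 0.0);
  }
};

inline int idx(int j, int i, int n) { return j + n * i; }

void forward_sample(const double* c1, const double* c2, const double* sg,
                    const double* V, const double* W,
                    double pc, double qc, const double* x,
                    bool tnorm_min, Work& w) {
  const int n = w.n, m = w.m, p = w.p;
  for (int j = 0; j < n; ++j) {
    double fl = tnorm_min ? R_PosInf : 1.0;
    double fu = tnorm_min ? R_PosInf : 1.0;
    int amin_l = 0, amin_u = 0;
    for (int i = 0; i < m; ++i) {
      const int k = idx(j, i, n);
      const double s = sg[k], s2 = s * s;
      const double d1 = x[i] - c1[k], d2 = x[i] - c2[k];
      const double g1 = std::exp(-d1 * d1 / s2);
      const double g2 = std::exp(-d2 * d2 / s2);
      double lo, hi;
      if (g1 <= g2) { lo = g1; w.act_lo[k] = 0; } else { lo = g2; w.act_lo[k] = 1; }
      if (x[i] < c1[k])      { hi = g1; w.br_hi[k] = -1; }
      else if (x[i] > c2[k]) { hi = g2; w.br_hi[k] = 1; }
      else                   { hi = 1.0; w.br_hi[k] = 0; }
      w.mulo[k] = lo; w.muhi[k] = hi;
      if (tnorm_min) {
        if (lo < fl) { fl = lo; amin_l = i; }
        if (hi < fu) { fu = hi; amin_u = i; }
      } else {
        fl *= lo; fu *= hi;
      }
    }
    w.fl[j] = fl; w.fu[j] = fu;
    w.amin_lo[j] = amin_l; w.amin_hi[j] = amin_u;
    double yj = 0.0;
    for (int i = 0; i < m; ++i) yj += x[i] * V[i + m * j];
    w.y[j] = yj;
  }
  double Sl = 0.0, Su = 0.0;
  for (int j = 0; j < n; ++j) { Sl += w.fl[j]; Su += w.fu[j]; }
  w.guarded = (Sl <= EPS_ZERO) || (Su <= EPS_ZERO);
  if (Sl <= EPS_ZERO) Sl += EPS_GUARD;
  if (Su <= EPS_ZERO) Su += EPS_GUARD;
  w.Sl = Sl; w.Su = Su;
  for (int k = 0; k < p; ++k) {
    double Al = 0.0, Au = 0.0;
    for (int j = 0; j < n; ++j) {
      Al += w.fl[j] * w.y[j] * W[j + n * k];
      Au += w.fu[j] * w.y[j] * W[j + n * k];
    }
    w.ul[k] = Al / Sl; w.uu[k] = Au / Su;
    w.u[k] = pc * w.ul[k] + qc * w.uu[k];
  }
}

// Analytic gradients of E = sum_k (ud_k - u_k)^2. The piecewise upper MF uses
// the active branch's derivative; at branch boundaries the interior (value-1)
// branch applies, whose derivative is zero.
void backward_sample(const double* c1, const double* c2, const double* sg,
                     const double* V, const double* W,
                     double pc, double qc, const double* x, const double* ud,
                     bool tnorm_min, Work& w,
                     double* gc1, double* gc2, double* gsg,
                     double* gV, double* gW, double* gp) {
  const int n = w.n, m = w.m, p = w.p;
  std::vector<double> r(p);
  for (int k = 0; k < p; ++k) r[k] = 2.0 * (w.u[k] - ud[k]);

  double gpq = 0.0;  // d E / d p_coef under the constraint q = 1 - p
  for (int k = 0; k < p; ++k) gpq += r[k] * (w.ul[k] - w.uu[k]);
  if (gp) *gp = gpq;

  std::vector<double> gfl(n), gfu(n), gy(n);
  for (int j = 0; j < n; ++j) {
    double a = 0.0, b = 0.0, c = 0.0;
    for (int k = 0; k < p; ++k) {
      const double wjk = W[j + n * k];
      a += r[k] * (w.y[j] * wjk - w.ul[k]);
      b += r[k] * (w.y[j] * wjk - w.uu[k]);
      c += r[k] * wjk;
      gW[j + n * k] += r[k] * (pc * w.fl[j] * w.y[j] / w.Sl +
                               qc * w.fu[j] * w.y[j] / w.Su);
    }
    gfl[j] = pc * a / w.Sl;
    gfu[j] = qc * b / w.Su;
    gy[j] = c * (pc * w.fl[j] / w.Sl + qc * w.fu[j] / w.Su);
    for (int i = 0; i < m; ++i) gV[i + m * j] += gy[j] * x[i];
  }

  std::vector<double> pre(m + 1), suf(m + 1), preh(m + 1), sufh(m + 1);
  for (int j = 0; j < n; ++j) {
    if (!tnorm_min) {
      pre[0] = 1.0; preh[0] = 1.0;
      for (int i = 0; i < m; ++i) {
        pre[i + 1] = pre[i] * w.mulo[idx(j, i, n)];
        preh[i + 1] = preh[i] * w.muhi[idx(j, i, n)];
      }
      suf[m] = 1.0; sufh[m] = 1.0;
      for (int i = m - 1; i >= 0; --i) {
        suf[i] = suf[i + 1] * w.mulo[idx(j, i, n)];
        sufh[i] = sufh[i + 1] * w.muhi[idx(j, i, n)];
      }
    }
    for (int i = 0; i < m; ++i) {
      const int k = idx(j, i, n);
      const double dfl_dmu = tnorm_min ? (w.amin_lo[j] == i ? 1.0 : 0.0)
                                       : pre[i] * suf[i + 1];
      const double dfu_dmu = tnorm_min ? (w.amin_hi[j] == i ? 1.0 : 0.0)
                                       : preh[i] * sufh[i + 1];
      const double s = sg[k], s2 = s * s;
      // lower MF: the farther center is active
      const double ca = (w.act_lo[k] == 0) ? c1[k] : c2[k];
      const double dl = x[i] - ca;
      const double dmu_dc = w.mulo[k] * 2.0 * dl / s2;
      const double dmu_ds = w.mulo[k] * 2.0 * dl * dl / (s2 * s);
      const double glo = gfl[j] * dfl_dmu;
      if (w.act_lo[k] == 0) gc1[k] += glo * dmu_dc; else gc2[k] += glo * dmu_dc;
      gsg[k] += glo * dmu_ds;
      // upper MF: derivative only outside [c1, c2]
      if (w.br_hi[k] != 0) {
        const double cb = (w.br_hi[k] < 0) ? c1[k] : c2[k];
        const double du = x[i] - cb;
        const double dmh_dc = w.muhi[k] * 2.0 * du / s2;
        const double dmh_ds = w.muhi[k] * 2.0 * du * du / (s2 * s);
        const double ghi = gfu[j] * dfu_dmu;
        if (w.br_hi[k] < 0) gc1[k] += ghi * dmh_dc; else gc2[k] += ghi * dmh_dc;
        gsg[k] += ghi * dmh_ds;
      }
    }
  }
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_forward_batch(NumericMatrix c1, NumericMatrix c2,
                                NumericMatrix sigma, NumericMatrix V,
                                NumericMatrix W, double p_coef, double q_coef,
                                NumericMatrix X, bool tnorm_min) {
  const int n = c1.nrow(), m = c1.ncol(), p = W.ncol(), N = X.nrow();
  if (X.ncol() != m) stop("X has %d columns but the model expects %d", X.ncol(), m);
  Work w; w.resize(n, m, p);
  NumericMatrix U(N, p);
  std::vector<double> x(m);
  int guarded = 0;
  for (int r = 0; r < N; ++r) {
    for (int i = 0; i < m; ++i) x[i] = X(r, i);
    forward_sample(c1.begin(), c2.begin(), sigma.begin(), V.begin(), W.begin(),
                   p_coef, q_coef, x.data(), tnorm_min, w);
    if (w.guarded) ++guarded;
    for (int k = 0; k < p; ++k) U(r, k) = w.u[k];
  }
  U.attr("guarded") = guarded;
  return U;
}

// [[Rcpp::export]]
List cpp_backward(NumericMatrix c1, NumericMatrix c2, NumericMatrix sigma,
                  NumericMatrix V, NumericMatrix W, double p_coef,
                  double q_coef, NumericVector x, NumericVector ud,
                  bool tnorm_min) {
  const int n = c1.nrow(), m = c1.ncol(), p = W.ncol();
  if (x.size() != m) stop("input vector must have length %d", m);
  if (ud.size() != p) stop("target vector must have length %d", p);
  Work w; w.resize(n, m, p);
  forward_sample(c1.begin(), c2.begin(), sigma.begin(), V.begin(), W.begin(),
                 p_coef, q_coef, x.begin(), tnorm_min, w);
  NumericMatrix gc1(n, m), gc2(n, m), gsg(n, m), gV(m, n), gW(n, p);
  double gp = 0.0;
  backward_sample(c1.begin(), c2.begin(), sigma.begin(), V.begin(), W.begin(),
                  p_coef, q_coef, x.begin(), ud.begin(), tnorm_min, w,
                  gc1.begin(), gc2.begin(), gsg.begin(), gV.begin(),
                  gW.begin(), &gp);
  NumericVector u(p);
  double E = 0.0;
  for (int k = 0; k < p; ++k) {
    u[k] = w.u[k];
    E += (ud[k] - w.u[k]) * (ud[k] - w.u[k]);
  }
  return List::create(_["c1"] = gc1, _["c2"] = gc2, _["sigma"] = gsg,
                      _["V"] = gV, _["W"] = gW, _["p_coef"] = gp,
                      _["u"] = u, _["E"] = E);
}

// One stochastic pass over the given sample order: per sample, forward,
// gate on max |ud - u| > delta, momentum update, then invariant repair
// (sigma floored at 1e-4; inverted center pairs swapped).
// [[Rcpp::export]]
List cpp_sgd_pass(NumericMatrix c1, NumericMatrix c2, NumericMatrix sigma,
                  NumericMatrix V, NumericMatrix W, double p_coef,
                  double q_coef, NumericMatrix X, NumericMatrix Ud,
                  IntegerVector order, double lr, double momentum,
                  double delta, bool tnorm_min, bool train_pq,
                  NumericMatrix vc1, NumericMatrix vc2, NumericMatrix vsigma,
                  NumericMatrix vV, NumericMatrix vW, double vp) {
  const int n = c1.nrow(), m = c1.ncol(), p = W.ncol();
  NumericMatrix c1_ = clone(c1), c2_ = clone(c2), sg_ = clone(sigma),
                V_ = clone(V), W_ = clone(W);
  NumericMatrix vc1_ = clone(vc1), vc2_ = clone(vc2), vsg_ = clone(vsigma),
                vV_ = clone(vV), vW_ = clone(vW);
  double pc = p_coef, qc = q_coef, vp_ = vp;
  Work w; w.resize(n, m, p);
  std::vector<double> x(m), ud(p);
  std::vector<double> gc1(n * m), gc2(n * m), gsg(n * m), gV(m * n), gW(n * p);
  int n_updates = 0, guarded = 0;
  for (int oi = 0; oi < order.size(); ++oi) {
    const int r = order[oi] - 1;
    if (r < 0 || r >= X.nrow()) stop("sample index out of range");
    for (int i = 0; i < m; ++i) x[i] = X(r, i);
    for (int k = 0; k < p; ++k) ud[k] = Ud(r, k);
    forward_sample(c1_.begin(), c2_.begin(), sg_.begin(), V_.begin(),
                   W_.begin(), pc, qc, x.data(), tnorm_min, w);
    if (w.guarded) ++guarded;
    double emax = 0.0;
    for (int k = 0; k < p; ++k) emax = std::max(emax, std::fabs(ud[k] - w.u[k]));
    if (!(emax > delta)) continue;
    std::fill(gc1.begin(), gc1.end(), 0.0);
    std::fill(gc2.begin(), gc2.end(), 0.0);
    std::fill(gsg.begin(), gsg.end(), 0.0);
    std::fill(gV.begin(), gV.end(), 0.0);
    std::fill(gW.begin(), gW.end(), 0.0);
    double gp = 0.0;
    backward_sample(c1_.begin(), c2_.begin(), sg_.begin(), V_.begin(),
                    W_.begin(), pc, qc, x.data(), ud.data(), tnorm_min, w,
                    gc1.data(), gc2.data(), gsg.data(), gV.data(), gW.data(),
                    &gp);
    double gmax = std::fabs(gp);
    bool finite = std::isfinite(gp);
    for (int k = 0; k < n * m; ++k) {
      gmax = std::max(gmax, std::max(std::fabs(gc1[k]),
                      std::max(std::fabs(gc2[k]), std::fabs(gsg[k]))));
      finite = finite && std::isfinite(gc1[k]) && std::isfinite(gc2[k]) &&
               std::isfinite(gsg[k]);
    }
    for (int k = 0; k < m * n; ++k) {
      gmax = std::max(gmax, std::fabs(gV[k]));
      finite = finite && std::isfinite(gV[k]);
    }
    for (int k = 0; k < n * p; ++k) {
      gmax = std::max(gmax, std::fabs(gW[k]));
      finite = finite && std::isfinite(gW[k]);
    }
    if (!finite) continue;  // defensive: skip a degenerate sample outright
    if (gmax > GRAD_CLIP) {
      const double scale = GRAD_CLIP / gmax;
      for (int k = 0; k < n * m; ++k) { gc1[k] *= scale; gc2[k] *= scale; gsg[k] *= scale; }
      for (int k = 0; k < m * n; ++k) gV[k] *= scale;
      for (int k = 0; k < n * p; ++k) gW[k] *= scale;
      gp *= scale;
    }
    for (int k = 0; k < n * m; ++k) {
      vc1_[k] = momentum * vc1_[k] - lr * gc1[k];
      c1_[k] += vc1_[k];
      vc2_[k] = momentum * vc2_[k] - lr * gc2[k];
      c2_[k] += vc2_[k];
      vsg_[k] = momentum * vsg_[k] - lr * gsg[k];
      sg_[k] += vsg_[k];
      if (sg_[k] < SIGMA_FLOOR) sg_[k] = SIGMA_FLOOR;
      if (c1_[k] > c2_[k]) std::swap(c1_[k], c2_[k]);
    }
    for (int k = 0; k < m * n; ++k) { vV_[k] = momentum * vV_[k] - lr * gV[k]; V_[k] += vV_[k]; }
    for (int k = 0; k < n * p; ++k) { vW_[k] = momentum * vW_[k] - lr * gW[k]; W_[k] += vW_[k]; }
    if (train_pq) {
      vp_ = momentum * vp_ - lr * gp;
      pc += vp_;
      if (pc < 0.0) pc = 0.0;
      if (pc > 1.0) pc = 1.0;
      qc = 1.0 - pc;
    }
    ++n_updates;
  }
  return List::create(_["c1"] = c1_, _["c2"] = c2_, _["sigma"] = sg_,
                      _["V"] = V_, _["W"] = W_, _["p_coef"] = pc,
                      _["q_coef"] = qc, _["vc1"] = vc1_, _["vc2"] = vc2_,
                      _["vsigma"] = vsg_, _["vV"] = vV_, _["vW"] = vW_,
                      _["vp"] = vp_, _["n_updates"] = n_updates,
                      _["guarded"] = guarded);
}
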