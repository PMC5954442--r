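// Metainference restraint (marginalized erf score), hinge-chain prior and
// multi-replica overdamped Langevin sampler with well-tempered metadynamics.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static const double TWO_PI_M32 = 0.06349363593424097; // (2*pi)^(-3/2)
static const double SQRT2 = 1.4142135623730951;
static const double LOG_2_SQRTPI = 0.1207822376352453; // log(2/sqrt(pi))
static const double TWO_SQRTPI = 1.1283791670955126;    // 2/sqrt(pi)

// ---------------------------------------------------------------------------
// marginalized per-component score: E(delta) = -kBT * log(erf(u)/(2*delta)),
// u = delta/(sqrt(2)*sigma). Written as -kBT*[log(erf(u)/u) - log(2*sqrt2*sigma)]
// which is even in delta and finite at delta = 0. Series below |u| = 0.1.
static double score_term(double delta, double sigma, double kBT,
                         double *dEdD) {
  const double u = delta / (SQRT2 * sigma);
  const double au = std::fabs(u);
  double lr, h;
  if (au < 0.1) {
    const double u2 = u * u;
    lr = LOG_2_SQRTPI + u2 * (-1.0 / 3.0 + u2 * (2.0 / 45.0 - u2 * 8.0 / 2835.0));
    h = u * (-2.0 / 3.0 + u2 * (8.0 / 45.0 - u2 * 16.0 / 945.0));
  } else {
    const double e = std::erf(au);
    lr = std::log(e / au);
    double ha = TWO_SQRTPI * std::exp(-au * au) / e - 1.0 / au;
    h = (u > 0) ? ha : -ha;
  }
  if (dEdD) *dEdD = -kBT * h / (SQRT2 * sigma);
  return -kBT * (lr - std::log(2.0 * SQRT2 * sigma));
}

// [[Rcpp::export]]
List cpp_score_terms(NumericVector delta, NumericVector sigma, double kBT) {
  const int n = delta.size();
  NumericVector e(n), g(n);
  for (int i = 0; i < n; ++i) {
    double d;
    e[i] = score_term(delta[i], sigma[i], kBT, &d);
    g[i] = d;
  }
  return List::create(_["energy"] = e, _["dEdDelta"] = g);
}

// ---------------------------------------------------------------------------
// Data-GMM combined with isotropic bead Gaussians: precomputed inverses.
struct DataGMM {
  int K;
  std::vector<double> pref;  // K x nclass: w_i*(2pi)^-3/2 det^-1/2
  std::vector<double> inv;   // K x nclass x 6 packed inverse
  std::vector<double> mu;    // K x 3
  std::vector<double> ovDD, sig; // per component
  int nclass;
  std::vector<int> cls; // bead -> class
  std::vector<double> wbead, s2bead;
};

static bool inv3p(const double S[6], double inv[6], double &det) {
  const double a = S[0], d = S[1], f = S[2], b = S[3], c = S[4], e = S[5];
  const double A = d * f - e * e, B = c * e - b * f, C = b * e - c * d;
  det = a * A + b * B + c * C;
  if (!(det > 1e-300)) return false;
  const double id = 1.0 / det;
  inv[0] = A * id; inv[3] = B * id; inv[4] = C * id;
  inv[1] = (a * f - c * c) * id; inv[5] = (b * c - a * e) * id;
  inv[2] = (a * d - b * b) * id;
  return true;
}

static DataGMM make_data(NumericVector wD, NumericMatrix muD,
                         NumericVector sigD, NumericVector ovDD,
                         NumericVector sigma_sem, NumericVector wbead,
                         NumericVector s2bead) {
  DataGMM g;
  g.K = wD.size();
  const int n = wbead.size();
  g.wbead.assign(wbead.begin(), wbead.end());
  g.s2bead.assign(s2bead.begin(), s2bead.end());
  g.ovDD.assign(ovDD.begin(), ovDD.end());
  g.sig.assign(sigma_sem.begin(), sigma_sem.end());
  // unique bead variance classes
  std::vector<double> uq;
  g.cls.resize(n);
  for (int m = 0; m < n; ++m) {
    int c = -1;
    for (size_t t = 0; t < uq.size(); ++t)
      if (std::fabs(uq[t] - s2bead[m]) < 1e-15) { c = (int)t; break; }
    if (c < 0) { uq.push_back(s2bead[m]); c = (int)uq.size() - 1; }
    g.cls[m] = c;
  }
  g.nclass = (int)uq.size();
  g.pref.resize((size_t)g.K * g.nclass);
  g.inv.resize((size_t)g.K * g.nclass * 6);
  g.mu.resize((size_t)g.K * 3);
  for (int i = 0; i < g.K; ++i) {
    for (int a = 0; a < 3; ++a) g.mu[3 * i + a] = muD(i, a);
    const double *m = REAL(sigD) + 9 * i;
    for (int c = 0; c < g.nclass; ++c) {
      double S[6] = {m[0] + uq[c], m[4] + uq[c], m[8] + uq[c],
                     m[1], m[2], m[5]};
      double det, I6[6];
      if (!inv3p(S, I6, det)) stop("degenerate combined covariance");
      g.pref[(size_t)i * g.nclass + c] = wD[i] * TWO_PI_M32 / std::sqrt(det);
      for (int t = 0; t < 6; ++t) g.inv[((size_t)i * g.nclass + c) * 6 + t] = I6[t];
    }
  }
  return g;
}

// neighbor list: for each data component, bead indices kept. qmax = -2*log(cutoff)
typedef std::vector<std::vector<int> > NList;

static NList build_nl(const DataGMM &g, const std::vector<const double *> &xs,
                      int n, double qmax) {
  NList nl(g.K);
  for (int i = 0; i < g.K; ++i) {
    const double *mi = &g.mu[3 * i];
    for (int m = 0; m < n; ++m) {
      const double *I6 = &g.inv[((size_t)i * g.nclass + g.cls[m]) * 6];
      double qmin = 1e300;
      for (size_t r = 0; r < xs.size(); ++r) {
        const double *x = xs[r] + 3 * m;
        const double dx = x[0] - mi[0], dy = x[1] - mi[1], dz = x[2] - mi[2];
        const double q = I6[0] * dx * dx + I6[1] * dy * dy + I6[2] * dz * dz +
                         2.0 * (I6[3] * dx * dy + I6[4] * dx * dz +
                                I6[5] * dy * dz);
        if (q < qmin) qmin = q;
      }
      if (qmin <= qmax) nl[i].push_back(m);
    }
  }
  return nl;
}

struct PairRec { int i, m; double ov, g0, g1, g2; }; // g = Sinv*(x-mu)

// per-replica overlaps + pair records
static void replica_pairs(const DataGMM &g, const double *x, const NList &nl,
                          std::vector<PairRec> &rec, std::vector<double> &ov) {
  rec.clear();
  ov.assign(g.K, 0.0);
  for (int i = 0; i < g.K; ++i) {
    const double *mi = &g.mu[3 * i];
    for (size_t t = 0; t < nl[i].size(); ++t) {
      const int m = nl[i][t];
      const double *I6 = &g.inv[((size_t)i * g.nclass + g.cls[m]) * 6];
      const double dx = x[3 * m] - mi[0], dy = x[3 * m + 1] - mi[1],
                   dz = x[3 * m + 2] - mi[2];
      const double q = I6[0] * dx * dx + I6[1] * dy * dy + I6[2] * dz * dz +
                       2.0 * (I6[3] * dx * dy + I6[4] * dx * dz +
                              I6[5] * dy * dz);
      const double o = g.wbead[m] * g.pref[(size_t)i * g.nclass + g.cls[m]] *
                       std::exp(-0.5 * q);
      ov[i] += o;
      PairRec p;
      p.i = i; p.m = m; p.ov = o;
      p.g0 = I6[0] * dx + I6[3] * dy + I6[4] * dz;
      p.g1 = I6[3] * dx + I6[1] * dy + I6[5] * dz;
      p.g2 = I6[4] * dx + I6[5] * dy + I6[2] * dz;
      rec.push_back(p);
    }
  }
}

// Ensemble metainference energy and forces; optionally per-replica CV
// (single-replica score) and its gradient.
struct MetaOut {
  double energy;
  std::vector<double> ovbar;               // K
  std::vector<std::vector<double> > ovr;   // N x K
  std::vector<double> cv;                  // N
};

static MetaOut meta_eval(const DataGMM &g,
                         const std::vector<const double *> &xs, int n,
                         const NList &nl, double kBT,
                         std::vector<std::vector<double> > *forces,
                         std::vector<std::vector<double> > *cvgrad) {
  const int N = (int)xs.size();
  MetaOut out;
  out.ovbar.assign(g.K, 0.0);
  out.ovr.resize(N);
  out.cv.assign(N, 0.0);
  std::vector<std::vector<PairRec> > recs(N);
  std::vector<double> ov;
  for (int r = 0; r < N; ++r) {
    replica_pairs(g, xs[r], nl, recs[r], ov);
    out.ovr[r] = ov;
    for (int i = 0; i < g.K; ++i) out.ovbar[i] += ov[i] / N;
  }
  out.energy = 0.0;
  std::vector<double> dEdD(g.K);
  for (int i = 0; i < g.K; ++i) {
    double d;
    out.energy += score_term(g.ovDD[i] - out.ovbar[i], g.sig[i], kBT, &d);
    dEdD[i] = d;
  }
  for (int r = 0; r < N; ++r) {
    // per-replica CV: single-replica score
    std::vector<double> dCVdD(g.K);
    for (int i = 0; i < g.K; ++i) {
      double d;
      out.cv[r] += score_term(g.ovDD[i] - out.ovr[r][i], g.sig[i], kBT, &d);
      dCVdD[i] = d;
    }
    if (forces) {
      std::vector<double> &F = (*forces)[r];
      std::vector<double> *G = cvgrad ? &(*cvgrad)[r] : 0;
      for (size_t t = 0; t < recs[r].size(); ++t) {
        const PairRec &p = recs[r][t];
        // dDelta_i/dx = +(1/N)*ov*Sinv*d  (Delta = ovDD - ovbar)
        const double c = dEdD[p.i] * p.ov / N;
        F[3 * p.m] -= c * p.g0;
        F[3 * p.m + 1] -= c * p.g1;
        F[3 * p.m + 2] -= c * p.g2;
        if (G) {
          const double cc = dCVdD[p.i] * p.ov; // dCV/dx = +ov*Sinv*d*dCVdD
          (*G)[3 * p.m] += cc * p.g0;
          (*G)[3 * p.m + 1] += cc * p.g1;
          (*G)[3 * p.m + 2] += cc * p.g2;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_meta_score(List positions, NumericVector wbead, NumericVector s2bead,
                    NumericVector wD, NumericMatrix muD, NumericVector sigD,
                    NumericVector ovDD, NumericVector sigma_sem, double kBT,
                    Nullable<List> nlist) {
  const int N = positions.size();
  std::vector<NumericMatrix> xs_(N);
  std::vector<const double *> xs(N);
  int n = 0;
  for (int r = 0; r < N; ++r) {
    xs_[r] = as<NumericMatrix>(positions[r]);
    n = xs_[r].nrow();
  }
  // positions arrive n x 3 column-major; repack to xyz-contiguous
  std::vector<std::vector<double> > packed(N, std::vector<double>(3 * n));
  for (int r = 0; r < N; ++r) {
    for (int m = 0; m < n; ++m)
      for (int a = 0; a < 3; ++a) packed[r][3 * m + a] = xs_[r](m, a);
    xs[r] = &packed[r][0];
  }
  DataGMM g = make_data(wD, muD, sigD, ovDD, sigma_sem, wbead, s2bead);
  NList nl;
  if (nlist.isNotNull()) {
    List L(nlist);
    nl.resize(g.K);
    for (int i = 0; i < g.K; ++i) {
      IntegerVector v = L[i];
      for (int t = 0; t < v.size(); ++t) nl[i].push_back(v[t] - 1);
    }
  } else {
    nl.resize(g.K);
    for (int i = 0; i < g.K; ++i)
      for (int m = 0; m < n; ++m) nl[i].push_back(m);
  }
  std::vector<std::vector<double> > forces(N, std::vector<double>(3 * n, 0.0));
  MetaOut out = meta_eval(g, xs, n, nl, kBT, &forces, 0);
  List Fl(N);
  for (int r = 0; r < N; ++r) {
    NumericMatrix Fm(n, 3);
    for (int m = 0; m < n; ++m)
      for (int a = 0; a < 3; ++a) Fm(m, a) = forces[r][3 * m + a];
    Fl[r] = Fm;
  }
  NumericMatrix ovr(N, g.K);
  for (int r = 0; r < N; ++r)
    for (int i = 0; i < g.K; ++i) ovr(r, i) = out.ovr[r][i];
  return List::create(_["energy"] = out.energy, _["forces"] = Fl,
                      _["ovbar"] = NumericVector(out.ovbar.begin(), out.ovbar.end()),
                      _["ov_replica"] = ovr,
                      _["cv"] = NumericVector(out.cv.begin(), out.cv.end()));
}

// ---------------------------------------------------------------------------
// Hinge-chain prior: harmonic bonds, harmonic angles (theta0 = pi), and a
// quartic double well (+ linear tilt) on one hinge angle.
struct ChainPrior {
  double kb, r0, ka, h, a, thetac, tilt;
  int hinge; // 0-based center bead of the hinge angle
  double com_k, com_ref[3]; // weak center-of-mass tether (0 = off)
};

static double chain_eval(const ChainPrior &p, const double *x, int n,
                         double *F) {
  double E = 0.0;
  if (F) for (int t = 0; t < 3 * n; ++t) F[t] = 0.0;
  for (int i = 0; i + 1 < n; ++i) {
    const double dx = x[3 * (i + 1)] - x[3 * i],
                 dy = x[3 * (i + 1) + 1] - x[3 * i + 1],
                 dz = x[3 * (i + 1) + 2] - x[3 * i + 2];
    const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    const double dr = r - p.r0;
    E += 0.5 * p.kb * dr * dr;
    if (F && r > 1e-12) {
      const double c = p.kb * dr / r;
      F[3 * i] += c * dx; F[3 * i + 1] += c * dy; F[3 * i + 2] += c * dz;
      F[3 * (i + 1)] -= c * dx; F[3 * (i + 1) + 1] -= c * dy;
      F[3 * (i + 1) + 2] -= c * dz;
    }
  }
  for (int j = 1; j + 1 < n; ++j) {
    const double *xi = x + 3 * (j - 1), *xj = x + 3 * j, *xk = x + 3 * (j + 1);
    double u[3] = {xi[0] - xj[0], xi[1] - xj[1], xi[2] - xj[2]};
    double v[3] = {xk[0] - xj[0], xk[1] - xj[1], xk[2] - xj[2]};
    const double nu = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
    const double nv = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
    double c = (u[0] * v[0] + u[1] * v[1] + u[2] * v[2]) / (nu * nv);
    if (c > 1.0) c = 1.0;
    if (c < -1.0) c = -1.0;
    const double th = std::acos(c);
    double dV;
    if (j == p.hinge) {
      const double t = th - p.thetac;
      const double a2 = p.a * p.a;
      const double q = t * t - a2;
      E += p.h * q * q / (a2 * a2) + p.tilt * t;
      dV = 4.0 * p.h * t * q / (a2 * a2) + p.tilt;
    } else {
      const double t = th - M_PI;
      E += 0.5 * p.ka * t * t;
      dV = p.ka * t;
    }
    if (F) {
      double s = std::sqrt(1.0 - c * c);
      if (s < 1e-8) s = 1e-8;
      // dtheta/dxi = -(1/s) * (v/(nu*nv) - c*u/nu^2), similarly for xk
      for (int a3 = 0; a3 < 3; ++a3) {
        const double dti = -(v[a3] / (nu * nv) - c * u[a3] / (nu * nu)) / s;
        const double dtk = -(u[a3] / (nu * nv) - c * v[a3] / (nv * nv)) / s;
        F[3 * (j - 1) + a3] -= dV * dti;
        F[3 * (j + 1) + a3] -= dV * dtk;
        F[3 * j + a3] += dV * (dti + dtk);
      }
    }
  }
  if (p.com_k > 0) {
    double c3[3] = {0, 0, 0};
    for (int m = 0; m < n; ++m)
      for (int a = 0; a < 3; ++a) c3[a] += x[3 * m + a] / n;
    double d[3] = {c3[0] - p.com_ref[0], c3[1] - p.com_ref[1],
                   c3[2] - p.com_ref[2]};
    E += 0.5 * p.com_k * (d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    if (F)
      for (int m = 0; m < n; ++m)
        for (int a = 0; a < 3; ++a) F[3 * m + a] -= p.com_k * d[a] / n;
  }
  return E;
}

static ChainPrior prior_from_list(List pr) {
  ChainPrior p;
  p.kb = pr["kb"]; p.r0 = pr["r0"]; p.ka = pr["ka"];
  p.h = pr["barrier"]; p.a = pr["half_sep"]; p.thetac = pr["theta_center"];
  p.tilt = pr["tilt"];
  p.hinge = as<int>(pr["hinge"]) - 1;
  p.com_k = pr.containsElementNamed("com_k") ? as<double>(pr["com_k"]) : 0.0;
  p.com_ref[0] = p.com_ref[1] = p.com_ref[2] = 0.0;
  if (pr.containsElementNamed("com_ref") && p.com_k > 0) {
    NumericVector cr = pr["com_ref"];
    for (int a = 0; a < 3; ++a) p.com_ref[a] = cr[a];
  }
  return p;
}

// [[Rcpp::export]]
List cpp_chain_energy(NumericMatrix x, List prior) {
  ChainPrior p = prior_from_list(prior);
  const int n = x.nrow();
  std::vector<double> xp(3 * n), F(3 * n);
  for (int m = 0; m < n; ++m)
    for (int a = 0; a < 3; ++a) xp[3 * m + a] = x(m, a);
  double E = chain_eval(p, &xp[0], n, &F[0]);
  NumericMatrix Fm(n, 3);
  for (int m = 0; m < n; ++m)
    for (int a = 0; a < 3; ++a) Fm(m, a) = F[3 * m + a];
  return List::create(_["energy"] = E, _["forces"] = Fm);
}

// ---------------------------------------------------------------------------
// Counter-free deterministic RNG: xoshiro-like via splitmix64 + Box-Muller.
struct RNG {
  uint64_t s;
  explicit RNG(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { // in (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  bool have_spare = false;
  double spare = 0.0;
  double gauss() {
    if (have_spare) { have_spare = false; return spare; }
    const double u1 = unif(), u2 = unif();
    const double r = std::sqrt(-2.0 * std::log(u1));
    spare = r * std::sin(2.0 * M_PI * u2);
    have_spare = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
};

// hinge angle of one replica and its gradient on the three hinge beads
static double hinge_cv(const double *x, int h, double dth[9]) {
  const double *xi = x + 3 * (h - 1), *xj = x + 3 * h, *xk = x + 3 * (h + 1);
  double u[3] = {xi[0] - xj[0], xi[1] - xj[1], xi[2] - xj[2]};
  double v[3] = {xk[0] - xj[0], xk[1] - xj[1], xk[2] - xj[2]};
  const double nu = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
  const double nv = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
  double c = (u[0] * v[0] + u[1] * v[1] + u[2] * v[2]) / (nu * nv);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  double sth = std::sqrt(1.0 - c * c);
  if (sth < 1e-8) sth = 1e-8;
  for (int a = 0; a < 3; ++a) {
    const double dti = -(v[a] / (nu * nv) - c * u[a] / (nu * nu)) / sth;
    const double dtk = -(u[a] / (nu * nv) - c * v[a] / (nv * nv)) / sth;
    dth[a] = dti;          // bead h-1
    dth[6 + a] = dtk;      // bead h+1
    dth[3 + a] = -dti - dtk; // bead h
  }
  return std::acos(c);
}

// 1-D metadynamics bias on a fixed grid, linear interpolation.
struct Bias {
  bool active = false;
  double lo = 0, dx = 1, W0 = 0, kBdT = 1, width = 1;
  std::vector<double> V;
  std::vector<double> hill_c, hill_h;
  void init(double center, double span, double w, double W0_, double kBdT_) {
    lo = center - span;
    width = w;
    dx = w / 5.0;
    V.assign((size_t)std::ceil(2.0 * span / dx) + 2, 0.0);
    W0 = W0_; kBdT = kBdT_;
    active = true;
  }
  double value(double s) const {
    double t = (s - lo) / dx;
    if (t <= 0) return V.front();
    if (t >= V.size() - 1) return V.back();
    int i = (int)t;
    double f = t - i;
    return V[i] * (1 - f) + V[i + 1] * f;
  }
  double deriv(double s) const {
    double t = (s - lo) / dx;
    if (t <= 0 || t >= V.size() - 1) return 0.0;
    int i = (int)t;
    return (V[i + 1] - V[i]) / dx;
  }
  void deposit(double s) {
    const double h = W0 * std::exp(-value(s) / kBdT);
    hill_c.push_back(s);
    hill_h.push_back(h);
    const int i0 = std::max(0, (int)((s - 6 * width - lo) / dx));
    const int i1 = std::min((int)V.size() - 1, (int)((s + 6 * width - lo) / dx) + 1);
    for (int i = i0; i <= i1; ++i) {
      const double d = lo + i * dx - s;
      V[i] += h * std::exp(-d * d / (2.0 * width * width));
    }
  }
};

// [[Rcpp::export]]
List cpp_run_meta(List positions, List prior, NumericVector wbead,
                  NumericVector s2bead, NumericVector wD, NumericMatrix muD,
                  NumericVector sigD, NumericVector ovDD,
                  NumericVector sigma_sem, double kBT, bool restraint_on,
                  double dt, double friction, int steps, int stride,
                  double nl_cutoff, int nl_update, int save_stride,
                  bool use_bias, double W0, double bias_gamma,
                  double hill_width, int pace, double bias_span, double seed,
                  double fmax, int ramp_steps, int cv_type, double bias_stop,
                  double bias_off) {
  const int N = positions.size();
  std::vector<NumericMatrix> x0(N);
  int n = 0;
  for (int r = 0; r < N; ++r) {
    x0[r] = as<NumericMatrix>(positions[r]);
    if (r == 0) n = x0[r].nrow();
    else if (x0[r].nrow() != n) stop("replica topology mismatch");
  }
  ChainPrior pp = prior_from_list(prior);
  std::vector<std::vector<double> > x(N, std::vector<double>(3 * n));
  for (int r = 0; r < N; ++r)
    for (int m = 0; m < n; ++m)
      for (int a = 0; a < 3; ++a) x[r][3 * m + a] = x0[r](m, a);

  DataGMM g;
  NList nl;
  const int K = restraint_on ? wD.size() : 0;
  if (restraint_on)
    g = make_data(wD, muD, sigD, ovDD, sigma_sem, wbead, s2bead);
  const double qmax = -2.0 * std::log(nl_cutoff);

  std::vector<RNG> rng;
  for (int r = 0; r < N; ++r)
    rng.push_back(RNG((uint64_t)seed * 2654435761ULL + 1000003ULL * (r + 1)));

  const double mob = dt / friction;
  const double noise = std::sqrt(2.0 * kBT * dt / friction);

  const int F = steps / save_stride;
  NumericVector traj(Dimension(3 * n, N, F));
  NumericMatrix ovbar_t(F, std::max(K, 1));
  NumericMatrix cv_t(F, N), ebias_t(F, N), erestr_t(F, 1);
  std::fill(ovbar_t.begin(), ovbar_t.end(), NA_REAL);
  std::fill(cv_t.begin(), cv_t.end(), NA_REAL);
  std::fill(ebias_t.begin(), ebias_t.end(), 0.0);
  std::fill(erestr_t.begin(), erestr_t.end(), NA_REAL);

  Bias bias;
  bias.W0 = W0;
  const double kBdT = (bias_gamma - 1.0) * kBT;

  std::vector<std::vector<double> > Fprior(N, std::vector<double>(3 * n));
  std::vector<std::vector<double> > Frestr(N, std::vector<double>(3 * n, 0.0));
  std::vector<std::vector<double> > cvgrad(N, std::vector<double>(3 * n, 0.0));
  std::vector<double> cv_now(N, NA_REAL), vbias_now(N, 0.0);
  std::vector<const double *> xp(N);
  std::vector<std::vector<double> > gprev(N, std::vector<double>(3 * n));
  for (int r = 0; r < N; ++r)
    for (int m = 0; m < 3 * n; ++m) gprev[r][m] = rng[r].gauss();
  double e_restr_now = NA_REAL;
  std::vector<double> ovbar_now(std::max(K, 1), NA_REAL);
  int halved = 0;

  for (int step = 0; step < steps; ++step) {
    for (int r = 0; r < N; ++r) xp[r] = &x[r][0];
    // annealing ramp: restraint force scaled from 0 to 1 over ramp_steps
    const double lambda =
        (ramp_steps > 0 && step < ramp_steps) ? (double)step / ramp_steps : 1.0;
    // bias amplitude: 1 during deposition, linear fade to 0 over
    // [bias_stop, bias_off] (adiabatic release), 0 after
    double mu = 0.0;
    if (use_bias) {
      if (step < bias_stop) mu = 1.0;
      else if (step < bias_off)
        mu = 1.0 - (step - bias_stop) / std::max(1.0, bias_off - bias_stop);
    }
    bool restr_step = restraint_on && (step % stride == 0);
    if (restr_step) {
      if (step % nl_update == 0) nl = build_nl(g, xp, n, qmax);
      for (int r = 0; r < N; ++r) {
        std::fill(Frestr[r].begin(), Frestr[r].end(), 0.0);
        std::fill(cvgrad[r].begin(), cvgrad[r].end(), 0.0);
      }
      MetaOut mo = meta_eval(g, xp, n, nl, kBT, &Frestr, &cvgrad);
      e_restr_now = mo.energy;
      for (int i = 0; i < K; ++i) ovbar_now[i] = mo.ovbar[i];
      for (int r = 0; r < N; ++r) cv_now[r] = mo.cv[r];
      if (use_bias && cv_type == 0 && mu > 0.0) {
        if (!bias.active && step < bias_stop) {
          double c0 = 0;
          for (int r = 0; r < N; ++r) c0 += mo.cv[r] / N;
          bias.init(c0, bias_span, hill_width, W0, kBdT);
        }
        if (bias.active) {
          if (step % pace == 0 && step < bias_stop)
            for (int r = 0; r < N; ++r) bias.deposit(mo.cv[r]);
          for (int r = 0; r < N; ++r)
            vbias_now[r] = mu * bias.value(mo.cv[r]);
        }
      }
    }
    // hinge-angle CV: evaluated every step, bias force on the hinge beads
    double angF[64 * 9]; // per replica: 3 beads x 3 components (N <= 64)
    double ang_now[64];
    bool angle_bias_step = use_bias && cv_type == 1 && mu > 0.0;
    if (angle_bias_step) {
      if (!bias.active) {
        bias.lo = 0.0;
        bias.width = hill_width;
        bias.dx = hill_width / 5.0;
        bias.V.assign((size_t)std::ceil(M_PI / bias.dx) + 2, 0.0);
        bias.W0 = W0;
        bias.kBdT = kBdT;
        bias.active = true;
      }
      for (int r = 0; r < N; ++r) {
        double dth[9];
        ang_now[r] = hinge_cv(&x[r][0], pp.hinge, dth);
        const double dv = mu * bias.deriv(ang_now[r]);
        for (int t = 0; t < 9; ++t) angF[r * 9 + t] = -dv * dth[t];
        vbias_now[r] = mu * bias.value(ang_now[r]);
      }
      if (step % pace == 0 && step < bias_stop)
        for (int r = 0; r < N; ++r) bias.deposit(ang_now[r]);
    }
    for (int r = 0; r < N; ++r) {
      chain_eval(pp, &x[r][0], n, &Fprior[r][0]);
      for (int m = 0; m < 3 * n; ++m) {
        double f = Fprior[r][m];
        if (restr_step) {
          f += stride * lambda * Frestr[r][m];
          if (use_bias && cv_type == 0 && bias.active && mu > 0.0) {
            const double dv = mu * bias.deriv(cv_now[r]);
            f += stride * (-dv * cvgrad[r][m]);
          }
        }
        if (angle_bias_step) {
          const int bead = m / 3, comp = m % 3;
          const int off = bead - (pp.hinge - 1);
          if (off >= 0 && off < 3) f += angF[r * 9 + off * 3 + comp];
        }
        if (std::fabs(f) > fmax) {
          if (halved == 0) { halved = 1; f = (f > 0 ? fmax : -fmax); }
          else stop("force overflow at step %d (|F| > %g kJ/mol/nm)", step, fmax);
        }
        // Leimkuhler-Matthews (BAOAB-limit) overdamped step: average of
        // consecutive noise increments gives O(dt^2) configurational bias
        const double g = rng[r].gauss();
        x[r][m] += mob * f + noise * 0.5 * (gprev[r][m] + g);
        gprev[r][m] = g;
      }
    }
    if ((step + 1) % save_stride == 0) {
      const int fr = (step + 1) / save_stride - 1;
      for (int r = 0; r < N; ++r)
        for (int m = 0; m < 3 * n; ++m) traj[m + 3 * n * (r + N * fr)] = x[r][m];
      if (restraint_on) {
        for (int i = 0; i < K; ++i) ovbar_t(fr, i) = ovbar_now[i];
        erestr_t(fr, 0) = e_restr_now;
        for (int r = 0; r < N; ++r) cv_t(fr, r) = cv_now[r];
      }
      for (int r = 0; r < N; ++r) ebias_t(fr, r) = vbias_now[r];
    }
  }
  List fin(N);
  for (int r = 0; r < N; ++r) {
    NumericMatrix xm(n, 3);
    for (int m = 0; m < n; ++m)
      for (int a = 0; a < 3; ++a) xm(m, a) = x[r][3 * m + a];
    fin[r] = xm;
  }
  List biasout = R_NilValue;
  if (use_bias && bias.active) {
    NumericVector grid(bias.V.size()), vv(bias.V.size());
    for (size_t i = 0; i < bias.V.size(); ++i) {
      grid[i] = bias.lo + i * bias.dx;
      vv[i] = bias.V[i];
    }
    biasout = List::create(
        _["grid"] = grid, _["potential"] = vv,
        _["hill_centers"] = NumericVector(bias.hill_c.begin(), bias.hill_c.end()),
        _["hill_heights"] = NumericVector(bias.hill_h.begin(), bias.hill_h.end()));
  }
  return List::create(_["traj"] = traj, _["ovbar"] = ovbar_t, _["cv"] = cv_t,
                      _["ebias"] = ebias_t, _["erestraint"] = erestr_t,
                      _["final"] = fin, _["bias"] = biasout,
                      _["halved"] = halved);
}
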