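// Analytic one- and two-electron integrals over contracted Cartesian
// Gaussians via McMurchie-Davidson Hermite expansion.
//
// A "basis" is a flat primitive table (matrix with one row per primitive):
//   col 0 coef (contraction coefficient, primitive norm included)
//   col 1 alpha (exponent)
//   col 2-4 lx, ly, lz (Cartesian powers)
//   col 5-7 Ax, Ay, Az (center, bohr)
//   col 8 fidx (1-based index of the contracted function this row belongs to)
// A contracted function may mix primitives of different angular momentum
// (center-derivative functions do), so all tables are per-primitive.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double PI = 3.14159265358979323846;

// ---------------------------------------------------------------------------
// Boys function F_m(T), m = 0..mmax.
// Series + downward recursion for small T, asymptotic + upward for large T.
static void boys(double T, int mmax, double* F) {
  if (T < 1e-13) {
    for (int m = 0; m <= mmax; ++m) F[m] = 1.0 / (2.0 * m + 1.0) - T / (2.0 * m + 3.0);
    return;
  }
  if (T < 35.0) {
    double e = std::exp(-T);
    double term = 1.0 / (2.0 * mmax + 1.0);
    double sum = term;
    for (int i = 1; i < 1000; ++i) {
      term *= 2.0 * T / (2.0 * mmax + 2.0 * i + 1.0);
      sum += term;
      if (term < 1e-17 * sum) break;
    }
    F[mmax] = e * sum;
    for (int m = mmax - 1; m >= 0; --m)
      F[m] = (2.0 * T * F[m + 1] + e) / (2.0 * m + 1.0);
  } else {
    double e = std::exp(-T);
    F[0] = 0.88622692545275801365 / std::sqrt(T); // erf(sqrt(T)) == 1 here
    for (int m = 0; m < mmax; ++m)
      F[m + 1] = ((2.0 * m + 1.0) * F[m] - e) / (2.0 * T);
  }
}

// ---------------------------------------------------------------------------
// Hermite expansion coefficients E_t^{ij} for a 1D primitive pair.
// Stored row-major in v[(i*(jmax+1) + j)*(imax+jmax+1) + t].
struct Etab {
  int imax, jmax, tdim;
  std::vector<double> v;
  inline double g(int i, int j, int t) const {
    if (t < 0 || t > i + j) return 0.0;
    return v[(size_t)(i * (jmax + 1) + j) * tdim + t];
  }
};

static void fillE(double a, double b, double AB, int imax, int jmax, Etab& E) {
  double p = a + b;
  double mu = a * b / p;
  double XPA = -b * AB / p; // P - A with AB = A - B
  double XPB = a * AB / p;  // P - B
  E.imax = imax; E.jmax = jmax; E.tdim = imax + jmax + 1;
  E.v.assign((size_t)(imax + 1) * (jmax + 1) * E.tdim, 0.0);
  auto set = [&](int i, int j, int t, double val) {
    E.v[(size_t)(i * (jmax + 1) + j) * E.tdim + t] = val;
  };
  set(0, 0, 0, std::exp(-mu * AB * AB));
  for (int i = 0; i < imax; ++i)
    for (int t = 0; t <= i + 1; ++t)
      set(i + 1, 0, t, (t > 0 ? E.g(i, 0, t - 1) / (2.0 * p) : 0.0)
                        + XPA * E.g(i, 0, t)
                        + (t + 1.0) * E.g(i, 0, t + 1));
  for (int j = 0; j < jmax; ++j)
    for (int i = 0; i <= imax; ++i)
      for (int t = 0; t <= i + j + 1; ++t)
        set(i, j + 1, t, (t > 0 ? E.g(i, j, t - 1) / (2.0 * p) : 0.0)
                          + XPB * E.g(i, j, t)
                          + (t + 1.0) * E.g(i, j, t + 1));
}

// ---------------------------------------------------------------------------
// Hermite Coulomb integrals R^0_{tuv}(p, PC) for t<=tmax, u<=umax, v<=vmax.
struct Rtab {
  int tmax, umax, vmax;
  std::vector<double> v;
  inline double g(int t, int u, int v_) const {
    return v[(size_t)(t * (umax + 1) + u) * (vmax + 1) + v_];
  }
};

static void fillR(double p, double X, double Y, double Z,
                  int tmax, int umax, int vmax, Rtab& R) {
  int N = tmax + umax + vmax;
  std::vector<double> F(N + 1);
  double T = p * (X * X + Y * Y + Z * Z);
  boys(T, N, F.data());
  // work array indexed [n][t][u][v]
  int dt = tmax + 1, du = umax + 1, dv = vmax + 1;
  std::vector<double> W((size_t)(N + 1) * dt * du * dv, 0.0);
  auto idx = [&](int n, int t, int u, int v_) {
    return ((size_t)n * dt * du * dv) + (size_t)(t * du + u) * dv + v_;
  };
  double m2p = 1.0;
  for (int n = 0; n <= N; ++n) { W[idx(n, 0, 0, 0)] = m2p * F[n]; m2p *= -2.0 * p; }
  for (int t = 0; t < tmax; ++t)
    for (int n = 0; n <= N - t - 1; ++n)
      W[idx(n, t + 1, 0, 0)] = (t > 0 ? t * W[idx(n + 1, t - 1, 0, 0)] : 0.0)
                               + X * W[idx(n + 1, t, 0, 0)];
  for (int u = 0; u < umax; ++u)
    for (int t = 0; t <= tmax; ++t)
      for (int n = 0; n <= N - t - u - 1; ++n)
        W[idx(n, t, u + 1, 0)] = (u > 0 ? u * W[idx(n + 1, t, u - 1, 0)] : 0.0)
                                 + Y * W[idx(n + 1, t, u, 0)];
  for (int v_ = 0; v_ < vmax; ++v_)
    for (int u = 0; u <= umax; ++u)
      for (int t = 0; t <= tmax; ++t)
        for (int n = 0; n <= N - t - u - v_ - 1; ++n)
          W[idx(n, t, u, v_ + 1)] = (v_ > 0 ? v_ * W[idx(n + 1, t, u, v_ - 1)] : 0.0)
                                    + Z * W[idx(n + 1, t, u, v_)];
  R.tmax = tmax; R.umax = umax; R.vmax = vmax;
  R.v.assign((size_t)dt * du * dv, 0.0);
  for (int t = 0; t <= tmax; ++t)
    for (int u = 0; u <= umax; ++u)
      for (int v_ = 0; v_ <= vmax; ++v_)
        R.v[(size_t)(t * du + u) * dv + v_] = W[idx(0, t, u, v_)];
}

// ---------------------------------------------------------------------------
struct Prim {
  double c, a;
  int l[3];
  double A[3];
  int f; // 0-based function index
};

static std::vector<Prim> parse(const NumericMatrix& m) {
  std::vector<Prim> out(m.nrow());
  for (int i = 0; i < m.nrow(); ++i) {
    Prim p;
    p.c = m(i, 0); p.a = m(i, 1);
    p.l[0] = (int)m(i, 2); p.l[1] = (int)m(i, 3); p.l[2] = (int)m(i, 4);
    p.A[0] = m(i, 5); p.A[1] = m(i, 6); p.A[2] = m(i, 7);
    p.f = (int)m(i, 8) - 1;
    out[i] = p;
  }
  return out;
}

static int nfun(const std::vector<Prim>& b) {
  int n = 0;
  for (auto& p : b) n = std::max(n, p.f + 1);
  return n;
}

// 1D overlap-type integral S(i,j) = E_0^{ij} sqrt(pi/p)
static inline double s1d(const Etab& E, int i, int j, double p) {
  return E.g(i, j, 0) * std::sqrt(PI / p);
}

// ---------------------------------------------------------------------------
// One-electron matrices.  type: 0 overlap, 1 kinetic, 2 nuclear, 3 nabla.
// For nuclear: Z (charges) and Rn (nat x 3) give the attracting centers.
// For nabla: dir in 0..2, operator d/dr_dir acting on the ket.
// [[Rcpp::export]]
NumericMatrix cpp_int1e(NumericMatrix primA, NumericMatrix primB, int type,
                        NumericVector Z, NumericMatrix Rn, int dir) {
  std::vector<Prim> A = parse(primA), B = parse(primB);
  int na = nfun(A), nb = nfun(B);
  NumericMatrix out(na, nb);
  Etab E[3];
  for (auto& pa : A) {
    for (auto& pb : B) {
      double p = pa.a + pb.a;
      int margin = (type == 1) ? 2 : (type == 3 ? 1 : 0);
      for (int d = 0; d < 3; ++d)
        fillE(pa.a, pb.a, pa.A[d] - pb.A[d], pa.l[d], pb.l[d] + margin, E[d]);
      double cc = pa.c * pb.c;
      double val = 0.0;
      if (type == 0) {
        val = s1d(E[0], pa.l[0], pb.l[0], p)
            * s1d(E[1], pa.l[1], pb.l[1], p)
            * s1d(E[2], pa.l[2], pb.l[2], p);
      } else if (type == 1) {
        double s[3], t[3];
        for (int d = 0; d < 3; ++d) {
          int i = pa.l[d], j = pb.l[d];
          double b = pb.a;
          s[d] = s1d(E[d], i, j, p);
          double sjm2 = (j >= 2) ? s1d(E[d], i, j - 2, p) : 0.0;
          t[d] = -0.5 * (j * (j - 1.0) * sjm2
                         - 2.0 * b * (2.0 * j + 1.0) * s[d]
                         + 4.0 * b * b * s1d(E[d], i, j + 2, p));
        }
        val = t[0] * s[1] * s[2] + s[0] * t[1] * s[2] + s[0] * s[1] * t[2];
      } else if (type == 3) {
        double s[3], dd[3];
        for (int d = 0; d < 3; ++d) {
          int i = pa.l[d], j = pb.l[d];
          s[d] = s1d(E[d], i, j, p);
          double sjm1 = (j >= 1) ? s1d(E[d], i, j - 1, p) : 0.0;
          dd[d] = j * sjm1 - 2.0 * pb.a * s1d(E[d], i, j + 1, p);
        }
        val = (dir == 0 ? dd[0] * s[1] * s[2]
               : (dir == 1 ? s[0] * dd[1] * s[2] : s[0] * s[1] * dd[2]));
      } else { // nuclear
        double P[3];
        for (int d = 0; d < 3; ++d) P[d] = (pa.a * pa.A[d] + pb.a * pb.A[d]) / p;
        int tmax = pa.l[0] + pb.l[0], umax = pa.l[1] + pb.l[1], vmax = pa.l[2] + pb.l[2];
        Rtab R;
        for (int c = 0; c < Z.size(); ++c) {
          fillR(p, P[0] - Rn(c, 0), P[1] - Rn(c, 1), P[2] - Rn(c, 2),
                tmax, umax, vmax, R);
          double acc = 0.0;
          for (int t = 0; t <= tmax; ++t)
            for (int u = 0; u <= umax; ++u)
              for (int v_ = 0; v_ <= vmax; ++v_)
                acc += E[0].g(pa.l[0], pb.l[0], t)
                     * E[1].g(pa.l[1], pb.l[1], u)
                     * E[2].g(pa.l[2], pb.l[2], v_)
                     * R.g(t, u, v_);
          val += -Z[c] * (2.0 * PI / p) * acc;
        }
      }
      out(pa.f, pb.f) += cc * val;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Primitive-pair data with Hermite tables for ERI assembly.
struct PPair {
  double p, P[3], cc;
  int li[3], lj[3];
  Etab E[3];
};

static void makePairs(const std::vector<Prim>& A, const std::vector<Prim>& B,
                      int ia, int ib, std::vector<PPair>& out,
                      const std::vector<std::vector<int>>& byfA,
                      const std::vector<std::vector<int>>& byfB) {
  out.clear();
  for (int i : byfA[ia]) {
    for (int j : byfB[ib]) {
      PPair q;
      const Prim &pa = A[i], &pb = B[j];
      q.p = pa.a + pb.a;
      q.cc = pa.c * pb.c;
      for (int d = 0; d < 3; ++d) {
        q.P[d] = (pa.a * pa.A[d] + pb.a * pb.A[d]) / q.p;
        q.li[d] = pa.l[d]; q.lj[d] = pb.l[d];
        fillE(pa.a, pb.a, pa.A[d] - pb.A[d], pa.l[d], pb.l[d], q.E[d]);
      }
      out.push_back(q);
    }
  }
}

static std::vector<std::vector<int>> groupByFun(const std::vector<Prim>& b, int n) {
  std::vector<std::vector<int>> g(n);
  for (size_t i = 0; i < b.size(); ++i) g[b[i].f].push_back((int)i);
  return g;
}

// contract one bra PPair with one ket PPair
static double eriPair(const PPair& a, const PPair& b) {
  double theta = a.p * b.p / (a.p + b.p);
  int tmax = a.li[0] + a.lj[0], umax = a.li[1] + a.lj[1], vmax = a.li[2] + a.lj[2];
  int Tmax = b.li[0] + b.lj[0], Umax = b.li[1] + b.lj[1], Vmax = b.li[2] + b.lj[2];
  Rtab R;
  fillR(theta, a.P[0] - b.P[0], a.P[1] - b.P[1], a.P[2] - b.P[2],
        tmax + Tmax, umax + Umax, vmax + Vmax, R);
  double acc = 0.0;
  for (int t = 0; t <= tmax; ++t) {
    double Ext = a.E[0].g(a.li[0], a.lj[0], t); if (Ext == 0.0) continue;
    for (int u = 0; u <= umax; ++u) {
      double Eyu = a.E[1].g(a.li[1], a.lj[1], u); if (Eyu == 0.0) continue;
      for (int v_ = 0; v_ <= vmax; ++v_) {
        double Ezv = a.E[2].g(a.li[2], a.lj[2], v_); if (Ezv == 0.0) continue;
        double braE = Ext * Eyu * Ezv;
        for (int T = 0; T <= Tmax; ++T) {
          double fT = b.E[0].g(b.li[0], b.lj[0], T); if (fT == 0.0) continue;
          for (int U = 0; U <= Umax; ++U) {
            double fU = b.E[1].g(b.li[1], b.lj[1], U); if (fU == 0.0) continue;
            for (int V = 0; V <= Vmax; ++V) {
              double fV = b.E[2].g(b.li[2], b.lj[2], V); if (fV == 0.0) continue;
              double sgn = ((T + U + V) % 2) ? -1.0 : 1.0;
              acc += braE * fT * fU * fV * sgn * R.g(t + T, u + U, v_ + V);
            }
          }
        }
      }
    }
  }
  double pref = 2.0 * std::pow(PI, 2.5) / (a.p * b.p * std::sqrt(a.p + b.p));
  return pref * a.cc * b.cc * acc;
}

// Full ERI tensor (mu nu | rho sigma), chemists' notation, 8-fold symmetry.
// Returned as vector of length n^4, column-major index
// mu + n*(nu + n*(rho + n*sigma)) (0-based).
// [[Rcpp::export]]
NumericVector cpp_eri(NumericMatrix prim) {
  std::vector<Prim> A = parse(prim);
  int n = nfun(A);
  auto byf = groupByFun(A, n);
  NumericVector out((R_xlen_t)n * n * n * n);
  double* o = REAL(out);
  size_t nn = (size_t)n;
  // precompute pair blocks for canonical (i>=j)
  int npair = n * (n + 1) / 2;
  std::vector<std::vector<PPair>> pairs(npair);
  std::vector<int> pi_(npair), pj_(npair);
  int k = 0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j <= i; ++j, ++k) {
      makePairs(A, A, i, j, pairs[k], byf, byf);
      pi_[k] = i; pj_[k] = j;
    }
  for (int a = 0; a < npair; ++a) {
    for (int b = 0; b <= a; ++b) {
      double val = 0.0;
      for (auto& pa : pairs[a])
        for (auto& pb : pairs[b])
          val += eriPair(pa, pb);
      int i = pi_[a], j = pj_[a], r = pi_[b], s = pj_[b];
      size_t idx[8][4] = {
        {(size_t)i,(size_t)j,(size_t)r,(size_t)s}, {(size_t)j,(size_t)i,(size_t)r,(size_t)s},
        {(size_t)i,(size_t)j,(size_t)s,(size_t)r}, {(size_t)j,(size_t)i,(size_t)s,(size_t)r},
        {(size_t)r,(size_t)s,(size_t)i,(size_t)j}, {(size_t)s,(size_t)r,(size_t)i,(size_t)j},
        {(size_t)r,(size_t)s,(size_t)j,(size_t)i}, {(size_t)s,(size_t)r,(size_t)j,(size_t)i}};
      for (int m = 0; m < 8; ++m)
        o[idx[m][0] + nn * (idx[m][1] + nn * (idx[m][2] + nn * idx[m][3]))] = val;
    }
  }
  return out;
}

// Mixed ERI block (e nu | rho sigma): bra pairs couple basis E with basis A,
// ket pairs are within basis A.  Returned as vector of length nE*n^3,
// column-major index e + nE*(nu + n*(rho + n*sigma)) (0-based).
// [[Rcpp::export]]
NumericVector cpp_eri_mixed(NumericMatrix primE, NumericMatrix primA) {
  std::vector<Prim> Eb = parse(primE), A = parse(primA);
  int ne = nfun(Eb), n = nfun(A);
  auto byfE = groupByFun(Eb, ne), byfA = groupByFun(A, n);
  NumericVector out((R_xlen_t)ne * n * n * n);
  double* o = REAL(out);
  size_t nn = (size_t)n, nne = (size_t)ne;
  // ket canonical pairs
  int npair = n * (n + 1) / 2;
  std::vector<std::vector<PPair>> ket(npair);
  std::vector<int> pr(npair), ps(npair);
  int k = 0;
  for (int r = 0; r < n; ++r)
    for (int s = 0; s <= r; ++s, ++k) {
      makePairs(A, A, r, s, ket[k], byfA, byfA);
      pr[k] = r; ps[k] = s;
    }
  std::vector<PPair> bra;
  for (int e = 0; e < ne; ++e) {
    for (int nu = 0; nu < n; ++nu) {
      makePairs(Eb, A, e, nu, bra, byfE, byfA);
      for (int b = 0; b < npair; ++b) {
        double val = 0.0;
        for (auto& pa : bra)
          for (auto& pb : ket[b])
            val += eriPair(pa, pb);
        o[(size_t)e + nne * ((size_t)nu + nn * ((size_t)pr[b] + nn * ps[b]))] = val;
        o[(size_t)e + nne * ((size_t)nu + nn * ((size_t)ps[b] + nn * pr[b]))] = val;
      }
    }
  }
  return out;
}
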