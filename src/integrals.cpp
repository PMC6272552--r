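// Gaussian integral core: McMurchie-Davidson Hermite scheme.
//
// Orbital shells arrive from R as lists:
//   center : numeric(3), bohr
//   l      : total angular momentum (<= 2)
//   comps  : integer matrix ncomp x 3 of Cartesian powers (lx,ly,lz)
//   exps   : primitive exponents (bohr^-2)
//   coefn  : ncomp x nprim matrix of fully normalized contraction
//            coefficients (primitive norm x contraction renorm included)
// Auxiliary (Hermite Gaussian) functions:
//   center : numeric(3); herm : integer(3) Hermite index; zeta : exponent;
//   norm   : normalization constant (self-overlap = 1 convention).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double PI_ = 3.14159265358979323846;

static double dfact(int n) { // n!! with (-1)!! = 0!! = 1
  double r = 1.0;
  for (int k = n; k > 1; k -= 2) r *= k;
  return r;
}

// ---------------------------------------------------------------- Boys F_n(x)
// Series + downward recursion below the switch point, asymptotic + upward
// recursion above.  Switch point 40 keeps both branches at ~1e-15 accuracy.
static void boys_fill(int nmax, double x, std::vector<double>& F) {
  F.assign(nmax + 1, 0.0);
  if (x < 1e-14) {
    for (int n = 0; n <= nmax; ++n) F[n] = 1.0 / (2.0 * n + 1.0);
    return;
  }
  if (x < 40.0) {
    // series for F_nmax, then downward
    double term = 1.0 / (2.0 * nmax + 1.0), sum = term;
    for (int k = 1; k < 1000; ++k) {
      term *= 2.0 * x / (2.0 * nmax + 2.0 * k + 1.0);
      sum += term;
      if (term < sum * 1e-17) break;
    }
    double ex = std::exp(-x);
    F[nmax] = sum * ex;
    for (int n = nmax; n > 0; --n)
      F[n - 1] = (2.0 * x * F[n] + ex) / (2.0 * n - 1.0);
  } else {
    double ex = std::exp(-x); // <= e^-40, kept for completeness
    F[0] = 0.5 * std::sqrt(PI_ / x);
    for (int n = 0; n < nmax; ++n)
      F[n + 1] = ((2.0 * n + 1.0) * F[n] - ex) / (2.0 * x);
  }
}

// [[Rcpp::export]]
NumericVector cpp_boys(int nmax, double x) {
  if (nmax < 0 || x < 0) stop("boys: arguments must be non-negative");
  std::vector<double> F;
  boys_fill(nmax, x, F);
  return NumericVector(F.begin(), F.end());
}

// ------------------------------------------------- Hermite expansion E-table
// E[i][j][t] per Cartesian direction; E000 carries the Gaussian prefactor.
struct Etab {
  int imax, jmax, tmax;
  std::vector<double> v;
  Etab(int i, int j) : imax(i), jmax(j), tmax(i + j),
    v((size_t)(i + 1) * (j + 1) * (i + j + 1), 0.0) {}
  inline double& at(int i, int j, int t) {
    return v[((size_t)i * (jmax + 1) + j) * (tmax + 1) + t];
  }
  inline double get(int i, int j, int t) const {
    if (t < 0 || t > i + j) return 0.0;
    return v[((size_t)i * (jmax + 1) + j) * (tmax + 1) + t];
  }
};

static void fill_etab(Etab& E, double p, double PA, double PB, double K) {
  double o2p = 0.5 / p;
  E.at(0, 0, 0) = K;
  for (int i = 0; i < E.imax; ++i)
    for (int t = 0; t <= i + 1; ++t)
      E.at(i + 1, 0, t) = o2p * E.get(i, 0, t - 1) + PA * E.get(i, 0, t)
                        + (t + 1) * E.get(i, 0, t + 1);
  for (int i = 0; i <= E.imax; ++i)
    for (int j = 0; j < E.jmax; ++j)
      for (int t = 0; t <= i + j + 1; ++t)
        E.at(i, j + 1, t) = o2p * E.get(i, j, t - 1) + PB * E.get(i, j, t)
                          + (t + 1) * E.get(i, j, t + 1);
}

// ------------------------------------------------------- Hermite R_tuv table
// Generic MD recursion on top of caller-supplied base values base[n].
struct Rtab {
  int L;
  std::vector<double> v; // flat cube (L+1)^3, slice n=0 only is kept valid
  Rtab(int L_) : L(L_), v((size_t)(L_ + 1) * (L_ + 1) * (L_ + 1), 0.0) {}
  inline double operator()(int t, int u, int w) const {
    return v[((size_t)t * (L + 1) + u) * (L + 1) + w];
  }
};

static Rtab fill_rtab(int L, const std::vector<double>& base,
                      double X, double Y, double Z) {
  // work array over n
  size_t cube = (size_t)(L + 1) * (L + 1) * (L + 1);
  std::vector<double> W((size_t)(L + 1) * cube, 0.0);
  auto idx = [&](int n, int t, int u, int w) {
    return (size_t)n * cube + ((size_t)t * (L + 1) + u) * (L + 1) + w;
  };
  for (int n = 0; n <= L; ++n) W[idx(n, 0, 0, 0)] = base[n];
  for (int tot = 1; tot <= L; ++tot) {
    for (int n = 0; n <= L - tot; ++n) {
      for (int t = tot; t >= 0; --t) for (int u = tot - t; u >= 0; --u) {
        int w = tot - t - u;
        double val;
        if (t > 0) {
          val = X * W[idx(n + 1, t - 1, u, w)];
          if (t > 1) val += (t - 1) * W[idx(n + 1, t - 2, u, w)];
        } else if (u > 0) {
          val = Y * W[idx(n + 1, t, u - 1, w)];
          if (u > 1) val += (u - 1) * W[idx(n + 1, t, u - 2, w)];
        } else {
          val = Z * W[idx(n + 1, t, u, w - 1)];
          if (w > 1) val += (w - 1) * W[idx(n + 1, t, u, w - 2)];
        }
        W[idx(n, t, u, w)] = val;
      }
    }
  }
  Rtab R(L);
  std::copy(W.begin(), W.begin() + cube, R.v.begin());
  return R;
}

// Coulomb Hermite integrals: base[n] = (-2p)^n F_n(p |PC|^2)
static Rtab coulomb_rtab(int L, double p, double X, double Y, double Z) {
  std::vector<double> F;
  boys_fill(L, p * (X * X + Y * Y + Z * Z), F);
  std::vector<double> base(L + 1);
  double f = 1.0;
  for (int n = 0; n <= L; ++n) { base[n] = f * F[n]; f *= -2.0 * p; }
  return fill_rtab(L, base, X, Y, Z);
}

// 1/R derivative tensors: base[n] = (-1)^n (2n-1)!! / R^(2n+1)
static Rtab invr_rtab(int L, double X, double Y, double Z) {
  double R2 = X * X + Y * Y + Z * Z;
  double R = std::sqrt(R2);
  if (R < 1e-12) stop("t_tensor: coincident centers");
  std::vector<double> base(L + 1);
  double f = 1.0 / R;
  for (int n = 0; n <= L; ++n) {
    base[n] = (n % 2 ? -1.0 : 1.0) * dfact(2 * n - 1) * f;
    f /= R2;
  }
  return fill_rtab(L, base, X, Y, Z);
}

// ------------------------------------------------------------ shell unpacking
struct Shell {
  double A[3];
  int l, ncomp, nprim;
  std::vector<int> lx, ly, lz;
  std::vector<double> z;      // exponents
  std::vector<double> c;      // coefn, ncomp x nprim column-major (R layout)
  inline double coef(int comp, int k) const { return c[(size_t)k * ncomp + comp]; }
};

static Shell unpack_shell(const List& s) {
  Shell sh;
  NumericVector ctr = s["center"];
  for (int i = 0; i < 3; ++i) sh.A[i] = ctr[i];
  sh.l = as<int>(s["l"]);
  IntegerMatrix comps = s["comps"];
  sh.ncomp = comps.nrow();
  sh.lx.resize(sh.ncomp); sh.ly.resize(sh.ncomp); sh.lz.resize(sh.ncomp);
  for (int i = 0; i < sh.ncomp; ++i) {
    sh.lx[i] = comps(i, 0); sh.ly[i] = comps(i, 1); sh.lz[i] = comps(i, 2);
  }
  NumericVector e = s["exps"];
  sh.z.assign(e.begin(), e.end());
  sh.nprim = sh.z.size();
  NumericMatrix cn = s["coefn"];
  sh.c.assign(cn.begin(), cn.end());
  return sh;
}

struct AuxFn {
  double C[3];
  int h[3];
  double zeta, norm;
};

static AuxFn unpack_aux(const List& a) {
  AuxFn f;
  NumericVector ctr = a["center"];
  for (int i = 0; i < 3; ++i) f.C[i] = ctr[i];
  IntegerVector h = a["herm"];
  for (int i = 0; i < 3; ++i) f.h[i] = h[i];
  f.zeta = as<double>(a["zeta"]);
  f.norm = as<double>(a["norm"]);
  return f;
}

// --------------------------------------------------------------- overlap(s)
// <a+m|b> for a list of raise indices m; returns array (na, nb, nm)
// [[Rcpp::export]]
NumericVector cpp_ov_block_upto(List A, List B, IntegerMatrix mlist) {
  Shell a = unpack_shell(A), b = unpack_shell(B);
  int nm = mlist.nrow();
  int mmax = 0;
  for (int r = 0; r < nm; ++r)
    for (int d = 0; d < 3; ++d) mmax = std::max(mmax, mlist(r, d));
  NumericVector out((size_t)a.ncomp * b.ncomp * nm);
  double AB[3] = {a.A[0] - b.A[0], a.A[1] - b.A[1], a.A[2] - b.A[2]};
  for (int ka = 0; ka < a.nprim; ++ka) for (int kb = 0; kb < b.nprim; ++kb) {
    double za = a.z[ka], zb = b.z[kb], p = za + zb, mu = za * zb / p;
    double sp = std::pow(PI_ / p, 1.5);
    Etab Ex(a.l + mmax, b.l), Ey(a.l + mmax, b.l), Ez(a.l + mmax, b.l);
    double P[3];
    for (int d = 0; d < 3; ++d) P[d] = (za * a.A[d] + zb * b.A[d]) / p;
    fill_etab(Ex, p, P[0] - a.A[0], P[0] - b.A[0], std::exp(-mu * AB[0] * AB[0]));
    fill_etab(Ey, p, P[1] - a.A[1], P[1] - b.A[1], std::exp(-mu * AB[1] * AB[1]));
    fill_etab(Ez, p, P[2] - a.A[2], P[2] - b.A[2], std::exp(-mu * AB[2] * AB[2]));
    for (int ca = 0; ca < a.ncomp; ++ca) for (int cb = 0; cb < b.ncomp; ++cb) {
      double cc = a.coef(ca, ka) * b.coef(cb, kb) * sp;
      for (int r = 0; r < nm; ++r) {
        double val = Ex.get(a.lx[ca] + mlist(r, 0), b.lx[cb], 0)
                   * Ey.get(a.ly[ca] + mlist(r, 1), b.ly[cb], 0)
                   * Ez.get(a.lz[ca] + mlist(r, 2), b.lz[cb], 0);
        out[((size_t)r * b.ncomp + cb) * a.ncomp + ca] += cc * val;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(a.ncomp, b.ncomp, nm);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_kin_block(List A, List B) {
  Shell a = unpack_shell(A), b = unpack_shell(B);
  NumericMatrix out(a.ncomp, b.ncomp);
  double AB[3] = {a.A[0] - b.A[0], a.A[1] - b.A[1], a.A[2] - b.A[2]};
  for (int ka = 0; ka < a.nprim; ++ka) for (int kb = 0; kb < b.nprim; ++kb) {
    double za = a.z[ka], zb = b.z[kb], p = za + zb, mu = za * zb / p;
    double sq = std::sqrt(PI_ / p);
    Etab Ex(a.l, b.l + 2), Ey(a.l, b.l + 2), Ez(a.l, b.l + 2);
    double P[3];
    for (int d = 0; d < 3; ++d) P[d] = (za * a.A[d] + zb * b.A[d]) / p;
    fill_etab(Ex, p, P[0] - a.A[0], P[0] - b.A[0], std::exp(-mu * AB[0] * AB[0]));
    fill_etab(Ey, p, P[1] - a.A[1], P[1] - b.A[1], std::exp(-mu * AB[1] * AB[1]));
    fill_etab(Ez, p, P[2] - a.A[2], P[2] - b.A[2], std::exp(-mu * AB[2] * AB[2]));
    auto S = [&](Etab& E, int i, int j) {
      return (j < 0) ? 0.0 : E.get(i, j, 0) * sq;
    };
    auto T1 = [&](Etab& E, int i, int j) {
      double v = -2.0 * zb * zb * S(E, i, j + 2)
               + zb * (2.0 * j + 1.0) * S(E, i, j)
               - 0.5 * j * (j - 1.0) * S(E, i, j - 2);
      return v;
    };
    for (int ca = 0; ca < a.ncomp; ++ca) for (int cb = 0; cb < b.ncomp; ++cb) {
      int i1 = a.lx[ca], i2 = a.ly[ca], i3 = a.lz[ca];
      int j1 = b.lx[cb], j2 = b.ly[cb], j3 = b.lz[cb];
      double val = T1(Ex, i1, j1) * S(Ey, i2, j2) * S(Ez, i3, j3)
                 + S(Ex, i1, j1) * T1(Ey, i2, j2) * S(Ez, i3, j3)
                 + S(Ex, i1, j1) * S(Ey, i2, j2) * T1(Ez, i3, j3);
      out(ca, cb) += a.coef(ca, ka) * b.coef(cb, kb) * val;
    }
  }
  return out;
}

// ---------------------------------------------------- nuclear attraction
// Sum over sites of q_D <a| 1/|r-D| |b>; with grad=true also d/dD contraction
// against unit charge per site is not needed -- gradients have own entry.
// [[Rcpp::export]]
NumericMatrix cpp_nai_sites_block(List A, List B, NumericMatrix sites,
                                  NumericVector q) {
  Shell a = unpack_shell(A), b = unpack_shell(B);
  int ns = sites.nrow();
  NumericMatrix out(a.ncomp, b.ncomp);
  int L = a.l + b.l;
  double AB[3] = {a.A[0] - b.A[0], a.A[1] - b.A[1], a.A[2] - b.A[2]};
  for (int ka = 0; ka < a.nprim; ++ka) for (int kb = 0; kb < b.nprim; ++kb) {
    double za = a.z[ka], zb = b.z[kb], p = za + zb, mu = za * zb / p;
    double pref = 2.0 * PI_ / p;
    Etab Ex(a.l, b.l), Ey(a.l, b.l), Ez(a.l, b.l);
    double P[3];
    for (int d = 0; d < 3; ++d) P[d] = (za * a.A[d] + zb * b.A[d]) / p;
    fill_etab(Ex, p, P[0] - a.A[0], P[0] - b.A[0], std::exp(-mu * AB[0] * AB[0]));
    fill_etab(Ey, p, P[1] - a.A[1], P[1] - b.A[1], std::exp(-mu * AB[1] * AB[1]));
    fill_etab(Ez, p, P[2] - a.A[2], P[2] - b.A[2], std::exp(-mu * AB[2] * AB[2]));
    for (int s = 0; s < ns; ++s) {
      Rtab R = coulomb_rtab(L, p, P[0] - sites(s, 0), P[1] - sites(s, 1),
                            P[2] - sites(s, 2));
      for (int ca = 0; ca < a.ncomp; ++ca) for (int cb = 0; cb < b.ncomp; ++cb) {
        double val = 0.0;
        for (int t = 0; t <= a.lx[ca] + b.lx[cb]; ++t)
          for (int u = 0; u <= a.ly[ca] + b.ly[cb]; ++u)
            for (int w = 0; w <= a.lz[ca] + b.lz[cb]; ++w)
              val += Ex.get(a.lx[ca], b.lx[cb], t) *
                     Ey.get(a.ly[ca], b.ly[cb], u) *
                     Ez.get(a.lz[ca], b.lz[cb], w) * R(t, u, w);
        out(ca, cb) += a.coef(ca, ka) * b.coef(cb, kb) * pref * q[s] * val;
      }
    }
  }
  return out;
}

// d<ab|1/|r-D||b>/dD, array (na, nb, 3)
// [[Rcpp::export]]
NumericVector cpp_nai_grad_block(List A, List B, NumericVector D) {
  Shell a = unpack_shell(A), b = unpack_shell(B);
  NumericVector out((size_t)a.ncomp * b.ncomp * 3);
  int L = a.l + b.l + 1;
  double AB[3] = {a.A[0] - b.A[0], a.A[1] - b.A[1], a.A[2] - b.A[2]};
  for (int ka = 0; ka < a.nprim; ++ka) for (int kb = 0; kb < b.nprim; ++kb) {
    double za = a.z[ka], zb = b.z[kb], p = za + zb, mu = za * zb / p;
    double pref = 2.0 * PI_ / p;
    Etab Ex(a.l, b.l), Ey(a.l, b.l), Ez(a.l, b.l);
    double P[3];
    for (int d = 0; d < 3; ++d) P[d] = (za * a.A[d] + zb * b.A[d]) / p;
    fill_etab(Ex, p, P[0] - a.A[0], P[0] - b.A[0], std::exp(-mu * AB[0] * AB[0]));
    fill_etab(Ey, p, P[1] - a.A[1], P[1] - b.A[1], std::exp(-mu * AB[1] * AB[1]));
    fill_etab(Ez, p, P[2] - a.A[2], P[2] - b.A[2], std::exp(-mu * AB[2] * AB[2]));
    Rtab R = coulomb_rtab(L, p, P[0] - D[0], P[1] - D[1], P[2] - D[2]);
    for (int ca = 0; ca < a.ncomp; ++ca) for (int cb = 0; cb < b.ncomp; ++cb) {
      double g[3] = {0.0, 0.0, 0.0};
      for (int t = 0; t <= a.lx[ca] + b.lx[cb]; ++t)
        for (int u = 0; u <= a.ly[ca] + b.ly[cb]; ++u)
          for (int w = 0; w <= a.lz[ca] + b.lz[cb]; ++w) {
            double e = Ex.get(a.lx[ca], b.lx[cb], t) *
                       Ey.get(a.ly[ca], b.ly[cb], u) *
                       Ez.get(a.lz[ca], b.lz[cb], w);
            // d/dD_x R_tuv(P-D) = -R_{t+1,u,v}
            g[0] -= e * R(t + 1, u, w);
            g[1] -= e * R(t, u + 1, w);
            g[2] -= e * R(t, u, w + 1);
          }
      double cc = a.coef(ca, ka) * b.coef(cb, kb) * pref;
      for (int d = 0; d < 3; ++d)
        out[((size_t)d * b.ncomp + cb) * a.ncomp + ca] += cc * g[d];
    }
  }
  out.attr("dim") = IntegerVector::create(a.ncomp, b.ncomp, 3);
  return out;
}

// ---------------------------------------------------------------- 3c ERIs
// [[Rcpp::export]]
NumericMatrix cpp_eri3_block(List A, List B, List aux) {
  Shell a = unpack_shell(A), b = unpack_shell(B);
  AuxFn f = unpack_aux(aux);
  NumericMatrix out(a.ncomp, b.ncomp);
  int habs = f.h[0] + f.h[1] + f.h[2];
  int L = a.l + b.l + habs;
  double sgn = (habs % 2) ? -1.0 : 1.0;
  double AB[3] = {a.A[0] - b.A[0], a.A[1] - b.A[1], a.A[2] - b.A[2]};
  for (int ka = 0; ka < a.nprim; ++ka) for (int kb = 0; kb < b.nprim; ++kb) {
    double za = a.z[ka], zb = b.z[kb], p = za + zb, mu = za * zb / p;
    double g = f.zeta;
    double pref = 2.0 * std::pow(PI_, 2.5) / (p * g * std::sqrt(p + g));
    double om = p * g / (p + g);
    Etab Ex(a.l, b.l), Ey(a.l, b.l), Ez(a.l, b.l);
    double P[3];
    for (int d = 0; d < 3; ++d) P[d] = (za * a.A[d] + zb * b.A[d]) / p;
    fill_etab(Ex, p, P[0] - a.A[0], P[0] - b.A[0], std::exp(-mu * AB[0] * AB[0]));
    fill_etab(Ey, p, P[1] - a.A[1], P[1] - b.A[1], std::exp(-mu * AB[1] * AB[1]));
    fill_etab(Ez, p, P[2] - a.A[2], P[2] - b.A[2], std::exp(-mu * AB[2] * AB[2]));
    Rtab R = coulomb_rtab(L, om, P[0] - f.C[0], P[1] - f.C[1], P[2] - f.C[2]);
    for (int ca = 0; ca < a.ncomp; ++ca) for (int cb = 0; cb < b.ncomp; ++cb) {
      double val = 0.0;
      for (int t = 0; t <= a.lx[ca] + b.lx[cb]; ++t)
        for (int u = 0; u <= a.ly[ca] + b.ly[cb]; ++u)
          for (int w = 0; w <= a.lz[ca] + b.lz[cb]; ++w)
            val += Ex.get(a.lx[ca], b.lx[cb], t) *
                   Ey.get(a.ly[ca], b.ly[cb], u) *
                   Ez.get(a.lz[ca], b.lz[cb], w) *
                   R(t + f.h[0], u + f.h[1], w + f.h[2]);
      out(ca, cb) += a.coef(ca, ka) * b.coef(cb, kb) * pref * sgn * f.norm * val;
    }
  }
  return out;
}

// [[Rcpp::export]]
double cpp_eri2(List aux1, List aux2) {
  AuxFn f = unpack_aux(aux1), g = unpack_aux(aux2);
  int h2 = g.h[0] + g.h[1] + g.h[2];
  int L = f.h[0] + f.h[1] + f.h[2] + h2;
  double al = f.zeta * g.zeta / (f.zeta + g.zeta);
  Rtab R = coulomb_rtab(L, al, f.C[0] - g.C[0], f.C[1] - g.C[1],
                        f.C[2] - g.C[2]);
  double pref = 2.0 * std::pow(PI_, 2.5) /
    (f.zeta * g.zeta * std::sqrt(f.zeta + g.zeta));
  double sgn = (h2 % 2) ? -1.0 : 1.0;
  return sgn * pref * f.norm * g.norm *
    R(f.h[0] + g.h[0], f.h[1] + g.h[1], f.h[2] + g.h[2]);
}

// ------------------------------------------------- 4c ERI (oracle/exchange)
// [[Rcpp::export]]
NumericVector cpp_eri4_block(List A, List B, List C, List D) {
  Shell a = unpack_shell(A), b = unpack_shell(B);
  Shell c = unpack_shell(C), d = unpack_shell(D);
  NumericVector out((size_t)a.ncomp * b.ncomp * c.ncomp * d.ncomp);
  int Lab = a.l + b.l, Lcd = c.l + d.l, L = Lab + Lcd;
  double AB[3] = {a.A[0] - b.A[0], a.A[1] - b.A[1], a.A[2] - b.A[2]};
  double CD[3] = {c.A[0] - d.A[0], c.A[1] - d.A[1], c.A[2] - d.A[2]};
  for (int ka = 0; ka < a.nprim; ++ka) for (int kb = 0; kb < b.nprim; ++kb) {
    double za = a.z[ka], zb = b.z[kb], p = za + zb, mu = za * zb / p;
    double P[3];
    for (int dd = 0; dd < 3; ++dd) P[dd] = (za * a.A[dd] + zb * b.A[dd]) / p;
    Etab Ex(a.l, b.l), Ey(a.l, b.l), Ez(a.l, b.l);
    fill_etab(Ex, p, P[0] - a.A[0], P[0] - b.A[0], std::exp(-mu * AB[0] * AB[0]));
    fill_etab(Ey, p, P[1] - a.A[1], P[1] - b.A[1], std::exp(-mu * AB[1] * AB[1]));
    fill_etab(Ez, p, P[2] - a.A[2], P[2] - b.A[2], std::exp(-mu * AB[2] * AB[2]));
    for (int kc = 0; kc < c.nprim; ++kc) for (int kd = 0; kd < d.nprim; ++kd) {
      double zc = c.z[kc], zd = d.z[kd], q = zc + zd, nu = zc * zd / q;
      double Q[3];
      for (int dd = 0; dd < 3; ++dd) Q[dd] = (zc * c.A[dd] + zd * d.A[dd]) / q;
      Etab Fx(c.l, d.l), Fy(c.l, d.l), Fz(c.l, d.l);
      fill_etab(Fx, q, Q[0] - c.A[0], Q[0] - d.A[0], std::exp(-nu * CD[0] * CD[0]));
      fill_etab(Fy, q, Q[1] - c.A[1], Q[1] - d.A[1], std::exp(-nu * CD[1] * CD[1]));
      fill_etab(Fz, q, Q[2] - c.A[2], Q[2] - d.A[2], std::exp(-nu * CD[2] * CD[2]));
      double al = p * q / (p + q);
      double pref = 2.0 * std::pow(PI_, 2.5) / (p * q * std::sqrt(p + q));
      Rtab R = coulomb_rtab(L, al, P[0] - Q[0], P[1] - Q[1], P[2] - Q[2]);
      for (int ca = 0; ca < a.ncomp; ++ca) for (int cb = 0; cb < b.ncomp; ++cb) {
        int tx = a.lx[ca] + b.lx[cb], ty = a.ly[ca] + b.ly[cb],
            tz = a.lz[ca] + b.lz[cb];
        for (int cc = 0; cc < c.ncomp; ++cc) for (int cd2 = 0; cd2 < d.ncomp; ++cd2) {
          int sx = c.lx[cc] + d.lx[cd2], sy = c.ly[cc] + d.ly[cd2],
              sz = c.lz[cc] + d.lz[cd2];
          double val = 0.0;
          for (int t = 0; t <= tx; ++t) for (int u = 0; u <= ty; ++u)
            for (int w = 0; w <= tz; ++w) {
              double e1 = Ex.get(a.lx[ca], b.lx[cb], t) *
                          Ey.get(a.ly[ca], b.ly[cb], u) *
                          Ez.get(a.lz[ca], b.lz[cb], w);
              if (e1 == 0.0) continue;
              for (int t2 = 0; t2 <= sx; ++t2) for (int u2 = 0; u2 <= sy; ++u2)
                for (int w2 = 0; w2 <= sz; ++w2) {
                  double e2 = Fx.get(c.lx[cc], d.lx[cd2], t2) *
                              Fy.get(c.ly[cc], d.ly[cd2], u2) *
                              Fz.get(c.lz[cc], d.lz[cd2], w2);
                  double sgn = ((t2 + u2 + w2) % 2) ? -1.0 : 1.0;
                  val += e1 * e2 * sgn * R(t + t2, u + u2, w + w2);
                }
            }
          double cf = a.coef(ca, ka) * b.coef(cb, kb) *
                      c.coef(cc, kc) * d.coef(cd2, kd) * pref;
          out[(((size_t)cd2 * c.ncomp + cc) * b.ncomp + cb) * a.ncomp + ca]
            += cf * val;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(a.ncomp, b.ncomp, c.ncomp, d.ncomp);
  return out;
}

// --------------------------------------------- T tensors (1/R derivatives)
// T_AD(m) = (d/dD)^m 1/|A-D|, cube indexed [mx+1, my+1, mz+1] in R.
// [[Rcpp::export]]
NumericVector cpp_ttensor(NumericVector A, NumericVector D, int mmax) {
  Rtab R = invr_rtab(mmax, A[0] - D[0], A[1] - D[1], A[2] - D[2]);
  NumericVector out((size_t)(mmax + 1) * (mmax + 1) * (mmax + 1));
  for (int t = 0; t <= mmax; ++t) for (int u = 0; u <= mmax - t; ++u)
    for (int w = 0; w <= mmax - t - u; ++w) {
      double sgn = ((t + u + w) % 2) ? -1.0 : 1.0;
      out[((size_t)w * (mmax + 1) + u) * (mmax + 1) + t] = sgn * R(t, u, w);
    }
  out.attr("dim") = IntegerVector::create(mmax + 1, mmax + 1, mmax + 1);
  return out;
}

// Sum over sites of q_D T_AD(m), same layout
// [[Rcpp::export]]
NumericVector cpp_tsum_sites(NumericVector A, NumericMatrix sites,
                             NumericVector q, int mmax) {
  NumericVector out((size_t)(mmax + 1) * (mmax + 1) * (mmax + 1));
  for (int s = 0; s < sites.nrow(); ++s) {
    Rtab R = invr_rtab(mmax, A[0] - sites(s, 0), A[1] - sites(s, 1),
                       A[2] - sites(s, 2));
    for (int t = 0; t <= mmax; ++t) for (int u = 0; u <= mmax - t; ++u)
      for (int w = 0; w <= mmax - t - u; ++w) {
        double sgn = ((t + u + w) % 2) ? -1.0 : 1.0;
        out[((size_t)w * (mmax + 1) + u) * (mmax + 1) + t] += q[s] * sgn * R(t, u, w);
      }
  }
  out.attr("dim") = IntegerVector::create(mmax + 1, mmax + 1, mmax + 1);
  return out;
}

// ------------------------------------------ aux function values on a grid
// [[Rcpp::export]]
NumericVector cpp_aux_values(List aux, NumericMatrix pts) {
  AuxFn f = unpack_aux(aux);
  int n = pts.nrow();
  NumericVector out(n);
  double sg = std::sqrt(f.zeta);
  for (int i = 0; i < n; ++i) {
    double v = f.norm;
    double r2 = 0.0;
    for (int d = 0; d < 3; ++d) {
      double dx = pts(i, d) - f.C[d];
      r2 += dx * dx;
      double y = sg * dx;
      int t = f.h[d];
      double H = (t == 0) ? 1.0 : (t == 1 ? 2.0 * y : 4.0 * y * y - 2.0);
      v *= std::pow(f.zeta, 0.5 * t) * H;
    }
    out[i] = v * std::exp(-f.zeta * r2);
  }
  return out;
}

// --------------------------------- near/far ERI counting (mixed SCF policy)
// Shell pairs with non-overlapping amplitude extents (negligible product
// density) are screened out entirely; for surviving pairs an auxiliary
// function is near-field iff its potential extent sphere overlaps either
// shell's classification sphere. Counts weighted by component counts;
// returns c(near, far).
// [[Rcpp::export]]
NumericVector cpp_count_near_eri(NumericMatrix shcen,
                                 NumericVector shext_screen,
                                 NumericVector shext_class,
                                 IntegerVector shncomp, NumericMatrix auxcen,
                                 NumericVector auxext) {
  int ns = shcen.nrow(), na = auxcen.nrow();
  double nearc = 0.0, farc = 0.0;
  for (int i = 0; i < ns; ++i) for (int j = i; j < ns; ++j) {
    double dij = 0.0;
    for (int d = 0; d < 3; ++d) {
      double x = shcen(i, d) - shcen(j, d); dij += x * x;
    }
    dij = std::sqrt(dij);
    if (dij > shext_screen[i] + shext_screen[j]) continue; // negligible pair
    double w = (double)shncomp[i] * shncomp[j];
    for (int k = 0; k < na; ++k) {
      double di = 0.0, dj = 0.0;
      for (int d = 0; d < 3; ++d) {
        double x = auxcen(k, d) - shcen(i, d); di += x * x;
        double y = auxcen(k, d) - shcen(j, d); dj += y * y;
      }
      di = std::sqrt(di); dj = std::sqrt(dj);
      if (di <= shext_class[i] + auxext[k] || dj <= shext_class[j] + auxext[k])
        nearc += w;
      else farc += w;
    }
  }
  return NumericVector::create(nearc, farc);
}
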