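// Gaussian one- and two-electron integrals over contracted cartesian shells
// (McMurchie-Davidson Hermite expansion, s/p/d angular momenta).
// Shells arrive from R as lists: l, exps, coefs (primitive-normalized),
// center (bohr).  Cartesian component order within a shell of angular
// momentum l: lx from l down to 0, ly from l-lx down to 0.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double PI = 3.14159265358979323846;

// ---------------------------------------------------------------------------
// Boys function F_m(T) for m = 0..mmax, downward recursion from a Kummer
// series (T <= 35) or upward from the asymptotic F_0 (T > 35).
static void boys(int mmax, double T, std::vector<double> &F) {
  F.assign(mmax + 1, 0.0);
  if (T > 35.0) {
    F[0] = 0.5 * std::sqrt(PI / T);
    double expT = std::exp(-T);
    for (int m = 0; m < mmax; ++m)
      F[m + 1] = ((2 * m + 1) * F[m] - expT) / (2.0 * T);
    return;
  }
  // series for F_mmax: e^{-T} * sum_i (2T)^i / (2m+1)(2m+3)...(2m+2i+1)
  double expT = std::exp(-T);
  double term = 1.0 / (2.0 * mmax + 1.0);
  double sum = term;
  for (int i = 1; i < 200; ++i) {
    term *= 2.0 * T / (2.0 * mmax + 2.0 * i + 1.0);
    sum += term;
    if (term < 1e-17 * sum) break;
  }
  F[mmax] = expT * sum;
  for (int m = mmax - 1; m >= 0; --m)
    F[m] = (2.0 * T * F[m + 1] + expT) / (2.0 * m + 1.0);
}

// ---------------------------------------------------------------------------
// Hermite expansion coefficients E_t^{ij} for a primitive pair in one
// dimension; table[i][j][t].
struct ETable {
  int imax, jmax;
  std::vector<double> v; // (imax+1)*(jmax+1)*(imax+jmax+1)
  double &at(int i, int j, int t) {
    return v[(i * (jmax + 1) + j) * (imax + jmax + 1) + t];
  }
};

static void build_E(ETable &E, int imax, int jmax, double a, double b,
                    double AB) {
  E.imax = imax;
  E.jmax = jmax;
  int tmax = imax + jmax;
  E.v.assign((imax + 1) * (jmax + 1) * (tmax + 1), 0.0);
  double p = a + b, q = a * b / p;
  double PA = -b * AB / p; // P - A with AB = A - B
  double PB = a * AB / p;  // P - B
  E.at(0, 0, 0) = std::exp(-q * AB * AB);
  for (int i = 0; i <= imax; ++i) {
    for (int j = 0; j <= jmax; ++j) {
      if (i == 0 && j == 0) continue;
      for (int t = 0; t <= i + j; ++t) {
        double val = 0.0;
        if (i > 0) {
          if (t > 0) val += E.at(i - 1, j, t - 1) / (2.0 * p);
          val += PA * E.at(i - 1, j, t);
          if (t + 1 <= i - 1 + j) val += (t + 1) * E.at(i - 1, j, t + 1);
        } else {
          if (t > 0) val += E.at(i, j - 1, t - 1) / (2.0 * p);
          val += PB * E.at(i, j - 1, t);
          if (t + 1 <= i + j - 1) val += (t + 1) * E.at(i, j - 1, t + 1);
        }
        E.at(i, j, t) = val;
      }
    }
  }
}

// ---------------------------------------------------------------------------
// Hermite Coulomb integrals R^n_{tuv}; memoized per primitive (quartet).
struct RTable {
  int L;
  std::vector<double> v;
  std::vector<char> have;
  std::vector<double> F;
  double p, X, Y, Z;
  void init(int Lmax, double pp, double Xpc, double Ypc, double Zpc) {
    L = Lmax;
    p = pp;
    X = Xpc;
    Y = Ypc;
    Z = Zpc;
    int n = (L + 1) * (L + 1) * (L + 1) * (L + 1);
    v.assign(n, 0.0);
    have.assign(n, 0);
    double T = p * (X * X + Y * Y + Z * Z);
    boys(L, T, F);
  }
  int idx(int t, int u, int w, int n) const {
    return ((t * (L + 1) + u) * (L + 1) + w) * (L + 1) + n;
  }
  double get(int t, int u, int w, int n) {
    if (t < 0 || u < 0 || w < 0) return 0.0;
    int k = idx(t, u, w, n);
    if (have[k]) return v[k];
    double val;
    if (t == 0 && u == 0 && w == 0) {
      val = std::pow(-2.0 * p, n) * F[n];
    } else if (t > 0) {
      val = (t - 1) * get(t - 2, u, w, n + 1) + X * get(t - 1, u, w, n + 1);
    } else if (u > 0) {
      val = (u - 1) * get(t, u - 2, w, n + 1) + Y * get(t, u - 1, w, n + 1);
    } else {
      val = (w - 1) * get(t, u, w - 2, n + 1) + Z * get(t, u, w - 1, n + 1);
    }
    have[k] = 1;
    v[k] = val;
    return val;
  }
};

// cartesian components of a shell with angular momentum l
static void components(int l, std::vector<std::array<int, 3>> &comp) {
  comp.clear();
  for (int lx = l; lx >= 0; --lx)
    for (int ly = l - lx; ly >= 0; --ly)
      comp.push_back({lx, ly, l - lx - ly});
}

struct Shell {
  int l;
  std::vector<double> exps, coefs;
  double A[3];
  std::vector<std::array<int, 3>> comp;
  int ncart() const { return (int)comp.size(); }
};

static std::vector<Shell> parse_shells(List shells) {
  std::vector<Shell> out;
  for (int s = 0; s < shells.size(); ++s) {
    List sh = shells[s];
    Shell S;
    S.l = as<int>(sh["l"]);
    S.exps = as<std::vector<double>>(sh["exps"]);
    S.coefs = as<std::vector<double>>(sh["coefs"]);
    NumericVector A = sh["center"];
    S.A[0] = A[0];
    S.A[1] = A[1];
    S.A[2] = A[2];
    components(S.l, S.comp);
    out.push_back(S);
  }
  return out;
}

// ---------------------------------------------------------------------------
// One-electron integrals: overlap, kinetic, nuclear attraction.
// [[Rcpp::export]]
List cpp_one_electron(List shells, NumericVector Z, NumericMatrix coords) {
  std::vector<Shell> sh = parse_shells(shells);
  int nsh = (int)sh.size();
  std::vector<int> off(nsh + 1, 0);
  for (int s = 0; s < nsh; ++s) off[s + 1] = off[s] + sh[s].ncart();
  int N = off[nsh];
  NumericMatrix S(N, N), T(N, N), V(N, N);
  int natom = Z.size();

  for (int sa = 0; sa < nsh; ++sa) {
    for (int sb = sa; sb < nsh; ++sb) {
      const Shell &A = sh[sa], &B = sh[sb];
      int la = A.l, lb = B.l;
      double AB[3] = {A.A[0] - B.A[0], A.A[1] - B.A[1], A.A[2] - B.A[2]};
      for (size_t pa = 0; pa < A.exps.size(); ++pa) {
        for (size_t pb = 0; pb < B.exps.size(); ++pb) {
          double a = A.exps[pa], b = B.exps[pb];
          double cc = A.coefs[pa] * B.coefs[pb];
          double p = a + b;
          double P[3];
          for (int d = 0; d < 3; ++d) P[d] = (a * A.A[d] + b * B.A[d]) / p;
          ETable E[3];
          // kinetic needs j+2 on bra-ket side: extend jmax by 2
          for (int d = 0; d < 3; ++d) build_E(E[d], la, lb + 2, a, b, AB[d]);
          double sfac = std::pow(PI / p, 1.5);

          for (int ca = 0; ca < A.ncart(); ++ca) {
            for (int cb = 0; cb < B.ncart(); ++cb) {
              const std::array<int, 3> &la3 = A.comp[ca];
              const std::array<int, 3> &lb3 = B.comp[cb];
              // 1D overlap factors (without sqrt(pi/p), folded via sfac)
              double s1[3], sp2[3], sm2[3];
              for (int d = 0; d < 3; ++d) {
                s1[d] = E[d].at(la3[d], lb3[d], 0);
                sp2[d] = E[d].at(la3[d], lb3[d] + 2, 0);
                sm2[d] = (lb3[d] >= 2) ? E[d].at(la3[d], lb3[d] - 2, 0) : 0.0;
              }
              double sval = cc * sfac * s1[0] * s1[1] * s1[2];
              // kinetic 1D: -2b^2 S_{i,j+2} + b(2j+1) S_{ij} - j(j-1)/2 S_{i,j-2}
              double tval = 0.0;
              for (int d = 0; d < 3; ++d) {
                int j = lb3[d];
                double td = -2.0 * b * b * sp2[d] + b * (2 * j + 1) * s1[d] -
                            0.5 * j * (j - 1) * sm2[d];
                double prod = td;
                for (int e = 0; e < 3; ++e)
                  if (e != d) prod *= s1[e];
                tval += prod;
              }
              tval *= cc * sfac;
              int ia = off[sa] + ca, ib = off[sb] + cb;
              S(ia, ib) += sval;
              T(ia, ib) += tval;

              // nuclear attraction
              double vsum = 0.0;
              for (int at = 0; at < natom; ++at) {
                RTable R;
                R.init(la + lb, p, P[0] - coords(at, 0), P[1] - coords(at, 1),
                       P[2] - coords(at, 2));
                double acc = 0.0;
                for (int t = 0; t <= la3[0] + lb3[0]; ++t)
                  for (int u = 0; u <= la3[1] + lb3[1]; ++u)
                    for (int w = 0; w <= la3[2] + lb3[2]; ++w)
                      acc += E[0].at(la3[0], lb3[0], t) *
                             E[1].at(la3[1], lb3[1], u) *
                             E[2].at(la3[2], lb3[2], w) * R.get(t, u, w, 0);
                vsum += -Z[at] * acc;
              }
              V(ia, ib) += cc * 2.0 * PI / p * vsum;
            }
          }
        }
      }
    }
  }
  // symmetrize
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < i; ++j) {
      S(i, j) = S(j, i);
      T(i, j) = T(j, i);
      V(i, j) = V(j, i);
    }
  return List::create(_["S"] = S, _["T"] = T, _["V"] = V);
}

// ---------------------------------------------------------------------------
// Two-electron repulsion integrals [ab|cd] (chemist notation), full N^4
// cartesian tensor with all 8 permutational copies filled.
// [[Rcpp::export]]
NumericVector cpp_eri(List shells) {
  std::vector<Shell> sh = parse_shells(shells);
  int nsh = (int)sh.size();
  std::vector<int> off(nsh + 1, 0);
  for (int s = 0; s < nsh; ++s) off[s + 1] = off[s] + sh[s].ncart();
  int N = off[nsh];
  NumericVector out((R_xlen_t)N * N * N * N);
  out.attr("dim") = IntegerVector::create(N, N, N, N);
  double *o = out.begin();
  size_t N2 = (size_t)N * N, N3 = N2 * N;

  for (int sa = 0; sa < nsh; ++sa)
    for (int sb = 0; sb <= sa; ++sb)
      for (int sc = 0; sc <= sa; ++sc)
        for (int sd = 0; sd <= (sc == sa ? sb : sc); ++sd) {
          const Shell &A = sh[sa], &B = sh[sb], &C = sh[sc], &D = sh[sd];
          int la = A.l, lb = B.l, lc = C.l, ld = D.l;
          int L = la + lb + lc + ld;
          double AB[3] = {A.A[0] - B.A[0], A.A[1] - B.A[1], A.A[2] - B.A[2]};
          double CD[3] = {C.A[0] - D.A[0], C.A[1] - D.A[1], C.A[2] - D.A[2]};
          int na = A.ncart(), nb = B.ncart(), nc = C.ncart(), nd = D.ncart();
          std::vector<double> block((size_t)na * nb * nc * nd, 0.0);

          for (size_t pa = 0; pa < A.exps.size(); ++pa)
            for (size_t pb = 0; pb < B.exps.size(); ++pb) {
              double a = A.exps[pa], b = B.exps[pb];
              double p = a + b;
              double P[3];
              for (int d = 0; d < 3; ++d)
                P[d] = (a * A.A[d] + b * B.A[d]) / p;
              ETable Eab[3];
              for (int d = 0; d < 3; ++d) build_E(Eab[d], la, lb, a, b, AB[d]);
              double cab = A.coefs[pa] * B.coefs[pb];
              for (size_t pc = 0; pc < C.exps.size(); ++pc)
                for (size_t pd = 0; pd < D.exps.size(); ++pd) {
                  double c = C.exps[pc], dd = D.exps[pd];
                  double q = c + dd;
                  double Q[3];
                  for (int d2 = 0; d2 < 3; ++d2)
                    Q[d2] = (c * C.A[d2] + dd * D.A[d2]) / q;
                  ETable Ecd[3];
                  for (int d2 = 0; d2 < 3; ++d2)
                    build_E(Ecd[d2], lc, ld, c, dd, CD[d2]);
                  double alpha = p * q / (p + q);
                  RTable R;
                  R.init(L, alpha, P[0] - Q[0], P[1] - Q[1], P[2] - Q[2]);
                  double pref = cab * C.coefs[pc] * D.coefs[pd] * 2.0 *
                                std::pow(PI, 2.5) /
                                (p * q * std::sqrt(p + q));

                  size_t bidx = 0;
                  for (int ca = 0; ca < na; ++ca)
                    for (int cb = 0; cb < nb; ++cb)
                      for (int cc2 = 0; cc2 < nc; ++cc2)
                        for (int cd2 = 0; cd2 < nd; ++cd2, ++bidx) {
                          const std::array<int, 3> &A3 = A.comp[ca];
                          const std::array<int, 3> &B3 = B.comp[cb];
                          const std::array<int, 3> &C3 = C.comp[cc2];
                          const std::array<int, 3> &D3 = D.comp[cd2];
                          double acc = 0.0;
                          for (int t = 0; t <= A3[0] + B3[0]; ++t) {
                            double ex = Eab[0].at(A3[0], B3[0], t);
                            if (ex == 0.0) continue;
                            for (int u = 0; u <= A3[1] + B3[1]; ++u) {
                              double exy = ex * Eab[1].at(A3[1], B3[1], u);
                              if (exy == 0.0) continue;
                              for (int w = 0; w <= A3[2] + B3[2]; ++w) {
                                double exyz =
                                    exy * Eab[2].at(A3[2], B3[2], w);
                                if (exyz == 0.0) continue;
                                for (int tt = 0; tt <= C3[0] + D3[0]; ++tt) {
                                  double fx =
                                      Ecd[0].at(C3[0], D3[0], tt);
                                  if (fx == 0.0) continue;
                                  for (int uu = 0; uu <= C3[1] + D3[1];
                                       ++uu) {
                                    double fxy =
                                        fx * Ecd[1].at(C3[1], D3[1], uu);
                                    if (fxy == 0.0) continue;
                                    for (int ww = 0; ww <= C3[2] + D3[2];
                                         ++ww) {
                                      double fxyz = fxy *
                                                    Ecd[2].at(C3[2], D3[2],
                                                              ww);
                                      if (fxyz == 0.0) continue;
                                      double sign =
                                          ((tt + uu + ww) % 2) ? -1.0 : 1.0;
                                      acc += exyz * fxyz * sign *
                                             R.get(t + tt, u + uu, w + ww,
                                                   0);
                                    }
                                  }
                                }
                              }
                            }
                          }
                          block[bidx] += pref * acc;
                        }
                }
            }

          // scatter block with 8-fold symmetry
          size_t bidx = 0;
          for (int ca = 0; ca < na; ++ca)
            for (int cb = 0; cb < nb; ++cb)
              for (int cc2 = 0; cc2 < nc; ++cc2)
                for (int cd2 = 0; cd2 < nd; ++cd2, ++bidx) {
                  double val = block[bidx];
                  size_t i = off[sa] + ca, j = off[sb] + cb,
                         k = off[sc] + cc2, l = off[sd] + cd2;
                  o[i + j * N + k * N2 + l * N3] = val;
                  o[j + i * N + k * N2 + l * N3] = val;
                  o[i + j * N + l * N2 + k * N3] = val;
                  o[j + i * N + l * N2 + k * N3] = val;
                  o[k + l * N + i * N2 + j * N3] = val;
                  o[l + k * N + i * N2 + j * N3] = val;
                  o[k + l * N + j * N2 + i * N3] = val;
                  o[l + k * N + j * N2 + i * N3] = val;
                }
        }
  return out;
}
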