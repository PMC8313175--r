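// Element-level assembly for the quasi-static disc solver.
//
// Total-Lagrangian trilinear hexahedra, 2x2x2 Gauss quadrature. At every
// Gauss point the total Cauchy stress is the sum of the Holmes-Mow matrix
// stress, the rank-one stress of each fiber generation (evaluated through
// the relative deformation gradient against that generation's deposition
// snapshot), and the Donnan osmotic term -pi(cF(J)) I. The element internal
// force is exact; the element tangent is obtained by forward finite
// differencing of the force vector, which keeps converged equilibria exact
// while avoiding hand-coded consistent tangents for the composite law.
//
// Units: mm - N - MPa - mM.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Mat3 {
  double a[9]; // row-major
  double &operator()(int i, int j) { return a[3 * i + j]; }
  double operator()(int i, int j) const { return a[3 * i + j]; }
};

inline Mat3 matmul(const Mat3 &A, const Mat3 &B) {
  Mat3 C;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      C(i, j) = A(i, 0) * B(0, j) + A(i, 1) * B(1, j) + A(i, 2) * B(2, j);
  return C;
}

inline double det3(const Mat3 &A) {
  return A(0, 0) * (A(1, 1) * A(2, 2) - A(1, 2) * A(2, 1)) -
         A(0, 1) * (A(1, 0) * A(2, 2) - A(1, 2) * A(2, 0)) +
         A(0, 2) * (A(1, 0) * A(2, 1) - A(1, 1) * A(2, 0));
}

inline bool inv3(const Mat3 &A, Mat3 &Ainv, double &d) {
  d = det3(A);
  if (!(std::abs(d) > 1e-300)) return false;
  double id = 1.0 / d;
  Ainv(0, 0) = (A(1, 1) * A(2, 2) - A(1, 2) * A(2, 1)) * id;
  Ainv(0, 1) = (A(0, 2) * A(2, 1) - A(0, 1) * A(2, 2)) * id;
  Ainv(0, 2) = (A(0, 1) * A(1, 2) - A(0, 2) * A(1, 1)) * id;
  Ainv(1, 0) = (A(1, 2) * A(2, 0) - A(1, 0) * A(2, 2)) * id;
  Ainv(1, 1) = (A(0, 0) * A(2, 2) - A(0, 2) * A(2, 0)) * id;
  Ainv(1, 2) = (A(0, 2) * A(1, 0) - A(0, 0) * A(1, 2)) * id;
  Ainv(2, 0) = (A(1, 0) * A(2, 1) - A(1, 1) * A(2, 0)) * id;
  Ainv(2, 1) = (A(0, 1) * A(2, 0) - A(0, 0) * A(2, 1)) * id;
  Ainv(2, 2) = (A(0, 0) * A(1, 1) - A(0, 1) * A(1, 0)) * id;
  return true;
}

// per-element material record
struct MatRec {
  double lam, mu, beta_m, c0F, phi0w, Ef, lambda0, beta_f;
  bool fibers;
};

// fiber generation data (per element slices are indexed externally)
struct GenRec {
  const double *vdep;   // ne x 3, row-major
  const double *Fdinv;  // ne x 9, row-major (inverse of deposition gradient)
  double scale;
};

// one-dimensional fiber stress dPsi/dlambda (toe power law / linear)
inline double fiber_sigma(double lam, const MatRec &m) {
  double In = lam * lam;
  if (In < 1.0) return 0.0;
  double I0 = m.lambda0 * m.lambda0;
  double b = m.beta_f;
  if (In <= I0)
    return m.Ef / (2.0 * (b - 1.0)) * std::pow(I0 - 1.0, 2.0 - b) * lam *
           std::pow(In - 1.0, b - 1.0);
  double sig0 = m.Ef / (2.0 * (b - 1.0)) * m.lambda0 * (I0 - 1.0);
  return sig0 + m.Ef * (lam - m.lambda0);
}

// total Cauchy stress at a Gauss point; returns false on inverted state
inline bool point_stress(const Mat3 &F, const MatRec &m,
                         const std::vector<GenRec> &gens, int e,
                         double alpha, double RTphi, double cbar,
                         Mat3 &sig) {
  double J = det3(F);
  if (!(J > 1e-8)) return false;
  // Holmes-Mow matrix
  Mat3 bt; // left Cauchy-Green b = F F^T
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      bt(i, j) = F(i, 0) * F(j, 0) + F(i, 1) * F(j, 1) + F(i, 2) * F(j, 2);
  double I1 = bt(0, 0) + bt(1, 1) + bt(2, 2);
  double b2sum = 0.0;
  Mat3 bb = matmul(bt, bt);
  b2sum = bb(0, 0) + bb(1, 1) + bb(2, 2);
  double I2 = 0.5 * (I1 * I1 - b2sum);
  double hA = m.lam + 2.0 * m.mu;
  double Q = ((2.0 * m.mu - m.lam) * (I1 - 3.0) + m.lam * (I2 - 3.0) -
              hA * std::log(J * J)) / hA;
  double eQ = std::exp(m.beta_m * Q);
  double c1 = eQ / (2.0 * J);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      sig(i, j) = c1 * ((2.0 * m.mu - m.lam + m.lam * I1) * bt(i, j) -
                        m.lam * bb(i, j) - (i == j ? hA : 0.0));
  // fibers (each generation referenced to its deposition configuration)
  if (m.fibers) {
    for (size_t g = 0; g < gens.size(); ++g) {
      const GenRec &gr = gens[g];
      if (gr.scale <= 0.0) continue;
      Mat3 Fdinv;
      for (int k = 0; k < 9; ++k) Fdinv.a[k] = gr.Fdinv[9 * e + k];
      Mat3 Frel = matmul(F, Fdinv);
      const double *v = gr.vdep + 3 * e;
      double w0 = Frel(0, 0) * v[0] + Frel(0, 1) * v[1] + Frel(0, 2) * v[2];
      double w1 = Frel(1, 0) * v[0] + Frel(1, 1) * v[1] + Frel(1, 2) * v[2];
      double w2 = Frel(2, 0) * v[0] + Frel(2, 1) * v[1] + Frel(2, 2) * v[2];
      double lamf = std::sqrt(w0 * w0 + w1 * w1 + w2 * w2);
      if (lamf <= 1.0) continue;
      double Jrel = det3(Frel);
      if (!(Jrel > 1e-8)) return false;
      double s1 = gr.scale * fiber_sigma(lamf, m);
      double coef = lamf * s1 / Jrel / (lamf * lamf); // = s1/(lamf*Jrel)
      // sigma += coef * w w^T  (w = lamf * m_hat)
      sig(0, 0) += coef * w0 * w0;
      sig(0, 1) += coef * w0 * w1;
      sig(0, 2) += coef * w0 * w2;
      sig(1, 0) += coef * w1 * w0;
      sig(1, 1) += coef * w1 * w1;
      sig(1, 2) += coef * w1 * w2;
      sig(2, 0) += coef * w2 * w0;
      sig(2, 1) += coef * w2 * w1;
      sig(2, 2) += coef * w2 * w2;
    }
  }
  // Donnan swelling
  double c0 = alpha * m.c0F;
  if (c0 > 0.0) {
    double den = J - 1.0 + m.phi0w;
    if (!(den > 1e-10)) return false;
    double cF = m.phi0w / den * c0;
    double pi = RTphi * (std::sqrt(cF * cF + cbar * cbar) - cbar);
    sig(0, 0) -= pi;
    sig(1, 1) -= pi;
    sig(2, 2) -= pi;
  }
  return true;
}

// trilinear shape function derivative signs
const int SGN[8][3] = {{-1, -1, -1}, {1, -1, -1}, {1, 1, -1}, {-1, 1, -1},
                       {-1, -1, 1},  {1, -1, 1},  {1, 1, 1},  {-1, 1, 1}};

// element internal force (24-vector); gradN/wdet precomputed per gp.
// returns false if any Gauss point is inverted.
inline bool element_force(const double gradN[8][8][3], const double wdet[8],
                          const double ue[24], const MatRec &m,
                          const std::vector<GenRec> &gens, int e,
                          double alpha, double RTphi, double cbar,
                          double fe[24]) {
  for (int k = 0; k < 24; ++k) fe[k] = 0.0;
  for (int q = 0; q < 8; ++q) {
    Mat3 F;
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) {
        double s = (a == b) ? 1.0 : 0.0;
        for (int n = 0; n < 8; ++n) s += ue[3 * n + a] * gradN[q][n][b];
        F(a, b) = s;
      }
    Mat3 sig;
    if (!point_stress(F, m, gens, e, alpha, RTphi, cbar, sig)) return false;
    // P = J sig F^{-T}
    Mat3 Finv;
    double J;
    if (!inv3(F, Finv, J)) return false;
    Mat3 P;
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b)
        P(a, b) = J * (sig(a, 0) * Finv(b, 0) + sig(a, 1) * Finv(b, 1) +
                       sig(a, 2) * Finv(b, 2));
    double w = wdet[q];
    for (int n = 0; n < 8; ++n)
      for (int a = 0; a < 3; ++a)
        fe[3 * n + a] += w * (P(a, 0) * gradN[q][n][0] +
                              P(a, 1) * gradN[q][n][1] +
                              P(a, 2) * gradN[q][n][2]);
  }
  return true;
}

void precompute_grads(const NumericMatrix &nodes, const IntegerMatrix &elem,
                      int e, double gradN[8][8][3], double wdet[8],
                      bool &ok) {
  const double g = 1.0 / std::sqrt(3.0);
  double X[8][3];
  for (int n = 0; n < 8; ++n) {
    int nd = elem(e, n) - 1;
    for (int a = 0; a < 3; ++a) X[n][a] = nodes(nd, a);
  }
  ok = true;
  for (int q = 0; q < 8; ++q) {
    double xi[3] = {g * SGN[q][0], g * SGN[q][1], g * SGN[q][2]};
    double dN[8][3];
    for (int n = 0; n < 8; ++n)
      for (int d = 0; d < 3; ++d) {
        int o1 = (d + 1) % 3, o2 = (d + 2) % 3;
        dN[n][d] = SGN[n][d] / 8.0 * (1.0 + SGN[n][o1] * xi[o1]) *
                   (1.0 + SGN[n][o2] * xi[o2]);
      }
    Mat3 J0;
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) {
        double s = 0.0;
        for (int n = 0; n < 8; ++n) s += X[n][a] * dN[n][b];
        J0(a, b) = s;
      }
    Mat3 Jinv;
    double d;
    if (!inv3(J0, Jinv, d) || d <= 0.0) { ok = false; return; }
    wdet[q] = d;
    for (int n = 0; n < 8; ++n)
      for (int b = 0; b < 3; ++b)
        gradN[q][n][b] = dN[n][0] * Jinv(0, b) + dN[n][1] * Jinv(1, b) +
                         dN[n][2] * Jinv(2, b);
  }
}

std::vector<GenRec> unpack_generations(const List &generations) {
  std::vector<GenRec> gens;
  for (int g = 0; g < generations.size(); ++g) {
    List gl = generations[g];
    GenRec gr;
    NumericVector vd = gl["v_dep_flat"];
    NumericVector fd = gl["F_dep_inv_flat"];
    gr.vdep = REAL(vd);
    gr.Fdinv = REAL(fd);
    gr.scale = as<double>(gl["modulus_scale"]);
    gens.push_back(gr);
  }
  return gens;
}

MatRec make_matrec(const NumericMatrix &matprops, int e) {
  MatRec m;
  double Em = matprops(e, 0), nu = matprops(e, 1);
  m.lam = Em * nu / ((1.0 + nu) * (1.0 - 2.0 * nu));
  m.mu = Em / (2.0 * (1.0 + nu));
  m.beta_m = matprops(e, 2);
  m.c0F = matprops(e, 3);
  m.phi0w = matprops(e, 4);
  m.Ef = matprops(e, 5);
  m.lambda0 = matprops(e, 6);
  m.beta_f = matprops(e, 7);
  m.fibers = matprops(e, 8) > 0.5;
  return m;
}

} // namespace

// [[Rcpp::export]]
List asm_system(NumericMatrix nodes, IntegerMatrix elem, NumericVector u,
                NumericMatrix matprops, List generations, double alpha,
                double RTphi, double cbar, bool want_K, double fd_h = 1e-6) {
  int ne = elem.nrow();
  int ndof = nodes.nrow() * 3;
  NumericVector f(ndof);
  std::vector<GenRec> gens = unpack_generations(generations);
  std::vector<int> Ki, Kj;
  std::vector<double> Kx;
  if (want_K) {
    Ki.reserve((size_t)ne * 576);
    Kj.reserve((size_t)ne * 576);
    Kx.reserve((size_t)ne * 576);
  }
  bool inverted = false;
  double gradN[8][8][3], wdet[8];
  double ue[24], fe[24], fp[24];
  double fscale2 = 0.0; // gross internal force level (sum over elements)
  for (int e = 0; e < ne && !inverted; ++e) {
    bool okg;
    precompute_grads(nodes, elem, e, gradN, wdet, okg);
    if (!okg) { inverted = true; break; }
    MatRec m = make_matrec(matprops, e);
    int dofs[24];
    for (int n = 0; n < 8; ++n) {
      int nd = elem(e, n) - 1;
      for (int a = 0; a < 3; ++a) {
        dofs[3 * n + a] = 3 * nd + a;
        ue[3 * n + a] = u[3 * nd + a];
      }
    }
    if (!element_force(gradN, wdet, ue, m, gens, e, alpha, RTphi, cbar, fe)) {
      inverted = true;
      break;
    }
    for (int k = 0; k < 24; ++k) {
      f[dofs[k]] += fe[k];
      fscale2 += fe[k] * fe[k];
    }
    if (want_K) {
      for (int k = 0; k < 24; ++k) {
        double keep = ue[k];
        ue[k] = keep + fd_h;
        if (!element_force(gradN, wdet, ue, m, gens, e, alpha, RTphi, cbar,
                           fp)) {
          inverted = true;
          break;
        }
        ue[k] = keep;
        for (int r = 0; r < 24; ++r) {
          double v = (fp[r] - fe[r]) / fd_h;
          if (v != 0.0) {
            Ki.push_back(dofs[r] + 1);
            Kj.push_back(dofs[k] + 1);
            Kx.push_back(v);
          }
        }
      }
    }
  }
  if (inverted)
    return List::create(Named("ok") = false);
  List out = List::create(Named("ok") = true, Named("f") = f,
                          Named("fscale") = std::sqrt(fscale2));
  if (want_K) {
    out["Ki"] = IntegerVector(Ki.begin(), Ki.end());
    out["Kj"] = IntegerVector(Kj.begin(), Kj.end());
    out["Kx"] = NumericVector(Kx.begin(), Kx.end());
  }
  return out;
}

// Deformation gradient at every element centroid (ne x 9, row-major).
// [[Rcpp::export]]
NumericMatrix elem_centroid_F(NumericMatrix nodes, IntegerMatrix elem,
                              NumericVector u) {
  int ne = elem.nrow();
  NumericMatrix out(ne, 9);
  for (int e = 0; e < ne; ++e) {
    double X[8][3], ue[8][3];
    for (int n = 0; n < 8; ++n) {
      int nd = elem(e, n) - 1;
      for (int a = 0; a < 3; ++a) {
        X[n][a] = nodes(nd, a);
        ue[n][a] = u[3 * nd + a];
      }
    }
    double dN[8][3];
    for (int n = 0; n < 8; ++n)
      for (int d = 0; d < 3; ++d) {
        int o1 = (d + 1) % 3, o2 = (d + 2) % 3;
        dN[n][d] = SGN[n][d] / 8.0;
        (void)o1; (void)o2;
      }
    Mat3 J0, Jinv;
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) {
        double s = 0.0;
        for (int n = 0; n < 8; ++n) s += X[n][a] * dN[n][b];
        J0(a, b) = s;
      }
    double d;
    inv3(J0, Jinv, d);
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) {
        double s = (a == b) ? 1.0 : 0.0;
        for (int n = 0; n < 8; ++n) {
          double g = dN[n][0] * Jinv(0, b) + dN[n][1] * Jinv(1, b) +
                     dN[n][2] * Jinv(2, b);
          s += ue[n][a] * g;
        }
        out(e, 3 * a + b) = s;
      }
  }
  return out;
}

// Total Cauchy stress at every element centroid (ne x 9, row-major), using
// the same constitutive path as the solver.
// [[Rcpp::export]]
NumericMatrix elem_centroid_stress(NumericMatrix nodes, IntegerMatrix elem,
                                   NumericVector u, NumericMatrix matprops,
                                   List generations, double alpha,
                                   double RTphi, double cbar) {
  NumericMatrix Fc = elem_centroid_F(nodes, elem, u);
  int ne = elem.nrow();
  std::vector<GenRec> gens = unpack_generations(generations);
  NumericMatrix out(ne, 9);
  for (int e = 0; e < ne; ++e) {
    Mat3 F, sig;
    for (int k = 0; k < 9; ++k) F.a[k] = Fc(e, k);
    MatRec m = make_matrec(matprops, e);
    if (!point_stress(F, m, gens, e, alpha, RTphi, cbar, sig))
      stop("inverted element in stress recovery");
    for (int k = 0; k < 9; ++k) out(e, k) = sig.a[k];
  }
  return out;
}
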