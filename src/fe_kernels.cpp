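// Total-Lagrangian kernels for 8-node trilinear hexahedra with a decoupled
// nearly-incompressible neo-Hookean law:
//   W = C10 (J^{-2/3} I1 - 3) + (1/D1) (J - 1)^2
// Deviatoric terms use full 2x2x2 Gauss quadrature; the volumetric term is
// integrated at the element centroid (selective reduced integration, the
// mean-dilatation remedy for volumetric locking of linear hexes).
// Units: um - nN - kPa (nN/um^2 = kPa), consistent throughout.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double LC[8][3] = {
  {-1, -1, -1}, {1, -1, -1}, {1, 1, -1}, {-1, 1, -1},
  {-1, -1,  1}, {1, -1,  1}, {1, 1,  1}, {-1, 1,  1}};

static const int VI[6][2] = {{0,0},{1,1},{2,2},{0,1},{1,2},{0,2}};

static const double GP = 0.5773502691896257645091488; // 1/sqrt(3)

static inline double det3(const double A[3][3]) {
  return A[0][0]*(A[1][1]*A[2][2]-A[1][2]*A[2][1])
       - A[0][1]*(A[1][0]*A[2][2]-A[1][2]*A[2][0])
       + A[0][2]*(A[1][0]*A[2][1]-A[1][1]*A[2][0]);
}

static inline bool inv3(const double A[3][3], double Ai[3][3]) {
  double d = det3(A);
  if (d == 0.0) return false;
  double id = 1.0/d;
  Ai[0][0] =  (A[1][1]*A[2][2]-A[1][2]*A[2][1])*id;
  Ai[0][1] = -(A[0][1]*A[2][2]-A[0][2]*A[2][1])*id;
  Ai[0][2] =  (A[0][1]*A[1][2]-A[0][2]*A[1][1])*id;
  Ai[1][0] = -(A[1][0]*A[2][2]-A[1][2]*A[2][0])*id;
  Ai[1][1] =  (A[0][0]*A[2][2]-A[0][2]*A[2][0])*id;
  Ai[1][2] = -(A[0][0]*A[1][2]-A[0][2]*A[1][0])*id;
  Ai[2][0] =  (A[1][0]*A[2][1]-A[1][1]*A[2][0])*id;
  Ai[2][1] = -(A[0][0]*A[2][1]-A[0][1]*A[2][0])*id;
  Ai[2][2] =  (A[0][0]*A[1][1]-A[0][1]*A[1][0])*id;
  return true;
}

static inline void shape_grad_local(double xi, double eta, double zeta,
                                    double dN[8][3]) {
  for (int a = 0; a < 8; a++) {
    dN[a][0] = 0.125*LC[a][0]*(1.0+eta*LC[a][1])*(1.0+zeta*LC[a][2]);
    dN[a][1] = 0.125*LC[a][1]*(1.0+xi*LC[a][0])*(1.0+zeta*LC[a][2]);
    dN[a][2] = 0.125*LC[a][2]*(1.0+xi*LC[a][0])*(1.0+eta*LC[a][1]);
  }
}

// Deviatoric (isochoric) PK2 stress, Voigt tangent and energy density.
static void nh_iso(const double C[3][3], const double Ci[3][3], double J,
                   double I1, double C10, double S[3][3], double D[6][6],
                   double &W, bool want_D) {
  double mu = 2.0*C10;
  double Jm23 = pow(J, -2.0/3.0);
  W = C10*(Jm23*I1 - 3.0);
  for (int i = 0; i < 3; i++)
    for (int j = 0; j < 3; j++)
      S[i][j] = mu*Jm23*((i == j ? 1.0 : 0.0) - (I1/3.0)*Ci[i][j]);
  if (!want_D) return;
  for (int p = 0; p < 6; p++) {
    int I = VI[p][0], Jj = VI[p][1];
    for (int q = 0; q < 6; q++) {
      int K = VI[q][0], L = VI[q][1];
      double dIJ = (I == Jj) ? 1.0 : 0.0;
      double dKL = (K == L) ? 1.0 : 0.0;
      D[p][q] = 2.0*mu*Jm23*( (I1/9.0)*Ci[I][Jj]*Ci[K][L]
               - (1.0/3.0)*(dIJ*Ci[K][L] + Ci[I][Jj]*dKL)
               + (I1/6.0)*(Ci[I][K]*Ci[Jj][L] + Ci[I][L]*Ci[Jj][K]) );
    }
  }
}

// Volumetric PK2 stress, Voigt tangent and energy density.
static void nh_vol(const double Ci[3][3], double J, double D1,
                   double S[3][3], double D[6][6], double &W, bool want_D) {
  double p = (2.0/D1)*(J - 1.0);
  W = (1.0/D1)*(J - 1.0)*(J - 1.0);
  for (int i = 0; i < 3; i++)
    for (int j = 0; j < 3; j++)
      S[i][j] = J*p*Ci[i][j];
  if (!want_D) return;
  double c1 = J*(p + J*(2.0/D1));
  for (int q6 = 0; q6 < 6; q6++) {
    int K = VI[q6][0], L = VI[q6][1];
    for (int p6 = 0; p6 < 6; p6++) {
      int I = VI[p6][0], Jj = VI[p6][1];
      D[p6][q6] = c1*Ci[I][Jj]*Ci[K][L]
                - J*p*(Ci[I][K]*Ci[Jj][L] + Ci[I][L]*Ci[Jj][K]);
    }
  }
}

// One Gauss-point contribution to f and K (Total Lagrangian, Voigt form).
static void gp_accumulate(const double G[8][3], const double F[3][3],
                          const double S[3][3], const double D[6][6],
                          double w, bool want_K, double *f, double *K) {
  double B[6][24];
  for (int b = 0; b < 8; b++) {
    for (int k = 0; k < 3; k++) {
      int c = 3*b + k;
      B[0][c] = F[k][0]*G[b][0];
      B[1][c] = F[k][1]*G[b][1];
      B[2][c] = F[k][2]*G[b][2];
      B[3][c] = F[k][0]*G[b][1] + F[k][1]*G[b][0];
      B[4][c] = F[k][1]*G[b][2] + F[k][2]*G[b][1];
      B[5][c] = F[k][0]*G[b][2] + F[k][2]*G[b][0];
    }
  }
  double Sv[6];
  for (int p = 0; p < 6; p++) Sv[p] = S[VI[p][0]][VI[p][1]];
  for (int c = 0; c < 24; c++) {
    double acc = 0.0;
    for (int p = 0; p < 6; p++) acc += B[p][c]*Sv[p];
    f[c] += w*acc;
  }
  if (!want_K) return;
  double DB[6][24];
  for (int p = 0; p < 6; p++) {
    for (int c = 0; c < 24; c++) {
      double acc = 0.0;
      for (int q = 0; q < 6; q++) acc += D[p][q]*B[q][c];
      DB[p][c] = acc;
    }
  }
  for (int r = 0; r < 24; r++) {
    for (int c = 0; c < 24; c++) {
      double acc = 0.0;
      for (int p = 0; p < 6; p++) acc += B[p][r]*DB[p][c];
      K[24*r + c] += w*acc;
    }
  }
  // geometric stiffness: delta_ik * (G_a S G_b)
  double T[8][3];
  for (int a = 0; a < 8; a++)
    for (int L = 0; L < 3; L++)
      T[a][L] = G[a][0]*S[0][L] + G[a][1]*S[1][L] + G[a][2]*S[2][L];
  for (int a = 0; a < 8; a++) {
    for (int b = 0; b < 8; b++) {
      double g = T[a][0]*G[b][0] + T[a][1]*G[b][1] + T[a][2]*G[b][2];
      for (int i = 0; i < 3; i++) K[24*(3*a+i) + (3*b+i)] += w*g;
    }
  }
}

// Full element: internal force, consistent tangent, stored energy.
// Returns false (with bad flag) on non-positive deformation Jacobian.
static bool elem_kernel(const double X[8][3], const double u[8][3],
                        double C10, double D1, bool want_K,
                        double *f, double *K, double &energy,
                        double &minJ, double &volume) {
  for (int c = 0; c < 24; c++) f[c] = 0.0;
  if (want_K) for (int c = 0; c < 576; c++) K[c] = 0.0;
  energy = 0.0; minJ = R_PosInf; volume = 0.0;

  double dN[8][3], J0[3][3], J0i[3][3], G[8][3], F[3][3];
  double C[3][3], Ci[3][3], S[3][3], D[6][6], W;

  for (int gp = 0; gp < 9; gp++) {
    bool vol_pt = (gp == 8);
    double xi  = vol_pt ? 0.0 : GP*LC[gp][0];
    double eta = vol_pt ? 0.0 : GP*LC[gp][1];
    double zet = vol_pt ? 0.0 : GP*LC[gp][2];
    shape_grad_local(xi, eta, zet, dN);
    for (int i = 0; i < 3; i++)
      for (int k = 0; k < 3; k++) {
        double acc = 0.0;
        for (int a = 0; a < 8; a++) acc += X[a][i]*dN[a][k];
        J0[i][k] = acc;
      }
    double dJ0 = det3(J0);
    if (dJ0 <= 0.0) return false;
    if (!inv3(J0, J0i)) return false;
    double w = vol_pt ? 8.0*dJ0 : dJ0;
    if (!vol_pt) volume += w;
    for (int a = 0; a < 8; a++)
      for (int j = 0; j < 3; j++)
        G[a][j] = dN[a][0]*J0i[0][j] + dN[a][1]*J0i[1][j] + dN[a][2]*J0i[2][j];
    for (int i = 0; i < 3; i++)
      for (int Jc = 0; Jc < 3; Jc++) {
        double acc = (i == Jc) ? 1.0 : 0.0;
        for (int a = 0; a < 8; a++) acc += u[a][i]*G[a][Jc];
        F[i][Jc] = acc;
      }
    double J = det3(F);
    if (J <= 0.0) return false;
    if (J < minJ) minJ = J;
    for (int i = 0; i < 3; i++)
      for (int j = 0; j < 3; j++) {
        double acc = 0.0;
        for (int k = 0; k < 3; k++) acc += F[k][i]*F[k][j];
        C[i][j] = acc;
      }
    if (!inv3(C, Ci)) return false;
    double I1 = C[0][0] + C[1][1] + C[2][2];
    if (vol_pt) nh_vol(Ci, J, D1, S, D, W, want_K);
    else        nh_iso(C, Ci, J, I1, C10, S, D, W, want_K);
    energy += w*W;
    gp_accumulate(G, F, S, D, w, want_K, f, K);
  }
  return true;
}

// [[Rcpp::export]]
List fe_element_cpp(NumericMatrix X, NumericMatrix u, double C10, double D1,
                    bool want_tangent = true) {
  double Xa[8][3], ua[8][3], f[24], K[576];
  for (int a = 0; a < 8; a++)
    for (int j = 0; j < 3; j++) { Xa[a][j] = X(a, j); ua[a][j] = u(a, j); }
  double energy, minJ, volume;
  bool ok = elem_kernel(Xa, ua, C10, D1, want_tangent, f, K,
                        energy, minJ, volume);
  NumericVector fv(24);
  NumericMatrix Km(24, 24);
  if (ok) {
    for (int c = 0; c < 24; c++) fv[c] = f[c];
    if (want_tangent)
      for (int r = 0; r < 24; r++)
        for (int c = 0; c < 24; c++) Km(r, c) = K[24*r + c];
  }
  return List::create(_["ok"] = ok, _["f"] = fv, _["K"] = Km,
                      _["energy"] = energy, _["min_J"] = minJ,
                      _["volume"] = volume);
}

// [[Rcpp::export]]
List fe_assemble_cpp(NumericMatrix nodes, IntegerMatrix elems,
                     NumericMatrix disp, NumericVector C10, NumericVector D1,
                     bool want_tangent = true) {
  int nel = elems.nrow();
  int nn = nodes.nrow();
  NumericVector fint(3*nn);
  NumericVector Kx(want_tangent ? (R_xlen_t)576*nel : 0);
  double X[8][3], u[8][3], f[24], K[576];
  double energy_tot = 0.0, volume_tot = 0.0, minJ_tot = R_PosInf;
  for (int e = 0; e < nel; e++) {
    for (int a = 0; a < 8; a++) {
      int n = elems(e, a) - 1;
      for (int j = 0; j < 3; j++) { X[a][j] = nodes(n, j); u[a][j] = disp(n, j); }
    }
    double energy, minJ, volume;
    bool ok = elem_kernel(X, u, C10[e], D1[e], want_tangent, f, K,
                          energy, minJ, volume);
    if (!ok) {
      return List::create(_["ok"] = false, _["bad_elem"] = e + 1);
    }
    energy_tot += energy; volume_tot += volume;
    if (minJ < minJ_tot) minJ_tot = minJ;
    for (int a = 0; a < 8; a++) {
      int base = 3*(elems(e, a) - 1);
      for (int i = 0; i < 3; i++) fint[base + i] += f[3*a + i];
    }
    if (want_tangent) {
      double *slot = &Kx[(R_xlen_t)576*e];
      for (int c = 0; c < 576; c++) slot[c] = K[c];
    }
  }
  return List::create(_["ok"] = true, _["fint"] = fint, _["Kx"] = Kx,
                      _["energy"] = energy_tot, _["volume"] = volume_tot,
                      _["min_J"] = minJ_tot, _["bad_elem"] = -1);
}

// Sparse-triplet row/column pattern matching the Kx layout of fe_assemble_cpp.
// [[Rcpp::export]]
List fe_pattern_cpp(IntegerMatrix elems) {
  int nel = elems.nrow();
  IntegerVector iv((R_xlen_t)576*nel), jv((R_xlen_t)576*nel);
  R_xlen_t s = 0;
  for (int e = 0; e < nel; e++) {
    int dof[24];
    for (int a = 0; a < 8; a++)
      for (int i = 0; i < 3; i++) dof[3*a + i] = 3*(elems(e, a) - 1) + i + 1;
    for (int r = 0; r < 24; r++)
      for (int c = 0; c < 24; c++) { iv[s] = dof[r]; jv[s] = dof[c]; s++; }
  }
  return List::create(_["i"] = iv, _["j"] = jv);
}

// Material-point evaluation for testing: energy, PK2 and Cauchy stress, and
// the full 3x3x3x3 material tangent (2 dS/dC), iso + vol combined.
// [[Rcpp::export]]
List nh_point_cpp(NumericMatrix Fm, double C10, double D1) {
  double F[3][3], C[3][3], Ci[3][3];
  for (int i = 0; i < 3; i++)
    for (int j = 0; j < 3; j++) F[i][j] = Fm(i, j);
  double J = det3(F);
  if (J <= 0.0) stop("deformation gradient has non-positive determinant");
  for (int i = 0; i < 3; i++)
    for (int j = 0; j < 3; j++) {
      double acc = 0.0;
      for (int k = 0; k < 3; k++) acc += F[k][i]*F[k][j];
      C[i][j] = acc;
    }
  inv3(C, Ci);
  double I1 = C[0][0] + C[1][1] + C[2][2];
  double Si[3][3], Sv[3][3], Di[6][6], Dv[6][6], Wi, Wv;
  nh_iso(C, Ci, J, I1, C10, Si, Di, Wi, true);
  nh_vol(Ci, J, D1, Sv, Dv, Wv, true);
  NumericMatrix S(3, 3), sigma(3, 3);
  for (int i = 0; i < 3; i++)
    for (int j = 0; j < 3; j++) S(i, j) = Si[i][j] + Sv[i][j];
  // sigma = F S F^T / J
  for (int i = 0; i < 3; i++)
    for (int j = 0; j < 3; j++) {
      double acc = 0.0;
      for (int a = 0; a < 3; a++)
        for (int b = 0; b < 3; b++) acc += F[i][a]*S(a, b)*F[j][b];
      sigma(i, j) = acc/J;
    }
  NumericVector tang(81);
  tang.attr("dim") = IntegerVector::create(3, 3, 3, 3);
  // expand Voigt (with both minor symmetries) back to the full tensor
  for (int I = 0; I < 3; I++)
    for (int Jj = 0; Jj < 3; Jj++)
      for (int K = 0; K < 3; K++)
        for (int L = 0; L < 3; L++) {
          int p = -1, q = -1;
          for (int v = 0; v < 6; v++) {
            if ((VI[v][0] == I && VI[v][1] == Jj) ||
                (VI[v][0] == Jj && VI[v][1] == I)) p = v;
            if ((VI[v][0] == K && VI[v][1] == L) ||
                (VI[v][0] == L && VI[v][1] == K)) q = v;
          }
          tang[I + 3*Jj + 9*K + 27*L] = Di[p][q] + Dv[p][q];
        }
  return List::create(_["energy"] = Wi + Wv, _["S"] = S, _["sigma"] = sigma,
                      _["tangent"] = tang, _["J"] = J);
}

// Reference-configuration Jacobian determinants at the 8 Gauss points.
// [[Rcpp::export]]
NumericMatrix mesh_jacobians_cpp(NumericMatrix nodes, IntegerMatrix elems) {
  int nel = elems.nrow();
  NumericMatrix out(nel, 8);
  double X[8][3], dN[8][3], J0[3][3];
  for (int e = 0; e < nel; e++) {
    for (int a = 0; a < 8; a++) {
      int n = elems(e, a) - 1;
      for (int j = 0; j < 3; j++) X[a][j] = nodes(n, j);
    }
    for (int gp = 0; gp < 8; gp++) {
      shape_grad_local(GP*LC[gp][0], GP*LC[gp][1], GP*LC[gp][2], dN);
      for (int i = 0; i < 3; i++)
        for (int k = 0; k < 3; k++) {
          double acc = 0.0;
          for (int a = 0; a < 8; a++) acc += X[a][i]*dN[a][k];
          J0[i][k] = acc;
        }
      out(e, gp) = det3(J0);
    }
  }
  return out;
}

// Scatter element-tangent values into the fixed CSC slot layout.
// [[Rcpp::export]]
NumericVector accumulate_slots_cpp(int n_out, IntegerVector slots,
                                   NumericVector vals) {
  NumericVector out(n_out);
  R_xlen_t n = slots.size();
  for (R_xlen_t k = 0; k < n; k++) out[slots[k] - 1] += vals[k];
  return out;
}
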