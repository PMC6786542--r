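#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Assemble stiffness and growth-strain load for a single layer of 6-node
// linear wedge (prism) elements spanning the shell wall. nodes: (2V) x 3
// positions (bottom sheet then top sheet); elems: E x 6 one-based node
// indices (3 bottom, 3 top); eps0: E x 6 specified growth strain per element
// in global Voigt order [xx, yy, zz, gamma_xy, gamma_yz, gamma_xz]
// (engineering shear).
//
// Each element is assembled in a local corotational frame whose z axis is
// the mid-surface normal, and the transverse-shear rows of B (gamma_yz,
// gamma_xz) are evaluated at the in-plane centroid only (selective reduced
// integration). Full integration of transverse shear makes flat linear
// elements lock in bending, which suppresses the buckling that resolves
// growth conflicts; centroid sampling of the shear strain removes the
// spurious constraint while leaving uniform-strain (membrane) response
// exact. Quadrature: 3-point in-plane x 2-point through thickness.
//
// Returns element stiffness values (column-major per element, for sparse
// triplet assembly in R), the load vector f = sum_e int B' C eps0, the
// constant energy term 0.5 int eps0' C eps0, and the minimum Jacobian
// determinant (negative values flag inverted elements).
// [[Rcpp::export]]
List assemble_wedge(const NumericMatrix& nodes, const IntegerMatrix& elems,
                    const NumericMatrix& eps0, double emod, double nu,
                    int nip = 3) {
  const int ne = elems.nrow();
  const int nn = nodes.nrow();
  const double lam = emod * nu / ((1.0 + nu) * (1.0 - 2.0 * nu));
  const double mu  = emod / (2.0 * (1.0 + nu));

  double C[6][6] = {{0}};
  for (int a = 0; a < 3; ++a) {
    for (int b = 0; b < 3; ++b) C[a][b] = lam;
    C[a][a] = lam + 2.0 * mu;
  }
  for (int a = 3; a < 6; ++a) C[a][a] = mu;

  const double qr3[3] = {1.0 / 6.0, 2.0 / 3.0, 1.0 / 6.0};
  const double qs3[3] = {1.0 / 6.0, 1.0 / 6.0, 2.0 / 3.0};
  const double qr1[1] = {1.0 / 3.0};
  const double qs1[1] = {1.0 / 3.0};
  const double* qr = (nip == 1) ? qr1 : qr3;
  const double* qs = (nip == 1) ? qs1 : qs3;
  const double gz = 1.0 / std::sqrt(3.0);
  const double qz[2] = {-gz, gz};
  const double wq = (nip == 1) ? 0.5 : 1.0 / 6.0;
  const double dLr[3] = {-1.0, 1.0, 0.0};
  const double dLs[3] = {-1.0, 0.0, 1.0};

  NumericVector vals((R_xlen_t)ne * 324);
  NumericVector rhs(3 * (R_xlen_t)nn);
  double e0const = 0.0;
  double mindet = R_PosInf;

  for (int e = 0; e < ne; ++e) {
    int nd[6];
    for (int i = 0; i < 6; ++i) nd[i] = elems(e, i) - 1;
    double Xg[6][3];
    for (int i = 0; i < 6; ++i)
      for (int c = 0; c < 3; ++c) Xg[i][c] = nodes(nd[i], c);

    // local frame: z along the mid-surface normal
    double m0[3], m1[3], m2[3];
    for (int c = 0; c < 3; ++c) {
      m0[c] = 0.5 * (Xg[0][c] + Xg[3][c]);
      m1[c] = 0.5 * (Xg[1][c] + Xg[4][c]);
      m2[c] = 0.5 * (Xg[2][c] + Xg[5][c]);
    }
    double u1[3], u2[3], nz[3];
    for (int c = 0; c < 3; ++c) { u1[c] = m1[c] - m0[c]; u2[c] = m2[c] - m0[c]; }
    nz[0] = u1[1] * u2[2] - u1[2] * u2[1];
    nz[1] = u1[2] * u2[0] - u1[0] * u2[2];
    nz[2] = u1[0] * u2[1] - u1[1] * u2[0];
    double nn2 = std::sqrt(nz[0] * nz[0] + nz[1] * nz[1] + nz[2] * nz[2]);
    for (int c = 0; c < 3; ++c) nz[c] /= nn2;
    double e1n = std::sqrt(u1[0] * u1[0] + u1[1] * u1[1] + u1[2] * u1[2]);
    double ex[3] = {u1[0] / e1n, u1[1] / e1n, u1[2] / e1n};
    double ey[3] = {nz[1] * ex[2] - nz[2] * ex[1],
                    nz[2] * ex[0] - nz[0] * ex[2],
                    nz[0] * ex[1] - nz[1] * ex[0]};
    double Q[3][3];  // columns ex, ey, nz; x_loc = Q^T (x - m0)
    for (int c = 0; c < 3; ++c) { Q[c][0] = ex[c]; Q[c][1] = ey[c]; Q[c][2] = nz[c]; }

    double X[6][3];
    for (int i = 0; i < 6; ++i)
      for (int a = 0; a < 3; ++a) {
        double s = 0;
        for (int c = 0; c < 3; ++c) s += Q[c][a] * (Xg[i][c] - m0[c]);
        X[i][a] = s;
      }

    // rotate specified strain into the local frame: S_loc = Q^T S Q
    double S[3][3];
    S[0][0] = eps0(e, 0); S[1][1] = eps0(e, 1); S[2][2] = eps0(e, 2);
    S[0][1] = S[1][0] = 0.5 * eps0(e, 3);
    S[1][2] = S[2][1] = 0.5 * eps0(e, 4);
    S[0][2] = S[2][0] = 0.5 * eps0(e, 5);
    double QS[3][3];
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) {
        double s = 0;
        for (int c = 0; c < 3; ++c) s += Q[c][a] * S[c][b];
        QS[a][b] = s;
      }
    double SL[3][3];
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) {
        double s = 0;
        for (int c = 0; c < 3; ++c) s += QS[a][c] * Q[c][b];
        SL[a][b] = s;
      }
    double ev[6] = {SL[0][0], SL[1][1], SL[2][2],
                    2.0 * SL[0][1], 2.0 * SL[1][2], 2.0 * SL[0][2]};
    double Ce0[6];
    for (int a = 0; a < 6; ++a) {
      double s = 0;
      for (int b = 0; b < 6; ++b) s += C[a][b] * ev[b];
      Ce0[a] = s;
    }
    double e0CE0 = 0;
    for (int a = 0; a < 6; ++a) e0CE0 += ev[a] * Ce0[a];

    double Ke[18][18] = {{0}};
    double fe[18] = {0};

    for (int iz = 0; iz < 2; ++iz) {
      const double z = qz[iz];
      const double zb = 0.5 * (1.0 - z), zt = 0.5 * (1.0 + z);

      // shape derivatives and gradients at the in-plane centroid (for the
      // reduced transverse-shear rows) and at the full quadrature points
      double gcen[6][3];
      {
        const double Lc[3] = {1.0 / 3.0, 1.0 / 3.0, 1.0 / 3.0};
        double dN[6][3];
        for (int i = 0; i < 3; ++i) {
          dN[i][0] = dLr[i] * zb; dN[i][1] = dLs[i] * zb; dN[i][2] = -0.5 * Lc[i];
          dN[i + 3][0] = dLr[i] * zt; dN[i + 3][1] = dLs[i] * zt; dN[i + 3][2] = 0.5 * Lc[i];
        }
        double J[3][3] = {{0}};
        for (int i = 0; i < 6; ++i)
          for (int a = 0; a < 3; ++a)
            for (int b = 0; b < 3; ++b) J[a][b] += dN[i][a] * X[i][b];
        const double det =
          J[0][0] * (J[1][1] * J[2][2] - J[1][2] * J[2][1]) -
          J[0][1] * (J[1][0] * J[2][2] - J[1][2] * J[2][0]) +
          J[0][2] * (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
        const double id = 1.0 / det;
        double cof[3][3];
        cof[0][0] =  (J[1][1] * J[2][2] - J[1][2] * J[2][1]);
        cof[0][1] = -(J[1][0] * J[2][2] - J[1][2] * J[2][0]);
        cof[0][2] =  (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
        cof[1][0] = -(J[0][1] * J[2][2] - J[0][2] * J[2][1]);
        cof[1][1] =  (J[0][0] * J[2][2] - J[0][2] * J[2][0]);
        cof[1][2] = -(J[0][0] * J[2][1] - J[0][1] * J[2][0]);
        cof[2][0] =  (J[0][1] * J[1][2] - J[0][2] * J[1][1]);
        cof[2][1] = -(J[0][0] * J[1][2] - J[0][2] * J[1][0]);
        cof[2][2] =  (J[0][0] * J[1][1] - J[0][1] * J[1][0]);
        for (int i = 0; i < 6; ++i)
          for (int b = 0; b < 3; ++b) {
            double sv = 0;
            for (int a = 0; a < 3; ++a) sv += cof[a][b] * id * dN[i][a];
            gcen[i][b] = sv;
          }
      }

      for (int ip = 0; ip < nip; ++ip) {
        const double r = qr[ip], s = qs[ip];
        const double L[3] = {1.0 - r - s, r, s};
        double dN[6][3];
        for (int i = 0; i < 3; ++i) {
          dN[i][0] = dLr[i] * zb; dN[i][1] = dLs[i] * zb; dN[i][2] = -0.5 * L[i];
          dN[i + 3][0] = dLr[i] * zt; dN[i + 3][1] = dLs[i] * zt; dN[i + 3][2] = 0.5 * L[i];
        }
        double J[3][3] = {{0}};
        for (int i = 0; i < 6; ++i)
          for (int a = 0; a < 3; ++a)
            for (int b = 0; b < 3; ++b) J[a][b] += dN[i][a] * X[i][b];
        const double det =
          J[0][0] * (J[1][1] * J[2][2] - J[1][2] * J[2][1]) -
          J[0][1] * (J[1][0] * J[2][2] - J[1][2] * J[2][0]) +
          J[0][2] * (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
        if (det < mindet) mindet = det;
        const double id = 1.0 / det;
        double cof[3][3];
        cof[0][0] =  (J[1][1] * J[2][2] - J[1][2] * J[2][1]);
        cof[0][1] = -(J[1][0] * J[2][2] - J[1][2] * J[2][0]);
        cof[0][2] =  (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
        cof[1][0] = -(J[0][1] * J[2][2] - J[0][2] * J[2][1]);
        cof[1][1] =  (J[0][0] * J[2][2] - J[0][2] * J[2][0]);
        cof[1][2] = -(J[0][0] * J[2][1] - J[0][1] * J[2][0]);
        cof[2][0] =  (J[0][1] * J[1][2] - J[0][2] * J[1][1]);
        cof[2][1] = -(J[0][0] * J[1][2] - J[0][2] * J[1][0]);
        cof[2][2] =  (J[0][0] * J[1][1] - J[0][1] * J[1][0]);
        double g[6][3];
        for (int i = 0; i < 6; ++i)
          for (int b = 0; b < 3; ++b) {
            double sv = 0;
            for (int a = 0; a < 3; ++a) sv += cof[a][b] * id * dN[i][a];
            g[i][b] = sv;
          }

        double B[6][18] = {{0}};
        for (int i = 0; i < 6; ++i) {
          const int c0 = 3 * i;
          const double gx = g[i][0], gy = g[i][1], gzz = g[i][2];
          const double hx = gcen[i][0], hy = gcen[i][1], hz = gcen[i][2];
          B[0][c0 + 0] = gx;  B[1][c0 + 1] = gy;  B[2][c0 + 2] = gzz;
          B[3][c0 + 0] = gy;  B[3][c0 + 1] = gx;
          // transverse shear from the in-plane centroid (reduced integration)
          B[4][c0 + 1] = hz;  B[4][c0 + 2] = hy;
          B[5][c0 + 0] = hz;  B[5][c0 + 2] = hx;
        }
        double CB[6][18];
        for (int a = 0; a < 6; ++a)
          for (int c = 0; c < 18; ++c) {
            double sv = 0;
            for (int b = 0; b < 6; ++b) sv += C[a][b] * B[b][c];
            CB[a][c] = sv;
          }
        const double w = wq * det;
        for (int rI = 0; rI < 18; ++rI) {
          double fr = 0;
          for (int a = 0; a < 6; ++a) fr += B[a][rI] * Ce0[a];
          fe[rI] += w * fr;
          for (int cI = rI; cI < 18; ++cI) {
            double kv = 0;
            for (int a = 0; a < 6; ++a) kv += B[a][rI] * CB[a][cI];
            Ke[rI][cI] += w * kv;
          }
        }
        e0const += 0.5 * w * e0CE0;
      }
    }
    for (int rI = 0; rI < 18; ++rI)
      for (int cI = 0; cI < rI; ++cI) Ke[rI][cI] = Ke[cI][rI];

    // rotate element matrices back to the global frame:
    // K_g = T K_l T', f_g = T f_l with T = blockdiag(Q) (x_loc = Q^T x_glob)
    double Kg[18][18];
    double fg[18];
    for (int a = 0; a < 6; ++a)
      for (int i = 0; i < 3; ++i) {
        double s = 0;
        for (int k = 0; k < 3; ++k) s += Q[i][k] * fe[3 * a + k];
        fg[3 * a + i] = s;
      }
    // temp = K_l T' : temp[r][3b+j] = sum_l K[r][3b+l] Q[j][l]
    double tmp[18][18];
    for (int rI = 0; rI < 18; ++rI)
      for (int b = 0; b < 6; ++b)
        for (int j = 0; j < 3; ++j) {
          double s = 0;
          for (int l = 0; l < 3; ++l) s += Ke[rI][3 * b + l] * Q[j][l];
          tmp[rI][3 * b + j] = s;
        }
    for (int a = 0; a < 6; ++a)
      for (int i = 0; i < 3; ++i)
        for (int cI = 0; cI < 18; ++cI) {
          double s = 0;
          for (int k = 0; k < 3; ++k) s += Q[i][k] * tmp[3 * a + k][cI];
          Kg[3 * a + i][cI] = s;
        }

    double* vp = &vals[(R_xlen_t)e * 324];
    for (int cI = 0; cI < 18; ++cI)
      for (int rI = 0; rI < 18; ++rI) vp[cI * 18 + rI] = Kg[rI][cI];
    for (int i = 0; i < 6; ++i)
      for (int c = 0; c < 3; ++c) rhs[3 * (R_xlen_t)nd[i] + c] += fg[3 * i + c];
  }
  return List::create(_["vals"] = vals, _["rhs"] = rhs,
                      _["e0const"] = e0const, _["mindet"] = mindet);
}

// Minimum wedge Jacobian determinant over all quadrature points, used to
// detect element inversion after a growth step.
// [[Rcpp::export]]
double wedge_min_jacobian(const NumericMatrix& nodes, const IntegerMatrix& elems) {
  const int ne = elems.nrow();
  const double qr[3] = {1.0 / 6.0, 2.0 / 3.0, 1.0 / 6.0};
  const double qs[3] = {1.0 / 6.0, 1.0 / 6.0, 2.0 / 3.0};
  const double gz = 1.0 / std::sqrt(3.0);
  const double qz[2] = {-gz, gz};
  double mindet = R_PosInf;
  for (int e = 0; e < ne; ++e) {
    double X[6][3];
    for (int i = 0; i < 6; ++i)
      for (int c = 0; c < 3; ++c) X[i][c] = nodes(elems(e, i) - 1, c);
    for (int ip = 0; ip < 3; ++ip) {
      const double r = qr[ip], s = qs[ip];
      const double L[3] = {1.0 - r - s, r, s};
      const double dLr[3] = {-1.0, 1.0, 0.0};
      const double dLs[3] = {-1.0, 0.0, 1.0};
      for (int iz = 0; iz < 2; ++iz) {
        const double z = qz[iz];
        const double zb = 0.5 * (1.0 - z), zt = 0.5 * (1.0 + z);
        double dN[6][3];
        for (int i = 0; i < 3; ++i) {
          dN[i][0] = dLr[i] * zb; dN[i][1] = dLs[i] * zb; dN[i][2] = -0.5 * L[i];
          dN[i + 3][0] = dLr[i] * zt; dN[i + 3][1] = dLs[i] * zt; dN[i + 3][2] = 0.5 * L[i];
        }
        double J[3][3] = {{0}};
        for (int i = 0; i < 6; ++i)
          for (int a = 0; a < 3; ++a)
            for (int b = 0; b < 3; ++b) J[a][b] += dN[i][a] * X[i][b];
        const double det =
          J[0][0] * (J[1][1] * J[2][2] - J[1][2] * J[2][1]) -
          J[0][1] * (J[1][0] * J[2][2] - J[1][2] * J[2][0]) +
          J[0][2] * (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
        if (det < mindet) mindet = det;
      }
    }
  }
  return mindet;
}
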