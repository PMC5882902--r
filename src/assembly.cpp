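// Compiled kernels: finite-strain mixed FEM assembly for a vessel
// cross-section (plane strain with prescribed out-of-plane stretch),
// and image resampling helpers used by registration / optical flow.
//
// The element residual is written once as a template over the scalar type;
// consistent tangents are obtained by complex-step differentiation of the
// element residual (exact to machine precision, no finite-difference error).

#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>

using namespace Rcpp;

typedef std::complex<double> cplx;

// ---------------------------------------------------------------------------
// small dense helpers (templated over double / complex<double>)
// ---------------------------------------------------------------------------

template <typename T>
inline T det2(const T a[2][2]) {
  return a[0][0] * a[1][1] - a[0][1] * a[1][0];
}

template <typename T>
inline void inv2(const T a[2][2], T ai[2][2], T &det) {
  det = det2(a);
  T idet = T(1.0) / det;
  ai[0][0] =  a[1][1] * idet;
  ai[0][1] = -a[0][1] * idet;
  ai[1][0] = -a[1][0] * idet;
  ai[1][1] =  a[0][0] * idet;
}

inline double re(double x) { return x; }
inline double re(const cplx &x) { return x.real(); }

inline double powm23(double J) { return std::pow(J, -2.0 / 3.0); }
inline cplx   powm23(const cplx &J) { return std::pow(J, cplx(-2.0 / 3.0)); }

// ---------------------------------------------------------------------------
// element residual, P1/P1 triangle, one-point quadrature
//
// dofs: ue[3][2] nodal displacements (mm), le[3] nodal pressure multiplier
// (Pa).  Xe holds the coordinates of the configuration the problem is posed
// on: material coordinates for the forward problem (mode 0), imaged/spatial
// coordinates for the preload problem (mode 1).
//
// Constitutive model: incompressible Neo-Hookean, psi = c/2 (I1bar - 3),
// S_iso = c J^(-2/3) (I - I1/3 C^-1); the multiplier enters as
// sigma = sigma_iso - lambda I (S_p = -lambda J C^-1).
// Out-of-plane stretch lamz is prescribed (generalized plane strain);
// incompressibility then reads lamz * det F2d = 1.
//
// The incompressibility equation is stabilized with a Brezzi-Pitkaranta
// pressure-diffusion term  -beta h^2 / c * int grad(q) . grad(lambda).
// ---------------------------------------------------------------------------

template <typename T>
void elem_residual(const double Xe[3][2], const T ue[3][2], const T le[3],
                   double c, double lamz, double beta, int mode, T R[9]) {
  // geometry of the reference-for-assembly triangle
  double Jx[2][2] = { { Xe[1][0] - Xe[0][0], Xe[2][0] - Xe[0][0] },
                      { Xe[1][1] - Xe[0][1], Xe[2][1] - Xe[0][1] } };
  double Jxi[2][2], detJ;
  inv2(Jx, Jxi, detJ);
  double A = 0.5 * detJ;            // signed; meshes are oriented CCW
  // shape-function gradients dN[a][j] = d N_a / d x_j
  const double gxi[3][2] = { { -1.0, -1.0 }, { 1.0, 0.0 }, { 0.0, 1.0 } };
  double dN[3][2];
  for (int a = 0; a < 3; ++a)
    for (int j = 0; j < 2; ++j)
      dN[a][j] = gxi[a][0] * Jxi[0][j] + gxi[a][1] * Jxi[1][j];

  // displacement gradient at the (single) quadrature point
  T Gu[2][2];
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < 2; ++j) {
      Gu[i][j] = T(0.0);
      for (int a = 0; a < 3; ++a) Gu[i][j] += ue[a][i] * dN[a][j];
    }
  T lamc = (le[0] + le[1] + le[2]) / T(3.0);
  T gradLam[2];
  for (int j = 0; j < 2; ++j) {
    gradLam[j] = T(0.0);
    for (int a = 0; a < 3; ++a) gradLam[j] += le[a] * dN[a][j];
  }

  T F2[2][2];              // in-plane deformation gradient (material->spatial)
  T constraint;            // det F - 1 in the active formulation
  T Pi[2][2];              // in-plane nominal/Cauchy stress used in residual

  if (mode == 0) {
    // forward problem on the material configuration
    F2[0][0] = T(1.0) + Gu[0][0]; F2[0][1] = Gu[0][1];
    F2[1][0] = Gu[1][0];          F2[1][1] = T(1.0) + Gu[1][1];
    T detF2 = det2(F2);
    T Jdet = T(lamz) * detF2;
    // C = F^T F (in-plane block), C33 = lamz^2
    T C2[2][2];
    C2[0][0] = F2[0][0]*F2[0][0] + F2[1][0]*F2[1][0];
    C2[0][1] = F2[0][0]*F2[0][1] + F2[1][0]*F2[1][1];
    C2[1][0] = C2[0][1];
    C2[1][1] = F2[0][1]*F2[0][1] + F2[1][1]*F2[1][1];
    T I1 = C2[0][0] + C2[1][1] + T(lamz * lamz);
    T Ci2[2][2], detC2;
    inv2(C2, Ci2, detC2);
    T Jm23 = powm23(Jdet);
    // S = S_iso + S_p (in-plane block)
    T S2[2][2];
    for (int i = 0; i < 2; ++i)
      for (int j = 0; j < 2; ++j) {
        T iso = T(c) * Jm23 * (T(i == j ? 1.0 : 0.0) - I1 / T(3.0) * Ci2[i][j]);
        S2[i][j] = iso - lamc * Jdet * Ci2[i][j];
      }
    // first Piola-Kirchhoff (in-plane): P = F S
    for (int i = 0; i < 2; ++i)
      for (int j = 0; j < 2; ++j)
        Pi[i][j] = F2[i][0]*S2[0][j] + F2[i][1]*S2[1][j];
    constraint = Jdet - T(1.0);
  } else {
    // preload (inverse) problem on the imaged/spatial configuration:
    // f = I - grad_s u ; F = f^-1 in-plane, F33 = lamz
    T f2[2][2];
    f2[0][0] = T(1.0) - Gu[0][0]; f2[0][1] = -Gu[0][1];
    f2[1][0] = -Gu[1][0];         f2[1][1] = T(1.0) - Gu[1][1];
    T detf2;
    inv2(f2, F2, detf2);
    T detF2 = T(1.0) / detf2;
    T Jdet = T(lamz) * detF2;
    T C2[2][2];
    C2[0][0] = F2[0][0]*F2[0][0] + F2[1][0]*F2[1][0];
    C2[0][1] = F2[0][0]*F2[0][1] + F2[1][0]*F2[1][1];
    C2[1][0] = C2[0][1];
    C2[1][1] = F2[0][1]*F2[0][1] + F2[1][1]*F2[1][1];
    T I1 = C2[0][0] + C2[1][1] + T(lamz * lamz);
    T Ci2[2][2], detC2;
    inv2(C2, Ci2, detC2);
    T Jm23 = powm23(Jdet);
    T S2[2][2];
    for (int i = 0; i < 2; ++i)
      for (int j = 0; j < 2; ++j)
        S2[i][j] = T(c) * Jm23 * (T(i == j ? 1.0 : 0.0) - I1 / T(3.0) * Ci2[i][j]);
    // Cauchy iso stress sigma = (1/J) F S F^T, then total = sigma - lambda I
    T FS[2][2];
    for (int i = 0; i < 2; ++i)
      for (int j = 0; j < 2; ++j)
        FS[i][j] = F2[i][0]*S2[0][j] + F2[i][1]*S2[1][j];
    for (int i = 0; i < 2; ++i)
      for (int j = 0; j < 2; ++j) {
        T sig = (FS[i][0]*F2[j][0] + FS[i][1]*F2[j][1]) / Jdet;
        Pi[i][j] = sig - (i == j ? lamc : T(0.0));
      }
    constraint = Jdet - T(1.0);
  }

  // residual: momentum rows then pressure rows
  double h2 = std::fabs(2.0 * A);       // characteristic element size squared
  double stab = beta * h2 / c;
  for (int a = 0; a < 3; ++a) {
    for (int i = 0; i < 2; ++i) {
      T r = T(0.0);
      for (int j = 0; j < 2; ++j) r += Pi[i][j] * T(dN[a][j]);
      R[2 * a + i] = T(A) * r;
    }
    T rs = -T(A) * constraint / T(3.0);
    rs -= T(stab * A) * (T(dN[a][0]) * gradLam[0] + T(dN[a][1]) * gradLam[1]);
    R[6 + a] = rs;
  }
}

// follower pressure on a lumen edge (forward problem); edge oriented CCW
// around the lumen so (t.y, -t.x) points into the wall.  Residual = -force.
template <typename T>
void edgeW_forward(const double Xe[2][2], const T ue[2][2],
                   double p, double lamz, T R[4]) {
  T x1[2] = { T(Xe[0][0]) + ue[0][0], T(Xe[0][1]) + ue[0][1] };
  T x2[2] = { T(Xe[1][0]) + ue[1][0], T(Xe[1][1]) + ue[1][1] };
  T t[2] = { x2[0] - x1[0], x2[1] - x1[1] };
  T n[2] = { t[1], -t[0] };
  for (int a = 0; a < 2; ++a) {
    R[2 * a + 0] = -T(0.5 * lamz * p) * n[0];
    R[2 * a + 1] = -T(0.5 * lamz * p) * n[1];
  }
}

// ---------------------------------------------------------------------------
// global assembly
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List assemble_system_cpp(NumericMatrix nodes, IntegerMatrix tri,
                         IntegerVector region, NumericVector c_region,
                         double lambda_z, double beta,
                         NumericMatrix u, NumericVector lam,
                         int mode, double pressure, IntegerMatrix edgesW,
                         double tau, IntegerMatrix edgesE, NumericMatrix uref,
                         bool want_tangent) {
  const int N = nodes.nrow(), NE = tri.nrow();
  const int ndof = 3 * N;
  NumericVector res(ndof);
  std::vector<int> ti, tj;
  std::vector<double> tx;
  if (want_tangent) {
    ti.reserve((size_t)NE * 81 + edgesW.nrow() * 16 + edgesE.nrow() * 8);
    tj.reserve(ti.capacity());
    tx.reserve(ti.capacity());
  }
  const double h = 1e-30;   // complex-step size

  auto udof = [](int node, int comp) { return 2 * node + comp; };

  double Xe[3][2];
  for (int e = 0; e < NE; ++e) {
    int nd[3] = { tri(e, 0) - 1, tri(e, 1) - 1, tri(e, 2) - 1 };
    for (int a = 0; a < 3; ++a) {
      Xe[a][0] = nodes(nd[a], 0);
      Xe[a][1] = nodes(nd[a], 1);
    }
    double c = c_region[region[e] - 1];
    double ue[3][2], le[3];
    for (int a = 0; a < 3; ++a) {
      ue[a][0] = u(nd[a], 0);
      ue[a][1] = u(nd[a], 1);
      le[a] = lam[nd[a]];
    }
    int gdof[9];
    for (int a = 0; a < 3; ++a) {
      gdof[2 * a] = udof(nd[a], 0);
      gdof[2 * a + 1] = udof(nd[a], 1);
      gdof[6 + a] = 2 * N + nd[a];
    }
    double Rr[9];
    elem_residual<double>(Xe, ue, le, c, lambda_z, beta, mode, Rr);
    for (int p = 0; p < 9; ++p) res[gdof[p]] += Rr[p];

    if (want_tangent) {
      cplx uc[3][2], lc[3], Rc[9];
      for (int q = 0; q < 9; ++q) {
        for (int a = 0; a < 3; ++a) {
          uc[a][0] = cplx(ue[a][0], 0.0);
          uc[a][1] = cplx(ue[a][1], 0.0);
          lc[a] = cplx(le[a], 0.0);
        }
        if (q < 6) uc[q / 2][q % 2] += cplx(0.0, h);
        else lc[q - 6] += cplx(0.0, h);
        elem_residual<cplx>(Xe, uc, lc, c, lambda_z, beta, mode, Rc);
        for (int p = 0; p < 9; ++p) {
          double k = Rc[p].imag() / h;
          if (k != 0.0) {
            ti.push_back(gdof[p]);
            tj.push_back(gdof[q]);
            tx.push_back(k);
          }
        }
      }
    }
  }

  // lumen pressure edges
  if (pressure != 0.0) {
    double Ee[2][2];
    for (int e = 0; e < edgesW.nrow(); ++e) {
      int nd[2] = { edgesW(e, 0) - 1, edgesW(e, 1) - 1 };
      for (int a = 0; a < 2; ++a) {
        Ee[a][0] = nodes(nd[a], 0);
        Ee[a][1] = nodes(nd[a], 1);
      }
      int gdof[4] = { udof(nd[0], 0), udof(nd[0], 1),
                      udof(nd[1], 0), udof(nd[1], 1) };
      if (mode == 0) {
        double ue[2][2] = { { u(nd[0], 0), u(nd[0], 1) },
                            { u(nd[1], 0), u(nd[1], 1) } };
        double Rr[4];
        edgeW_forward<double>(Ee, ue, pressure, lambda_z, Rr);
        for (int p = 0; p < 4; ++p) res[gdof[p]] += Rr[p];
        if (want_tangent) {
          cplx uc[2][2], Rc[4];
          for (int q = 0; q < 4; ++q) {
            for (int a = 0; a < 2; ++a) {
              uc[a][0] = cplx(ue[a][0], 0.0);
              uc[a][1] = cplx(ue[a][1], 0.0);
            }
            uc[q / 2][q % 2] += cplx(0.0, h);
            edgeW_forward<cplx>(Ee, uc, pressure, lambda_z, Rc);
            for (int p = 0; p < 4; ++p) {
              double k = Rc[p].imag() / h;
              if (k != 0.0) {
                ti.push_back(gdof[p]);
                tj.push_back(gdof[q]);
                tx.push_back(k);
              }
            }
          }
        }
      } else {
        // dead load on the fixed imaged boundary
        double t[2] = { Ee[1][0] - Ee[0][0], Ee[1][1] - Ee[0][1] };
        double n[2] = { t[1], -t[0] };
        for (int a = 0; a < 2; ++a) {
          res[gdof[2 * a + 0]] -= 0.5 * pressure * n[0];
          res[gdof[2 * a + 1]] -= 0.5 * pressure * n[1];
        }
      }
    }
  }

  // Robin support on the external boundary (forward problem only):
  // traction tau * (u - uref) on the nominal edge, consistent 2-node mass
  if (mode == 0 && tau > 0.0) {
    for (int e = 0; e < edgesE.nrow(); ++e) {
      int nd[2] = { edgesE(e, 0) - 1, edgesE(e, 1) - 1 };
      double dx = nodes(nd[1], 0) - nodes(nd[0], 0);
      double dy = nodes(nd[1], 1) - nodes(nd[0], 1);
      double L0 = std::sqrt(dx * dx + dy * dy);
      double d0[2] = { u(nd[0], 0) - uref(nd[0], 0), u(nd[0], 1) - uref(nd[0], 1) };
      double d1[2] = { u(nd[1], 0) - uref(nd[1], 0), u(nd[1], 1) - uref(nd[1], 1) };
      for (int i = 0; i < 2; ++i) {
        res[udof(nd[0], i)] += tau * L0 * (d0[i] / 3.0 + d1[i] / 6.0);
        res[udof(nd[1], i)] += tau * L0 * (d1[i] / 3.0 + d0[i] / 6.0);
        if (want_tangent) {
          int ga = udof(nd[0], i), gb = udof(nd[1], i);
          ti.push_back(ga); tj.push_back(ga); tx.push_back(tau * L0 / 3.0);
          ti.push_back(gb); tj.push_back(gb); tx.push_back(tau * L0 / 3.0);
          ti.push_back(ga); tj.push_back(gb); tx.push_back(tau * L0 / 6.0);
          ti.push_back(gb); tj.push_back(ga); tx.push_back(tau * L0 / 6.0);
        }
      }
    }
  }

  return List::create(_["res"] = res,
                      _["i"] = wrap(ti), _["j"] = wrap(tj), _["x"] = wrap(tx));
}

// minimum in-plane det F over elements for a candidate state (used to reject
// inverted configurations during line search)
// [[Rcpp::export]]
NumericVector element_detF_cpp(NumericMatrix nodes, IntegerMatrix tri,
                               NumericMatrix u, int mode) {
  const int NE = tri.nrow();
  NumericVector out(NE);
  for (int e = 0; e < NE; ++e) {
    int nd[3] = { tri(e, 0) - 1, tri(e, 1) - 1, tri(e, 2) - 1 };
    double Jx[2][2] = {
      { nodes(nd[1], 0) - nodes(nd[0], 0), nodes(nd[2], 0) - nodes(nd[0], 0) },
      { nodes(nd[1], 1) - nodes(nd[0], 1), nodes(nd[2], 1) - nodes(nd[0], 1) } };
    double Jxi[2][2], detJ;
    inv2(Jx, Jxi, detJ);
    const double gxi[3][2] = { { -1, -1 }, { 1, 0 }, { 0, 1 } };
    double dN[3][2];
    for (int a = 0; a < 3; ++a)
      for (int j = 0; j < 2; ++j)
        dN[a][j] = gxi[a][0] * Jxi[0][j] + gxi[a][1] * Jxi[1][j];
    double Gu[2][2] = { { 0, 0 }, { 0, 0 } };
    for (int i = 0; i < 2; ++i)
      for (int j = 0; j < 2; ++j)
        for (int a = 0; a < 3; ++a) Gu[i][j] += u(nd[a], i) * dN[a][j];
    double F2[2][2];
    if (mode == 0) {
      F2[0][0] = 1 + Gu[0][0]; F2[0][1] = Gu[0][1];
      F2[1][0] = Gu[1][0];     F2[1][1] = 1 + Gu[1][1];
      out[e] = det2(F2);
    } else {
      double f2[2][2] = { { 1 - Gu[0][0], -Gu[0][1] },
                          { -Gu[1][0], 1 - Gu[1][1] } };
      out[e] = 1.0 / det2(f2);
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// imaging helpers
// ---------------------------------------------------------------------------

// bilinear sampling of an image (matrix, row = y, col = x) at continuous
// 1-based coordinates; returns NA outside the footprint
// [[Rcpp::export]]
NumericVector bilinear_sample_cpp(NumericMatrix img, NumericVector x,
                                  NumericVector y) {
  int H = img.nrow(), W = img.ncol(), n = x.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    double xx = x[k], yy = y[k];
    if (xx < 1.0 || xx > (double)W || yy < 1.0 || yy > (double)H) {
      out[k] = NA_REAL;
      continue;
    }
    int x0 = (int)std::floor(xx); if (x0 == W) x0 = W - 1;
    int y0 = (int)std::floor(yy); if (y0 == H) y0 = H - 1;
    double fx = xx - x0, fy = yy - y0;
    double v00 = img(y0 - 1, x0 - 1), v01 = img(y0 - 1, x0);
    double v10 = img(y0, x0 - 1),     v11 = img(y0, x0);
    out[k] = (1 - fy) * ((1 - fx) * v00 + fx * v01) +
             fy * ((1 - fx) * v10 + fx * v11);
  }
  return out;
}

static inline double lik_term(double d) {
  // d - log(exp(2 d) + 1), evaluated in a numerically stable symmetric form
  double a = std::fabs(d);
  return -a - std::log1p(std::exp(-2.0 * a));
}

// mean per-pixel log-likelihood of Is transformed by (tx, ty, angle about
// the image centre) against ID; out-of-frame samples are excluded
// [[Rcpp::export]]
List likelihood_search_cpp(NumericMatrix Is, NumericMatrix ID,
                           NumericVector txs, NumericVector tys,
                           NumericVector angles) {
  int H = ID.nrow(), W = ID.ncol();
  double cx = (W + 1) / 2.0, cy = (H + 1) / 2.0;
  double best = -1e300;
  double btx = 0, bty = 0, bang = 0;
  for (int ia = 0; ia < angles.size(); ++ia) {
    double ca = std::cos(angles[ia]), sa = std::sin(angles[ia]);
    for (int it = 0; it < txs.size(); ++it) {
      for (int iu = 0; iu < tys.size(); ++iu) {
        double tx = txs[it], ty = tys[iu];
        double s = 0.0;
        int cnt = 0;
        for (int y = 1; y <= H; ++y) {
          for (int x = 1; x <= W; ++x) {
            // source coordinates in Is
            double rx = x - cx, ry = y - cy;
            double sx = ca * rx - sa * ry + cx + tx;
            double sy = sa * rx + ca * ry + cy + ty;
            if (sx < 1.0 || sx > W || sy < 1.0 || sy > H) continue;
            int x0 = (int)std::floor(sx); if (x0 == W) x0 = W - 1;
            int y0 = (int)std::floor(sy); if (y0 == H) y0 = H - 1;
            double fx = sx - x0, fy = sy - y0;
            double v = (1 - fy) * ((1 - fx) * Is(y0 - 1, x0 - 1) + fx * Is(y0 - 1, x0)) +
                       fy * ((1 - fx) * Is(y0, x0 - 1) + fx * Is(y0, x0));
            s += lik_term(v - ID(y - 1, x - 1));
            ++cnt;
          }
        }
        if (cnt > 0) {
          double m = s / cnt;
          if (m > best) { best = m; btx = tx; bty = ty; bang = angles[ia]; }
        }
      }
    }
  }
  return List::create(_["tx"] = btx, _["ty"] = bty, _["angle"] = bang,
                      _["value"] = best);
}
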