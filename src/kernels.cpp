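#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Explicit convection term for P1 triangles: Galerkin transport plus
// residual-based streamline (SUPG) stabilization. Basis gradients are
// constant per element and precomputed on the R side.
//
// Returns the assembled nodal vectors N_x, N_y of
//   (w, u.grad u) + sum_e tau_e (u.grad w, R)_e,
//   R = u.grad u + grad p / rho - f   (P1: elementwise Laplacian is zero)
// [[Rcpp::export(name = ".cpp_advection_rhs")]]
List cpp_advection_rhs(IntegerMatrix tri, NumericVector area,
                       NumericMatrix gx, NumericMatrix gy,
                       NumericVector he,
                       NumericVector u, NumericVector v,
                       NumericVector p,
                       NumericVector fx, NumericVector fy,
                       double rho, double nu, bool supg) {
  int m = tri.nrow();
  int n = u.size();
  NumericVector Nx(n), Ny(n);
  bool has_f = fx.size() == n;

  for (int e = 0; e < m; ++e) {
    int i0 = tri(e, 0) - 1, i1 = tri(e, 1) - 1, i2 = tri(e, 2) - 1;
    double A = area[e];
    // constant velocity gradient on the element
    double dudx = gx(e, 0) * u[i0] + gx(e, 1) * u[i1] + gx(e, 2) * u[i2];
    double dudy = gy(e, 0) * u[i0] + gy(e, 1) * u[i1] + gy(e, 2) * u[i2];
    double dvdx = gx(e, 0) * v[i0] + gx(e, 1) * v[i1] + gx(e, 2) * v[i2];
    double dvdy = gy(e, 0) * v[i0] + gy(e, 1) * v[i1] + gy(e, 2) * v[i2];
    double dpdx = gx(e, 0) * p[i0] + gx(e, 1) * p[i1] + gx(e, 2) * p[i2];
    double dpdy = gy(e, 0) * p[i0] + gy(e, 1) * p[i1] + gy(e, 2) * p[i2];

    // Galerkin: int phi_i (u_h . grad) u_h, exact for the quadratic integrand
    double su0 = u[i0] * dudx + v[i0] * dudy; // x-component advection at nodes
    double su1 = u[i1] * dudx + v[i1] * dudy;
    double su2 = u[i2] * dudx + v[i2] * dudy;
    double sv0 = u[i0] * dvdx + v[i0] * dvdy;
    double sv1 = u[i1] * dvdx + v[i1] * dvdy;
    double sv2 = u[i2] * dvdx + v[i2] * dvdy;
    double Su = su0 + su1 + su2, Sv = sv0 + sv1 + sv2;
    double c = A / 12.0;
    Nx[i0] += c * (Su + su0); Nx[i1] += c * (Su + su1); Nx[i2] += c * (Su + su2);
    Ny[i0] += c * (Sv + sv0); Ny[i1] += c * (Sv + sv1); Ny[i2] += c * (Sv + sv2);

    if (supg) {
      double ubx = (u[i0] + u[i1] + u[i2]) / 3.0;
      double uby = (v[i0] + v[i1] + v[i2]) / 3.0;
      double umag = std::sqrt(ubx * ubx + uby * uby);
      double h = he[e];
      double a1 = 2.0 * umag / h;
      double a2 = 4.0 * nu / (h * h);
      double denom = std::sqrt(a1 * a1 + a2 * a2);
      if (denom < 1e-300) continue;
      double tau = 1.0 / denom;
      double fbx = 0.0, fby = 0.0;
      if (has_f) {
        fbx = (fx[i0] + fx[i1] + fx[i2]) / 3.0;
        fby = (fy[i0] + fy[i1] + fy[i2]) / 3.0;
      }
      double Rx = ubx * dudx + uby * dudy + dpdx / rho - fbx;
      double Ry = ubx * dvdx + uby * dvdy + dpdy / rho - fby;
      double w0 = ubx * gx(e, 0) + uby * gy(e, 0);
      double w1 = ubx * gx(e, 1) + uby * gy(e, 1);
      double w2 = ubx * gx(e, 2) + uby * gy(e, 2);
      double tA = tau * A;
      Nx[i0] += tA * w0 * Rx; Nx[i1] += tA * w1 * Rx; Nx[i2] += tA * w2 * Rx;
      Ny[i0] += tA * w0 * Ry; Ny[i1] += tA * w1 * Ry; Ny[i2] += tA * w2 * Ry;
    }
  }
  return List::create(_["Nx"] = Nx, _["Ny"] = Ny);
}

// One explicit step of cell-centered finite-volume scalar advection with
// MUSCL reconstruction (Green-Gauss gradients, Barth-Jespersen limiter).
// Faces carry precomputed volumetric fluxes F (positive = left -> right).
// right[f] >= 1 : interior neighbour cell; 0 : boundary (inflow carries
// concentration c_in, outflow removes the upwind value).
//
// Returns updated concentrations plus the mass leaving the domain.
// [[Rcpp::export(name = ".cpp_scalar_step")]]
List cpp_scalar_step(NumericVector c0,
                     IntegerVector left, IntegerVector right,
                     NumericVector flux,
                     NumericMatrix cell_xy, NumericMatrix face_xy,
                     NumericMatrix face_normal_len, // nx*len, ny*len
                     NumericVector cell_area,
                     double dt, double c_in, int order) {
  int m = c0.size();
  int nf = flux.size();
  NumericVector c = clone(c0);
  NumericVector gxc(m), gyc(m), cmin(m), cmax(m), psi(m);
  for (int i = 0; i < m; ++i) { cmin[i] = c[i]; cmax[i] = c[i]; psi[i] = 1.0; }

  if (order >= 2) {
    // Green-Gauss gradient with face value = adjacent-cell average
    for (int f = 0; f < nf; ++f) {
      int L = left[f] - 1, R = right[f] - 1;
      double cf = (R >= 0) ? 0.5 * (c[L] + c[R]) : c[L];
      gxc[L] += cf * face_normal_len(f, 0);
      gyc[L] += cf * face_normal_len(f, 1);
      if (R >= 0) {
        gxc[R] -= cf * face_normal_len(f, 0);
        gyc[R] -= cf * face_normal_len(f, 1);
        if (c[L] < cmin[R]) cmin[R] = c[L];
        if (c[L] > cmax[R]) cmax[R] = c[L];
        if (c[R] < cmin[L]) cmin[L] = c[R];
        if (c[R] > cmax[L]) cmax[L] = c[R];
      }
    }
    for (int i = 0; i < m; ++i) { gxc[i] /= cell_area[i]; gyc[i] /= cell_area[i]; }
    // Barth-Jespersen limiter
    for (int f = 0; f < nf; ++f) {
      for (int side = 0; side < 2; ++side) {
        int i = (side == 0) ? left[f] - 1 : right[f] - 1;
        if (i < 0) continue;
        double d = gxc[i] * (face_xy(f, 0) - cell_xy(i, 0)) +
                   gyc[i] * (face_xy(f, 1) - cell_xy(i, 1));
        double r = 1.0;
        if (d > 1e-14) r = (cmax[i] - c[i]) / d;
        else if (d < -1e-14) r = (cmin[i] - c[i]) / d;
        if (r < psi[i]) psi[i] = r;
      }
    }
    for (int i = 0; i < m; ++i) {
      if (psi[i] > 1.0) psi[i] = 1.0;
      if (psi[i] < 0.0) psi[i] = 0.0;
    }
  }

  NumericVector dc(m);
  double mass_out = 0.0, mass_in = 0.0;
  for (int f = 0; f < nf; ++f) {
    int L = left[f] - 1, R = right[f] - 1;
    double F = flux[f];
    if (F == 0.0) continue;
    double cf;
    if (F > 0.0) { // upwind = left
      cf = c[L];
      if (order >= 2)
        cf += psi[L] * (gxc[L] * (face_xy(f, 0) - cell_xy(L, 0)) +
                        gyc[L] * (face_xy(f, 1) - cell_xy(L, 1)));
    } else if (R >= 0) { // upwind = right
      cf = c[R];
      if (order >= 2)
        cf += psi[R] * (gxc[R] * (face_xy(f, 0) - cell_xy(R, 0)) +
                        gyc[R] * (face_xy(f, 1) - cell_xy(R, 1)));
    } else { // boundary inflow
      cf = c_in;
    }
    dc[L] -= F * cf;
    if (R >= 0) dc[R] += F * cf;
    else if (F > 0.0) mass_out += F * cf;
    else mass_in -= F * cf;
  }
  for (int i = 0; i < m; ++i) c[i] += dt * dc[i] / cell_area[i];
  return List::create(_["c"] = c,
                      _["mass_out"] = mass_out * dt,
                      _["mass_in"] = mass_in * dt);
}

// Brute-force point location with barycentric coordinates.
// Returns 1-based triangle index (0 when outside) and the barycentric weights.
// [[Rcpp::export(name = ".cpp_locate_points")]]
List cpp_locate_points(NumericVector px, NumericVector py,
                       IntegerMatrix tri,
                       NumericVector vx, NumericVector vy,
                       double tol) {
  int np = px.size(), m = tri.nrow();
  IntegerVector idx(np);
  NumericMatrix bary(np, 3);
  for (int q = 0; q < np; ++q) {
    idx[q] = 0;
    double best_bad = 1e300;
    for (int e = 0; e < m; ++e) {
      int a = tri(e, 0) - 1, b = tri(e, 1) - 1, cix = tri(e, 2) - 1;
      double x1 = vx[a], y1 = vy[a], x2 = vx[b], y2 = vy[b];
      double x3 = vx[cix], y3 = vy[cix];
      double det = (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3);
      if (std::fabs(det) < 1e-300) continue;
      double l1 = ((y2 - y3) * (px[q] - x3) + (x3 - x2) * (py[q] - y3)) / det;
      double l2 = ((y3 - y1) * (px[q] - x3) + (x1 - x3) * (py[q] - y3)) / det;
      double l3 = 1.0 - l1 - l2;
      double bad = 0.0;
      if (l1 < 0) bad -= l1;
      if (l2 < 0) bad -= l2;
      if (l3 < 0) bad -= l3;
      if (bad == 0.0) {
        idx[q] = e + 1;
        bary(q, 0) = l1; bary(q, 1) = l2; bary(q, 2) = l3;
        break;
      }
      if (bad < best_bad && bad <= tol) {
        best_bad = bad;
        idx[q] = e + 1;
        bary(q, 0) = l1; bary(q, 1) = l2; bary(q, 2) = l3;
      }
    }
  }
  return List::create(_["triangle"] = idx, _["bary"] = bary);
}
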