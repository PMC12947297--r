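#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Shared conventions
// ------------------
// Pressure tensors are R arrays dim (Nt, Nv, Nr), column-major, so the
// linear offset of sample (w, v, j) is w + Nt*(v + Nv*j).  Transducers are
// enumerated view-major, q = v*Nr + j, and `positions` rows follow q.
// Volumes are R arrays dim (nx, ny, nz); voxel (i, j, k) sits at
// origin + h*(i, j, k).  All distances in mm, times in microseconds,
// speeds in mm/us.

static inline R_xlen_t pidx(int w, int q, int Nt, int Nv, int Nr) {
  int v = q / Nr, j = q % Nr;
  return (R_xlen_t)w + (R_xlen_t)Nt * ((R_xlen_t)v + (R_xlen_t)Nv * j);
}

// Spreading stage S of the interpolation-based forward operator followed by
// the central-difference time derivative D.  Each voxel deposits onto the
// time bins bracketing its arrival tau = d/c0 via the triangle kernel
// lambda(u) = max(0, 1 - |u|), u = (w dt - tau) / tk, with half-width
// tk = max(dt, h/c0): exactly the two-bin linear interpolation whenever the
// sampling interval is no finer than the voxel transit time, and an
// anti-aliased shell quadrature (mass-preserving, 1/tk normalization)
// otherwise.  Voxel-as-point quadrature with weight h^3.  Loop order:
// voxel-major outer, transducer inner.
// [[Rcpp::export(name = ".cpp_forward")]]
NumericVector cpp_forward(NumericVector f,
                          IntegerVector ndim, NumericVector origin, double h,
                          NumericMatrix positions, int Nt, int Nv, int Nr,
                          double dt, double c0) {
  const int nx = ndim[0], ny = ndim[1], nz = ndim[2];
  const int Nq = positions.nrow();
  const double h3 = h * h * h;
  const double tk = std::max(dt, h / c0);
  const double norm = h3 / (4.0 * M_PI * c0 * c0 * tk);
  NumericVector s((R_xlen_t)Nt * Nv * Nr);
  NumericVector p((R_xlen_t)Nt * Nv * Nr);

  for (int k = 0; k < nz; ++k) {
    double z = origin[2] + h * k;
    for (int j = 0; j < ny; ++j) {
      double y = origin[1] + h * j;
      for (int i = 0; i < nx; ++i) {
        double fn = f[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
        if (fn == 0.0) continue;
        double x = origin[0] + h * i;
        for (int q = 0; q < Nq; ++q) {
          double dx = positions(q, 0) - x;
          double dy = positions(q, 1) - y;
          double dz = positions(q, 2) - z;
          double d = std::sqrt(dx * dx + dy * dy + dz * dz);
          if (d < 1e-9)
            stop("singular distance: transducer coincides with a voxel center");
          double tau = d / c0;
          double amp = fn * norm / d;
          int wlo = (int)std::ceil((tau - tk) / dt);
          int whi = (int)std::floor((tau + tk) / dt);
          if (wlo < 0) wlo = 0;
          if (whi >= Nt) whi = Nt - 1;
          for (int w = wlo; w <= whi; ++w) {
            double lam = 1.0 - std::fabs(w * dt - tau) / tk;
            if (lam > 0.0) s[pidx(w, q, Nt, Nv, Nr)] += amp * lam;
          }
        }
      }
    }
  }
  // derivative stage: p[w] = (s[w+1] - s[w-1]) / (2 dt), zero outside range
  for (int q = 0; q < Nq; ++q) {
    for (int w = 0; w < Nt; ++w) {
      double sp = (w + 1 < Nt) ? s[pidx(w + 1, q, Nt, Nv, Nr)] : 0.0;
      double sm = (w - 1 >= 0) ? s[pidx(w - 1, q, Nt, Nv, Nr)] : 0.0;
      p[pidx(w, q, Nt, Nv, Nr)] = (sp - sm) / (2.0 * dt);
    }
  }
  p.attr("dim") = IntegerVector::create(Nt, Nv, Nr);
  return p;
}

// Exact algebraic transpose of cpp_forward.  D^T first, then per-voxel
// gather with the same triangle weights and 1/(4 pi c0^2 d dt) factors.
// Voxels outside the y slab [y0, y1) are left at zero; per-voxel summation
// order (transducer index increasing) is independent of the slab, so slab
// values are bit-identical to the full adjoint.
// [[Rcpp::export(name = ".cpp_adjoint")]]
NumericVector cpp_adjoint(NumericVector p,
                          IntegerVector ndim, NumericVector origin, double h,
                          NumericMatrix positions, int Nt, int Nv, int Nr,
                          double dt, double c0, int y0, int y1) {
  const int nx = ndim[0], ny = ndim[1], nz = ndim[2];
  const int Nq = positions.nrow();
  const double h3 = h * h * h;
  const double tk = std::max(dt, h / c0);
  const double norm = h3 / (4.0 * M_PI * c0 * c0 * tk);
  NumericVector sadj((R_xlen_t)Nt * Nv * Nr);
  NumericVector f((R_xlen_t)nx * ny * nz);

  for (int q = 0; q < Nq; ++q) {
    for (int w = 0; w < Nt; ++w) {
      double pm = (w - 1 >= 0) ? p[pidx(w - 1, q, Nt, Nv, Nr)] : 0.0;
      double pp = (w + 1 < Nt) ? p[pidx(w + 1, q, Nt, Nv, Nr)] : 0.0;
      sadj[pidx(w, q, Nt, Nv, Nr)] = (pm - pp) / (2.0 * dt);
    }
  }
  for (int k = 0; k < nz; ++k) {
    double z = origin[2] + h * k;
    for (int j = y0; j < y1; ++j) {
      double y = origin[1] + h * j;
      for (int i = 0; i < nx; ++i) {
        double x = origin[0] + h * i;
        double acc = 0.0;
        for (int q = 0; q < Nq; ++q) {
          double dx = positions(q, 0) - x;
          double dy = positions(q, 1) - y;
          double dz = positions(q, 2) - z;
          double d = std::sqrt(dx * dx + dy * dy + dz * dz);
          if (d < 1e-9)
            stop("singular distance: transducer coincides with a voxel center");
          double tau = d / c0;
          double amp = norm / d;
          double g = 0.0;
          int wlo = (int)std::ceil((tau - tk) / dt);
          int whi = (int)std::floor((tau + tk) / dt);
          if (wlo < 0) wlo = 0;
          if (whi >= Nt) whi = Nt - 1;
          for (int w = wlo; w <= whi; ++w) {
            double lam = 1.0 - std::fabs(w * dt - tau) / tk;
            if (lam > 0.0) g += sadj[pidx(w, q, Nt, Nv, Nr)] * lam;
          }
          acc += amp * g;
        }
        f[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = acc;
      }
    }
  }
  f.attr("dim") = ndim;
  return f;
}

// Weighted backprojection of already-filtered data b for the standard FBP
// baseline: fhat[n] = sum_q w_qn b(q, tau/dt) / sum_q w_qn with
// w_qn = area_q |nhat_q . (r_n - r_q)| / d^2 and linear temporal
// interpolation of b at the continuous index tau/dt.
// [[Rcpp::export(name = ".cpp_backproject_ubp")]]
NumericVector cpp_backproject_ubp(NumericVector b,
                                  IntegerVector ndim, NumericVector origin,
                                  double h, NumericMatrix positions,
                                  NumericMatrix normals, NumericVector areas,
                                  int Nt, int Nv, int Nr,
                                  double dt, double c0) {
  const int nx = ndim[0], ny = ndim[1], nz = ndim[2];
  const int Nq = positions.nrow();
  NumericVector f((R_xlen_t)nx * ny * nz);

  for (int k = 0; k < nz; ++k) {
    double z = origin[2] + h * k;
    for (int j = 0; j < ny; ++j) {
      double y = origin[1] + h * j;
      for (int i = 0; i < nx; ++i) {
        double x = origin[0] + h * i;
        double num = 0.0, den = 0.0;
        for (int q = 0; q < Nq; ++q) {
          double dx = x - positions(q, 0);
          double dy = y - positions(q, 1);
          double dz = z - positions(q, 2);
          double d2 = dx * dx + dy * dy + dz * dz;
          double d = std::sqrt(d2);
          if (d < 1e-9) continue;
          double u = d / (c0 * dt);
          int w0 = (int)std::floor(u);
          double frac = u - w0;
          double bv = 0.0;
          if (w0 >= 0 && w0 < Nt) bv += b[pidx(w0, q, Nt, Nv, Nr)] * (1.0 - frac);
          if (w0 + 1 >= 0 && w0 + 1 < Nt) bv += b[pidx(w0 + 1, q, Nt, Nv, Nr)] * frac;
          double dotn = normals(q, 0) * dx + normals(q, 1) * dy + normals(q, 2) * dz;
          double wgt = areas[q] * std::fabs(dotn) / d2;
          num += wgt * bv;
          den += wgt;
        }
        f[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] =
          (den > 0.0) ? num / den : 0.0;
      }
    }
  }
  f.attr("dim") = ndim;
  return f;
}
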