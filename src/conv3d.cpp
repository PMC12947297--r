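#include <Rcpp.h>
using namespace Rcpp;

// Dense 3D convolution primitives for the strictly linear filtering network.
//
// Feature tensors are R arrays dim (T, V, R, C) (time, view, ring, channel),
// column-major.  Kernels are dim (kt, kv, kr, Cin, Cout).  All convolutions
// are "valid" (padding is handled by the caller) and correlation-style
// (no kernel flip), matching the usual deep-learning convention.

static inline R_xlen_t tidx(int t, int v, int r, int c,
                            int T, int V, int R) {
  return (R_xlen_t)t +
         (R_xlen_t)T * ((R_xlen_t)v +
         (R_xlen_t)V * ((R_xlen_t)r + (R_xlen_t)R * c));
}

static inline R_xlen_t widx(int a, int b, int c, int ci, int co,
                            int kt, int kv, int kr, int Cin) {
  return (R_xlen_t)a +
         (R_xlen_t)kt * ((R_xlen_t)b +
         (R_xlen_t)kv * ((R_xlen_t)c +
         (R_xlen_t)kr * ((R_xlen_t)ci + (R_xlen_t)Cin * co)));
}

// y[t,v,r,co] = sum_{a,b,c,ci} x[t*s+a, v*s+b, r*s+c, ci] w[a,b,c,ci,co]
// [[Rcpp::export(name = ".cpp_conv3d_fwd")]]
NumericVector cpp_conv3d_fwd(NumericVector x, IntegerVector xd,
                             NumericVector w, IntegerVector wd, int s) {
  const int T = xd[0], V = xd[1], R = xd[2], Cin = xd[3];
  const int kt = wd[0], kv = wd[1], kr = wd[2], Cout = wd[4];
  const int To = (T - kt) / s + 1, Vo = (V - kv) / s + 1, Ro = (R - kr) / s + 1;
  NumericVector y((R_xlen_t)To * Vo * Ro * Cout);
  for (int co = 0; co < Cout; ++co)
    for (int r = 0; r < Ro; ++r)
      for (int v = 0; v < Vo; ++v)
        for (int t = 0; t < To; ++t) {
          double acc = 0.0;
          for (int ci = 0; ci < Cin; ++ci)
            for (int c = 0; c < kr; ++c)
              for (int b = 0; b < kv; ++b)
                for (int a = 0; a < kt; ++a)
                  acc += x[tidx(t * s + a, v * s + b, r * s + c, ci, T, V, R)] *
                         w[widx(a, b, c, ci, co, kt, kv, kr, Cin)];
          y[tidx(t, v, r, co, To, Vo, Ro)] = acc;
        }
  y.attr("dim") = IntegerVector::create(To, Vo, Ro, Cout);
  return y;
}

// gradient of cpp_conv3d_fwd w.r.t. x
// [[Rcpp::export(name = ".cpp_conv3d_bwd_x")]]
NumericVector cpp_conv3d_bwd_x(NumericVector gy, IntegerVector xd,
                               NumericVector w, IntegerVector wd, int s) {
  const int T = xd[0], V = xd[1], R = xd[2], Cin = xd[3];
  const int kt = wd[0], kv = wd[1], kr = wd[2], Cout = wd[4];
  const int To = (T - kt) / s + 1, Vo = (V - kv) / s + 1, Ro = (R - kr) / s + 1;
  NumericVector gx((R_xlen_t)T * V * R * Cin);
  for (int co = 0; co < Cout; ++co)
    for (int r = 0; r < Ro; ++r)
      for (int v = 0; v < Vo; ++v)
        for (int t = 0; t < To; ++t) {
          double g = gy[tidx(t, v, r, co, To, Vo, Ro)];
          if (g == 0.0) continue;
          for (int ci = 0; ci < Cin; ++ci)
            for (int c = 0; c < kr; ++c)
              for (int b = 0; b < kv; ++b)
                for (int a = 0; a < kt; ++a)
                  gx[tidx(t * s + a, v * s + b, r * s + c, ci, T, V, R)] +=
                    g * w[widx(a, b, c, ci, co, kt, kv, kr, Cin)];
        }
  gx.attr("dim") = xd;
  return gx;
}

// gradient of cpp_conv3d_fwd w.r.t. w
// [[Rcpp::export(name = ".cpp_conv3d_bwd_w")]]
NumericVector cpp_conv3d_bwd_w(NumericVector x, IntegerVector xd,
                               NumericVector gy, IntegerVector wd, int s) {
  const int T = xd[0], V = xd[1], R = xd[2], Cin = xd[3];
  const int kt = wd[0], kv = wd[1], kr = wd[2], Cout = wd[4];
  const int To = (T - kt) / s + 1, Vo = (V - kv) / s + 1, Ro = (R - kr) / s + 1;
  NumericVector gw((R_xlen_t)kt * kv * kr * Cin * Cout);
  for (int co = 0; co < Cout; ++co)
    for (int r = 0; r < Ro; ++r)
      for (int v = 0; v < Vo; ++v)
        for (int t = 0; t < To; ++t) {
          double g = gy[tidx(t, v, r, co, To, Vo, Ro)];
          if (g == 0.0) continue;
          for (int ci = 0; ci < Cin; ++ci)
            for (int c = 0; c < kr; ++c)
              for (int b = 0; b < kv; ++b)
                for (int a = 0; a < kt; ++a)
                  gw[widx(a, b, c, ci, co, kt, kv, kr, Cin)] +=
                    g * x[tidx(t * s + a, v * s + b, r * s + c, ci, T, V, R)];
        }
  gw.attr("dim") = wd;
  return gw;
}

// Transposed convolution with kernel size == stride (the upsampling layer):
// y[s*t+a, s*v+b, s*r+c, co] = sum_ci x[t,v,r,ci] w[a,b,c,ci,co]
// [[Rcpp::export(name = ".cpp_convt3d_fwd")]]
NumericVector cpp_convt3d_fwd(NumericVector x, IntegerVector xd,
                              NumericVector w, IntegerVector wd, int s) {
  const int T = xd[0], V = xd[1], R = xd[2], Cin = xd[3];
  const int kt = wd[0], kv = wd[1], kr = wd[2], Cout = wd[4];
  const int To = T * s, Vo = V * s, Ro = R * s;
  NumericVector y((R_xlen_t)To * Vo * Ro * Cout);
  for (int co = 0; co < Cout; ++co)
    for (int r = 0; r < R; ++r)
      for (int v = 0; v < V; ++v)
        for (int t = 0; t < T; ++t)
          for (int ci = 0; ci < Cin; ++ci) {
            double xv = x[tidx(t, v, r, ci, T, V, R)];
            if (xv == 0.0) continue;
            for (int c = 0; c < kr; ++c)
              for (int b = 0; b < kv; ++b)
                for (int a = 0; a < kt; ++a)
                  y[tidx(t * s + a, v * s + b, r * s + c, co, To, Vo, Ro)] +=
                    xv * w[widx(a, b, c, ci, co, kt, kv, kr, Cin)];
          }
  y.attr("dim") = IntegerVector::create(To, Vo, Ro, Cout);
  return y;
}

// gradient of cpp_convt3d_fwd w.r.t. x
// [[Rcpp::export(name = ".cpp_convt3d_bwd_x")]]
NumericVector cpp_convt3d_bwd_x(NumericVector gy, IntegerVector xd,
                                NumericVector w, IntegerVector wd, int s) {
  const int T = xd[0], V = xd[1], R = xd[2], Cin = xd[3];
  const int kt = wd[0], kv = wd[1], kr = wd[2], Cout = wd[4];
  const int To = T * s, Vo = V * s, Ro = R * s;
  NumericVector gx((R_xlen_t)T * V * R * Cin);
  for (int co = 0; co < Cout; ++co)
    for (int r = 0; r < R; ++r)
      for (int v = 0; v < V; ++v)
        for (int t = 0; t < T; ++t)
          for (int ci = 0; ci < Cin; ++ci) {
            double acc = 0.0;
            for (int c = 0; c < kr; ++c)
              for (int b = 0; b < kv; ++b)
                for (int a = 0; a < kt; ++a)
                  acc += gy[tidx(t * s + a, v * s + b, r * s + c, co, To, Vo, Ro)] *
                         w[widx(a, b, c, ci, co, kt, kv, kr, Cin)];
            gx[tidx(t, v, r, ci, T, V, R)] += acc;
          }
  gx.attr("dim") = xd;
  return gx;
}

// gradient of cpp_convt3d_fwd w.r.t. w
// [[Rcpp::export(name = ".cpp_convt3d_bwd_w")]]
NumericVector cpp_convt3d_bwd_w(NumericVector x, IntegerVector xd,
                                NumericVector gy, IntegerVector wd, int s) {
  const int T = xd[0], V = xd[1], R = xd[2], Cin = xd[3];
  const int kt = wd[0], kv = wd[1], kr = wd[2], Cout = wd[4];
  const int To = T * s, Vo = V * s, Ro = R * s;
  NumericVector gw((R_xlen_t)kt * kv * kr * Cin * Cout);
  for (int co = 0; co < Cout; ++co)
    for (int r = 0; r < R; ++r)
      for (int v = 0; v < V; ++v)
        for (int t = 0; t < T; ++t)
          for (int ci = 0; ci < Cin; ++ci) {
            double xv = x[tidx(t, v, r, ci, T, V, R)];
            if (xv == 0.0) continue;
            for (int c = 0; c < kr; ++c)
              for (int b = 0; b < kv; ++b)
                for (int a = 0; a < kt; ++a)
                  gw[widx(a, b, c, ci, co, kt, kv, kr, Cin)] +=
                    xv * gy[tidx(t * s + a, v * s + b, r * s + c, co, To, Vo, Ro)];
          }
  gw.attr("dim") = wd;
  return gw;
}
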