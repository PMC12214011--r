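#include <Rcpp.h>
using namespace Rcpp;

// Method-of-lines right-hand side of the tumour-immune reaction-diffusion
// system on a masked uniform grid. Fields are stacked (u, v, w) over the
// active nodes. `nb` holds ghost-reflected neighbour indices (1-based):
// 2 columns (left, right) in 1D, 8 columns (E, W, N, S and the four
// diagonals) in 2D for the compact 9-point stencil. `nbf` holds raw face
// neighbours (NA outside) for the conservative nonlinear tumour flux.
// Dirichlet boundary dosing of w is realised by overwriting dw/dt with the
// prescribed derivative dBw on rim nodes (their values are initialised to
// B_w(0) and then track B_w(t) exactly).

// [[Rcpp::export]]
NumericVector rhs_core(double t, NumericVector y, IntegerMatrix nb,
                       IntegerMatrix nbf, double h, int dim,
                       double delta_u, double delta_w, NumericVector kin,
                       double su, double sw, bool dirichlet_w,
                       IntegerVector rim, double dBw, bool nonlinear_v,
                       double atto_floor) {
  const int N = y.size() / 3;
  const double alpha = kin[0], mu_u = kin[1], rho_u = kin[2],
    mu_w = kin[3], rho_w = kin[4], gamma_v = kin[5], gamma_w = kin[6];
  const double ih2 = 1.0 / (h * h);
  NumericVector dy(3 * N);
  const double *u = &y[0], *v = &y[N], *w = &y[2 * N];

  for (int i = 0; i < N; ++i) {
    double lap_u, lap_v = 0.0, lap_w;
    if (dim == 1) {
      int l = nb(i, 0) - 1, r = nb(i, 1) - 1;
      lap_u = (u[l] + u[r] - 2.0 * u[i]) * ih2;
      lap_w = (w[l] + w[r] - 2.0 * w[i]) * ih2;
      if (!nonlinear_v) lap_v = (v[l] + v[r] - 2.0 * v[i]) * ih2;
    } else {
      double eu = 0.0, ev = 0.0, ew = 0.0, cu = 0.0, cv = 0.0, cw = 0.0;
      for (int k = 0; k < 4; ++k) {
        int q = nb(i, k) - 1;
        eu += u[q]; ev += v[q]; ew += w[q];
      }
      for (int k = 4; k < 8; ++k) {
        int q = nb(i, k) - 1;
        cu += u[q]; cv += v[q]; cw += w[q];
      }
      lap_u = (4.0 * eu + cu - 20.0 * u[i]) * ih2 / 6.0;
      lap_w = (4.0 * ew + cw - 20.0 * w[i]) * ih2 / 6.0;
      if (!nonlinear_v) lap_v = (4.0 * ev + cv - 20.0 * v[i]) * ih2 / 6.0;
    }
    if (nonlinear_v) {
      // conservative flux form of div((1-v)^2 grad v): face diffusivity is
      // the average of (1-v)^2 at the two cells; missing faces carry no flux
      double di = (1.0 - v[i]) * (1.0 - v[i]);
      double acc = 0.0;
      int nf = nbf.ncol();
      for (int k = 0; k < nf; ++k) {
        int q = nbf(i, k);
        if (q == NA_INTEGER) continue;
        double dq = (1.0 - v[q - 1]) * (1.0 - v[q - 1]);
        acc += 0.5 * (di + dq) * (v[q - 1] - v[i]);
      }
      lap_v = acc * ih2;
    }
    double ui = u[i], vi = v[i], wi = w[i];
    dy[i] = delta_u * lap_u + alpha * vi - mu_u * ui +
      rho_u * ui * wi / (1.0 + wi) + su;
    double dv = lap_v + vi * (1.0 - vi) - ui * vi / (gamma_v + vi);
    if (atto_floor > 0.0 && vi < atto_floor) dv -= vi;
    dy[N + i] = dv;
    dy[2 * N + i] = delta_w * lap_w + rho_w * ui * vi / (gamma_w + vi) -
      mu_w * wi + sw;
  }
  if (dirichlet_w)
    for (int k = 0; k < rim.size(); ++k)
      dy[2 * N + rim[k] - 1] = dBw;
  return dy;
}
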