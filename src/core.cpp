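#include <Rcpp.h>
using namespace Rcpp;

// Reflect an index into [0, n-1] (replicate border, Neumann).
static inline int clampi(int i, int n) {
  if (i < 0) return 0;
  if (i >= n) return n - 1;
  return i;
}

// One explicit step of Perona-Malik anisotropic diffusion on a 2D band.
// Four-neighbour scheme with per-edge conduction; zero-flux boundaries, so
// the pixel sum is conserved.  conduction = 0: c(s) = exp(-(s/g)^2)
// (standard); conduction = 1: c(s) = exp(1 + (s/g)^2) (as-printed variant,
// for study only).
// [[Rcpp::export(name = ".ad_step_cpp")]]
NumericMatrix ad_step_cpp(NumericMatrix I, double dt, double gthr,
                          int conduction) {
  int n = I.nrow(), m = I.ncol();
  NumericMatrix out(n, m);
  double g2 = gthr * gthr;
  for (int c = 0; c < m; ++c) {
    for (int r = 0; r < n; ++r) {
      double v = I(r, c);
      double dN = I(clampi(r - 1, n), c) - v;
      double dS = I(clampi(r + 1, n), c) - v;
      double dW = I(r, clampi(c - 1, m)) - v;
      double dE = I(r, clampi(c + 1, m)) - v;
      double cN, cS, cW, cE;
      if (conduction == 0) {
        cN = std::exp(-(dN * dN) / g2);
        cS = std::exp(-(dS * dS) / g2);
        cW = std::exp(-(dW * dW) / g2);
        cE = std::exp(-(dE * dE) / g2);
      } else {
        cN = std::exp(1.0 + (dN * dN) / g2);
        cS = std::exp(1.0 + (dS * dS) / g2);
        cW = std::exp(1.0 + (dW * dW) / g2);
        cE = std::exp(1.0 + (dE * dE) / g2);
      }
      out(r, c) = v + dt * (cN * dN + cS * dS + cW * dW + cE * dE);
    }
  }
  return out;
}

// Core of one evolution step, writing into `out`; see evolve_step_cpp for
// the discretization contract.
static void evolve_once(const double* phi, const double* g, double* out,
                        double* nx, double* ny, double* gnx, double* gny,
                        double* lap, int n, int m,
                        double mu, double lambda, double nu,
                        double alpha, double dt) {
  const double eps = 1e-10;
  for (int c = 0; c < m; ++c) {
    int cl = clampi(c - 1, m), cr = clampi(c + 1, m);
    for (int r = 0; r < n; ++r) {
      int rt = clampi(r - 1, n), rb = clampi(r + 1, n);
      double px = (phi[r + cr * n] - phi[r + cl * n]) / 2.0;
      double py = (phi[rb + c * n] - phi[rt + c * n]) / 2.0;
      double nrm = std::sqrt(px * px + py * py);
      if (nrm < eps) nrm = eps;
      int i = r + c * n;
      nx[i] = px / nrm;
      ny[i] = py / nrm;
      gnx[i] = g[i] * nx[i];
      gny[i] = g[i] * ny[i];
      lap[i] = phi[r + cr * n] + phi[r + cl * n] + phi[rb + c * n] +
               phi[rt + c * n] - 4.0 * phi[i];
    }
  }
  for (int c = 0; c < m; ++c) {
    int cl = clampi(c - 1, m), cr = clampi(c + 1, m);
    for (int r = 0; r < n; ++r) {
      int rt = clampi(r - 1, n), rb = clampi(r + 1, n);
      int i = r + c * n;
      double curv = (nx[r + cr * n] - nx[r + cl * n]) / 2.0 +
                    (ny[rb + c * n] - ny[rt + c * n]) / 2.0;
      double divg = (gnx[r + cr * n] - gnx[r + cl * n]) / 2.0 +
                    (gny[rb + c * n] - gny[rt + c * n]) / 2.0;
      double s = phi[i];
      double del = 0.0;
      if (s >= -alpha && s <= alpha)
        del = (1.0 + std::cos(M_PI * s / alpha)) / (2.0 * alpha);
      double rhs = mu * (lap[i] - curv) + lambda * del * divg +
                   nu * g[i] * del;
      out[i] = s + dt * rhs;
    }
  }
}

// Run up to max_iter evolution steps, stopping once max |phi_{t+1} - phi_t|
// stays below tol for `calm` consecutive iterations.  Returns the final
// field plus iteration count, convergence flag and last update size.
// [[Rcpp::export(name = ".evolve_run_cpp")]]
List evolve_run_cpp(NumericMatrix phi0, NumericMatrix g,
                    double mu, double lambda, double nu,
                    double alpha, double dt,
                    int max_iter, double tol, int calm) {
  int n = phi0.nrow(), m = phi0.ncol();
  std::vector<double> a(phi0.begin(), phi0.end()), b(n * m),
      nx(n * m), ny(n * m), gnx(n * m), gny(n * m), lap(n * m);
  double* cur = a.data();
  double* nxt = b.data();
  int it = 0, quiet = 0;
  bool converged = false;
  double last_delta = 0.0;
  bool finite = true;
  while (it < max_iter) {
    evolve_once(cur, g.begin(), nxt, nx.data(), ny.data(), gnx.data(),
                gny.data(), lap.data(), n, m, mu, lambda, nu, alpha, dt);
    ++it;
    double d = 0.0;
    for (int i = 0; i < n * m; ++i) {
      double ad = std::fabs(nxt[i] - cur[i]);
      if (ad > d) d = ad;
    }
    last_delta = d;
    if (!std::isfinite(d)) { finite = false; break; }
    std::swap(cur, nxt);
    quiet = (d < tol) ? quiet + 1 : 0;
    if (quiet >= calm) { converged = true; break; }
  }
  NumericMatrix out(n, m);
  std::copy(cur, cur + n * m, out.begin());
  return List::create(_["phi"] = out, _["iterations"] = it,
                      _["converged"] = converged,
                      _["final_delta"] = last_delta,
                      _["finite"] = finite);
}

// One explicit-Euler step of the reinitialization-free level-set flow
//   dphi/dt = mu [ Lap(phi) - div(grad phi / |grad phi|) ]
//           + lambda delta_a(phi) div( g grad phi / |grad phi| )
//           + nu g delta_a(phi)
// Laplacian: 5-point stencil.  All first derivatives: central differences.
// Borders: replicated (Neumann).  |grad phi| floored at 1e-10.
// delta_a(s) = (1 + cos(pi s / a)) / (2 a) on |s| <= a, else 0.
// [[Rcpp::export(name = ".evolve_step_cpp")]]
NumericMatrix evolve_step_cpp(NumericMatrix phi, NumericMatrix g,
                              double mu, double lambda, double nu,
                              double alpha, double dt) {
  int n = phi.nrow(), m = phi.ncol();
  const double eps = 1e-10;
  NumericMatrix nx(n, m), ny(n, m), gnx(n, m), gny(n, m), lap(n, m);
  for (int c = 0; c < m; ++c) {
    int cl = clampi(c - 1, m), cr = clampi(c + 1, m);
    for (int r = 0; r < n; ++r) {
      int rt = clampi(r - 1, n), rb = clampi(r + 1, n);
      double px = (phi(r, cr) - phi(r, cl)) / 2.0;
      double py = (phi(rb, c) - phi(rt, c)) / 2.0;
      double nrm = std::sqrt(px * px + py * py);
      if (nrm < eps) nrm = eps;
      nx(r, c) = px / nrm;
      ny(r, c) = py / nrm;
      gnx(r, c) = g(r, c) * nx(r, c);
      gny(r, c) = g(r, c) * ny(r, c);
      lap(r, c) = phi(r, cr) + phi(r, cl) + phi(rb, c) + phi(rt, c)
                  - 4.0 * phi(r, c);
    }
  }
  NumericMatrix out(n, m);
  for (int c = 0; c < m; ++c) {
    int cl = clampi(c - 1, m), cr = clampi(c + 1, m);
    for (int r = 0; r < n; ++r) {
      int rt = clampi(r - 1, n), rb = clampi(r + 1, n);
      double curv = (nx(r, cr) - nx(r, cl)) / 2.0 +
                    (ny(rb, c) - ny(rt, c)) / 2.0;
      double divg = (gnx(r, cr) - gnx(r, cl)) / 2.0 +
                    (gny(rb, c) - gny(rt, c)) / 2.0;
      double s = phi(r, c);
      double del = 0.0;
      if (s >= -alpha && s <= alpha)
        del = (1.0 + std::cos(M_PI * s / alpha)) / (2.0 * alpha);
      double rhs = mu * (lap(r, c) - curv) + lambda * del * divg +
                   nu * g(r, c) * del;
      out(r, c) = s + dt * rhs;
    }
  }
  return out;
}
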