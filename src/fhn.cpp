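#include <Rcpp.h>
using namespace Rcpp;

// Explicit-Euler integration of a two-variable relaxation oscillator with
// diffusion of the fast activator u and a spatially varying rate eps of the
// slow recovery variable w:
//   du/dt = k (u - u^3/3 - w) + D lap(u)
//   dw/dt = eps(x) (u + a - b w)
// Zero-flux boundaries on the grid edge and outside the mask.
// [[Rcpp::export]]
NumericVector fhn_integrate_cpp(NumericMatrix u0, NumericMatrix w0,
                                NumericMatrix eps, LogicalMatrix mask,
                                double a, double b, double k, double D,
                                double h, double dt, int n_steps,
                                int save_every) {
  const int nr = u0.nrow(), nc = u0.ncol();
  std::vector<double> u(u0.begin(), u0.end()), w(w0.begin(), w0.end());
  std::vector<double> un(nr * nc);
  const double ih2 = D / (h * h);
  const int n_saved = n_steps / save_every + 1;
  NumericVector out(Dimension(nr, nc, n_saved));

  auto save = [&](int slot) {
    for (int i = 0; i < nr * nc; ++i) out[slot * nr * nc + i] = u[i];
  };
  save(0);
  int slot = 1;
  for (int step = 1; step <= n_steps; ++step) {
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        const int i = c * nr + r;
        if (!mask(r, c)) { un[i] = u[i]; continue; }
        const double uc = u[i];
        const double uL = (c > 0 && mask(r, c - 1)) ? u[i - nr] : uc;
        const double uR = (c < nc - 1 && mask(r, c + 1)) ? u[i + nr] : uc;
        const double uU = (r > 0 && mask(r - 1, c)) ? u[i - 1] : uc;
        const double uD = (r < nr - 1 && mask(r + 1, c)) ? u[i + 1] : uc;
        const double lap = (uL + uR + uU + uD - 4.0 * uc) * ih2;
        un[i] = uc + dt * (k * (uc - uc * uc * uc / 3.0 - w[i]) + lap);
      }
    }
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        const int i = c * nr + r;
        if (!mask(r, c)) continue;
        w[i] += dt * eps(r, c) * (u[i] + a - b * w[i]);
      }
    }
    std::swap(u, un);
    if (step % save_every == 0 && slot < n_saved) save(slot++);
  }
  return out;
}
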