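#include <Rcpp.h>
using namespace Rcpp;

// One causal sweep of the swarm over the prey trajectory s.
// Member i updates
//   v_i[n] = v_i[n-1] + delta * (F_drive + F_coh)
//   p_i[n] = p_i[n-1] + delta * v_i[n]
// with F_drive = a*(s[n] - p_i[n-1]) - drag*v_i[n-1] (prey attraction plus
// finite agility) and F_coh = c*(mean_j p_j[n-1] - p_i[n-1]) minus a
// short-range repulsion active below rep_scale. Output is the swarm-mean
// position. Throws if any member position exceeds the divergence guard.
static std::vector<double> sweep(const std::vector<double>& s, int M,
                                 double delta, double a, double c,
                                 double drag, double rep_scale,
                                 double guard) {
  const int L = (int)s.size();
  std::vector<double> p(M), v(M, 0.0), y(L);
  const double eps = 1e-6 * std::max(1.0, std::fabs(s[0]));
  for (int i = 0; i < M; ++i)
    p[i] = (M == 1) ? s[0] : s[0] - eps + 2.0 * eps * i / (M - 1);
  double pm = 0.0;
  for (int i = 0; i < M; ++i) pm += p[i];
  pm /= M;
  y[0] = pm;
  std::vector<double> rep(M);
  const bool use_rep = rep_scale > 0.0;
  for (int n = 1; n < L; ++n) {
    if (use_rep) {
      for (int i = 0; i < M; ++i) {
        double r = 0.0;
        for (int j = 0; j < M; ++j) {
          if (j == i) continue;
          double d = p[i] - p[j];
          double ad = std::fabs(d);
          if (ad < rep_scale)
            r += (d >= 0 ? 1.0 : -1.0) * (rep_scale - ad) / rep_scale;
        }
        rep[i] = c * r / M;
      }
    }
    double pm_new = 0.0;
    for (int i = 0; i < M; ++i) {
      double F = a * (s[n] - p[i]) - drag * v[i] + c * (pm - p[i]);
      if (use_rep) F += rep[i];
      v[i] += delta * F;
      p[i] += delta * v[i];
      if (!std::isfinite(p[i]) || std::fabs(p[i]) > guard)
        throw std::range_error("swarm diverged (reduce delta)");
      pm_new += p[i];
    }
    pm = pm_new / M;
    y[n] = pm;
  }
  return y;
}

// [[Rcpp::export]]
NumericVector swarm_sweep_cpp(NumericVector s, int n_members, double delta,
                              double drive_gain, double cohesion_gain,
                              double drag, double repulsion_scale,
                              bool zero_phase) {
  std::vector<double> x(s.begin(), s.end());
  double mx = 0.0;
  for (double xi : x) mx = std::max(mx, std::fabs(xi));
  // absolute floor keeps the guard meaningful for silent inputs,
  // whose members still start on the +/- 1e-6 initial spread
  const double guard = 1e6 * std::max(mx, 1e-6);
  std::vector<double> y;
  try {
    y = sweep(x, n_members, delta, drive_gain, cohesion_gain, drag,
              repulsion_scale, guard);
    if (zero_phase) {
      std::reverse(y.begin(), y.end());
      y = sweep(y, n_members, delta, drive_gain, cohesion_gain, drag,
                repulsion_scale, guard);
      std::reverse(y.begin(), y.end());
    }
  } catch (std::range_error&) {
    stop("swarm diverged (reduce delta)");
  }
  return NumericVector(y.begin(), y.end());
}
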