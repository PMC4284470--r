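#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Channel kinds:
// 0 cleavage, 1 complex association, 2 complex dissociation,
// 3 final condensation, 4 lipid growth, 5 transport in, 6 transport out.
// Bimolecular propensities carry the 1/V mass-action scaling; buffered
// participants contribute ext_conc * V in place of a tracked count, so
// e.g. k * (c*V) * x / V = k * c * x. Geometry (V, A) is recomputed after
// every firing: the jump process stays exact because the volume changes
// only at discrete growth events.

static inline double inner_radius(double C, double delta, double rho) {
  double u = C / (M_PI * rho * delta * delta * delta) - 1.0 / 3.0;
  if (u < 1.0) u = 1.0; // clamp at zero inner radius (guarded upstream)
  return 0.5 * delta * (std::sqrt(u) - 1.0);
}

// [[Rcpp::export]]
List ssa_run_cpp(NumericVector counts0, double t0, double C0,
                 IntegerVector kind, NumericVector kk,
                 IntegerVector r1, IntegerVector r2,
                 IntegerVector eff_ptr, IntegerVector eff_sp,
                 IntegerVector eff_delta,
                 LogicalVector buffered, NumericVector ext_conc,
                 NumericVector k_cont,
                 double delta, double rho, double theta, int g,
                 double horizon, bool stop_at_division,
                 double max_events, int thin) {
  int n_sp = counts0.size();
  int n_ch = kind.size();
  std::vector<double> x(counts0.begin(), counts0.end());
  double t = t0, C = C0;
  double n_events = 0.0;
  long since_rec = 0;
  bool divided = false, truncated = false;

  std::vector<double> rec_t, rec_C, rec_V;
  std::vector<double> rec_x; // row-major n_sp per snapshot
  auto record = [&](double V) {
    rec_t.push_back(t); rec_C.push_back(C); rec_V.push_back(V);
    for (int i = 0; i < n_sp; ++i) rec_x.push_back(x[i]);
  };

  std::vector<double> a(n_ch);
  double V = 0.0, A = 0.0;
  {
    double r = inner_radius(C, delta, rho);
    V = 4.0 / 3.0 * M_PI * r * r * r;
    A = 4.0 * M_PI * r * r;
  }
  record(V);

  auto eff_count = [&](int i) {
    return buffered[i] ? ext_conc[i] * V : x[i];
  };

  while (true) {
    if (n_events >= max_events) { truncated = true; break; }
    // propensities
    double a0 = 0.0;
    for (int j = 0; j < n_ch; ++j) {
      double aj = 0.0;
      switch (kind[j]) {
      case 0: case 1: case 3: { // bimolecular
        int i1 = r1[j], i2 = r2[j];
        if (i1 == i2 && !buffered[i1]) {
          aj = kk[j] * x[i1] * (x[i1] - 1.0) / V;
        } else {
          aj = kk[j] * eff_count(i1) * eff_count(i2) / V;
        }
        break;
      }
      case 2: // unimolecular
        aj = kk[j] * eff_count(r1[j]);
        break;
      case 4: { // lipid growth, batched by g
        double s = 0.0;
        for (int i = 0; i < n_sp; ++i)
          if (k_cont[i] > 0.0) s += k_cont[i] * eff_count(i);
        aj = s / g;
        break;
      }
      case 5: // transport in: D * A * [M_out]
        aj = kk[j] * A * ext_conc[r1[j]];
        break;
      case 6: // transport out: D * A * x / V
        aj = kk[j] * A * x[r1[j]] / V;
        break;
      }
      if (aj < 0.0) aj = 0.0;
      a[j] = aj;
      a0 += aj;
    }
    if (a0 <= 0.0) { t = horizon; break; }
    double dt = exp_rand() / a0;
    if (t + dt >= horizon) { t = horizon; break; }
    t += dt;
    // channel selection
    double u = unif_rand() * a0, acc = 0.0;
    int j = n_ch - 1;
    for (int jj = 0; jj < n_ch; ++jj) {
      acc += a[jj];
      if (u <= acc) { j = jj; break; }
    }
    // apply effects (skipped on buffered slots: infinite bath)
    for (int e = eff_ptr[j]; e < eff_ptr[j + 1]; ++e) {
      int i = eff_sp[e];
      if (!buffered[i]) {
        x[i] += eff_delta[e];
        if (x[i] < -0.5) stop("negative species count: inconsistent state");
      }
    }
    n_events += 1.0;
    if (kind[j] == 4) {
      C += g;
      double r = inner_radius(C, delta, rho);
      V = 4.0 / 3.0 * M_PI * r * r * r;
      A = 4.0 * M_PI * r * r;
      if (stop_at_division && C >= theta) { divided = true; break; }
    }
    if (thin > 0 && ++since_rec >= thin) { record(V); since_rec = 0; }
  }
  record(V);

  int n_rec = rec_t.size();
  NumericMatrix traj(n_rec, 3 + n_sp);
  for (int r = 0; r < n_rec; ++r) {
    traj(r, 0) = rec_t[r];
    traj(r, 1) = rec_C[r];
    traj(r, 2) = rec_V[r];
    for (int i = 0; i < n_sp; ++i) traj(r, 3 + i) = rec_x[(size_t)r * n_sp + i];
  }
  return List::create(
    _["counts"] = NumericVector(x.begin(), x.end()),
    _["t"] = t, _["C"] = C,
    _["n_events"] = n_events,
    _["divided"] = divided,
    _["truncated"] = truncated,
    _["trajectory"] = traj
  );
}
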