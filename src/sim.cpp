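#include <Rcpp.h>
using namespace Rcpp;

// One MT ensemble at a fixed angular coordinate, stepped for n_steps.
//
// Scheme per step (must stay in lock-step with the R reference
// implementation in step_ensemble(), which draws runif(n) for switching and
// then, in bernoulli mode, runif(n) for coupling — so the uniforms here are
// drawn in two full passes, not interleaved):
//   1. phase switching: growing -> shrinking w.p. f_cat*dt,
//      shrinking -> growing w.p. f_res*dt
//   2. coupling indicator c: pr itself ("mean" mode) or Bernoulli(pr)
//   3. move: growing +(v_plus - c*vr)*dt, shrinking -(v_minus + c*vr)*dt
//   4. boundaries: r >= R -> clamp to R, forced catastrophe;
//      r <= 0 -> clamp to 0, shrinking tips switch to growing
//   5. p = fraction with r > cutoff (strict); vr = v0 / (1 + beta*p)
//
// vr entering step k is the value computed at the end of step k-1
// (instantaneous algebraic force balance, no relaxation dynamics).
// Uses R's RNG so set.seed() in R controls the stream.
// [[Rcpp::export(name = ".sim_angle_kernel")]]
List sim_angle_kernel(NumericVector r0, LogicalVector growing0, double vr0,
                      double R, double cutoff, double pr,
                      double v_plus, double v_minus,
                      double f_cat, double f_res,
                      double v0, double beta,
                      double dt, int n_steps, int record_stride,
                      bool bernoulli) {
  const int n = r0.size();
  std::vector<double> r(r0.begin(), r0.end());
  std::vector<int> grow(n);
  for (int i = 0; i < n; ++i) grow[i] = growing0[i] ? 1 : 0;
  std::vector<double> u(n), uc(bernoulli ? n : 0);

  double vr = vr0;
  const double p_cat = f_cat * dt, p_res = f_res * dt;

  const int n_rec = n_steps / record_stride + 1;
  NumericVector t_out(n_rec), p_out(n_rec), vr_out(n_rec);
  int k = 0;
  {
    int cnt = 0;
    for (int i = 0; i < n; ++i) if (r[i] > cutoff) ++cnt;
    t_out[k] = 0.0;
    p_out[k] = (double)cnt / n;
    vr_out[k] = vr;
    ++k;
  }

  for (int s = 1; s <= n_steps; ++s) {
    for (int i = 0; i < n; ++i) u[i] = unif_rand();
    if (bernoulli)
      for (int i = 0; i < n; ++i) uc[i] = unif_rand();

    int cnt = 0;
    for (int i = 0; i < n; ++i) {
      if (grow[i]) { if (u[i] < p_cat) grow[i] = 0; }
      else         { if (u[i] < p_res) grow[i] = 1; }

      double c = bernoulli ? (uc[i] < pr ? 1.0 : 0.0) : pr;
      if (grow[i]) r[i] += (v_plus - c * vr) * dt;
      else         r[i] -= (v_minus + c * vr) * dt;

      if (r[i] >= R) { r[i] = R; grow[i] = 0; }
      else if (r[i] <= 0.0) { r[i] = 0.0; if (!grow[i]) grow[i] = 1; }

      if (r[i] > cutoff) ++cnt;
    }
    double p = (double)cnt / n;
    vr = v0 / (1.0 + beta * p);

    if (s % record_stride == 0) {
      t_out[k] = s * dt;
      p_out[k] = p;
      vr_out[k] = vr;
      ++k;
    }
  }

  NumericVector r_fin(r.begin(), r.end());
  LogicalVector g_fin(n);
  for (int i = 0; i < n; ++i) g_fin[i] = grow[i] == 1;
  return List::create(_["t"] = t_out, _["p"] = p_out, _["vr"] = vr_out,
                      _["r"] = r_fin, _["growing"] = g_fin, _["vr_end"] = vr);
}
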