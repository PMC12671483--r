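#include <Rcpp.h>
using namespace Rcpp;

// Catch-slip double exponential: sum of a force-relieved (catch) and a
// force-accelerated (slip) pathway.
static inline double off_rate(double F, double kc, double Fc,
                              double ks, double Fs) {
  return kc * std::exp(-F / Fc) + ks * std::exp(F / Fs);
}

// Fixed-timestep Monte Carlo update of the clutch ensemble. Deterministic
// force update (motor force-velocity, series-spring loading) followed by
// stochastic transitions with exponential probabilities 1 - exp(-rate*dt),
// which stay bounded for arbitrarily large transient rates. Uses R's RNG so
// runs are reproducible under set.seed().
// [[Rcpp::export]]
List clutch_run_cpp(int n_steps, int record_every, double dt, double t_start,
                    int n_motors, double stall_force, double v0,
                    double k_clutch, double k_sub,
                    double k_on,
                    double koff_catch_rate, double koff_catch_force,
                    double koff_slip_rate, double koff_slip_force,
                    double kunfold_0, double kunfold_force, double kfold_0,
                    double d_int0, double d_add, double cap_factor,
                    NumericVector ext0, LogicalVector bound0,
                    LogicalVector unf0, double d_int_cur) {
  const int n = ext0.size();
  std::vector<double> ext(ext0.begin(), ext0.end());
  std::vector<int> bound(n), unf(n);
  for (int i = 0; i < n; ++i) { bound[i] = bound0[i]; unf[i] = unf0[i]; }

  const double keff = (k_clutch * k_sub) / (k_clutch + k_sub);
  const double d_max = cap_factor * d_int0;
  const double f_stall_tot = (double)n_motors * stall_force;
  double d_int = d_int_cur;
  double t = t_start;
  double v_actual = (n_motors > 0) ? v0 : 0.0;
  long cum_unfold = 0;

  const int n_rec = (record_every > 0) ? n_steps / record_every : 0;
  NumericVector rec_t(n_rec), rec_d(n_rec), rec_b(n_rec);
  std::vector<double> unfold_times;
  int rec_i = 0;

  for (int s = 1; s <= n_steps; ++s) {
    // (1) retrograde speed from linear motor force-velocity
    double f_tot = 0.0;
    for (int i = 0; i < n; ++i)
      if (bound[i]) f_tot += keff * ext[i];
    double v_frac = (f_stall_tot > 0.0)
                        ? std::max(0.0, 1.0 - f_tot / f_stall_tot)
                        : 0.0;
    v_actual = v0 * v_frac;

    // (2) bound clutches are loaded through the series spring
    for (int i = 0; i < n; ++i)
      if (bound[i]) ext[i] += v_actual * dt;

    // (3)-(5) stochastic transitions; refolding is evaluated on the talin
    // state entering this step so a domain cannot unfold and refold in one dt
    const double p_on = 1.0 - std::exp(-k_on * d_int * dt);
    const double p_fold = 1.0 - std::exp(-kfold_0 * dt);
    int unfolds = 0;
    for (int i = 0; i < n; ++i) {
      const int was_unfolded = unf[i];
      if (!bound[i]) {
        if (R::unif_rand() < p_on) { bound[i] = 1; ext[i] = 0.0; }
      } else {
        const double F = keff * ext[i];
        const double p_off = 1.0 - std::exp(
            -off_rate(F, koff_catch_rate, koff_catch_force,
                      koff_slip_rate, koff_slip_force) * dt);
        if (R::unif_rand() < p_off) {
          bound[i] = 0;
          ext[i] = 0.0;
        } else if (!unf[i] && kunfold_0 > 0.0) {
          const double p_unf = 1.0 - std::exp(
              -kunfold_0 * std::exp(F / kunfold_force) * dt);
          if (R::unif_rand() < p_unf) { unf[i] = 1; ++unfolds; }
        }
      }
      if (was_unfolded && R::unif_rand() < p_fold) unf[i] = 0;
    }

    // (6) every unfolding event reinforces the adhesion independently,
    // then the density is capped
    t = t_start + s * dt;
    if (unfolds > 0) {
      cum_unfold += unfolds;
      for (int k = 0; k < unfolds; ++k) unfold_times.push_back(t);
      d_int = std::min(d_int + unfolds * d_add, d_max);
    }

    if (record_every > 0 && s % record_every == 0) {
      rec_t[rec_i] = t;
      rec_d[rec_i] = d_int / d_int0;
      int nb = 0;
      for (int i = 0; i < n; ++i) nb += bound[i];
      rec_b[rec_i] = nb;
      ++rec_i;
    }
  }

  return List::create(
      _["time"] = t, _["extension"] = NumericVector(ext.begin(), ext.end()),
      _["bound"] = LogicalVector(bound.begin(), bound.end()),
      _["talin_unfolded"] = LogicalVector(unf.begin(), unf.end()),
      _["d_int_current"] = d_int, _["retrograde_speed"] = v_actual,
      _["cumulative_unfolding_events"] = (double)cum_unfold,
      _["rec_time"] = rec_t, _["rec_density"] = rec_d,
      _["rec_bound"] = rec_b,
      _["unfold_times"] = NumericVector(unfold_times.begin(),
                                        unfold_times.end()));
}

// 8- (or 4-) connected component labelling of a binary mask by flood fill.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, bool eight_connected) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next_label = 0;
  std::vector<std::pair<int, int> > stack;
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 1, 0, 0};
  const int dc4[4] = {0, 0, -1, 1};
  const int *dr = eight_connected ? dr8 : dr4;
  const int *dc = eight_connected ? dc8 : dc4;
  const int nd = eight_connected ? 8 : 4;

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      lab(r, c) = ++next_label;
      stack.clear();
      stack.push_back(std::make_pair(r, c));
      while (!stack.empty()) {
        std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int k = 0; k < nd; ++k) {
          const int rr = p.first + dr[k], cc = p.second + dc[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next_label;
            stack.push_back(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  return lab;
}
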