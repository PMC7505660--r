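#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Propensity kinds; must match the table in R/network.R.
// State layout: 0 m_tf, 1 m_target, 2 x, 3 r_free, 4 b_tf, 5 b_target,
//               6 b_decoy, 7 y.
static inline double channel_prop(int kind, double rate, const double* s,
                                  double n_decoy) {
  switch (kind) {
  case 1:  return rate;
  case 2:  return rate * (1.0 - s[4]);
  case 3:  return rate * (1.0 - s[5]);
  case 4:  return rate * s[0];
  case 5:  return rate * s[1];
  case 6:  return rate * s[2] * (s[2] - 1.0) * 0.5;
  case 7:  return rate * s[3];
  case 8:  return rate * s[3] * (1.0 - s[4]);
  case 9:  return rate * s[3] * (1.0 - s[5]);
  case 10: return rate * s[3] * (n_decoy - s[6]);
  case 11: return rate * s[4];
  case 12: return rate * s[5];
  case 13: return rate * s[6];
  case 14: return rate * s[2];
  case 15: return rate * s[7];
  default: return 0.0;
  }
}

// Gillespie direct method.  Snapshots are taken at fixed times
// burn_in + ts, burn_in + 2*ts, ..., <= t_end.  If the total propensity
// hits zero the state can never change again; the remaining snapshots are
// filled with the frozen state and a flag is raised.
// [[Rcpp::export]]
List ssa_run_cpp(IntegerMatrix stoich, NumericVector rate, IntegerVector kind,
                 double n_decoy, NumericVector init, double t_end,
                 double burn_in, double ts) {
  const int ns = 8;
  const int K = rate.size();
  if (stoich.nrow() != ns || stoich.ncol() != K)
    stop("stoich must be 8 x K");
  std::vector<double> s(init.begin(), init.end());
  const int n_rec = (int)std::floor((t_end - burn_in) / ts + 1e-9);
  if (n_rec < 1) stop("sampling plan yields no snapshots");
  NumericMatrix snaps(n_rec, ns);
  NumericVector times(n_rec);
  std::vector<double> a(K);
  std::vector<double> events(K, 0.0), prop_time(K, 0.0);
  double t = 0.0;
  int irec = 0;
  bool frozen = false;
  while (irec < n_rec) {
    double a0 = 0.0;
    for (int k = 0; k < K; ++k) {
      a[k] = channel_prop(kind[k], rate[k], s.data(), n_decoy);
      a0 += a[k];
    }
    if (a0 <= 0.0) {
      frozen = true;
      for (; irec < n_rec; ++irec) {
        times[irec] = burn_in + ts * (irec + 1);
        for (int j = 0; j < ns; ++j) snaps(irec, j) = s[j];
      }
      break;
    }
    double dt = R::exp_rand() / a0;
    if (t < burn_in) {  // time-averaged propensities over the burn-in
      double w = std::min(dt, burn_in - t);
      for (int k = 0; k < K; ++k) prop_time[k] += a[k] * w;
    }
    double next_rec = burn_in + ts * (irec + 1);
    while (irec < n_rec && t + dt >= next_rec) {
      times[irec] = next_rec;
      for (int j = 0; j < ns; ++j) snaps(irec, j) = s[j];
      ++irec;
      next_rec = burn_in + ts * (irec + 1);
    }
    t += dt;
    if (irec >= n_rec) break;
    double u = unif_rand() * a0, cum = 0.0;
    int kc = K - 1;
    for (int k = 0; k < K; ++k) {
      cum += a[k];
      if (u <= cum) { kc = k; break; }
    }
    if (t <= burn_in) events[kc] += 1.0;
    for (int j = 0; j < ns; ++j) s[j] += stoich(j, kc);
  }
  return List::create(
    _["time"] = times, _["state"] = snaps, _["frozen"] = frozen,
    _["events_burnin"] = NumericVector(events.begin(), events.end()),
    _["prop_time_burnin"] = NumericVector(prop_time.begin(), prop_time.end()));
}
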