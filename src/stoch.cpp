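#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Finite-population Moran-type simulator over genotype compartments.
//
// Events (genotype i, locus l, n = compartment counts, N = total):
//   birth  i -> i+1             rate B * f_i * n_i
//   death  i -> i-1             rate B * (N/N0) * n_i
//   mutation i -> j=i^(1<<l)    rate mu * n_i            (per neighbour)
//   recombination i -> i^(1<<l) rate (r/L) * n_i * A_l(opp)/N
// where A_l(opp) counts individuals whose allele at locus l is opposite to
// i's (the free-DNA pool mirrors population allele frequencies).
//
// Exact SSA, with optional tau-leaping for channels whose source compartment
// exceeds tau_threshold (Cao-style tau selection; leaps that would drive a
// count negative are re-drawn with halved tau).

struct Channel {
  int src;    // source compartment
  int dst;    // destination compartment (-1 = none)
  int dsrc;   // change to src (+1 birth, -1 otherwise)
};

// [[Rcpp::export]]
List sim_population_cpp(NumericVector f, int L, double B, double N0,
                        double mu, double r, double fix_threshold,
                        double t_max, NumericVector n_init, int peak,
                        double tau_threshold, double tau_eps,
                        NumericVector snapshot_times, bool stop_peak_loss) {
  const int n = f.size();
  const int nch_per = 2 + 2 * L;
  const int nch = n * nch_per;
  const double rho = (L > 0) ? r / L : 0.0;

  std::vector<double> cnt(n);
  for (int i = 0; i < n; ++i) cnt[i] = n_init[i];

  std::vector<double> rate(nch);
  std::vector<Channel> ch(nch);
  for (int i = 0; i < n; ++i) {
    int base = i * nch_per;
    ch[base]     = {i, -1, +1};                      // birth
    ch[base + 1] = {i, -1, -1};                      // death
    for (int l = 0; l < L; ++l) {
      int j = i ^ (1 << l);
      ch[base + 2 + l]     = {i, j, -1};             // mutation at locus l
      ch[base + 2 + L + l] = {i, j, -1};             // recombination at locus l
    }
  }

  const int nsnap = snapshot_times.size();
  NumericMatrix snaps(nsnap, n);
  int snap_idx = 0;

  double t = 0.0;
  bool fixed = false, extinct = false, peak_lost = false;
  double t_fix = NA_REAL;
  long long n_steps = 0;

  std::vector<double> A1(L);         // count of 1-alleles per locus
  std::vector<double> drift(n), diff2(n);

  auto record_until = [&](double t_new) {
    while (snap_idx < nsnap && snapshot_times[snap_idx] <= t_new) {
      for (int i = 0; i < n; ++i) snaps(snap_idx, i) = cnt[i];
      ++snap_idx;
    }
  };
  record_until(t);  // snapshots at (or before) time 0

  while (t < t_max && !fixed && !extinct) {
    double N = 0.0;
    for (int i = 0; i < n; ++i) N += cnt[i];
    if (N <= 0.0) { extinct = true; break; }

    for (int l = 0; l < L; ++l) {
      double a = 0.0;
      for (int i = 0; i < n; ++i) if (i & (1 << l)) a += cnt[i];
      A1[l] = a;
    }

    double R_tot = 0.0, R_small = 0.0;
    bool any_large = false;
    for (int i = 0; i < n; ++i) {
      int base = i * nch_per;
      double ni = cnt[i];
      if (ni <= 0.0) {
        for (int c = 0; c < nch_per; ++c) rate[base + c] = 0.0;
        continue;
      }
      rate[base]     = B * f[i] * ni;
      rate[base + 1] = B * (N / N0) * ni;
      for (int l = 0; l < L; ++l) {
        rate[base + 2 + l] = mu * ni;
        double A_opp = (i & (1 << l)) ? (N - A1[l]) : A1[l];
        rate[base + 2 + L + l] = rho * ni * A_opp / N;
      }
      bool large = ni > tau_threshold;
      if (large) any_large = true;
      for (int c = 0; c < nch_per; ++c) {
        double rc = rate[base + c];
        R_tot += rc;
        if (!large) R_small += rc;
      }
    }
    if (R_tot <= 0.0) break;  // frozen state (cannot happen while N > 0)

    bool do_ssa = !any_large;
    double tau_cand = R_PosInf;

    if (!do_ssa) {
      // Cao tau selection over compartments, leap channels only
      std::fill(drift.begin(), drift.end(), 0.0);
      std::fill(diff2.begin(), diff2.end(), 0.0);
      for (int c = 0; c < nch; ++c) {
        if (rate[c] <= 0.0 || cnt[ch[c].src] <= tau_threshold) continue;
        drift[ch[c].src] += ch[c].dsrc * rate[c];
        diff2[ch[c].src] += rate[c];
        if (ch[c].dst >= 0) {
          drift[ch[c].dst] += rate[c];
          diff2[ch[c].dst] += rate[c];
        }
      }
      for (int i = 0; i < n; ++i) {
        double bound = std::max(tau_eps * std::max(cnt[i], 1.0), 1.0);
        if (drift[i] != 0.0)
          tau_cand = std::min(tau_cand, bound / std::fabs(drift[i]));
        if (diff2[i] > 0.0)
          tau_cand = std::min(tau_cand, bound * bound / diff2[i]);
      }
      if (tau_cand < 10.0 / R_tot) do_ssa = true;  // leaping not worthwhile
    }

    if (do_ssa) {
      double dt = R::exp_rand() / R_tot;
      if (t + dt > t_max) { record_until(t_max); t = t_max; break; }
      record_until(t + dt);
      t += dt;
      double u = unif_rand() * R_tot;
      int c = 0;
      for (; c < nch - 1; ++c) { u -= rate[c]; if (u <= 0.0) break; }
      cnt[ch[c].src] += ch[c].dsrc;
      if (ch[c].dst >= 0) cnt[ch[c].dst] += 1.0;
    } else {
      double t_small = (R_small > 0.0) ? R::exp_rand() / R_small : R_PosInf;
      double tau = std::min(tau_cand, t_small);
      tau = std::min(tau, t_max - t);
      bool ok = false;
      std::vector<double> trial(n);
      for (int attempt = 0; attempt < 30 && !ok; ++attempt) {
        trial = cnt;
        for (int c = 0; c < nch; ++c) {
          if (rate[c] <= 0.0 || cnt[ch[c].src] <= tau_threshold) continue;
          double k = R::rpois(rate[c] * tau);
          if (k == 0.0) continue;
          trial[ch[c].src] += ch[c].dsrc * k;
          if (ch[c].dst >= 0) trial[ch[c].dst] += k;
        }
        bool neg = false;
        for (int i = 0; i < n; ++i) if (trial[i] < 0.0) { neg = true; break; }
        if (neg) tau *= 0.5; else ok = true;
      }
      if (!ok) {
        // fall back to one exact event over all channels
        double dt = R::exp_rand() / R_tot;
        if (t + dt > t_max) { record_until(t_max); t = t_max; break; }
        record_until(t + dt);
        t += dt;
        double u = unif_rand() * R_tot;
        int c = 0;
        for (; c < nch - 1; ++c) { u -= rate[c]; if (u <= 0.0) break; }
        cnt[ch[c].src] += ch[c].dsrc;
        if (ch[c].dst >= 0) cnt[ch[c].dst] += 1.0;
        ++n_steps;
        goto check;
      }
      record_until(t + tau);
      cnt = trial;
      t += tau;
      if (t_small <= tau && R_small > 0.0) {
        // one exact event among the small channels
        double u = unif_rand() * R_small;
        int pick = -1;
        for (int c = 0; c < nch; ++c) {
          if (rate[c] <= 0.0 || cnt[ch[c].src] > tau_threshold) continue;
          u -= rate[c];
          if (u <= 0.0) { pick = c; break; }
        }
        if (pick >= 0 && cnt[ch[pick].src] > 0.0) {
          cnt[ch[pick].src] += ch[pick].dsrc;
          if (ch[pick].dst >= 0) cnt[ch[pick].dst] += 1.0;
        }
      }
    }
    ++n_steps;

  check:
    {
      double N2 = 0.0;
      for (int i = 0; i < n; ++i) N2 += cnt[i];
      if (N2 <= 0.0) { extinct = true; break; }
      if (cnt[peak] / N2 > fix_threshold) { fixed = true; t_fix = t; }
      if (stop_peak_loss && cnt[peak] <= 0.0) { peak_lost = true; break; }
    }
    if (n_steps % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  record_until(R_PosInf);  // remaining snapshots hold the final state
  NumericVector final_counts(n);
  for (int i = 0; i < n; ++i) final_counts[i] = cnt[i];
  return List::create(_["fixed"] = fixed, _["extinct"] = extinct,
                      _["peak_lost"] = peak_lost,
                      _["t_fix"] = t_fix, _["t_end"] = t,
                      _["n_final"] = final_counts,
                      _["snapshots"] = snaps,
                      _["n_steps"] = (double)n_steps);
}
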