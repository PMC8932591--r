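#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Angles are wrapped to (-pi, pi], matching wrap_angle() on the R side.
static inline double wrap_angle_cpp(double a) {
  double w = a - 2.0 * M_PI * std::floor((a + M_PI) / (2.0 * M_PI));
  if (w <= -M_PI) w = M_PI;
  return w;
}

// gamma draw with given mean and CV, rejected below 10% of the mean
static inline double rgamma_truncated_cpp(double mean, double cv) {
  double shape = 1.0 / (cv * cv);
  double scale = mean / shape;
  for (;;) {
    double x = R::rgamma(shape, scale);
    if (x >= 0.1 * mean) return x;
  }
}

// Event-driven burst-and-coast school simulation.
//
// State per fish: position at kick onset, heading during the current kick,
// kick onset time, kick duration and length. The next event is always the
// earliest kick end (ties broken by lowest fish id). At an event the focal
// fish moves to its glide endpoint, perceives all other fish at their
// glide-interpolated positions (headings are their current kick headings),
// ranks them by influence |delta_phi_ij|, sums the contributions of the top
// k, adds Gaussian heading noise, and starts a newly sampled kick.
//
// RNG: all draws come from R's global stream (norm_rand / R::rgamma), so a
// single set.seed() upstream makes the run fully deterministic. Draw order
// per event: noise (skipped when gamma_r == 0), then kick length, then kick
// duration (both skipped in fixed mode).
// [[Rcpp::export]]
List cpp_run_school(NumericVector x0, NumericVector y0, NumericVector phi0,
                    NumericVector kick_start0, NumericVector kick_len0,
                    NumericVector kick_dur0,
                    double gamma_att, double gamma_ali,
                    double l_att, double l_ali,
                    double d_att, double d_ali, int k,
                    double gamma_r,
                    double mean_len, double mean_dur, double cv, bool sampled,
                    double tau0,
                    int n_events, double sampling_dt,
                    bool record_kicks, bool record_neighbors) {
  const int n = x0.size();
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> phi(phi0.begin(), phi0.end());
  std::vector<double> ks(kick_start0.begin(), kick_start0.end());
  std::vector<double> kl(kick_len0.begin(), kick_len0.end());
  std::vector<double> kd(kick_dur0.begin(), kick_dur0.end());
  std::vector<double> kend(n), cphi(n), sphi(n), denom(n), vpeak(n);
  std::vector<int> kick_count(n, 0);

  for (int i = 0; i < n; ++i) {
    kend[i] = ks[i] + kd[i];
    cphi[i] = std::cos(phi[i]);
    sphi[i] = std::sin(phi[i]);
    denom[i] = 1.0 - std::exp(-kd[i] / tau0);
    vpeak[i] = kl[i] / (tau0 * denom[i]);
  }

  // snapshot storage (row-major, one row per sampling instant)
  std::vector<double> snap_t;
  std::vector<double> snap_x, snap_y, snap_phi, snap_v;
  double next_snap = sampling_dt;

  // kick-event storage
  std::vector<double> ev_t, ev_x, ev_y, ev_phi_old, ev_phi_new,
                      ev_soc, ev_noise;
  std::vector<int> ev_fish, ev_nb1, ev_nb2;
  std::vector<double> ev_rx1, ev_ry1, ev_rx2, ev_ry2;
  if (record_kicks) {
    ev_t.reserve(n_events); ev_fish.reserve(n_events);
  }

  std::vector<double> dphi_j(n), infl_j(n);
  std::vector<int> selected(std::max(k, 1));

  const double inv_l_att2 = 1.0 / (l_att * l_att);
  const double inv_l_ali2 = 1.0 / (l_ali * l_ali);

  std::vector<int> batch; batch.reserve(n);
  std::vector<double> new_phi(n), new_len(n), new_dur(n), new_x(n), new_y(n);

  int ev = 0;
  while (ev < n_events) {
    // next event time: earliest kick end; all fish ending exactly then form
    // one batch evaluated against the common pre-update state (ids
    // ascending), so exactly simultaneous kicks perceive the same school
    int i0 = 0;
    for (int j = 1; j < n; ++j) if (kend[j] < kend[i0]) i0 = j;
    double t = kend[i0];
    batch.clear();
    for (int j = 0; j < n; ++j)
      if (kend[j] == t && ev + (int)batch.size() < n_events)
        batch.push_back(j);

    // emit snapshots strictly before this event time (and at it)
    while (next_snap <= t) {
      snap_t.push_back(next_snap);
      for (int j = 0; j < n; ++j) {
        double s = next_snap - ks[j];
        if (s < 0) s = 0;                      // before first kick onset
        double f = (1.0 - std::exp(-s / tau0)) / denom[j];
        snap_x.push_back(x[j] + kl[j] * f * cphi[j]);
        snap_y.push_back(y[j] + kl[j] * f * sphi[j]);
        snap_phi.push_back(phi[j]);
        snap_v.push_back(vpeak[j] * std::exp(-s / tau0));
      }
      next_snap += sampling_dt;
    }

    for (size_t bi = 0; bi < batch.size(); ++bi) {
    int i = batch[bi];
    // move focal fish to its glide endpoint
    double xi = x[i] + kl[i] * cphi[i];
    double yi = y[i] + kl[i] * sphi[i];

    // social turn: evaluate all neighbors at time t (pre-update state)
    double dphi_s = 0.0;
    int nsel = 0;
    if (n > 1 && (gamma_att > 0 || gamma_ali > 0)) {
      for (int j = 0; j < n; ++j) {
        if (j == i) { infl_j[j] = -1.0; dphi_j[j] = 0.0; continue; }
        double s = t - ks[j];
        if (s < 0) s = 0;
        if (s > kd[j]) s = kd[j];
        double f = (1.0 - std::exp(-s / tau0)) / denom[j];
        double xj = x[j] + kl[j] * f * cphi[j];
        double yj = y[j] + kl[j] * f * sphi[j];
        double dx = xj - xi, dy = yj - yi;
        double d = std::sqrt(dx * dx + dy * dy);
        double psi = (d == 0.0) ? 0.0
                     : wrap_angle_cpp(std::atan2(dy, dx) - phi[i]);
        double phir = wrap_angle_cpp(phi[j] - phi[i]);
        double fatt = gamma_att * (d / d_att - 1.0) / (1.0 + d * d * inv_l_att2);
        double oatt = 1.395 * std::sin(psi) * (1.0 - 0.33 * std::cos(psi));
        double eatt = 0.9326 * (1.0 - 0.48 * std::cos(phir)
                                 - 0.31 * std::cos(2.0 * phir));
        double fali = gamma_ali * (d / d_ali + 1.0)
                      * std::exp(-d * d * inv_l_ali2);
        double eali = 0.9012 * (1.0 + 0.6 * std::cos(psi)
                                 - 0.32 * std::cos(2.0 * psi));
        double oali = 1.6385 * std::sin(phir)
                      * (1.0 + 0.3 * std::cos(2.0 * phir));
        double dp = fatt * oatt * eatt + fali * eali * oali;
        dphi_j[j] = dp;
        infl_j[j] = std::fabs(dp);
      }
      // top-k by influence descending, lowest id first on ties
      int kk = std::min(k, n - 1);
      for (int r = 0; r < kk; ++r) {
        int best = -1;
        for (int j = 0; j < n; ++j) {
          if (j == i) continue;
          bool taken = false;
          for (int q = 0; q < r; ++q) if (selected[q] == j) { taken = true; break; }
          if (taken) continue;
          if (best < 0 || infl_j[j] > infl_j[best]) best = j;
        }
        selected[r] = best;
        dphi_s += dphi_j[best];
      }
      nsel = kk;
    }

    double dphi_r = (gamma_r > 0) ? gamma_r * norm_rand() : 0.0;
    double phi_old = phi[i];
    double phi_new = wrap_angle_cpp(phi_old + dphi_s + dphi_r);

    if (record_kicks) {
      ev_t.push_back(t); ev_fish.push_back(i + 1);
      ev_x.push_back(xi); ev_y.push_back(yi);
      ev_phi_old.push_back(phi_old); ev_phi_new.push_back(phi_new);
      ev_soc.push_back(dphi_s); ev_noise.push_back(dphi_r);
      if (record_neighbors) {
        // relative position of the top-2 selected neighbors in the focal
        // frame: focal at the origin, heading pointing north (+y)
        double rx[2] = {NA_REAL, NA_REAL}, ry[2] = {NA_REAL, NA_REAL};
        int id[2] = {NA_INTEGER, NA_INTEGER};
        for (int r = 0; r < std::min(nsel, 2); ++r) {
          int j = selected[r];
          double s = t - ks[j];
          if (s < 0) s = 0;
          if (s > kd[j]) s = kd[j];
          double f = (1.0 - std::exp(-s / tau0)) / denom[j];
          double dx = x[j] + kl[j] * f * cphi[j] - xi;
          double dy = y[j] + kl[j] * f * sphi[j] - yi;
          rx[r] = dx * sphi[i] - dy * cphi[i];
          ry[r] = dx * cphi[i] + dy * sphi[i];
          id[r] = j + 1;
        }
        ev_nb1.push_back(id[0]); ev_nb2.push_back(id[1]);
        ev_rx1.push_back(rx[0]); ev_ry1.push_back(ry[0]);
        ev_rx2.push_back(rx[1]); ev_ry2.push_back(ry[1]);
      }
    }

    // sample the next kick now (draw order: noise, length, duration per
    // fish, ids ascending within a batch) but defer the state update until
    // the whole batch is evaluated
    double nl, nd;
    if (sampled && cv > 0) {
      nl = rgamma_truncated_cpp(mean_len, cv);
      nd = rgamma_truncated_cpp(mean_dur, cv);
    } else {
      nl = mean_len; nd = mean_dur;
    }
    new_x[i] = xi; new_y[i] = yi; new_phi[i] = phi_new;
    new_len[i] = nl; new_dur[i] = nd;
    ++ev;
    }  // batch evaluation

    for (size_t bi = 0; bi < batch.size(); ++bi) {
      int i = batch[bi];
      x[i] = new_x[i]; y[i] = new_y[i]; phi[i] = new_phi[i];
      ks[i] = t; kl[i] = new_len[i]; kd[i] = new_dur[i];
      kend[i] = t + new_dur[i];
      cphi[i] = std::cos(phi[i]); sphi[i] = std::sin(phi[i]);
      denom[i] = 1.0 - std::exp(-kd[i] / tau0);
      vpeak[i] = kl[i] / (tau0 * denom[i]);
      kick_count[i] += 1;
    }
  }

  const int nt = snap_t.size();
  NumericMatrix sx(nt, n), sy(nt, n), sphi_m(nt, n), sv(nt, n);
  for (int r = 0; r < nt; ++r)
    for (int j = 0; j < n; ++j) {
      sx(r, j) = snap_x[(size_t)r * n + j];
      sy(r, j) = snap_y[(size_t)r * n + j];
      sphi_m(r, j) = snap_phi[(size_t)r * n + j];
      sv(r, j) = snap_v[(size_t)r * n + j];
    }

  List kicks = R_NilValue;
  if (record_kicks) {
    List cols = List::create(
      _["time"] = wrap(ev_t), _["fish_id"] = wrap(ev_fish),
      _["x"] = wrap(ev_x), _["y"] = wrap(ev_y),
      _["heading_old"] = wrap(ev_phi_old),
      _["heading_new"] = wrap(ev_phi_new),
      _["dphi_social"] = wrap(ev_soc), _["dphi_noise"] = wrap(ev_noise));
    if (record_neighbors) {
      cols["nb1"] = wrap(ev_nb1); cols["nb2"] = wrap(ev_nb2);
      cols["rel_x1"] = wrap(ev_rx1); cols["rel_y1"] = wrap(ev_ry1);
      cols["rel_x2"] = wrap(ev_rx2); cols["rel_y2"] = wrap(ev_ry2);
    }
    cols.attr("class") = "data.frame";
    cols.attr("row.names") = IntegerVector::create(NA_INTEGER, -(int)ev_t.size());
    kicks = cols;
  }

  return List::create(
    _["snap_times"] = wrap(snap_t),
    _["snap_x"] = sx, _["snap_y"] = sy,
    _["snap_heading"] = sphi_m, _["snap_speed"] = sv,
    _["kicks"] = kicks,
    _["kick_count"] = wrap(kick_count),
    _["final_x"] = wrap(x), _["final_y"] = wrap(y),
    _["final_heading"] = wrap(phi),
    _["final_kick_start"] = wrap(ks),
    _["final_kick_length"] = wrap(kl),
    _["final_kick_duration"] = wrap(kd));
}

// Most influential neighbor (k = 1 rule) of every fish in one snapshot.
// Returns 1-based neighbor indices; ties by lowest id. Used for the
// distinct-most-influential-neighbor (DMIN) diagnostic.
// [[Rcpp::export]]
IntegerVector cpp_most_influential(NumericVector x, NumericVector y,
                                   NumericVector phi,
                                   double gamma_att, double gamma_ali,
                                   double l_att, double l_ali,
                                   double d_att, double d_ali) {
  const int n = x.size();
  IntegerVector out(n);
  const double inv_l_att2 = 1.0 / (l_att * l_att);
  const double inv_l_ali2 = 1.0 / (l_ali * l_ali);
  for (int i = 0; i < n; ++i) {
    int best = -1; double best_inf = -1.0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = x[j] - x[i], dy = y[j] - y[i];
      double d = std::sqrt(dx * dx + dy * dy);
      double psi = (d == 0.0) ? 0.0 : wrap_angle_cpp(std::atan2(dy, dx) - phi[i]);
      double phir = wrap_angle_cpp(phi[j] - phi[i]);
      double fatt = gamma_att * (d / d_att - 1.0) / (1.0 + d * d * inv_l_att2);
      double oatt = 1.395 * std::sin(psi) * (1.0 - 0.33 * std::cos(psi));
      double eatt = 0.9326 * (1.0 - 0.48 * std::cos(phir)
                               - 0.31 * std::cos(2.0 * phir));
      double fali = gamma_ali * (d / d_ali + 1.0) * std::exp(-d * d * inv_l_ali2);
      double eali = 0.9012 * (1.0 + 0.6 * std::cos(psi)
                               - 0.32 * std::cos(2.0 * psi));
      double oali = 1.6385 * std::sin(phir) * (1.0 + 0.3 * std::cos(2.0 * phir));
      double inf = std::fabs(fatt * oatt * eatt + fali * eali * oali);
      if (inf > best_inf) { best_inf = inf; best = j; }
    }
    out[i] = best + 1;
  }
  return out;
}
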