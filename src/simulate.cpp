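#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Discrete-time integration of the cascaded system
//   dx = v dt + sigma dW            (decision stage)
//   dy = a (x_in - y)               (motor preparation; a = lambda*dt, or the
//                                    time-varying Kalman-Bucy gain when kb)
//   zL = max(-y - g, 0), zR = max(y - g, 0)
// with event extraction on the grid t_n = n*dt:
//   - the response is issued at the first grid point where zL or zR >= r;
//   - t_g is the last grid point with z = 0 before the final positive
//     excursion of the winning channel;
//   - earlier maximal positive excursions (either channel) of duration
//     >= min_burst_steps grid points are partial bursts, with onset reported
//     at the last zero point before the excursion.
// The per-step gain is capped at 1 so that very large lambda degrades
// gracefully into y tracking x with a one-step delay (the unfiltered limit).
// All noise comes from R's RNG so R-level and C++-level code share one
// seed stream; draws with zero scale consume no draws (R's rnorm/runif
// conventions).

struct Events {
  int hit_idx;       // grid index of threshold attainment, -1 if omitted
  int tg_idx;        // grid index of t_g (last zero before final excursion)
  int channel;       // +1 upper, -1 lower, 0 none
  std::vector<double> b_onset;
  std::vector<int>    b_channel;
  std::vector<double> b_dur;
};

static void sim_core(double v, double x0, double lambda, double xi,
                     double sigma, double g, double r, double dt,
                     int max_steps, int min_burst_steps, bool kb,
                     bool record, bool stop_at_hit,
                     std::vector<double>* xs, std::vector<double>* ys,
                     Events* ev)
{
  const double sqrt_dt = std::sqrt(dt);
  const double sd_x = sigma * sqrt_dt;       // same arithmetic as R's rnorm
  const double sd_obs = kb ? xi / sqrt_dt : 0.0;
  const double v_dt = v * dt;
  const bool filt = std::isfinite(lambda);
  const double a_const = filt ? std::min(lambda * dt, 1.0) : 0.0;
  double x = x0, y = x0;
  int cur_ch = 0, cur_start = -1;
  ev->hit_idx = -1; ev->tg_idx = -1; ev->channel = 0;

  if (record) { xs->push_back(x); ys->push_back(y); }

  // state at n = 0
  {
    double zR = y - g, zL = -y - g;
    int ch = (zR > 0.0) ? 1 : ((zL > 0.0) ? -1 : 0);
    if (ch != 0) { cur_ch = ch; cur_start = 0; }
    if (ch == 1 && zR >= r) { ev->hit_idx = 0; ev->tg_idx = 0; ev->channel = 1; if (stop_at_hit) return; }
    if (ch == -1 && zL >= r) { ev->hit_idx = 0; ev->tg_idx = 0; ev->channel = -1; if (stop_at_hit) return; }
  }

  for (int n = 1; n <= max_steps; ++n) {
    x += v_dt + (sd_x > 0.0 ? sd_x * norm_rand() : 0.0);
    if (!filt) {
      y = x;
    } else if (kb) {
      double xin = x + (sd_obs > 0.0 ? sd_obs * norm_rand() : 0.0);
      double a = lambda * std::tanh(lambda * (n - 1) * dt) * dt;
      if (a > 1.0) a = 1.0;
      y += a * (xin - y);
    } else {
      y += a_const * (x - y);
    }
    if (record) { xs->push_back(x); ys->push_back(y); }

    double zR = y - g, zL = -y - g;
    int ch = (zR > 0.0) ? 1 : ((zL > 0.0) ? -1 : 0);
    if (ch != cur_ch) {
      if (cur_ch != 0 && !(ev->hit_idx >= 0)) {
        int len = n - cur_start;                 // positive points cur_start..n-1
        if (len >= min_burst_steps) {
          int onset = cur_start - 1; if (onset < 0) onset = 0;
          ev->b_onset.push_back(onset * dt);
          ev->b_channel.push_back(cur_ch);
          ev->b_dur.push_back(len * dt);
        }
      }
      cur_ch = ch;
      cur_start = (ch != 0) ? n : -1;
    }
    if (ev->hit_idx < 0) {
      if ((ch == 1 && zR >= r) || (ch == -1 && zL >= r)) {
        ev->hit_idx = n;
        ev->channel = ch;
        int tg = cur_start - 1; if (tg < 0) tg = 0;
        ev->tg_idx = tg;
        if (stop_at_hit) return;
      }
    }
  }
}

static List events_to_list(const Events& ev, double dt) {
  return List::create(
    _["hit_idx"] = ev.hit_idx,
    _["tg_idx"] = ev.tg_idx,
    _["channel"] = ev.channel,
    _["hit_time"] = ev.hit_idx >= 0 ? ev.hit_idx * dt : NA_REAL,
    _["tg"] = ev.hit_idx >= 0 ? ev.tg_idx * dt : NA_REAL,
    _["burst_onset"] = NumericVector(ev.b_onset.begin(), ev.b_onset.end()),
    _["burst_channel"] = IntegerVector(ev.b_channel.begin(), ev.b_channel.end()),
    _["burst_dur"] = NumericVector(ev.b_dur.begin(), ev.b_dur.end()));
}

// [[Rcpp::export]]
List cpp_sim_events(double v, double x0, double lambda, double xi,
                    double sigma, double g, double r, double dt,
                    int max_steps, int min_burst_steps, bool kb)
{
  Events ev;
  sim_core(v, x0, lambda, xi, sigma, g, r, dt, max_steps, min_burst_steps,
           kb, false, true, nullptr, nullptr, &ev);
  return events_to_list(ev, dt);
}

// [[Rcpp::export]]
List cpp_integrate(double v, double x0, double lambda, double xi,
                   double sigma, double g, double r, double dt,
                   int max_steps, int min_burst_steps, bool kb,
                   bool stop_at_hit)
{
  Events ev;
  std::vector<double> xs, ys;
  xs.reserve(max_steps + 1); ys.reserve(max_steps + 1);
  sim_core(v, x0, lambda, xi, sigma, g, r, dt, max_steps, min_burst_steps,
           kb, true, stop_at_hit, &xs, &ys, &ev);
  List out = events_to_list(ev, dt);
  out["x"] = NumericVector(xs.begin(), xs.end());
  out["y"] = NumericVector(ys.begin(), ys.end());
  return out;
}

// Value of the filtered path at a fixed grid point, for Monte-Carlo
// checks of the closed-form mean trajectory (no thresholds, no events).
// [[Rcpp::export]]
double cpp_integrate_y_at(double v, double x0, double lambda, double sigma,
                          double dt, int n_steps)
{
  const double sqrt_dt = std::sqrt(dt);
  double x = x0, y = x0;
  double a = lambda * dt; if (a > 1.0) a = 1.0;
  for (int n = 1; n <= n_steps; ++n) {
    x += v * dt + R::rnorm(0.0, sigma * sqrt_dt);
    y += a * (x - y);
  }
  return y;
}

// Whole-dataset fast path: per trial, reseed R's RNG from its own seed
// (trial-level reproducibility and frozen per-trial-index noise streams),
// draw the realized parameters in the same order as sample_trial_params(),
// then integrate and extract events.
// [[Rcpp::export(rng = false)]]
List cpp_sim_dataset(IntegerVector seeds, double v_mean, double sv,
                     double x0, double sx0, double Te, double sTe,
                     double Tr, double sTr, double lambda, double slambda,
                     double xi, double sigma, double g, double r,
                     double dt, int max_steps, int min_burst_steps, bool kb)
{
  int n = seeds.size();
  Environment base = Environment::base_env();
  Function set_seed = base["set.seed"];

  IntegerVector response(n);        // +1 / -1 / NA
  NumericVector tg(n), hit(n), pmt(n), mt(n);
  IntegerVector n_bursts(n), fb_channel(n);
  NumericVector fb_latency(n);
  LogicalVector omitted(n);

  for (int i = 0; i < n; ++i) {
    set_seed(seeds[i]);
    GetRNGstate();
    double vt  = R::rnorm(v_mean, sv);
    double x0t = R::runif(x0 - sx0 / 2.0, x0 + sx0 / 2.0);
    double tet = R::runif(Te - sTe / 2.0, Te + sTe / 2.0);
    double trt = R::runif(Tr - sTr / 2.0, Tr + sTr / 2.0);
    double lt  = std::isfinite(lambda)
      ? R::runif(lambda - slambda / 2.0, lambda + slambda / 2.0)
      : R_PosInf;
    Events ev;
    sim_core(vt, x0t, lt, xi, sigma, g, r, dt, max_steps, min_burst_steps,
             kb, false, true, nullptr, nullptr, &ev);
    PutRNGstate();

    if (ev.hit_idx < 0) {
      omitted[i] = true;
      response[i] = NA_INTEGER;
      tg[i] = NA_REAL; hit[i] = NA_REAL; pmt[i] = NA_REAL; mt[i] = NA_REAL;
      n_bursts[i] = NA_INTEGER; fb_channel[i] = NA_INTEGER;
      fb_latency[i] = NA_REAL;
    } else {
      omitted[i] = false;
      response[i] = ev.channel;
      tg[i] = ev.tg_idx * dt;
      hit[i] = ev.hit_idx * dt;
      pmt[i] = tet + tg[i];
      mt[i] = (hit[i] - tg[i]) + trt;
      int nb = (int) ev.b_onset.size();
      n_bursts[i] = nb;
      if (nb > 0) {
        fb_channel[i] = ev.b_channel[0];
        fb_latency[i] = tet + ev.b_onset[0];
      } else {
        fb_channel[i] = NA_INTEGER;
        fb_latency[i] = NA_REAL;
      }
    }
  }
  return List::create(
    _["response"] = response, _["tg"] = tg, _["hit"] = hit,
    _["pmt"] = pmt, _["mt"] = mt, _["n_bursts"] = n_bursts,
    _["first_burst_channel"] = fb_channel,
    _["first_burst_latency"] = fb_latency,
    _["omitted"] = omitted);
}
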