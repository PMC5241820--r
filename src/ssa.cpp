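// Exact stochastic simulation (Gillespie) of the one- and two-population
// birth-death chains, plus the triplet-sampling microscopic construction.
// All randomness is drawn from R's RNG so set.seed() governs replication.

#include <Rcpp.h>
using namespace Rcpp;

// Draw an exponential waiting time with total rate rtot.
static inline double wait_time(double rtot) { return exp_rand() / rtot; }

// [[Rcpp::export]]
List ssa_1d_cpp(NumericVector Tplus, NumericVector Tminus, int n0,
                double t_max, double max_events, bool record_path) {
  const int N = Tplus.size() - 1;
  if (n0 < 0 || n0 > N) stop("initial state outside the lattice");
  int n = n0;
  double t = 0.0;
  double events = 0.0;
  bool absorbed = (n == 0 || n == N);
  bool censored = false;
  std::vector<double> times;
  std::vector<int> states;
  if (record_path) { times.push_back(0.0); states.push_back(n); }

  while (!absorbed) {
    const double rp = Tplus[n], rm = Tminus[n];
    const double rtot = rp + rm;
    if (rtot <= 0.0) { absorbed = true; break; }
    const double dt = wait_time(rtot);
    if (t + dt > t_max) { censored = true; t = t_max; break; }
    t += dt;
    n += (unif_rand() * rtot < rp) ? 1 : -1;
    events += 1.0;
    if (record_path) { times.push_back(t); states.push_back(n); }
    if (n == 0 || n == N) { absorbed = true; break; }
    if (events >= max_events) { censored = true; break; }
  }
  List out = List::create(
    _["absorbed"] = absorbed && !censored,
    _["censored"] = censored,
    _["state"] = n,
    _["time"] = t,
    _["events"] = events);
  if (record_path) {
    out["times"] = NumericVector(times.begin(), times.end());
    out["states"] = IntegerVector(states.begin(), states.end());
  }
  return out;
}

// Simulate while recording the state at prescribed sample times (the state
// holding just before each sample instant). Runs until absorption or the
// final sample time.
// [[Rcpp::export]]
List ssa_1d_sampled_cpp(NumericVector Tplus, NumericVector Tminus, int n0,
                        NumericVector sample_times, double max_events) {
  const int N = Tplus.size() - 1;
  if (n0 < 0 || n0 > N) stop("initial state outside the lattice");
  const int S = sample_times.size();
  IntegerVector samples(S, NA_INTEGER);
  int n = n0, si = 0;
  double t = 0.0, events = 0.0;
  bool absorbed = (n == 0 || n == N), censored = false;

  while (si < S) {
    double rtot = 0.0, rp = 0.0;
    if (!absorbed) { rp = Tplus[n]; rtot = rp + Tminus[n]; }
    double dt = (absorbed || rtot <= 0.0) ? R_PosInf : wait_time(rtot);
    while (si < S && t + dt > sample_times[si]) samples[si++] = n;
    if (si >= S) break;
    if (absorbed || rtot <= 0.0) break;
    t += dt;
    n += (unif_rand() * rtot < rp) ? 1 : -1;
    events += 1.0;
    if (n == 0 || n == N) absorbed = true;
    if (events >= max_events) { censored = true; break; }
  }
  // absorbed before the remaining sample times: state stays put
  while (si < S) samples[si++] = n;
  return List::create(_["samples"] = samples, _["absorbed"] = absorbed,
                      _["censored"] = censored, _["state"] = n,
                      _["time"] = t, _["events"] = events);
}

// [[Rcpp::export]]
List ssa_2d_cpp(NumericMatrix TAp, NumericMatrix TAm, NumericMatrix TBp,
                NumericMatrix TBm, int n0, int m0, double t_max,
                double max_events, bool record_path) {
  const int N = TAp.nrow() - 1;
  if (n0 < 0 || n0 > N || m0 < 0 || m0 > N)
    stop("initial state outside the lattice");
  int n = n0, m = m0;
  double t = 0.0, events = 0.0;
  bool censored = false;
  std::vector<double> times;
  std::vector<int> ns, ms;
  if (record_path) { times.push_back(0.0); ns.push_back(n); ms.push_back(m); }

  for (;;) {
    const double r1 = TAp(n, m), r2 = TAm(n, m), r3 = TBp(n, m),
                 r4 = TBm(n, m);
    const double rtot = r1 + r2 + r3 + r4;
    if (rtot <= 0.0) break;  // absorbing corner
    const double dt = wait_time(rtot);
    if (t + dt > t_max) { censored = true; t = t_max; break; }
    t += dt;
    const double u = unif_rand() * rtot;
    if (u < r1) ++n;
    else if (u < r1 + r2) --n;
    else if (u < r1 + r2 + r3) ++m;
    else --m;
    events += 1.0;
    if (record_path) { times.push_back(t); ns.push_back(n); ms.push_back(m); }
    if (events >= max_events) { censored = true; break; }
  }
  const bool absorbed = !censored;
  List out = List::create(
    _["absorbed"] = absorbed, _["censored"] = censored,
    _["state"] = IntegerVector::create(n, m),
    _["time"] = t, _["events"] = events);
  if (record_path) {
    out["times"] = NumericVector(times.begin(), times.end());
    out["n"] = IntegerVector(ns.begin(), ns.end());
    out["m"] = IntegerVector(ms.begin(), ms.end());
  }
  return out;
}

// [[Rcpp::export]]
List ssa_2d_sampled_cpp(NumericMatrix TAp, NumericMatrix TAm,
                        NumericMatrix TBp, NumericMatrix TBm, int n0, int m0,
                        NumericVector sample_times, double max_events) {
  const int N = TAp.nrow() - 1;
  if (n0 < 0 || n0 > N || m0 < 0 || m0 > N)
    stop("initial state outside the lattice");
  const int S = sample_times.size();
  IntegerVector sn(S, NA_INTEGER), sm(S, NA_INTEGER);
  int n = n0, m = m0, si = 0;
  double t = 0.0, events = 0.0;
  bool censored = false, absorbed = false;

  while (si < S) {
    const double r1 = TAp(n, m), r2 = TAm(n, m), r3 = TBp(n, m),
                 r4 = TBm(n, m);
    const double rtot = r1 + r2 + r3 + r4;
    absorbed = (rtot <= 0.0);
    const double dt = absorbed ? R_PosInf : wait_time(rtot);
    while (si < S && t + dt > sample_times[si]) { sn[si] = n; sm[si] = m; ++si; }
    if (si >= S || absorbed) break;
    t += dt;
    const double u = unif_rand() * rtot;
    if (u < r1) ++n;
    else if (u < r1 + r2) --n;
    else if (u < r1 + r2 + r3) ++m;
    else --m;
    events += 1.0;
    if (events >= max_events) { censored = true; break; }
  }
  while (si < S) { sn[si] = n; sm[si] = m; ++si; }
  return List::create(_["n"] = sn, _["m"] = sm, _["absorbed"] = absorbed,
                      _["censored"] = censored,
                      _["state"] = IntegerVector::create(n, m),
                      _["time"] = t, _["events"] = events);
}

// Microscopic triplet-sampling construction (payoff-based fitness only):
// per event an ordered triplet (primary, secondary, adversary) is drawn
// with replacement; primary and secondary both play the adversary and the
// secondary is replaced by the primary's type with probability
// g(a[i1, ia], a[i2, ia]) = [1 + Gamma (a[i1,ia] - a[i2,ia])]/2.
// Returns per-state attempt and up/down transition counts.
// [[Rcpp::export]]
List triplet_sim_cpp(NumericMatrix a, int N, double Gamma, int n0,
                     double n_events, bool restart) {
  if (n0 < 0 || n0 > N) stop("initial state outside the lattice");
  NumericVector attempts(N + 1), ups(N + 1), downs(N + 1);
  int n = n0;
  for (double e = 0.0; e < n_events; e += 1.0) {
    if (n == 0 || n == N) {       // absorbed: composition frozen
      if (!restart) break;
      n = n0;                     // fresh independent pass
    }
    const double x = static_cast<double>(n) / N;
    const int i1 = (unif_rand() < x) ? 0 : 1;  // primary (0 = type 1)
    const int i2 = (unif_rand() < x) ? 0 : 1;  // secondary
    const int ia = (unif_rand() < x) ? 0 : 1;  // adversary
    attempts[n] += 1.0;
    const double g = 0.5 * (1.0 + Gamma * (a(i1, ia) - a(i2, ia)));
    if (unif_rand() < g && i1 != i2) {
      if (i1 == 0) { ups[n] += 1.0; ++n; }
      else { downs[n] += 1.0; --n; }
    }
  }
  return List::create(_["attempts"] = attempts, _["ups"] = ups,
                      _["downs"] = downs, _["state"] = n);
}
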