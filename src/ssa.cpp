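#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Density factor g(N/K) for integer population sizes.
// kind: 1 = logistic, 2 = gompertz, 3 = richards.
// Gompertz is only evaluated at n >= 1 in the stochastic process (a birth
// requires at least one parent), where g = log(K/n) <= log(K).
static inline double dens_factor(int kind, double beta, double n, double K) {
  if (n >= K) return 0.0;
  if (n <= 0.0) return (kind == 2) ? std::log(K) : 1.0;
  double x = n / K;
  switch (kind) {
  case 1:  return 1.0 - x;
  case 2:  return (n < 1.0) ? std::log(K) : std::log(K / n);
  default: return 1.0 - std::pow(x, beta);
  }
}

// Zero-truncated normal phase duration by rejection (exact; acceptance >= 1/2
// because mean_tau > 0). sigma == 0 is the deterministic case.
static inline double draw_duration(double tau, double sigma) {
  if (sigma <= 0.0) return tau;
  for (;;) {
    double d = tau + sigma * norm_rand();
    if (d > 0.0) return d;
  }
}

// Pick a lineage index proportional to current lineage sizes.
static inline int pick_lineage(const std::vector<int>& count, int total) {
  double u = unif_rand() * total;
  double acc = 0.0;
  for (size_t i = 0; i < count.size(); ++i) {
    acc += count[i];
    if (u < acc) return (int)i;
  }
  return (int)count.size() - 1;  // numerical guard
}

// One exact realization of the two-genotype density-regulated birth-death
// process in the alternating harsh/favourable environment (harsh first).
// Absorbs at total extinction or when the mutant count reaches
// rescue_threshold. Uses R's RNG (seed it from R).
// [[Rcpp::export]]
List ssa_realization_cpp(double b_WF, double b_WH, double d_W,
                         double b_M, double d_M, double mu,
                         double K, int growth_kind, double growth_beta,
                         double tau, double sigma,
                         int init_wt, int init_mut,
                         int rescue_threshold, double max_events,
                         bool record_traj, double t_max) {
  RNGScope scope;
  int NW = init_wt, NM = init_mut;
  std::vector<int> lin_count;
  std::vector<double> lin_time;
  if (init_mut > 0) { lin_count.push_back(init_mut); lin_time.push_back(0.0); }

  bool harsh = true;
  double t = 0.0;
  double t_switch = draw_duration(tau, sigma);
  int qF = 0, n_mut_events = 0;
  double n_events = 0.0;

  std::vector<double> tr_t, tr_W, tr_M;
  std::vector<int> tr_ph;
  if (record_traj) {
    tr_t.push_back(0.0); tr_W.push_back(NW); tr_M.push_back(NM); tr_ph.push_back(1);
  }

  int fate = -1;           // 0 = extinct, 1 = rescued, 2 = censored at t_max
  double T0 = NA_REAL, rescue_time = NA_REAL, first_success = NA_REAL;
  int extinct_harsh = NA_INTEGER;

  while (true) {
    if (t >= t_max) { fate = 2; t = t_max; break; }
    if (NW + NM <= 0) {
      fate = 0; T0 = t; extinct_harsh = harsh ? 1 : 0;
      break;
    }
    if (NM >= rescue_threshold) {
      fate = 1; rescue_time = t;
      double oldest = R_PosInf;
      for (size_t i = 0; i < lin_count.size(); ++i)
        if (lin_count[i] > 0 && lin_time[i] < oldest) oldest = lin_time[i];
      first_success = oldest;
      break;
    }
    double bW = harsh ? b_WH : b_WF;
    double g  = dens_factor(growth_kind, growth_beta, (double)(NW + NM), K);
    double r_wb = NW * bW * g;
    double r_wd = NW * d_W;
    double r_mb = NM * b_M * g;
    double r_md = NM * d_M;
    double total = r_wb + r_wd + r_mb + r_md;

    if (total <= 0.0) {       // frozen state: jump to the next switch
      if (t_switch >= t_max) { fate = 2; t = t_max; break; }
      t = t_switch;
      if (!harsh) ++qF;
      harsh = !harsh;
      t_switch += draw_duration(tau, sigma);
      continue;
    }
    double dt = exp_rand() / total;
    if (t + dt >= t_max && t_switch >= t_max) { fate = 2; t = t_max; break; }
    if (t + dt >= t_switch) { // cap the step at the environmental switch
      t = t_switch;
      if (!harsh) ++qF;
      harsh = !harsh;
      t_switch += draw_duration(tau, sigma);
      if (record_traj) {
        tr_t.push_back(t); tr_W.push_back(NW); tr_M.push_back(NM);
        tr_ph.push_back(harsh ? 1 : 0);
      }
      continue;
    }
    t += dt;
    if (++n_events > max_events)
      stop("no absorption reached within max_events; check parameterization");
    double u = unif_rand() * total;
    if (u < r_wb) {
      if (mu > 0.0 && unif_rand() < mu) {
        ++NM; ++n_mut_events;
        lin_count.push_back(1); lin_time.push_back(t);
      } else {
        ++NW;
      }
    } else if (u < r_wb + r_wd) {
      --NW;
    } else if (u < r_wb + r_wd + r_mb) {
      if (NM > 0 && !lin_count.empty()) ++lin_count[pick_lineage(lin_count, NM)];
      ++NM;
    } else {
      if (NM > 0 && !lin_count.empty()) --lin_count[pick_lineage(lin_count, NM)];
      --NM;
    }
    if (record_traj) {
      tr_t.push_back(t); tr_W.push_back(NW); tr_M.push_back(NM);
      tr_ph.push_back(harsh ? 1 : 0);
    }
  }

  CharacterVector ext_phase(1);
  if (fate == 0) ext_phase[0] = (extinct_harsh == 1) ? "H" : "F";
  else ext_phase[0] = NA_STRING;
  std::string fate_str = (fate == 1) ? "rescued" : (fate == 0 ? "extinct" : "censored");
  List out = List::create(
    _["fate"] = fate_str,
    _["T0"] = T0,
    _["rescue_time"] = rescue_time,
    _["q_F"] = qF,
    _["extinct_phase"] = ext_phase,
    _["first_success_mutant_time"] = first_success,
    _["n_mutation_events"] = n_mut_events,
    _["n_events"] = n_events,
    _["N_W_final"] = NW,
    _["N_M_final"] = NM);
  if (record_traj) {
    out["trajectory"] = DataFrame::create(
      _["t"] = tr_t, _["N_W"] = tr_W, _["N_M"] = tr_M, _["harsh"] = tr_ph);
  }
  return out;
}

// First passage of the wild-type-only chain in a constant favourable
// environment: does the population hit 0 before first reaching `upper`?
// [[Rcpp::export]]
List ssa_first_passage_cpp(double b, double d, double K,
                           int growth_kind, double growth_beta,
                           int n0, int upper, double max_events) {
  RNGScope scope;
  int N = n0;
  double t = 0.0, n_events = 0.0;
  while (N > 0 && N < upper) {
    double g = dens_factor(growth_kind, growth_beta, (double)N, K);
    double rb = N * b * g, rd = N * d;
    double total = rb + rd;
    if (total <= 0.0) stop("frozen state in first-passage simulation");
    t += exp_rand() / total;
    if (++n_events > max_events) stop("max_events exceeded");
    if (unif_rand() * total < rb) ++N; else --N;
  }
  return List::create(_["hit_zero"] = (N <= 0), _["time"] = t);
}

// Single mutant lineage in the deterministic periodic wild-type background
// (linear birth-death with 2*tau-periodic birth rate b_M * g(<N_W>(t)/K)),
// simulated exactly by thinning. The background is passed as a uniform grid
// of <N_W> values over one full cycle [0, 2*tau]. Absorbs at 0 (loss) or at
// `threshold` copies (establishment).
// [[Rcpp::export]]
List ssa_lineage_cpp(double b_M, double d_M, double K,
                     int growth_kind, double growth_beta,
                     double tau, double t0,
                     NumericVector bg_N, int threshold, double max_events) {
  RNGScope scope;
  int m = bg_N.size();            // grid over [0, 2*tau], uniform
  double period = 2.0 * tau;
  double h = period / (m - 1);
  double g_max = 0.0;
  std::vector<double> beta_grid(m);
  for (int i = 0; i < m; ++i) {
    beta_grid[i] = b_M * dens_factor(growth_kind, growth_beta, bg_N[i], K);
    if (beta_grid[i] > g_max) g_max = beta_grid[i];
  }
  auto beta_at = [&](double time) {
    double s = time - period * std::floor(time / period);
    if (s < 0) s += period;
    double idx = s / h;
    int i0 = (int)idx;
    if (i0 >= m - 1) return beta_grid[m - 1];
    double w = idx - i0;
    return (1.0 - w) * beta_grid[i0] + w * beta_grid[i0 + 1];
  };

  int n = 1;
  double t = t0, n_events = 0.0;
  while (n > 0 && n < threshold) {
    double lam_bar = n * (g_max + d_M);
    t += exp_rand() / lam_bar;
    if (++n_events > max_events) stop("max_events exceeded");
    double rb = n * beta_at(t), rd = n * d_M;
    double u = unif_rand() * lam_bar;
    if (u < rb) ++n;
    else if (u < rb + rd) --n;
    // else: thinned (phantom) event
  }
  return List::create(_["established"] = (n >= threshold), _["time"] = t);
}
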