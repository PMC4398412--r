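#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Repertoires are bitmasks over the three languages: 1 = E, 2 = A, 4 = C.
// Agents 0..n_eu-1 are Europeans (implicit, fixed {E}); the repertoire
// vector holds the n_m Mulattos followed by the n_b Bozals.

static inline int rep_size(int m) { return (m & 1) + ((m >> 1) & 1) + ((m >> 2) & 1); }

static inline int pick_language(int mask) {
  int k = rep_size(mask);
  int idx = (int)(unif_rand() * k);
  if (idx >= k) idx = k - 1;
  for (int b = 0; b < 3; ++b) {
    int l = 1 << b;
    if (mask & l) {
      if (idx == 0) return l;
      --idx;
    }
  }
  return 1; /* unreachable */
}

struct Engine {
  int n_eu, n_m, n_b, N, nmb;
  std::vector<int> rep;
  double gamma, delta, epsilon;
  bool creolize_only_on_change, eps_null_advances_time;
  // language weights over M+B agents: each agent contributes 1/|rep| per
  // language held, so wE + wA + wC == nmb at all times
  double wE, wA, wC;
  int cnt_only_e;   // agents whose repertoire is exactly {E}
  long long creolizations;

  void init(int neu, IntegerVector rm, IntegerVector rb, double g, double d,
            double e, bool strict, bool eps_adv) {
    n_eu = neu; n_m = rm.size(); n_b = rb.size();
    nmb = n_m + n_b; N = n_eu + nmb;
    gamma = g; delta = d; epsilon = e;
    creolize_only_on_change = strict; eps_null_advances_time = eps_adv;
    rep.resize(nmb);
    for (int i = 0; i < n_m; ++i) rep[i] = rm[i];
    for (int i = 0; i < n_b; ++i) rep[n_m + i] = rb[i];
    wE = wA = wC = 0.0; cnt_only_e = 0; creolizations = 0;
    for (int i = 0; i < nmb; ++i) {
      int m = rep[i];
      if (m <= 0 || m > 7) stop("invalid repertoire mask");
      double inv = 1.0 / rep_size(m);
      if (m & 1) wE += inv;
      if (m & 2) wA += inv;
      if (m & 4) wC += inv;
      if (m == 1) ++cnt_only_e;
    }
  }

  void set_rep(int idx, int newm) {
    int old = rep[idx];
    if (old == newm) return;
    double invo = 1.0 / rep_size(old), invn = 1.0 / rep_size(newm);
    if (old & 1) wE -= invo;
    if (old & 2) wA -= invo;
    if (old & 4) wC -= invo;
    if (newm & 1) wE += invn;
    if (newm & 2) wA += invn;
    if (newm & 4) wC += invn;
    if (old == 1) --cnt_only_e;
    if (newm == 1) ++cnt_only_e;
    rep[idx] = newm;
  }

  // One counted time step (Eu-Eu draws are discarded without counting; an
  // epsilon-rejected Eu-B draw is a counted null step by default, or is
  // redrawn when eps_null_advances_time is false).
  void step() {
    int sp, hr;
    for (;;) {
      int i = (int)(unif_rand() * N); if (i >= N) i = N - 1;
      int j = (int)(unif_rand() * (N - 1)); if (j >= N - 1) j = N - 2;
      if (j >= i) ++j;
      if (i < n_eu && j < n_eu) continue;            // two Europeans: redraw
      if (i < n_eu)      { sp = i; hr = j; }         // Europeans only speak
      else if (j < n_eu) { sp = j; hr = i; }
      else if (unif_rand() < 0.5) { sp = i; hr = j; }
      else               { sp = j; hr = i; }
      if (sp < n_eu && hr >= n_eu + n_m) {           // Eu speaker, B hearer
        if (unif_rand() >= epsilon) {
          if (eps_null_advances_time) return;        // null step
          continue;                                  // rate-reweighting variant
        }
      }
      break;
    }
    bool sp_eu = sp < n_eu;
    int s = sp_eu ? 1 : rep[sp - n_eu];
    int hi = hr - n_eu;
    int h = rep[hi];
    int l = sp_eu ? 1 : pick_language(s);
    int h_new = h, s_new = s;
    if (!(h & l)) {
      h_new = h | l;                                 // learning
    } else {
      bool success = (l != 2) || (unif_rand() < delta);
      if (success) { h_new = l; s_new = l; }         // collapse to utterance
    }
    if ((h_new & 3) == 3 && (!creolize_only_on_change || h_new != h)) {
      if (unif_rand() < gamma) { h_new = 4; ++creolizations; }
    }
    set_rep(hi, h_new);
    if (!sp_eu && s_new != s) set_rep(sp - n_eu, s_new);
  }
};

// [[Rcpp::export]]
List ng_run_cpp(int n_eu, IntegerVector rep_m, IntegerVector rep_b,
                double gamma, double delta, double epsilon,
                double max_inter_per_agent, double tail_window_fraction,
                bool creolize_only_on_change, bool eps_null_advances_time,
                int n_trajectory_points) {
  Engine eng;
  eng.init(n_eu, rep_m, rep_b, gamma, delta, epsilon,
           creolize_only_on_change, eps_null_advances_time);
  if (eng.nmb < 1) stop("need at least one Mulatto or Bozal agent");

  long long T = (long long)(max_inter_per_agent * eng.nmb + 0.5);
  if (T < 1) T = 1;
  long long tail_len = (long long)(tail_window_fraction * T);
  if (tail_len < 1) tail_len = 1;
  long long tail_start = T - tail_len;  // accumulate for t > tail_start

  long long rec_every = 0;
  std::vector<double> traj_t, traj_e, traj_a, traj_c;
  if (n_trajectory_points > 0) {
    rec_every = T / n_trajectory_points;
    if (rec_every < 1) rec_every = 1;
  }

  double accE = 0, accA = 0, accC = 0;
  long long n_acc = 0, t = 0;
  bool absorbed = false;
  double inv_nmb = 1.0 / eng.nmb;

  while (t < T) {
    eng.step();
    ++t;
    if (t > tail_start) {
      accE += eng.wE * inv_nmb;
      accA += eng.wA * inv_nmb;
      accC += eng.wC * inv_nmb;
      ++n_acc;
    }
    if (rec_every > 0 && (t % rec_every == 0)) {
      traj_t.push_back((double)t);
      traj_e.push_back(eng.wE * inv_nmb);
      traj_a.push_back(eng.wA * inv_nmb);
      traj_c.push_back(eng.wC * inv_nmb);
    }
    if (eng.cnt_only_e == eng.nmb) {  // all-E: absorbing, fractions frozen
      absorbed = true;
      long long rest = T - std::max(t, tail_start);
      if (rest > 0) { accE += (double)rest; n_acc += rest; }
      break;
    }
    if ((t & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  IntegerVector out_m(eng.n_m), out_b(eng.n_b);
  for (int i = 0; i < eng.n_m; ++i) out_m[i] = eng.rep[i];
  for (int i = 0; i < eng.n_b; ++i) out_b[i] = eng.rep[eng.n_m + i];

  List res = List::create(
      _["rep_m"] = out_m, _["rep_b"] = out_b,
      _["f_E"] = accE / n_acc, _["f_A"] = accA / n_acc, _["f_C"] = accC / n_acc,
      _["absorbed_all_E"] = absorbed,
      _["interactions"] = (double)t,
      _["creolizations"] = (double)eng.creolizations);
  if (rec_every > 0)
    res["trajectory"] = DataFrame::create(
        _["interaction"] = traj_t, _["f_E"] = traj_e,
        _["f_A"] = traj_a, _["f_C"] = traj_c);
  return res;
}

// Draw n_samples independent single counted steps from the same starting
// configuration; each row holds the resulting M+B repertoire masks.
// [[Rcpp::export]]
IntegerMatrix ng_one_step_sample_cpp(int n_eu, IntegerVector rep_m,
                                     IntegerVector rep_b, double gamma,
                                     double delta, double epsilon,
                                     bool creolize_only_on_change,
                                     bool eps_null_advances_time,
                                     int n_samples) {
  Engine eng;
  eng.init(n_eu, rep_m, rep_b, gamma, delta, epsilon,
           creolize_only_on_change, eps_null_advances_time);
  std::vector<int> start = eng.rep;
  IntegerMatrix out(n_samples, eng.nmb);
  for (int r = 0; r < n_samples; ++r) {
    for (int i = 0; i < eng.nmb; ++i) eng.set_rep(i, start[i]);
    eng.step();
    for (int i = 0; i < eng.nmb; ++i) out(r, i) = eng.rep[i];
  }
  return out;
}
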