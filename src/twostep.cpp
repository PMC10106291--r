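#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Two-step task core: per-trial likelihood, generative simulation and
// reward sweeps for the hybrid model-based/model-free chooser with either
// an incremental (ISTL) or a counting ("Typical") transition learner.
//
// Parameter vector layout (columns), shared by both learners:
//   0 gamma   transition learning rate (ignored by the counting learner)
//   1 alpha   value learning rate; chosen-action values decay by 1 - alpha
//   2 decay   unchosen-action value decay D (toward 0)
//   3 b_mb    model-based weight
//   4 b_mf    model-free weight
//   5 b_2     second-stage inverse temperature
//   6 stick   first-stage choice perseveration
//
// Actions and states are 1-based in R, 0-based here. The true transition
// structure is T1: action 1 -> state 1 with p_common, action 2 -> state 2
// with p_common.

namespace {

struct TwoStepAgent {
  int model;            // 0 = ISTL, 1 = Typical counting
  bool decay_unchosen;  // ISTL: decay untaken action's belief toward 0.5
  double gamma, alpha, D, bmb, bmf, b2, stick;
  double P[2][2];       // belief P(s | a)
  double C[2][2];       // transition counts C[a][s]
  double Q2[2][2];      // second-stage values Q2[s][a]
  double Qmf[2];        // first-stage model-free values
  int prev;             // previous first-stage action, -1 on first trial

  void init(const double* par, int model_, bool decay_unchosen_) {
    model = model_;
    decay_unchosen = decay_unchosen_;
    gamma = par[0]; alpha = par[1]; D = par[2];
    bmb = par[3]; bmf = par[4]; b2 = par[5]; stick = par[6];
    for (int a = 0; a < 2; ++a)
      for (int s = 0; s < 2; ++s) {
        P[a][s] = 0.5; C[a][s] = 0.0; Q2[s][a] = 0.0;
      }
    Qmf[0] = Qmf[1] = 0.0;
    prev = -1;
  }

  // current transition estimate (belief or inferred candidate matrix)
  void trans(double T[2][2]) const {
    if (model == 0) {
      std::memcpy(T, P, sizeof(P));
    } else {
      double diag = C[0][0] + C[1][1], off = C[0][1] + C[1][0];
      double p = diag > off ? 0.7 : (diag < off ? 0.3 : 0.5);
      T[0][0] = p; T[0][1] = 1.0 - p;
      T[1][0] = 1.0 - p; T[1][1] = p;
    }
  }

  // first-stage net values (pre-softmax)
  void stage1_values(double v[2]) const {
    double T[2][2];
    trans(T);
    double vmax[2];
    for (int s = 0; s < 2; ++s) vmax[s] = std::max(Q2[s][0], Q2[s][1]);
    for (int a = 0; a < 2; ++a) {
      double qmb = T[a][0] * vmax[0] + T[a][1] * vmax[1];
      v[a] = bmb * qmb + bmf * Qmf[a] + (a == prev ? stick : 0.0);
    }
  }

  void update(int a1, int s2, int a2, double r) {
    if (model == 0) {
      P[a1][s2] += gamma * (1.0 - P[a1][s2]);
      P[a1][1 - s2] = 1.0 - P[a1][s2];
      if (decay_unchosen) {
        int u = 1 - a1;
        P[u][0] += gamma * (0.5 - P[u][0]);
        P[u][1] = 1.0 - P[u][0];
      }
    } else {
      C[a1][s2] += 1.0;
    }
    // model-free values: chosen updated toward reward (TD with lambda = 1
    // at stage 1), every unchosen value decays toward 0 by factor (1 - D)
    Qmf[a1] = (1.0 - alpha) * Qmf[a1] + alpha * r;
    Qmf[1 - a1] *= (1.0 - D);
    Q2[s2][a2] = (1.0 - alpha) * Q2[s2][a2] + alpha * r;
    Q2[s2][1 - a2] *= (1.0 - D);
    Q2[1 - s2][0] *= (1.0 - D);
    Q2[1 - s2][1] *= (1.0 - D);
    prev = a1;
  }
};

inline double log_softmax_choice(const double v[2], int chosen) {
  double m = std::max(v[0], v[1]);
  double z = std::exp(v[0] - m) + std::exp(v[1] - m);
  return v[chosen] - m - std::log(z);
}

inline int softmax_draw(const double v[2]) {
  double m = std::max(v[0], v[1]);
  double e0 = std::exp(v[0] - m), e1 = std::exp(v[1] - m);
  return (unif_rand() < e0 / (e0 + e1)) ? 0 : 1;
}

inline double reflect(double x, double lo, double hi) {
  while (x < lo || x > hi) {
    if (x < lo) x = 2.0 * lo - x;
    if (x > hi) x = 2.0 * hi - x;
  }
  return x;
}

// one generative session; fills the log arrays when keep is true and
// returns total reward
double run_twostep(TwoStepAgent& ag, int n_trials, double p_common,
                   double drift_sd, double lo, double hi,
                   int* a1v, int* s2v, int* a2v, double* rv, bool keep) {
  double pr[2][2];  // reward probability per state x action
  for (int s = 0; s < 2; ++s)
    for (int a = 0; a < 2; ++a) pr[s][a] = lo + unif_rand() * (hi - lo);
  double total = 0.0;
  for (int t = 0; t < n_trials; ++t) {
    double v[2];
    ag.stage1_values(v);
    int a1 = softmax_draw(v);
    int s2 = (unif_rand() < p_common) ? a1 : 1 - a1;
    double v2[2] = {ag.b2 * ag.Q2[s2][0], ag.b2 * ag.Q2[s2][1]};
    int a2 = softmax_draw(v2);
    double r = (unif_rand() < pr[s2][a2]) ? 1.0 : 0.0;
    total += r;
    ag.update(a1, s2, a2, r);
    if (keep) { a1v[t] = a1 + 1; s2v[t] = s2 + 1; a2v[t] = a2 + 1; rv[t] = r; }
    if (drift_sd > 0.0)
      for (int s = 0; s < 2; ++s)
        for (int a = 0; a < 2; ++a)
          pr[s][a] = reflect(pr[s][a] + norm_rand() * drift_sd, lo, hi);
  }
  return total;
}

}  // namespace

// [[Rcpp::export]]
NumericVector loglik_twostep_cpp(int model, NumericMatrix params,
                                 IntegerVector a1, IntegerVector s2,
                                 IntegerVector a2, NumericVector r,
                                 bool decay_unchosen = true) {
  const int K = params.nrow(), n = a1.size();
  if (params.ncol() != 7) stop("params must have 7 columns");
  NumericVector out(K);
  TwoStepAgent ag;
  double par[7];
  for (int k = 0; k < K; ++k) {
    for (int j = 0; j < 7; ++j) par[j] = params(k, j);
    ag.init(par, model, decay_unchosen);
    double ll = 0.0;
    for (int t = 0; t < n; ++t) {
      int ca = a1[t] - 1, cs = s2[t] - 1, ca2 = a2[t] - 1;
      double v[2];
      ag.stage1_values(v);
      ll += log_softmax_choice(v, ca);
      double v2[2] = {ag.b2 * ag.Q2[cs][0], ag.b2 * ag.Q2[cs][1]};
      ll += log_softmax_choice(v2, ca2);
      ag.update(ca, cs, ca2, r[t]);
    }
    out[k] = ll;
  }
  return out;
}

// [[Rcpp::export]]
List simulate_twostep_cpp(int model, NumericVector params, int n_trials,
                          double p_common, double drift_sd,
                          double lo, double hi, bool decay_unchosen = true) {
  if (params.size() != 7) stop("params must have length 7");
  RNGScope scope;
  TwoStepAgent ag;
  ag.init(params.begin(), model, decay_unchosen);
  IntegerVector a1(n_trials), s2(n_trials), a2(n_trials);
  NumericVector r(n_trials);
  double total = run_twostep(ag, n_trials, p_common, drift_sd, lo, hi,
                             a1.begin(), s2.begin(), a2.begin(), r.begin(),
                             true);
  return List::create(_["action1"] = a1, _["state2"] = s2,
                      _["action2"] = a2, _["reward"] = r,
                      _["total_reward"] = total);
}

// [[Rcpp::export]]
NumericVector sweep_twostep_cpp(NumericVector gammas, NumericVector base,
                                int n_reps, int n_trials, double p_common,
                                double drift_sd, double lo, double hi,
                                int model = 0, bool decay_unchosen = true) {
  if (base.size() != 7) stop("base params must have length 7");
  RNGScope scope;
  NumericVector out(gammas.size());
  TwoStepAgent ag;
  double par[7];
  for (int g = 0; g < gammas.size(); ++g) {
    for (int j = 0; j < 7; ++j) par[j] = base[j];
    par[0] = gammas[g];
    double acc = 0.0;
    for (int rep = 0; rep < n_reps; ++rep) {
      ag.init(par, model, decay_unchosen);
      acc += run_twostep(ag, n_trials, p_common, drift_sd, lo, hi,
                         nullptr, nullptr, nullptr, nullptr, false);
    }
    out[g] = acc / n_reps;
    Rcpp::checkUserInterrupt();
  }
  return out;
}
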