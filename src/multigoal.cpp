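#include <Rcpp.h>
using namespace Rcpp;

// Multi-goal pursuit task: two actions, a reward state and a punishment
// state reached independently with drifting probabilities. The integrated
// agent combines four strategies (model-based, goal-perseveration,
// model-free, action-perseveration) in a weighted-sum softmax.
//
// Parameter vector layout (columns):
//   0 gamma     transition learning rate
//   1 b_mbr     model-based reward weight
//   2 b_mbp     model-based punishment weight
//   3 b_gpr     goal-perseveration reward weight
//   4 b_gpp     goal-perseveration punishment weight
//   5 b_mf      model-free weight
//   6 b_ap      action-perseveration weight
//   7 alpha_mf  model-free learning rate
//
// Goals are 1 = seek reward, 2 = avoid punishment. On a seek-reward trial
// the instructed-goal vector is (1, 0); on avoid-punishment it is (0, -1);
// goal perseveration always uses (1, -1). Reaching a state the instructions
// did not mention carries no points.

namespace {

struct MultiGoalAgent {
  double gamma, bmbr, bmbp, bgpr, bgpp, bmf, bap, amf;
  bool decay_unchosen;
  double Pr[2], Pp[2];  // beliefs P(reward state | a), P(punish state | a)
  double Qmf[2];
  int prev;

  void init(const double* par, bool decay_unchosen_) {
    gamma = par[0]; bmbr = par[1]; bmbp = par[2]; bgpr = par[3];
    bgpp = par[4]; bmf = par[5]; bap = par[6]; amf = par[7];
    decay_unchosen = decay_unchosen_;
    Pr[0] = Pr[1] = Pp[0] = Pp[1] = 0.5;
    Qmf[0] = Qmf[1] = 0.0;
    prev = -1;
  }

  void values(int goal, double v[2]) const {
    for (int a = 0; a < 2; ++a) {
      double qmbr = (goal == 1) ? Pr[a] : 0.0;   // goal vector (1,0)
      double qmbp = (goal == 2) ? -Pp[a] : 0.0;  // goal vector (0,-1)
      double qgpr = Pr[a];                       // fixed goal vector (1,-1)
      double qgpp = -Pp[a];
      v[a] = bmbr * qmbr + bmbp * qmbp + bgpr * qgpr + bgpp * qgpp +
             bmf * Qmf[a] + (a == prev ? bap : 0.0);
    }
  }

  void update(int a, int reach_r, int reach_p, double points) {
    Pr[a] += gamma * (reach_r - Pr[a]);
    Pp[a] += gamma * (reach_p - Pp[a]);
    if (decay_unchosen) {
      int u = 1 - a;
      Pr[u] += gamma * (0.5 - Pr[u]);
      Pp[u] += gamma * (0.5 - Pp[u]);
    }
    Qmf[a] += amf * (points - Qmf[a]);
    prev = a;
  }
};

inline double log_softmax_choice2(const double v[2], int chosen) {
  double m = std::max(v[0], v[1]);
  double z = std::exp(v[0] - m) + std::exp(v[1] - m);
  return v[chosen] - m - std::log(z);
}

inline int softmax_draw2(const double v[2]) {
  double m = std::max(v[0], v[1]);
  double e0 = std::exp(v[0] - m), e1 = std::exp(v[1] - m);
  return (unif_rand() < e0 / (e0 + e1)) ? 0 : 1;
}

inline double reflect2(double x, double lo, double hi) {
  while (x < lo || x > hi) {
    if (x < lo) x = 2.0 * lo - x;
    if (x > hi) x = 2.0 * hi - x;
  }
  return x;
}

inline double score(int goal, int reach_r, int reach_p) {
  if (goal == 1 && reach_r) return 1.0;
  if (goal == 2 && reach_p) return -1.0;
  return 0.0;
}

double run_multigoal(MultiGoalAgent& ag, const int* goals, int n_trials,
                     double drift_sd, double lo, double hi,
                     int* av, int* rrv, int* rpv, double* pv, bool keep) {
  double P[2][2];  // true P(state | a): column 0 reward, 1 punish
  for (int a = 0; a < 2; ++a)
    for (int s = 0; s < 2; ++s) P[a][s] = lo + unif_rand() * (hi - lo);
  double total = 0.0;
  for (int t = 0; t < n_trials; ++t) {
    int goal = goals[t];
    double v[2];
    ag.values(goal, v);
    int a = softmax_draw2(v);
    int rr = unif_rand() < P[a][0] ? 1 : 0;
    int rp = unif_rand() < P[a][1] ? 1 : 0;
    double pts = score(goal, rr, rp);
    total += pts;
    ag.update(a, rr, rp, pts);
    if (keep) { av[t] = a + 1; rrv[t] = rr; rpv[t] = rp; pv[t] = pts; }
    if (drift_sd > 0.0)
      for (int ai = 0; ai < 2; ++ai)
        for (int s = 0; s < 2; ++s)
          P[ai][s] = reflect2(P[ai][s] + norm_rand() * drift_sd, lo, hi);
  }
  return total;
}

// balanced goal sequence (half seek-reward, half avoid-punishment) in
// random order via Fisher-Yates on R's RNG
void balanced_goals(int* g, int n) {
  for (int i = 0; i < n; ++i) g[i] = (i < (n + 1) / 2) ? 1 : 2;
  for (int i = n - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(g[i], g[j]);
  }
}

}  // namespace

// [[Rcpp::export]]
NumericVector loglik_multigoal_cpp(NumericMatrix params, IntegerVector action,
                                   IntegerVector reached_reward,
                                   IntegerVector reached_punish,
                                   NumericVector points, IntegerVector goal,
                                   bool decay_unchosen = true) {
  const int K = params.nrow(), n = action.size();
  if (params.ncol() != 8) stop("params must have 8 columns");
  NumericVector out(K);
  MultiGoalAgent ag;
  double par[8];
  for (int k = 0; k < K; ++k) {
    for (int j = 0; j < 8; ++j) par[j] = params(k, j);
    ag.init(par, decay_unchosen);
    double ll = 0.0;
    for (int t = 0; t < n; ++t) {
      int a = action[t] - 1;
      double v[2];
      ag.values(goal[t], v);
      ll += log_softmax_choice2(v, a);
      ag.update(a, reached_reward[t], reached_punish[t], points[t]);
    }
    out[k] = ll;
  }
  return out;
}

// [[Rcpp::export]]
List simulate_multigoal_cpp(NumericVector params, IntegerVector goals,
                            double drift_sd, double lo, double hi,
                            bool decay_unchosen = true) {
  if (params.size() != 8) stop("params must have length 8");
  RNGScope scope;
  const int n = goals.size();
  MultiGoalAgent ag;
  ag.init(params.begin(), decay_unchosen);
  IntegerVector a(n), rr(n), rp(n);
  NumericVector pts(n);
  double total = run_multigoal(ag, goals.begin(), n, drift_sd, lo, hi,
                               a.begin(), rr.begin(), rp.begin(),
                               pts.begin(), true);
  return List::create(_["action"] = a, _["reached_reward"] = rr,
                      _["reached_punish"] = rp, _["points"] = pts,
                      _["total_points"] = total);
}

// [[Rcpp::export]]
NumericVector sweep_multigoal_cpp(NumericVector gammas, NumericVector base,
                                  int n_reps, int n_trials, double drift_sd,
                                  double lo, double hi,
                                  bool decay_unchosen = true) {
  if (base.size() != 8) stop("base params must have length 8");
  RNGScope scope;
  NumericVector out(gammas.size());
  std::vector<int> goals(n_trials);
  MultiGoalAgent ag;
  double par[8];
  for (int g = 0; g < gammas.size(); ++g) {
    for (int j = 0; j < 8; ++j) par[j] = base[j];
    par[0] = gammas[g];
    double acc = 0.0;
    for (int rep = 0; rep < n_reps; ++rep) {
      balanced_goals(goals.data(), n_trials);
      ag.init(par, decay_unchosen);
      acc += run_multigoal(ag, goals.data(), n_trials, drift_sd, lo, hi,
                           nullptr, nullptr, nullptr, nullptr, false);
    }
    out[g] = acc / n_reps;
    Rcpp::checkUserInterrupt();
  }
  return out;
}
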