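#include <Rcpp.h>
using namespace Rcpp;

// Rescorla-Wagner / softmax sequence likelihood.
//
// choice:  0 = left, 1 = right
// outcome: +1 = reward, -1 = punishment
// session: session index per trial (values reset at a session boundary
//          only when carry_over is false)
//
// Q starts at (0, 0). On every trial the choice probability is the softmax
// of the current values; the chosen action's value is then updated by
// eps * (R_t - Q(a_chosen)), with R_t = beta_rew for reward and -beta_pun
// for punishment. PE_t = R_t - Q_{t-1}(a_chosen).
// [[Rcpp::export]]
List rw_loglik_cpp(IntegerVector choice, IntegerVector outcome,
                   IntegerVector session, double eps, double beta_rew,
                   double beta_pun, bool carry_over) {
  int n = choice.size();
  NumericVector q_left(n), q_right(n), r_eff(n), pe(n), logp(n);
  double q0 = 0.0, q1 = 0.0;
  double ll = 0.0;
  int cur_session = n > 0 ? session[0] : 0;

  for (int t = 0; t < n; ++t) {
    if (!carry_over && session[t] != cur_session) {
      q0 = 0.0;
      q1 = 0.0;
    }
    cur_session = session[t];
    q_left[t] = q0;
    q_right[t] = q1;

    // softmax with max-subtraction for numerical stability
    double m = q0 > q1 ? q0 : q1;
    double e0 = std::exp(q0 - m), e1 = std::exp(q1 - m);
    double z = e0 + e1;
    double p_chosen = (choice[t] == 0 ? e0 : e1) / z;
    logp[t] = std::log(p_chosen);
    ll += logp[t];

    double r = outcome[t] > 0 ? beta_rew : -beta_pun;
    r_eff[t] = r;
    double qc = choice[t] == 0 ? q0 : q1;
    pe[t] = r - qc;
    if (choice[t] == 0)
      q0 += eps * pe[t];
    else
      q1 += eps * pe[t];
  }

  return List::create(_["loglik"] = ll, _["q_left"] = q_left,
                      _["q_right"] = q_right, _["r_eff"] = r_eff,
                      _["pe"] = pe, _["logp"] = logp);
}
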