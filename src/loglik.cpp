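#include <Rcpp.h>
using namespace Rcpp;

// Trial-wise choice log-likelihood of the hybrid model-based/model-free
// learner over a flattened cohort.  All index vectors are 1-based (0 marks a
// missed/absent entry).  `reset` flags the first trial of each session
// (agent state re-initialized).  `oidx`/`aidx` select, per trial, which
// column of the subject's omega/alpha matrix applies (parameter tying
// resolved by the caller).  `tmap` is the flattened 2x2 transition map:
// tmap[(state-1)*2 + (choice-1)] = creature (1/2).
//
// Missed trials (choice == 0) contribute 0 to the log-likelihood, freeze
// the agent state and leave the previous response unchanged.
//
// [[Rcpp::export]]
NumericVector cpp_hybrid_loglik(IntegerVector subj, IntegerVector reset,
                                IntegerVector state, IntegerVector choice,
                                IntegerVector resp, IntegerVector creature,
                                NumericVector reward, IntegerVector key_a,
                                IntegerVector oidx, IntegerVector aidx,
                                IntegerVector tmap,
                                NumericMatrix omega, NumericMatrix alpha,
                                NumericVector lam, NumericVector pik,
                                NumericVector beta, double q0,
                                bool pointwise) {
  const int n = subj.size();
  const int S = omega.nrow();
  NumericVector out(pointwise ? n : S);

  double qmf[2][2];
  double q2[2];
  int prev = 0;

  for (int t = 0; t < n; ++t) {
    const int s = subj[t] - 1;
    if (s < 0 || s >= S) stop("subject index out of range");
    if (reset[t] == 1) {
      qmf[0][0] = qmf[0][1] = qmf[1][0] = qmf[1][1] = q0;
      q2[0] = q2[1] = q0;
      prev = 0;
    }
    if (choice[t] == 0) continue;  // missed trial

    const int st = state[t] - 1;
    const int ch = choice[t] - 1;
    const int cr = creature[t] - 1;
    const double om = omega(s, oidx[t] - 1);
    const double al = alpha(s, aidx[t] - 1);
    const double r = reward[t];
    if (r < 0.0 || r > 9.0) stop("reward outside [0, 9] at trial %d", t + 1);

    // hybrid values of dwellings a and b in this state
    const int cra = tmap[st * 2 + 0] - 1;
    const int crb = tmap[st * 2 + 1] - 1;
    double va = om * q2[cra] + (1.0 - om) * qmf[st][0];
    double vb = om * q2[crb] + (1.0 - om) * qmf[st][1];

    // stickiness on the response key; key of dwelling a is key_a[t]
    if (prev != 0) {
      if (key_a[t] == prev) va += pik[s];
      else vb += pik[s];
    }

    const double za = beta[s] * va, zb = beta[s] * vb;
    const double m = za > zb ? za : zb;
    const double lse = m + std::log(std::exp(za - m) + std::exp(zb - m));
    const double ll = (ch == 0 ? za : zb) - lse;
    if (pointwise) out[t] = ll; else out[s] += ll;

    // SARSA(lambda)-style update with the observed choice and outcome
    const double d1 = q2[cr] - qmf[st][ch];
    qmf[st][ch] += al * d1;
    const double d2 = r - q2[cr];
    q2[cr] += al * d2;
    qmf[st][ch] += al * lam[s] * d2;

    prev = (ch == 0) ? key_a[t] : 3 - key_a[t];
  }
  return out;
}
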