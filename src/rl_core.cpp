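#include <Rcpp.h>
using namespace Rcpp;

// Forward pass of the feature-value RL model family over a trial sequence.
//
// chosen:      n x 3 integer matrix, chosen feature value (1/2) per dimension
//              (color, location, motion); the nonchosen stimulus always
//              carries the complementary features.
// reward:      0/1 outcomes.
// new_session: TRUE where a new session starts (state reset); never reset at
//              block boundaries because reversals are uncued to the model.
// params:      (eta, beta, phi, omega); unused parameters are ignored
//              (phi) or fixed (omega = 1 for non-decay variants).
// variant:     1 = F-NS, 2 = F-S, 3 = F-DW, 4 = F-Dec, 5 = F-DW-Dec.
// v0:          initial and decay-target feature value.
//
// Returns per-trial value of the chosen stimulus, RPE = R - V, and the
// softmax probability of the observed choice. Must stay numerically
// identical to the pure-R rl_forward_r() reference.
// [[Rcpp::export]]
List rl_forward_cpp(IntegerMatrix chosen, NumericVector reward,
                    LogicalVector new_session, NumericVector params,
                    int variant, double v0) {
  const int n = chosen.nrow();
  const double eta = params[0], beta = params[1];
  const double phi = params[2], omega = params[3];
  const bool weighted = (variant == 3 || variant == 5);
  const bool decay = (variant == 4 || variant == 5);

  double V[2][3];
  double w[3];
  NumericVector v_chosen(n), rpe(n), p_choice(n);

  for (int t = 0; t < n; ++t) {
    if (t == 0 || new_session[t]) {
      for (int d = 0; d < 3; ++d) {
        V[0][d] = v0;
        V[1][d] = v0;
        w[d] = 1.0 / 3.0;
      }
    }
    int ch[3];
    for (int d = 0; d < 3; ++d) ch[d] = chosen(t, d) - 1;

    double v_ch, v_ot;
    if (variant == 2) {  // F-S: color only
      v_ch = V[ch[0]][0];
      v_ot = V[1 - ch[0]][0];
    } else if (weighted) {
      v_ch = v_ot = 0.0;
      for (int d = 0; d < 3; ++d) {
        v_ch += w[d] * V[ch[d]][d];
        v_ot += w[d] * V[1 - ch[d]][d];
      }
    } else {  // F-NS, F-Dec: uniform weights
      v_ch = v_ot = 0.0;
      for (int d = 0; d < 3; ++d) {
        v_ch += V[ch[d]][d] / 3.0;
        v_ot += V[1 - ch[d]][d] / 3.0;
      }
    }
    // stabilized two-option softmax
    double m = v_ch > v_ot ? v_ch : v_ot;
    double e1 = std::exp(beta * (v_ch - m)), e2 = std::exp(beta * (v_ot - m));
    p_choice[t] = e1 / (e1 + e2);
    v_chosen[t] = v_ch;
    double pe = reward[t] - v_ch;
    rpe[t] = pe;

    if (variant == 2) {
      V[ch[0]][0] += eta * pe;
    } else if (weighted) {
      for (int d = 0; d < 3; ++d) V[ch[d]][d] += eta * w[d] * pe;
    } else {
      for (int d = 0; d < 3; ++d) V[ch[d]][d] += eta * pe;
    }
    if (decay) {
      for (int d = 0; d < 3; ++d)
        V[1 - ch[d]][d] = omega * V[1 - ch[d]][d] + (1.0 - omega) * v0;
    }
    if (weighted) {
      double s[3], ssum = 0.0;
      for (int d = 0; d < 3; ++d) {
        s[d] = std::fabs(V[0][d] - V[1][d]);
        ssum += s[d];
      }
      double wsum = 0.0;
      for (int d = 0; d < 3; ++d) {
        double target = ssum > 0 ? s[d] / ssum : 1.0 / 3.0;
        w[d] = (1.0 - phi) * w[d] + phi * target;
        wsum += w[d];
      }
      for (int d = 0; d < 3; ++d) w[d] /= wsum;
    }
  }
  return List::create(Named("v_chosen") = v_chosen, Named("rpe") = rpe,
                      Named("p_choice") = p_choice);
}
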