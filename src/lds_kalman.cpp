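#include <Rcpp.h>
using namespace Rcpp;

// Exact forward filter + RTS smoother for the scalar-state response
// preparedness model:
//   x_{t+1} = A x_t + u_t + q_t,   q_t ~ N(0, Q)
//   y_t     = x_t + o_t + r_t,     r_t ~ N(0, R)
// u_t = B.Y_t + F e_t and o_t = D.K_t are deterministic per-trial inputs
// computed in R. `block` marks independent segments: the state prior
// (m1, P1) is re-applied at each segment start and no information flows
// across segment boundaries. Missing observations (obs[t] == 0) propagate
// the prediction without an update.
// [[Rcpp::export]]
List lds_estep_cpp(NumericVector y, LogicalVector obs, NumericVector o,
                   NumericVector u, IntegerVector block,
                   double A, double Q, double R, double m1, double P1) {
  const int n = y.size();
  NumericVector xp(n), Pp(n), xf(n), Pf(n), xs(n), Ps(n);
  NumericVector C(n);     // C[t] = Cov(x_t, x_{t+1} | y) within a segment
  double ll = 0.0;
  const double LOG2PI = 1.8378770664093453;

  // forward filter
  for (int t = 0; t < n; ++t) {
    if (t == 0 || block[t] != block[t - 1]) {
      xp[t] = m1;
      Pp[t] = P1;
    } else {
      xp[t] = A * xf[t - 1] + u[t - 1];
      Pp[t] = A * A * Pf[t - 1] + Q;
    }
    if (obs[t]) {
      double S = Pp[t] + R;
      double innov = y[t] - xp[t] - o[t];
      double K = Pp[t] / S;
      xf[t] = xp[t] + K * innov;
      Pf[t] = (1.0 - K) * Pp[t];
      ll += -0.5 * (LOG2PI + std::log(S) + innov * innov / S);
    } else {
      xf[t] = xp[t];
      Pf[t] = Pp[t];
    }
  }

  // RTS smoother (runs backwards, restarting at segment ends)
  for (int t = n - 1; t >= 0; --t) {
    if (t == n - 1 || block[t] != block[t + 1]) {
      xs[t] = xf[t];
      Ps[t] = Pf[t];
      C[t] = NA_REAL;
    } else {
      double J = (Pp[t + 1] > 0.0) ? Pf[t] * A / Pp[t + 1] : 0.0;
      xs[t] = xf[t] + J * (xs[t + 1] - xp[t + 1]);
      Ps[t] = Pf[t] + J * J * (Ps[t + 1] - Pp[t + 1]);
      C[t] = J * Ps[t + 1];
    }
  }

  return List::create(_["xs"] = xs, _["Ps"] = Ps, _["C"] = C,
                      _["xf"] = xf, _["Pf"] = Pf,
                      _["xp"] = xp, _["Pp"] = Pp, _["loglik"] = ll);
}
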