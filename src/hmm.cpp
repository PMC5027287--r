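#include <Rcpp.h>
using namespace Rcpp;

// Gaussian-emission hidden Markov machinery for smFRET trajectory
// idealization. Scaled forward-backward (Baum-Welch) and Viterbi for a
// small, fixed number of states; emissions are one Gaussian per state.

static inline double dnorm_log(double x, double mu, double sd) {
  static const double LOG_SQRT_2PI = 0.9189385332046727;
  double z = (x - mu) / sd;
  return -0.5 * z * z - std::log(sd) - LOG_SQRT_2PI;
}

// One pass of scaled forward-backward. Returns the data log-likelihood and
// fills gamma (T x K state responsibilities) and xi_sum (K x K expected
// transition counts).
static double forward_backward(const NumericVector& obs,
                               const NumericVector& mu,
                               const NumericVector& sd,
                               const NumericMatrix& trans,
                               const NumericVector& start,
                               NumericMatrix& gamma,
                               NumericMatrix& xi_sum) {
  const int T = obs.size(), K = mu.size();
  NumericMatrix logb(T, K), alpha(T, K), beta(T, K);
  NumericVector scale(T);

  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k)
      logb(t, k) = dnorm_log(obs[t], mu[k], sd[k]);

  // emissions in linear space, renormalized per frame to avoid underflow
  NumericMatrix b(T, K);
  for (int t = 0; t < T; ++t) {
    double m = logb(t, 0);
    for (int k = 1; k < K; ++k) if (logb(t, k) > m) m = logb(t, k);
    for (int k = 0; k < K; ++k) b(t, k) = std::exp(logb(t, k) - m);
    scale[t] = m;  // reuse as per-frame emission offset
  }

  double loglik = 0.0;
  NumericVector c(T);
  for (int k = 0; k < K; ++k) alpha(0, k) = start[k] * b(0, k);
  double s0 = 0.0;
  for (int k = 0; k < K; ++k) s0 += alpha(0, k);
  c[0] = s0;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s0;
  for (int t = 1; t < T; ++t) {
    double st = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * trans(j, k);
      alpha(t, k) = a * b(t, k);
      st += alpha(t, k);
    }
    c[t] = st;
    for (int k = 0; k < K; ++k) alpha(t, k) /= st;
  }
  for (int t = 0; t < T; ++t) loglik += std::log(c[t]) + scale[t];

  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int j = 0; j < K; ++j) {
      double s = 0.0;
      for (int k = 0; k < K; ++k)
        s += trans(j, k) * b(t + 1, k) * beta(t + 1, k);
      beta(t, j) = s / c[t + 1];
    }
  }

  for (int t = 0; t < T; ++t) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) {
      gamma(t, k) = alpha(t, k) * beta(t, k);
      s += gamma(t, k);
    }
    for (int k = 0; k < K; ++k) gamma(t, k) /= s;
  }

  std::fill(xi_sum.begin(), xi_sum.end(), 0.0);
  for (int t = 0; t < T - 1; ++t) {
    double s = 0.0;
    NumericMatrix xi(K, K);
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k) {
        xi(j, k) = alpha(t, j) * trans(j, k) * b(t + 1, k) * beta(t + 1, k);
        s += xi(j, k);
      }
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k) xi_sum(j, k) += xi(j, k) / s;
  }
  return loglik;
}

// [[Rcpp::export(name = ".hmm_em")]]
List hmm_em(NumericVector obs, NumericVector mu0, NumericVector sd0,
            NumericMatrix trans0, NumericVector start0,
            bool fix_means, int max_iter, double tol, double sd_floor,
            bool tie_sds) {
  const int T = obs.size(), K = mu0.size();
  NumericVector mu = clone(mu0), sd = clone(sd0), start = clone(start0);
  NumericMatrix trans = clone(trans0);
  NumericMatrix gamma(T, K), xi_sum(K, K);

  double loglik = R_NegInf, prev = R_NegInf;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    loglik = forward_backward(obs, mu, sd, trans, start, gamma, xi_sum);
    if (it > 0 && std::fabs(loglik - prev) < tol) break;
    prev = loglik;

    // M-step
    NumericVector occ(K);
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int t = 0; t < T; ++t) s += gamma(t, k);
      occ[k] = s;
    }
    for (int k = 0; k < K; ++k) {
      start[k] = gamma(0, k);
      if (occ[k] < 1e-8) continue;  // empty state: keep its parameters
      if (!fix_means) {
        double m = 0.0;
        for (int t = 0; t < T; ++t) m += gamma(t, k) * obs[t];
        mu[k] = m / occ[k];
      }
      double v = 0.0;
      for (int t = 0; t < T; ++t) {
        double d = obs[t] - mu[k];
        v += gamma(t, k) * d * d;
      }
      double s = std::sqrt(v / occ[k]);
      sd[k] = (s < sd_floor) ? sd_floor : s;
    }
    if (tie_sds) {  // homoscedastic emissions: one sd for all states
      double v = 0.0, w = 0.0;
      for (int k = 0; k < K; ++k) {
        if (occ[k] < 1e-8) continue;
        v += sd[k] * sd[k] * occ[k];
        w += occ[k];
      }
      double s = (w > 0) ? std::sqrt(v / w) : sd_floor;
      if (s < sd_floor) s = sd_floor;
      for (int k = 0; k < K; ++k) sd[k] = s;
    }
    for (int j = 0; j < K; ++j) {
      double row = 0.0;
      for (int k = 0; k < K; ++k) row += xi_sum(j, k);
      if (row < 1e-12) {  // state never left (or never entered): stay put
        for (int k = 0; k < K; ++k) trans(j, k) = (j == k) ? 1.0 : 0.0;
      } else {
        for (int k = 0; k < K; ++k) trans(j, k) = xi_sum(j, k) / row;
      }
    }
  }

  NumericVector occupancy(K);
  for (int k = 0; k < K; ++k) {
    double s = 0.0;
    for (int t = 0; t < T; ++t) s += gamma(t, k);
    occupancy[k] = s / T;
  }

  return List::create(_["means"] = mu, _["sds"] = sd, _["trans"] = trans,
                      _["start"] = start, _["loglik"] = loglik,
                      _["iterations"] = it + 1, _["occupancy"] = occupancy);
}

// Pooled Baum-Welch over several trajectories: one shared set of emission
// means/sds, transition matrix and start distribution, responsibilities
// computed per trajectory. `lengths` partitions `obs` into trajectories.
// [[Rcpp::export(name = ".hmm_em_multi")]]
List hmm_em_multi(NumericVector obs, IntegerVector lengths,
                  NumericVector mu0, NumericVector sd0,
                  NumericMatrix trans0, NumericVector start0,
                  bool fix_means, int max_iter, double tol, double sd_floor,
                  bool tie_sds) {
  const int K = mu0.size(), R = lengths.size();
  const int T = obs.size();
  NumericVector mu = clone(mu0), sd = clone(sd0), start = clone(start0);
  NumericMatrix trans = clone(trans0);

  double loglik = R_NegInf, prev = R_NegInf;
  int it = 0;
  NumericMatrix gamma_all(T, K);
  for (it = 0; it < max_iter; ++it) {
    double ll = 0.0;
    NumericMatrix xi_tot(K, K);
    NumericVector start_acc(K);
    int off = 0;
    for (int r = 0; r < R; ++r) {
      int Tr = lengths[r];
      NumericVector o(obs.begin() + off, obs.begin() + off + Tr);
      NumericMatrix gamma(Tr, K), xi(K, K);
      ll += forward_backward(o, mu, sd, trans, start, gamma, xi);
      for (int t = 0; t < Tr; ++t)
        for (int k = 0; k < K; ++k) gamma_all(off + t, k) = gamma(t, k);
      for (int j = 0; j < K; ++j) {
        start_acc[j] += gamma(0, j);
        for (int k = 0; k < K; ++k) xi_tot(j, k) += xi(j, k);
      }
      off += Tr;
    }
    loglik = ll;
    if (it > 0 && std::fabs(loglik - prev) < tol) break;
    prev = loglik;

    NumericVector occ(K);
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int t = 0; t < T; ++t) s += gamma_all(t, k);
      occ[k] = s;
    }
    for (int k = 0; k < K; ++k) {
      start[k] = start_acc[k] / R;
      if (occ[k] < 1e-8) continue;
      if (!fix_means) {
        double m = 0.0;
        for (int t = 0; t < T; ++t) m += gamma_all(t, k) * obs[t];
        mu[k] = m / occ[k];
      }
      double v = 0.0;
      for (int t = 0; t < T; ++t) {
        double d = obs[t] - mu[k];
        v += gamma_all(t, k) * d * d;
      }
      double s = std::sqrt(v / occ[k]);
      sd[k] = (s < sd_floor) ? sd_floor : s;
    }
    if (tie_sds) {  // homoscedastic emissions: one sd for all states
      double v = 0.0, w = 0.0;
      for (int k = 0; k < K; ++k) {
        if (occ[k] < 1e-8) continue;
        v += sd[k] * sd[k] * occ[k];
        w += occ[k];
      }
      double s = (w > 0) ? std::sqrt(v / w) : sd_floor;
      if (s < sd_floor) s = sd_floor;
      for (int k = 0; k < K; ++k) sd[k] = s;
    }
    for (int j = 0; j < K; ++j) {
      double row = 0.0;
      for (int k = 0; k < K; ++k) row += xi_tot(j, k);
      if (row < 1e-12) {
        for (int k = 0; k < K; ++k) trans(j, k) = (j == k) ? 1.0 : 0.0;
      } else {
        for (int k = 0; k < K; ++k) trans(j, k) = xi_tot(j, k) / row;
      }
    }
  }

  NumericVector occupancy(K);
  for (int k = 0; k < K; ++k) {
    double s = 0.0;
    for (int t = 0; t < T; ++t) s += gamma_all(t, k);
    occupancy[k] = s / T;
  }
  return List::create(_["means"] = mu, _["sds"] = sd, _["trans"] = trans,
                      _["start"] = start, _["loglik"] = loglik,
                      _["iterations"] = it + 1, _["occupancy"] = occupancy);
}

// Viterbi decoding; on exact ties the lower state index wins so that the
// output is deterministic.
// [[Rcpp::export(name = ".hmm_viterbi")]]
IntegerVector hmm_viterbi(NumericVector obs, NumericVector mu,
                          NumericVector sd, NumericMatrix trans,
                          NumericVector start) {
  const int T = obs.size(), K = mu.size();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  const double NEG = -1e300;

  for (int k = 0; k < K; ++k) {
    double lp = start[k] > 0 ? std::log(start[k]) : NEG;
    delta(0, k) = lp + dnorm_log(obs[0], mu[k], sd[k]);
  }
  NumericMatrix ltr(K, K);
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k)
      ltr(j, k) = trans(j, k) > 0 ? std::log(trans(j, k)) : NEG;

  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = delta(t - 1, 0) + ltr(0, k);
      int arg = 0;
      for (int j = 1; j < K; ++j) {
        double cand = delta(t - 1, j) + ltr(j, k);
        if (cand > best) { best = cand; arg = j; }  // strict: ties keep lower j
      }
      delta(t, k) = best + dnorm_log(obs[t], mu[k], sd[k]);
      psi(t, k) = arg;
    }
  }

  IntegerVector path(T);
  int best = 0;
  for (int k = 1; k < K; ++k) if (delta(T - 1, k) > delta(T - 1, best)) best = k;
  path[T - 1] = best;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  for (int t = 0; t < T; ++t) path[t] += 1;  // 1-based for R
  return path;
}
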