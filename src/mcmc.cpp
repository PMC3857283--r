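// Metropolis-within-Gibbs sampler for the data-augmented SECR model with a
// trap-specific behavioural response (half-normal encounter rate, Bernoulli
// observations). Uses R's RNG throughout so runs are reproducible from
// set.seed() on the R side.
//
// Sufficient statistics: for each observed individual i and trap j the
// active occasions split at the first capture into a pre state (rate
// lambda0 * exp(-d^2/(2 sigma^2))) and a post state (rate multiplied by
// exp(b1)); with counts (K0, y0) and (K1, y1) the Bernoulli log-likelihood
// is y0*log(p0) - (K0-y0)*rate0 + y1*log(p1) - (K1-y1)*rate1, since
// log(1 - p) = -rate under p = 1 - exp(-rate). Augmented individuals have
// all-zero histories, so their contribution is -lambda0 * sum_j A_j *
// exp(-d^2/(2 sigma^2)) with A_j the trap's active-night count.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Model {
  const IntegerMatrix &y0, &y1, &K0, &K1;
  const NumericVector &Aj;
  const NumericMatrix &D2;  // G x J squared distances, suitable mesh only
  int n_obs, G, J;

  Model(const IntegerMatrix &y0_, const IntegerMatrix &y1_,
        const IntegerMatrix &K0_, const IntegerMatrix &K1_,
        const NumericVector &Aj_, const NumericMatrix &D2_)
      : y0(y0_), y1(y1_), K0(K0_), K1(K1_), Aj(Aj_), D2(D2_),
        n_obs(y0_.nrow()), G(D2_.nrow()), J(D2_.ncol()) {}

  // log-likelihood of observed individual i with centre g
  double obs_ll(int i, int g, double l0, double sig, double b1) const {
    const double inv2s2 = 1.0 / (2.0 * sig * sig);
    const double eb1 = std::exp(b1);
    double ll = 0.0;
    for (int j = 0; j < J; ++j) {
      const double rate0 = l0 * std::exp(-D2(g, j) * inv2s2);
      const double rate1 = rate0 * eb1;
      if (y0(i, j) > 0) {
        const double p0 = -std::expm1(-rate0);
        ll += (p0 > 0.0) ? y0(i, j) * std::log(p0) : R_NegInf;
      }
      ll -= (K0(i, j) - y0(i, j)) * rate0;
      if (y1(i, j) > 0) {
        const double p1 = -std::expm1(-rate1);
        ll += (p1 > 0.0) ? y1(i, j) * std::log(p1) : R_NegInf;
      }
      ll -= (K1(i, j) - y1(i, j)) * rate1;
    }
    return ll;
  }

  // sum_j A_j * exp(-d^2/(2 sigma^2)) at centre g: the all-zero history
  // log-likelihood is -lambda0 * this.
  double sumexp(int g, double sig) const {
    const double inv2s2 = 1.0 / (2.0 * sig * sig);
    double s = 0.0;
    for (int j = 0; j < J; ++j) s += Aj[j] * std::exp(-D2(g, j) * inv2s2);
    return s;
  }
};

inline double sq(double x) { return x * x; }

}  // namespace

// [[Rcpp::export]]
List secr_mcmc_cpp(IntegerMatrix y0, IntegerMatrix y1, IntegerMatrix K0,
                   IntegerMatrix K1, NumericVector Aj, NumericMatrix D2,
                   IntegerMatrix neigh, int M, int n_iter, int burn,
                   int thin, double lambda0, double sigma, double b1,
                   double psi, IntegerVector centres0, NumericVector prior,
                   NumericVector step0, double long_jump, bool adapt,
                   int pv_every) {
  const Model mod(y0, y1, K0, K1, Aj, D2);
  const int n_obs = mod.n_obs, G = mod.G, J = mod.J;
  if (G < 1) stop("state space has no suitable points");
  if (M < n_obs) stop("augmented size smaller than observed count");

  std::vector<int> cent(centres0.begin(), centres0.end());
  std::vector<int> z(M, 1);
  for (int i = n_obs; i < M; ++i) z[i] = (unif_rand() < psi) ? 1 : 0;

  // cache: S[g] = sum_j A_j exp(-d^2/(2 sigma^2)); depends on sigma only
  std::vector<double> S(G);
  auto rebuildS = [&](double sig) {
    for (int g = 0; g < G; ++g) S[g] = mod.sumexp(g, sig);
  };
  rebuildS(sigma);

  // full log-likelihood at proposed parameters; uses cached S only when
  // sigma is unchanged (use_cache)
  auto total_ll = [&](double l0, double sig, double b1p, bool use_cache) {
    double ll = 0.0;
    for (int i = 0; i < n_obs; ++i) ll += mod.obs_ll(i, cent[i], l0, sig, b1p);
    double saug = 0.0;
    for (int i = n_obs; i < M; ++i) {
      if (z[i]) saug += use_cache ? S[cent[i]] : mod.sumexp(cent[i], sig);
    }
    return ll - l0 * saug;
  };

  auto log_prior = [&](double l0, double sig, double b1p) {
    return R::dnorm(std::log(l0), prior[0], prior[1], 1) +
           R::dnorm(std::log(sig), prior[2], prior[3], 1) +
           R::dnorm(b1p, prior[4], prior[5], 1);
  };

  const int n_keep = (n_iter - burn) / thin;
  NumericMatrix draws(n_keep, 5);
  colnames(draws) = CharacterVector::create("lambda0", "sigma", "b1", "psi",
                                            "Ns");
  std::vector<double> Tobs_v, Trep_v;
  double step[3] = {step0[0], step0[1], step0[2]};
  long acc[5] = {0, 0, 0, 0, 0};  // l0, sigma, b1, centres_obs, centres_aug
  long try_[5] = {0, 0, 0, 0, 0};
  long win_acc[3] = {0, 0, 0}, win_try[3] = {0, 0, 0};
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    // --- z: Gibbs for augmented individuals (observed fixed at 1) ---
    for (int i = n_obs; i < M; ++i) {
      const double q = std::exp(-lambda0 * S[cent[i]]);
      const double pz = psi * q / (psi * q + 1.0 - psi);
      z[i] = (unif_rand() < pz) ? 1 : 0;
    }
    int n1 = n_obs;
    for (int i = n_obs; i < M; ++i) n1 += z[i];

    // --- psi: conjugate Beta under its uniform prior ---
    psi = R::rbeta(1.0 + n1, 1.0 + M - n1);

    // --- activity centres ---
    for (int i = 0; i < M; ++i) {
      if (i >= n_obs && !z[i]) {
        // excluded individuals: full conditional is uniform over the mesh
        cent[i] = std::min(G - 1, (int)(unif_rand() * G));
        continue;
      }
      int gp;
      if (unif_rand() < long_jump) {
        gp = std::min(G - 1, (int)(unif_rand() * G));
      } else {
        const int k = std::min(7, (int)(unif_rand() * 8));
        gp = neigh(cent[i], k);
        if (gp < 0) continue;  // off-grid / unsuitable: reject
      }
      const int slot = (i < n_obs) ? 3 : 4;
      ++try_[slot];
      double ll_cur, ll_prop;
      if (i < n_obs) {
        ll_cur = mod.obs_ll(i, cent[i], lambda0, sigma, b1);
        ll_prop = mod.obs_ll(i, gp, lambda0, sigma, b1);
      } else {
        ll_cur = -lambda0 * S[cent[i]];
        ll_prop = -lambda0 * S[gp];
      }
      if (std::log(unif_rand()) < ll_prop - ll_cur) {
        cent[i] = gp;
        ++acc[slot];
      }
    }

    // --- detection parameters: random-walk Metropolis ---
    double cur_ll = total_ll(lambda0, sigma, b1, true);
    double cur_lp = log_prior(lambda0, sigma, b1);
    // lambda0 (log walk)
    ++try_[0]; ++win_try[0];
    if (step[0] > 0.0) {
      const double l0p = lambda0 * std::exp(step[0] * norm_rand());
      const double llp = total_ll(l0p, sigma, b1, true);
      const double lpp = log_prior(l0p, sigma, b1);
      if (std::log(unif_rand()) < (llp + lpp) - (cur_ll + cur_lp)) {
        lambda0 = l0p; cur_ll = llp; cur_lp = lpp;
        ++acc[0]; ++win_acc[0];
      }
    }
    // sigma (log walk; invalidates S on acceptance)
    ++try_[1]; ++win_try[1];
    if (step[1] > 0.0) {
      const double sigp = sigma * std::exp(step[1] * norm_rand());
      const double llp = total_ll(lambda0, sigp, b1, false);
      const double lpp = log_prior(lambda0, sigp, b1);
      if (std::log(unif_rand()) < (llp + lpp) - (cur_ll + cur_lp)) {
        sigma = sigp; cur_ll = llp; cur_lp = lpp;
        rebuildS(sigma);
        ++acc[1]; ++win_acc[1];
      }
    }
    // b1 (plain walk; only observed individuals involve b1)
    ++try_[2]; ++win_try[2];
    if (step[2] > 0.0) {
      const double b1p = b1 + step[2] * norm_rand();
      const double llp = total_ll(lambda0, sigma, b1p, true);
      const double lpp = log_prior(lambda0, sigma, b1p);
      if (std::log(unif_rand()) < (llp + lpp) - (cur_ll + cur_lp)) {
        b1 = b1p;
        ++acc[2]; ++win_acc[2];
      }
    }

    // --- step-size adaptation during burn-in, then frozen ---
    if (adapt && it < burn && (it + 1) % 50 == 0) {
      for (int k = 0; k < 3; ++k) {
        const double r = (double)win_acc[k] / std::max(1L, win_try[k]);
        if (r > 0.4) step[k] *= 1.2;
        else if (r < 0.2) step[k] *= 0.8;
        win_acc[k] = win_try[k] = 0;
      }
    }

    // --- record ---
    if (it >= burn && (it - burn) % thin == 0) {
      draws(kept, 0) = lambda0;
      draws(kept, 1) = sigma;
      draws(kept, 2) = b1;
      draws(kept, 3) = psi;
      draws(kept, 4) = n1;

      // posterior predictive discrepancy (Freeman-Tukey on individual x
      // trap encounter counts), every pv_every-th retained draw
      if (pv_every > 0 && kept % pv_every == 0) {
        const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
        const double eb1 = std::exp(b1);
        double Tobs = 0.0, Trep = 0.0;
        for (int i = 0; i < M; ++i) {
          if (i >= n_obs && !z[i]) continue;
          for (int j = 0; j < J; ++j) {
            const int A = (i < n_obs) ? (K0(i, j) + K1(i, j)) : (int)Aj[j];
            if (A == 0) continue;
            const double rate0 = lambda0 * std::exp(-D2(cent[i], j) * inv2s2);
            const double p0 = -std::expm1(-rate0);
            const double p1 = -std::expm1(-rate0 * eb1);
            double E = 0.0;
            int rep = 0;
            if (p0 > 1e-300) {
              // 1 - (1-p0)^A via expm1 to avoid cancellation at tiny rates
              const double one_m_q0A = -std::expm1(-rate0 * A);
              E = std::max(0.0, (p0 - p1) * one_m_q0A / p0 + p1 * A);
              // replicate: geometric time to first capture, then Bernoulli
              const double t1 = 1.0 + R::rgeom(p0);
              if (t1 <= (double)A) {
                rep = 1 + (int)R::rbinom((double)A - t1, p1);
              }
            }
            const int obs = (i < n_obs) ? (y0(i, j) + y1(i, j)) : 0;
            Tobs += sq(std::sqrt((double)obs) - std::sqrt(E));
            Trep += sq(std::sqrt((double)rep) - std::sqrt(E));
          }
        }
        Tobs_v.push_back(Tobs);
        Trep_v.push_back(Trep);
      }
      ++kept;
    }
  }

  NumericVector acc_rate(5);
  for (int k = 0; k < 5; ++k) {
    acc_rate[k] = try_[k] > 0 ? (double)acc[k] / try_[k] : NA_REAL;
  }
  acc_rate.names() = CharacterVector::create("lambda0", "sigma", "b1",
                                             "centres_obs", "centres_aug");
  return List::create(
      _["draws"] = draws, _["accept"] = acc_rate,
      _["steps"] = NumericVector::create(step[0], step[1], step[2]),
      _["T_obs"] = wrap(Tobs_v), _["T_rep"] = wrap(Trep_v));
}
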