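#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for a three-component Gaussian mixture empirical null on
// association z-scores. Component 0 is the null (its posterior-mean mean is
// the bias, its posterior-mean SD the inflation); components 1 and 2 capture
// negative and positive alternatives, with means truncated below/above the
// current null mean so labels stay identified. Conjugate priors:
// Dirichlet(alpha) on weights and normal-inverse-gamma on (mean, variance).
// Uses R's RNG so results are reproducible under set.seed().

// [[Rcpp::export]]
List empnull_gibbs_cpp(NumericVector z, int niter, int burnin,
                       NumericVector alpha, double kappa_null,
                       double kappa_alt, double a0, double b0,
                       double prior_sep) {
  const int m = z.size();
  NumericVector zs = clone(z);
  std::sort(zs.begin(), zs.end());
  double med = (m % 2) ? zs[m / 2] : 0.5 * (zs[m / 2 - 1] + zs[m / 2]);
  NumericVector ad(m);
  for (int i = 0; i < m; ++i) ad[i] = std::fabs(z[i] - med);
  std::sort(ad.begin(), ad.end());
  double s = 1.4826 * ((m % 2) ? ad[m / 2] : 0.5 * (ad[m / 2 - 1] + ad[m / 2]));
  if (s <= 0) s = 1.0;

  double mu[3] = {med, med - 3 * s, med + 3 * s};
  double s2[3] = {s * s, s * s, s * s};
  double pi[3] = {0.9, 0.05, 0.05};

  double acc_mu0 = 0, acc_sd0 = 0, acc_pi[3] = {0, 0, 0};
  double acc_mu[3] = {0, 0, 0}, acc_sd[3] = {0, 0, 0};
  int kept = 0;

  for (int it = 0; it < niter; ++it) {
    double n_k[3] = {0, 0, 0}, sum_k[3] = {0, 0, 0}, sumsq_k[3] = {0, 0, 0};
    double sd0 = std::sqrt(s2[0]), sd1 = std::sqrt(s2[1]), sd2 = std::sqrt(s2[2]);
    for (int i = 0; i < m; ++i) {
      double p0 = pi[0] * R::dnorm(z[i], mu[0], sd0, 0);
      double p1 = pi[1] * R::dnorm(z[i], mu[1], sd1, 0);
      double p2 = pi[2] * R::dnorm(z[i], mu[2], sd2, 0);
      double tot = p0 + p1 + p2;
      int c = 0;
      if (tot > 0) {
        double u = R::unif_rand() * tot;
        c = (u < p0) ? 0 : ((u < p0 + p1) ? 1 : 2);
      }
      n_k[c] += 1.0;
      sum_k[c] += z[i];
      sumsq_k[c] += z[i] * z[i];
    }

    double g[3], gs = 0;
    for (int k = 0; k < 3; ++k) {
      g[k] = R::rgamma(alpha[k] + n_k[k], 1.0);
      gs += g[k];
    }
    for (int k = 0; k < 3; ++k) pi[k] = g[k] / gs;

    double prior_mean[3] = {0.0, mu[0] - prior_sep * s, mu[0] + prior_sep * s};
    double kap[3] = {kappa_null, kappa_alt, kappa_alt};
    for (int k = 0; k < 3; ++k) {
      double n_ = n_k[k];
      double zbar = n_ > 0 ? sum_k[k] / n_ : 0.0;
      double ss = n_ > 0 ? sumsq_k[k] - n_ * zbar * zbar : 0.0;
      if (ss < 0) ss = 0;
      double kn = kap[k] + n_;
      double mn = (kap[k] * prior_mean[k] + sum_k[k]) / kn;
      double an = a0 + n_ / 2.0;
      double dev = zbar - prior_mean[k];
      double bn = b0 + 0.5 * ss + 0.5 * kap[k] * n_ / kn * dev * dev;
      double s2new = bn / R::rgamma(an, 1.0);
      // alternative components may not be narrower than the null: keeps them
      // from shrink-wrapping the null's tails (identifiability constraint)
      if (k > 0 && s2new < s2[0]) s2new = s2[0];
      double sdmu = std::sqrt(s2new / kn);
      double munew;
      // alternative means kept at least 1.5 null-SDs away from the null
      // mean, so a wide alternative cannot model half of the null itself
      double sep = 1.5 * std::sqrt(s2[0]);
      if (k == 0) {
        munew = R::rnorm(mn, sdmu);
      } else if (k == 1) {  // truncated above at (null mean - separation)
        double bound = mu[0] - sep;
        double ub = R::pnorm(bound, mn, sdmu, 1, 0);
        if (ub < 1e-300) munew = bound - 1e-8;
        else munew = R::qnorm(R::unif_rand() * ub, mn, sdmu, 1, 0);
      } else {              // truncated below at (null mean + separation)
        double bound = mu[0] + sep;
        double lb = R::pnorm(bound, mn, sdmu, 1, 0);
        if (lb > 1.0 - 1e-16) munew = bound + 1e-8;
        else munew = R::qnorm(lb + R::unif_rand() * (1.0 - lb), mn, sdmu, 1, 0);
      }
      if (!R_finite(munew)) munew = mu[0];
      mu[k] = munew;
      s2[k] = s2new;
    }

    if (it >= burnin) {
      ++kept;
      acc_mu0 += mu[0];
      acc_sd0 += std::sqrt(s2[0]);
      for (int k = 0; k < 3; ++k) {
        acc_pi[k] += pi[k];
        acc_mu[k] += mu[k];
        acc_sd[k] += std::sqrt(s2[k]);
      }
    }
  }

  NumericVector w(3), mus(3), sds(3);
  for (int k = 0; k < 3; ++k) {
    w[k] = acc_pi[k] / kept;
    mus[k] = acc_mu[k] / kept;
    sds[k] = acc_sd[k] / kept;
  }
  return List::create(_["bias"] = acc_mu0 / kept,
                      _["inflation"] = acc_sd0 / kept,
                      _["weights"] = w, _["means"] = mus, _["sds"] = sds,
                      _["kept_iterations"] = kept);
}
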