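// MCMC for the quantitative-genetic threshold model: a latent liability
// and an observed continuous value evolve as correlated Brownian motion
// on a phylogeny; the observed binary state is the sign of the
// liability.  Liabilities are Gibbs-sampled tip-wise from truncated
// conditional normals; the correlation r, the value scale sigma, and
// the two root means move by adaptive random-walk Metropolis.
// Liability variance is fixed at 1 for identifiability.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// standard normal truncated to (alpha, +inf), Robert (1995) for far tails
static double rtnorm_lower(double alpha) {
  if (alpha < 4.0) {
    double pa = R::pnorm(alpha, 0.0, 1.0, 1, 0);
    double u = R::runif(pa, 1.0);
    if (u >= 1.0) u = 1.0 - 1e-16;
    return R::qnorm(u, 0.0, 1.0, 1, 0);
  }
  double lam = 0.5 * (alpha + std::sqrt(alpha * alpha + 4.0));
  for (int it = 0; it < 1000; ++it) {
    double z = alpha + R::exp_rand() / lam;
    double rho = std::exp(-0.5 * (z - lam) * (z - lam));
    if (R::unif_rand() <= rho) return z;
  }
  return alpha + 1e-8;  // unreachable in practice
}

struct QuadState {
  arma::vec u, v;          // Cinv * z_l, Cinv * z_x
  double qll, qlx, qxx;
};

static void recompute(QuadState& qs, const arma::mat& Cinv,
                      const arma::vec& l, const arma::vec& x,
                      double al, double ax) {
  arma::vec zl = l - al, zx = x - ax;
  qs.u = Cinv * zl;
  qs.v = Cinv * zx;
  qs.qll = arma::dot(zl, qs.u);
  qs.qlx = arma::dot(zl, qs.v);
  qs.qxx = arma::dot(zx, qs.v);
}

// log density (up to a constant) of (l, x) given r, sigma, means
static double logdens(const QuadState& qs, double r, double sigma, int n) {
  double one_m_r2 = 1.0 - r * r;
  double ldetR = std::log(sigma * sigma * one_m_r2);
  double R11 = 1.0 / one_m_r2;
  double R12 = -r / (sigma * one_m_r2);
  double R22 = 1.0 / (sigma * sigma * one_m_r2);
  double quad = R11 * qs.qll + 2.0 * R12 * qs.qlx + R22 * qs.qxx;
  return -0.5 * (n * ldetR + quad);
}

// [[Rcpp::export]]
List cpp_threshold_mcmc(arma::mat Cinv, arma::vec x, arma::ivec ypos,
                        int n_gen, int n_burn, int adapt_every,
                        double r_init, double sigma_init) {
  const int n = x.n_elem;
  RNGScope scope;

  double r = r_init, sigma = sigma_init;
  double al = 0.0, ax = arma::mean(x);
  arma::vec l(n);
  for (int i = 0; i < n; ++i) l(i) = ypos(i) ? 0.5 : -0.5;

  QuadState qs;
  recompute(qs, Cinv, l, x, al, ax);

  double step_r = 0.1, step_s = 0.2, step_al = 0.3, step_ax = 0.3;
  int acc_r = 0, try_r = 0, acc_s = 0, try_s = 0;
  int acc_al = 0, try_al = 0, acc_ax = 0, try_ax = 0;
  int acc_r_total = 0, try_r_total = 0;

  int n_keep = n_gen - n_burn;
  arma::vec out_r(n_keep), out_sigma(n_keep), out_al(n_keep),
      out_ax(n_keep), out_ll(n_keep);

  for (int g = 0; g < n_gen; ++g) {
    // --- Gibbs sweep over tip liabilities ---
    double one_m_r2 = 1.0 - r * r;
    double R11 = 1.0 / one_m_r2;
    double R12 = -r / (sigma * one_m_r2);
    for (int i = 0; i < n; ++i) {
      double cii = Cinv(i, i);
      double w = R11 * cii;                       // conditional precision
      double grad = R11 * qs.u(i) + R12 * qs.v(i); // d(quad)/d l_i / 2
      double m = l(i) - grad / w;
      double s = 1.0 / std::sqrt(w);
      double lnew;
      if (ypos(i)) {
        double alpha = (0.0 - m) / s;
        lnew = m + s * rtnorm_lower(alpha);
      } else {
        double alpha = (0.0 + m) / s;  // truncate above 0
        lnew = m - s * rtnorm_lower(alpha);
      }
      double d = lnew - l(i);
      if (d != 0.0) {
        qs.qll += 2.0 * d * qs.u(i) + d * d * cii;
        qs.qlx += d * qs.v(i);
        qs.u += d * Cinv.col(i);
        l(i) = lnew;
      }
    }

    double cur = logdens(qs, r, sigma, n);

    // --- r ---
    ++try_r; ++try_r_total;
    double rp = r + step_r * R::norm_rand();
    if (rp > -1.0 && rp < 1.0) {
      double prop = logdens(qs, rp, sigma, n);
      if (std::log(R::unif_rand()) < prop - cur) {
        r = rp; cur = prop; ++acc_r; ++acc_r_total;
      }
    }

    // --- sigma (log scale, flat prior on log sigma) ---
    ++try_s;
    double sp = sigma * std::exp(step_s * R::norm_rand());
    if (sp > 1e-6 && sp < 1e6) {
      double prop = logdens(qs, r, sp, n);
      if (std::log(R::unif_rand()) < prop - cur) {
        sigma = sp; cur = prop; ++acc_s;
      }
    }

    // --- root means ---
    ++try_al;
    {
      double alp = al + step_al * R::norm_rand();
      QuadState q2 = qs;
      double d = al - alp;  // z_l shifts by +d
      double su = arma::dot(qs.u, arma::ones<arma::vec>(n));
      double sv = arma::dot(qs.v, arma::ones<arma::vec>(n));
      double s1 = arma::accu(Cinv);
      q2.qll = qs.qll + 2.0 * d * su + d * d * s1;
      q2.qlx = qs.qlx + d * sv;
      double prop = logdens(q2, r, sigma, n);
      if (std::log(R::unif_rand()) < prop - cur) {
        al = alp;
        recompute(qs, Cinv, l, x, al, ax);
        cur = logdens(qs, r, sigma, n);
        ++acc_al;
      }
    }
    ++try_ax;
    {
      double axp = ax + step_ax * R::norm_rand();
      QuadState q2 = qs;
      double d = ax - axp;  // z_x shifts by +d
      double su = arma::accu(qs.u);
      double sv = arma::accu(qs.v);
      double s1 = arma::accu(Cinv);
      q2.qxx = qs.qxx + 2.0 * d * sv + d * d * s1;
      q2.qlx = qs.qlx + d * su;
      double prop = logdens(q2, r, sigma, n);
      if (std::log(R::unif_rand()) < prop - cur) {
        ax = axp;
        recompute(qs, Cinv, l, x, al, ax);
        cur = logdens(qs, r, sigma, n);
        ++acc_ax;
      }
    }

    // --- adaptation during burn-in ---
    if (g < n_burn && adapt_every > 0 && (g + 1) % adapt_every == 0) {
      auto tune = [&](double& step, int& acc, int& tries) {
        if (tries > 0) {
          double rate = double(acc) / tries;
          if (rate > 0.44) step *= 1.25;
          else if (rate < 0.2) step *= 0.8;
        }
        acc = 0; tries = 0;
      };
      tune(step_r, acc_r, try_r);
      tune(step_s, acc_s, try_s);
      tune(step_al, acc_al, try_al);
      tune(step_ax, acc_ax, try_ax);
    }

    // periodic exact refresh against numeric drift
    if ((g + 1) % 5000 == 0) recompute(qs, Cinv, l, x, al, ax);

    if (g >= n_burn) {
      int k = g - n_burn;
      out_r(k) = r;
      out_sigma(k) = sigma;
      out_al(k) = al;
      out_ax(k) = ax;
      out_ll(k) = cur;
    }
  }

  double acc_rate_r = try_r_total > 0 ?
      double(acc_r_total) / try_r_total : NA_REAL;
  return List::create(
      _["r"] = out_r, _["sigma"] = out_sigma,
      _["mean_liability"] = out_al, _["mean_value"] = out_ax,
      _["logdens"] = out_ll, _["accept_rate_r"] = acc_rate_r,
      _["liability"] = l);
}
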