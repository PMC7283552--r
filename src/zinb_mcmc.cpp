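// MCMC sampler for the hierarchical zero-inflated negative binomial model
// with a Dirichlet-process (stick-breaking) prior on log size factors.
//
// Model, per cell (i, j) of an n x p count matrix Y:
//   y_ij ~ pi_i * I(y_ij = 0) + (1 - pi_i) * NB(mean = s_i * alpha_ij, disp = phi_j)
//   NB variance = lambda + lambda^2 / phi  (phi_j is the size parameter)
//   log alpha_ij ~ N(mu_j, sig2_j),  mu_j | sig2_j ~ N(0, h0 * sig2_j),
//   sig2_j ~ InvGamma(a0, b0)  (conjugate NIG; its marginal over a column is a
//   non-standardized Student-t density)
//   log s_i ~ sum_m psi_m [ t_m N(nu_m, sigma_s^2) +
//                           (1 - t_m) N(-t_m nu_m / (1 - t_m), sigma_s^2) ]
//   (the inner two-component mixture has mean exactly 0, so E log s_i = 0)
//
// Metropolis-within-Gibbs: eta and pi by exact conjugate draws, phi / log alpha
// / log s by adaptive random-walk MH, (mu, sig2) by NIG Gibbs, DPP by blocked
// Gibbs at truncation M with conjugate V and nu updates and MH for t.
// Uses R's RNG throughout so set.seed() in R makes runs reproducible.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

static inline double nb_loglik(double y, double phi, double lmu) {
  // log NB(y; mean mu = exp(lmu), size phi), mean/dispersion parameterization
  double mu = std::exp(lmu);
  double lse = std::log(phi + mu);
  return R::lgammafn(y + phi) - R::lgammafn(phi) - R::lgammafn(y + 1.0) +
         phi * (std::log(phi) - lse) + y * (lmu - lse);
}

// mean-dependent part only: valid in MH ratios where phi (and y) are fixed,
// since the lgamma terms cancel
static inline double nb_loglik_mean(double y, double phi, double lmu) {
  double mu = std::exp(lmu);
  double lse = std::log(phi + mu);
  return phi * (std::log(phi) - lse) + y * (lmu - lse);
}

static inline double dnorm_log(double x, double m, double v) {
  double d = x - m;
  return -0.5 * std::log(2.0 * M_PI * v) - 0.5 * d * d / v;
}

static inline double logsumexp2(double a, double b) {
  double m = std::max(a, b);
  if (!std::isfinite(m)) return m;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// second inner-mixture component mean: -t nu / (1 - t)
static inline double inner_mean2(double t, double nu) {
  return -t * nu / (1.0 - t);
}

static void adapt_step(double &step, double acc, int n_prop, double target) {
  if (n_prop == 0) return;
  double rate = acc / n_prop;
  step *= std::exp(0.5 * (rate - target));
  step = std::min(std::max(step, 1e-3), 10.0);
}

// [[Rcpp::export(name = ".zinb_dpp_mcmc")]]
List zinb_dpp_mcmc(const arma::mat &Y, int n_iter, int burn_in,
                   double a_pi, double b_pi, double a_phi, double b_phi,
                   double a0, double b0, double h0,
                   int M, double sigma_s_sq, double tau_nu,
                   double a_t, double b_t, double a_m, double b_m,
                   const arma::vec &pi_init, const arma::vec &phi_init,
                   const arma::vec &ls_init, const arma::mat &la_init,
                   const arma::umat &eta_init) {
  const int n = Y.n_rows, p = Y.n_cols;
  const double ss2 = sigma_s_sq;

  arma::umat eta = eta_init;            // zero-inflation indicators
  arma::vec  pi_v = pi_init;
  arma::vec  phi = phi_init;
  arma::vec  ls = ls_init;              // log size factors
  arma::mat  la = la_init;              // log normalized abundances
  arma::vec  mu(p, arma::fill::zeros);
  arma::vec  sig2(p, arma::fill::ones);

  // DPP state
  arma::uvec clus(n);                   // component labels 0..M-1
  arma::uvec g(n, arma::fill::zeros);   // inner-mixture indicator
  arma::vec  V(M, arma::fill::value(0.5));
  arma::vec  nu(M, arma::fill::zeros);
  arma::vec  tv(M, arma::fill::value(0.5));
  for (int i = 0; i < n; ++i) clus(i) = i % M;
  V(M - 1) = 1.0;                       // truncation: remainder to component M

  // adaptive RW step sizes
  arma::vec step_phi(p, arma::fill::value(0.5));
  double step_la = 0.5;
  arma::vec step_ls(n, arma::fill::value(0.5));
  arma::vec step_t(M, arma::fill::value(0.5));

  // acceptance bookkeeping (post burn-in)
  double acc_phi = 0, prop_phi = 0, acc_la = 0, prop_la = 0;
  double acc_ls = 0, prop_ls = 0, acc_t = 0, prop_t = 0;
  // windows for adaptation during burn-in
  arma::vec win_acc_phi(p, arma::fill::zeros), win_prop_phi(p, arma::fill::zeros);
  double win_acc_la = 0, win_prop_la = 0;
  arma::vec win_acc_ls(n, arma::fill::zeros), win_prop_ls(n, arma::fill::zeros);
  arma::vec win_acc_t(M, arma::fill::zeros), win_prop_t(M, arma::fill::zeros);

  const int B = n_iter - burn_in;
  arma::mat sum_la(n, p, arma::fill::zeros);
  arma::mat sum_eta(n, p, arma::fill::zeros);
  arma::mat pi_draws(B, n), phi_draws(B, p), ls_draws(B, n);

  arma::umat is_zero(n, p);
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < n; ++i) is_zero(i, j) = (Y(i, j) == 0.0) ? 1u : 0u;

  GetRNGstate();
  for (int it = 0; it < n_iter; ++it) {
    // --- 1. eta | rest : exact Bernoulli full conditional at zero cells
    for (int j = 0; j < p; ++j) {
      for (int i = 0; i < n; ++i) {
        if (!is_zero(i, j)) continue;
        double lmu = ls(i) + la(i, j);
        double mu_ij = std::exp(lmu);
        double p0 = std::exp(phi(j) * (std::log(phi(j)) - std::log(phi(j) + mu_ij)));
        double pr = pi_v(i) / (pi_v(i) + (1.0 - pi_v(i)) * p0);
        eta(i, j) = (unif_rand() < pr) ? 1u : 0u;
      }
    }

    // --- 2. pi_i | eta : Beta(a_pi + sum_j eta_ij, b_pi + sum_j (1 - eta_ij))
    for (int i = 0; i < n; ++i) {
      double se = 0;
      for (int j = 0; j < p; ++j) se += eta(i, j);
      pi_v(i) = R::rbeta(a_pi + se, b_pi + (double)p - se);
    }

    // --- 3. phi_j : RW-MH on log phi
    for (int j = 0; j < p; ++j) {
      double lphi = std::log(phi(j));
      double lphi_new = lphi + step_phi(j) * norm_rand();
      double phi_new = std::exp(lphi_new);
      double d = 0.0;
      for (int i = 0; i < n; ++i) {
        if (eta(i, j)) continue;        // point-mass cells carry no NB term
        double lmu = ls(i) + la(i, j);
        d += nb_loglik(Y(i, j), phi_new, lmu) - nb_loglik(Y(i, j), phi(j), lmu);
      }
      // Gamma(a_phi, b_phi) prior on phi plus log-scale Jacobian
      d += a_phi * (lphi_new - lphi) - b_phi * (phi_new - phi(j));
      win_prop_phi(j) += 1;
      if (std::log(unif_rand()) < d) { phi(j) = phi_new; win_acc_phi(j) += 1;
        if (it >= burn_in) acc_phi += 1; }
      if (it >= burn_in) prop_phi += 1;
    }

    // --- 4. log alpha_ij : RW-MH at NB cells, prior draw at point-mass cells
    for (int j = 0; j < p; ++j) {
      double sdj = std::sqrt(sig2(j));
      for (int i = 0; i < n; ++i) {
        if (eta(i, j)) {                // conditional = its Gaussian prior
          la(i, j) = mu(j) + sdj * norm_rand();
          continue;
        }
        double cur = la(i, j);
        double cand = cur + step_la * norm_rand();
        double lmu_c = ls(i) + cand, lmu_o = ls(i) + cur;
        double d = nb_loglik_mean(Y(i, j), phi(j), lmu_c) -
                   nb_loglik_mean(Y(i, j), phi(j), lmu_o);
        double dc = cand - mu(j), doo = cur - mu(j);
        d += -0.5 * (dc * dc - doo * doo) / sig2(j);
        win_prop_la += 1;
        if (it >= burn_in) prop_la += 1;
        if (std::log(unif_rand()) < d) { la(i, j) = cand; win_acc_la += 1;
          if (it >= burn_in) acc_la += 1; }
      }
    }

    // --- 5. (mu_j, sig2_j) : conjugate Normal-Inverse-Gamma Gibbs
    {
      double kn = (double)n + 1.0 / h0;
      for (int j = 0; j < p; ++j) {
        double Sx = 0, Sx2 = 0;
        for (int i = 0; i < n; ++i) { Sx += la(i, j); Sx2 += la(i, j) * la(i, j); }
        double an = a0 + 0.5 * n;
        double bn = b0 + 0.5 * (Sx2 - Sx * Sx / kn);
        if (bn <= 0) bn = 1e-12;
        sig2(j) = 1.0 / R::rgamma(an, 1.0 / bn);
        mu(j) = R::rnorm(Sx / kn, std::sqrt(sig2(j) / kn));
      }
    }

    // --- 6. log s_i : RW-MH against NB likelihood and assigned DPP component
    for (int i = 0; i < n; ++i) {
      int m = clus(i);
      double pm = (g(i) == 0) ? nu(m) : inner_mean2(tv(m), nu(m));
      double cur = ls(i);
      double cand = cur + step_ls(i) * norm_rand();
      double d = 0.0;
      for (int j = 0; j < p; ++j) {
        if (eta(i, j)) continue;
        d += nb_loglik_mean(Y(i, j), phi(j), cand + la(i, j)) -
             nb_loglik_mean(Y(i, j), phi(j), cur + la(i, j));
      }
      d += dnorm_log(cand, pm, ss2) - dnorm_log(cur, pm, ss2);
      win_prop_ls(i) += 1;
      if (it >= burn_in) prop_ls += 1;
      if (std::log(unif_rand()) < d) { ls(i) = cand; win_acc_ls(i) += 1;
        if (it >= burn_in) acc_ls += 1; }
    }

    // --- 7. DPP blocked Gibbs
    {
      // stick-breaking log weights (V_M = 1: remainder to last component)
      arma::vec lpsi(M);
      double lrem = 0.0;
      for (int m = 0; m < M; ++m) {
        double Vm = (m == M - 1) ? 1.0 : V(m);
        lpsi(m) = lrem + std::log(Vm);
        lrem += std::log1p(-std::min(Vm, 1.0 - 1e-15));
      }
      // component labels and inner indicators
      arma::vec lw(M);
      for (int i = 0; i < n; ++i) {
        for (int m = 0; m < M; ++m) {
          double l1 = std::log(tv(m)) + dnorm_log(ls(i), nu(m), ss2);
          double l2 = std::log1p(-tv(m)) +
                      dnorm_log(ls(i), inner_mean2(tv(m), nu(m)), ss2);
          lw(m) = lpsi(m) + logsumexp2(l1, l2);
        }
        double mx = lw.max();
        arma::vec w = arma::exp(lw - mx);
        double tot = arma::accu(w), u = unif_rand() * tot, c = 0;
        int pick = M - 1;
        for (int m = 0; m < M; ++m) { c += w(m); if (u <= c) { pick = m; break; } }
        clus(i) = pick;
        double l1 = std::log(tv(pick)) + dnorm_log(ls(i), nu(pick), ss2);
        double l2 = std::log1p(-tv(pick)) +
                    dnorm_log(ls(i), inner_mean2(tv(pick), nu(pick)), ss2);
        double pg1 = 1.0 / (1.0 + std::exp(l2 - l1)); // P(g = 0)
        g(i) = (unif_rand() < pg1) ? 0u : 1u;
      }
      // V_m conjugate Beta updates (m < M)
      arma::vec cnt(M, arma::fill::zeros);
      for (int i = 0; i < n; ++i) cnt(clus(i)) += 1;
      double tail = 0;
      for (int m = M - 1; m >= 0; --m) { tail += cnt(m); }
      double above = tail;
      for (int m = 0; m < M - 1; ++m) {
        above -= cnt(m);
        V(m) = R::rbeta(a_m + cnt(m), b_m + above);
        V(m) = std::min(std::max(V(m), 1e-12), 1.0 - 1e-12);
      }
      // nu_m conjugate Gaussian update (log s_i = c_i nu_m + eps)
      for (int m = 0; m < M; ++m) {
        double prec = 1.0 / tau_nu, sxy = 0;
        for (int i = 0; i < n; ++i) {
          if ((int)clus(i) != m) continue;
          double ci = (g(i) == 0) ? 1.0 : -tv(m) / (1.0 - tv(m));
          prec += ci * ci / ss2;
          sxy += ci * ls(i) / ss2;
        }
        nu(m) = R::rnorm(sxy / prec, std::sqrt(1.0 / prec));
      }
      // t_m : RW-MH on logit scale
      for (int m = 0; m < M; ++m) {
        double lt = std::log(tv(m) / (1.0 - tv(m)));
        double lt_new = lt + step_t(m) * norm_rand();
        double t_new = 1.0 / (1.0 + std::exp(-lt_new));
        t_new = std::min(std::max(t_new, 1e-12), 1.0 - 1e-12);
        double d = 0.0;
        for (int i = 0; i < n; ++i) {
          if ((int)clus(i) != m) continue;
          if (g(i) == 0)
            d += std::log(t_new) - std::log(tv(m));
          else
            d += std::log1p(-t_new) - std::log1p(-tv(m)) +
                 dnorm_log(ls(i), inner_mean2(t_new, nu(m)), ss2) -
                 dnorm_log(ls(i), inner_mean2(tv(m), nu(m)), ss2);
        }
        // Beta(a_t, b_t) prior + logit Jacobian t(1-t)
        d += a_t * (std::log(t_new) - std::log(tv(m))) +
             b_t * (std::log1p(-t_new) - std::log1p(-tv(m)));
        win_prop_t(m) += 1;
        if (it >= burn_in) prop_t += 1;
        if (std::log(unif_rand()) < d) { tv(m) = t_new; win_acc_t(m) += 1;
          if (it >= burn_in) acc_t += 1; }
      }
    }

    // --- 8. likelihood-invariant recentering of log s (finite-sample location)
    {
      double mls = arma::mean(ls);
      ls -= mls;
      la += mls;
    }

    if (!la.is_finite() || !ls.is_finite() || !phi.is_finite())
      stop("non-finite sampler state at iteration %d", it + 1);

    // --- adaptation during burn-in (every 100 iterations)
    if (it < burn_in && (it + 1) % 100 == 0) {
      for (int j = 0; j < p; ++j)
        adapt_step(step_phi(j), win_acc_phi(j), (int)win_prop_phi(j), 0.35);
      adapt_step(step_la, win_acc_la, (int)win_prop_la, 0.35);
      for (int i = 0; i < n; ++i)
        adapt_step(step_ls(i), win_acc_ls(i), (int)win_prop_ls(i), 0.35);
      for (int m = 0; m < M; ++m)
        adapt_step(step_t(m), win_acc_t(m), (int)win_prop_t(m), 0.35);
      win_acc_phi.zeros(); win_prop_phi.zeros();
      win_acc_la = win_prop_la = 0;
      win_acc_ls.zeros(); win_prop_ls.zeros();
      win_acc_t.zeros(); win_prop_t.zeros();
    }

    // --- accumulate post burn-in
    if (it >= burn_in) {
      int b = it - burn_in;
      sum_la += la;
      for (int j = 0; j < p; ++j)
        for (int i = 0; i < n; ++i)
          if (is_zero(i, j) && eta(i, j)) sum_eta(i, j) += 1.0;
      pi_draws.row(b) = pi_v.t();
      phi_draws.row(b) = phi.t();
      ls_draws(b, arma::span::all) = ls.t();
    }
  }
  PutRNGstate();

  arma::mat z_mean = sum_la / (double)B;
  arma::mat p_eta = sum_eta / (double)B;   // meaningful only at zero cells

  return List::create(
    _["z_mean"] = z_mean,
    _["p_eta"] = p_eta,
    _["is_zero"] = is_zero,
    _["pi_draws"] = pi_draws,
    _["phi_draws"] = phi_draws,
    _["logs_draws"] = ls_draws,
    _["n_kept"] = B,
    _["acceptance"] = List::create(
      _["phi"] = prop_phi > 0 ? acc_phi / prop_phi : NA_REAL,
      _["log_alpha"] = prop_la > 0 ? acc_la / prop_la : NA_REAL,
      _["log_s"] = prop_ls > 0 ? acc_ls / prop_ls : NA_REAL,
      _["t_m"] = prop_t > 0 ? acc_t / prop_t : NA_REAL));
}
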