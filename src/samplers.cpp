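// Metropolis-within-Gibbs samplers for dynamic occupancy models:
//  - data-augmented multi-species multi-season community model
//  - single-species multi-season model with site random intercepts
// Latent occupancy chains are drawn exactly by forward filtering /
// backward sampling (FFBS); logit intercepts move by Gaussian random walk
// with proposal SDs adapted during burn-in; hyper-means are conjugate and
// hyper-SDs use a bounded slice sampler. All randomness goes through R's
// RNG so results are reproducible from set.seed().
#include <Rcpp.h>
using namespace Rcpp;

static inline double ilogit_c(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// FFBS for one two-state chain of length T.
// emis1[t] = p(y_t | z_t = 1) (binomial kernel, coefficient may be dropped),
// emis0[t] = p(y_t | z_t = 0) (1 if y_t == 0 else 0).
// phi, gamma have length T-1. Writes z[0..T-1]; returns marginal history
// probability (the forward normaliser) -- needed for the membership update.
static double ffbs_chain(int T, const double* emis0, const double* emis1,
                         double psi1, const double* phi, const double* gamma,
                         int* z) {
  double a0[16], a1[16]; // T is tiny (seasons); 16 is ample
  a0[0] = (1.0 - psi1) * emis0[0];
  a1[0] = psi1 * emis1[0];
  for (int t = 1; t < T; ++t) {
    a1[t] = (a0[t - 1] * gamma[t - 1] + a1[t - 1] * phi[t - 1]) * emis1[t];
    a0[t] = (a0[t - 1] * (1.0 - gamma[t - 1]) + a1[t - 1] * (1.0 - phi[t - 1])) * emis0[t];
  }
  double tot = a0[T - 1] + a1[T - 1];
  if (tot <= 0.0) return 0.0;
  z[T - 1] = (unif_rand() < a1[T - 1] / tot) ? 1 : 0;
  for (int t = T - 2; t >= 0; --t) {
    double w1, w0;
    if (z[t + 1] == 1) { w1 = a1[t] * phi[t];          w0 = a0[t] * gamma[t]; }
    else               { w1 = a1[t] * (1.0 - phi[t]);  w0 = a0[t] * (1.0 - gamma[t]); }
    z[t] = (unif_rand() < w1 / (w1 + w0)) ? 1 : 0;
  }
  return tot;
}

// forward marginal only (no sampling)
static double forward_prob(int T, const double* emis0, const double* emis1,
                           double psi1, const double* phi, const double* gamma) {
  double a0 = (1.0 - psi1) * emis0[0];
  double a1 = psi1 * emis1[0];
  for (int t = 1; t < T; ++t) {
    double n1 = (a0 * gamma[t - 1] + a1 * phi[t - 1]) * emis1[t];
    double n0 = (a0 * (1.0 - gamma[t - 1]) + a1 * (1.0 - phi[t - 1])) * emis0[t];
    a1 = n1; a0 = n0;
  }
  return a0 + a1;
}

// bounded stepping-out + shrinkage slice sampler for the hyper-SD
template <typename F>
static double slice_bounded(double x0, F logpost, double lower, double upper,
                            double w = 0.5) {
  double ly = logpost(x0) + std::log(unif_rand());
  double l = std::max(lower, x0 - unif_rand() * w);
  double r = std::min(upper, l + w);
  while (l > lower && logpost(l) > ly) l = std::max(lower, l - w);
  while (r < upper && logpost(r) > ly) r = std::min(upper, r + w);
  for (int it = 0; it < 1000; ++it) {
    double x = l + unif_rand() * (r - l);
    if (logpost(x) > ly) return x;
    if (x < x0) l = x; else r = x;
  }
  return x0;
}

// conjugate Normal mean + slice SD update for a logit-normal family
static void update_hyper(const std::vector<double>& e, double mu_prior_sd,
                         double sigma_max, double& mu, double& sigma) {
  int n = (int)e.size();
  if (n == 0) return;
  double s = 0.0;
  for (double v : e) s += v;
  if (sigma <= 0.0 || sigma >= sigma_max) sigma = sigma_max / 2.0;
  double post_var = 1.0 / (n / (sigma * sigma) + 1.0 / (mu_prior_sd * mu_prior_sd));
  mu = norm_rand() * std::sqrt(post_var) + post_var * s / (sigma * sigma);
  double mu_loc = mu;
  auto lp = [&](double sd) {
    if (sd <= 0.0 || sd >= sigma_max) return -std::numeric_limits<double>::infinity();
    double ll = -n * std::log(sd), inv = 1.0 / (2.0 * sd * sd);
    for (double v : e) { double d = v - mu_loc; ll -= d * d * inv; }
    return ll;
  };
  sigma = slice_bounded(sigma, lp, 1e-6, sigma_max);
}

// [[Rcpp::export]]
List community_mcmc_cpp(IntegerVector Y, IntegerMatrix K, int n_obs,
                        int n_iter, int n_burnin, int thin,
                        bool year_specific, double mu_prior_sd,
                        double sigma_max, double proposal_sd_init,
                        bool fix_effects, List fixed,
                        bool save_effects, bool save_z) {
  IntegerVector dims = Y.attr("dim");
  const int M = dims[0], J = dims[1], T = dims[2];
  const int nT = T, nTr = T - 1;
  auto yidx = [&](int i, int j, int t) { return i + M * (j + J * t); };

  // effect matrices (logit scale)
  std::vector<double> b0(M), a(M * nT), c(M * std::max(nTr, 1)),
      d(M * std::max(nTr, 1));
  // hyper: psi1 scalar family; p, gamma, phi either shared or per year
  const int nHp = year_specific ? nT : 1;
  const int nHt = year_specific ? std::max(nTr, 1) : 1;
  std::vector<double> mu_p(nHp, 0.0), sig_p(nHp, 1.0);
  std::vector<double> mu_g(nHt, -1.0), sig_g(nHt, 1.0);
  std::vector<double> mu_f(nHt, 0.0), sig_f(nHt, 1.0);
  double mu_psi = 0.0, sig_psi = 1.0;

  if (fix_effects) {
    NumericVector fb = fixed["b0"];
    NumericMatrix fa = fixed["a"], fc = fixed["c"], fd = fixed["d"];
    for (int i = 0; i < M; ++i) {
      b0[i] = fb[i];
      for (int t = 0; t < nT; ++t) a[i + M * t] = fa(i, t);
      for (int t = 0; t < nTr; ++t) { c[i + M * t] = fc(i, t); d[i + M * t] = fd(i, t); }
    }
  } else {
    for (int i = 0; i < M; ++i) {
      b0[i] = mu_psi + sig_psi * norm_rand();
      for (int t = 0; t < nT; ++t)
        a[i + M * t] = mu_p[year_specific ? t : 0] + sig_p[year_specific ? t : 0] * norm_rand();
      for (int t = 0; t < nTr; ++t) {
        c[i + M * t] = mu_g[year_specific ? t : 0] + sig_g[year_specific ? t : 0] * norm_rand();
        d[i + M * t] = mu_f[year_specific ? t : 0] + sig_f[year_specific ? t : 0] * norm_rand();
      }
    }
  }

  std::vector<int> z(M * J * T, 0), omega(M, 0);
  std::vector<int> detected(M, 0), sumY(M, 0);
  for (int i = 0; i < M; ++i) {
    long s = 0;
    for (int j = 0; j < J; ++j)
      for (int t = 0; t < T; ++t) s += Y[yidx(i, j, t)];
    sumY[i] = (int)s;
    detected[i] = s > 0;
    omega[i] = detected[i] ? 1 : (unif_rand() < 0.5 ? 1 : 0);
  }
  double Omega = 0.5;

  // adaptive proposal SDs per family
  double psd[4] = {proposal_sd_init, proposal_sd_init, proposal_sd_init,
                   proposal_sd_init};
  long acc[4] = {0, 0, 0, 0}, att[4] = {0, 0, 0, 0};

  const int n_save = (n_iter - n_burnin) / thin;
  if (n_save <= 0) stop("no post-burn-in draws: check n_iter/n_burnin/thin");
  NumericVector dOmega(n_save), dN(n_save);
  NumericMatrix dRich(n_save, T);
  IntegerMatrix dOmegaI(n_save, M);
  const int nHyp = 2 * (1 + nHp + 2 * nHt);
  NumericMatrix dHyper(n_save, nHyp);
  NumericMatrix dB0, dA, dC, dD;
  if (save_effects) {
    dB0 = NumericMatrix(n_save, M);
    dA = NumericMatrix(n_save, M * nT);
    dC = NumericMatrix(n_save, M * std::max(nTr, 1));
    dD = NumericMatrix(n_save, M * std::max(nTr, 1));
  }
  IntegerMatrix dZ;
  if (save_z) dZ = IntegerMatrix(n_save, M * J * T);

  std::vector<double> emis0(nT), emis1(nT), phi_i(std::max(nTr, 1)),
      gam_i(std::max(nTr, 1)), p_i(nT);
  int zbuf[16];
  int save_at = 0;

  for (int iter = 1; iter <= n_iter; ++iter) {
    // --- 1. latent states z and membership omega -------------------------
    for (int i = 0; i < M; ++i) {
      double psi1 = ilogit_c(b0[i]);
      for (int t = 0; t < nT; ++t) p_i[t] = ilogit_c(a[i + M * t]);
      for (int t = 0; t < nTr; ++t) {
        gam_i[t] = ilogit_c(c[i + M * t]);
        phi_i[t] = ilogit_c(d[i + M * t]);
      }
      if (!detected[i]) {
        // membership update for an all-zero species: P(y = 0 | member)
        double logL0 = 0.0;
        for (int j = 0; j < J; ++j) {
          for (int t = 0; t < nT; ++t) {
            int k = K(j, t);
            emis0[t] = 1.0;
            emis1[t] = std::pow(1.0 - p_i[t], (double)k);
          }
          logL0 += std::log(forward_prob(nT, emis0.data(), emis1.data(), psi1,
                                         phi_i.data(), gam_i.data()));
        }
        double lo = std::log(Omega) - std::log1p(-Omega) + logL0;
        double pr = 1.0 / (1.0 + std::exp(-lo));
        omega[i] = (Omega <= 0.0) ? 0 : ((unif_rand() < pr) ? 1 : 0);
      }
      if (omega[i] == 1) {
        for (int j = 0; j < J; ++j) {
          for (int t = 0; t < nT; ++t) {
            int y = Y[yidx(i, j, t)], k = K(j, t);
            emis0[t] = (y == 0) ? 1.0 : 0.0;
            emis1[t] = std::pow(p_i[t], (double)y) *
                       std::pow(1.0 - p_i[t], (double)(k - y));
          }
          ffbs_chain(nT, emis0.data(), emis1.data(), psi1, phi_i.data(),
                     gam_i.data(), zbuf);
          for (int t = 0; t < nT; ++t) z[yidx(i, j, t)] = zbuf[t];
        }
      } else {
        for (int j = 0; j < J; ++j)
          for (int t = 0; t < nT; ++t) z[yidx(i, j, t)] = 0;
      }
    }

    // --- 2. Omega | omega (conjugate Beta under Uniform(0,1)) -----------
    int s_om = 0;
    for (int i = 0; i < M; ++i) s_om += omega[i];
    Omega = R::rbeta(1.0 + s_om, 1.0 + (M - s_om));

    // --- 3. species effects ---------------------------------------------
    if (!fix_effects) {
      for (int i = 0; i < M; ++i) {
        if (omega[i] == 0) {
          // no data constrains this slot: refresh from the hyper-distribution
          b0[i] = mu_psi + sig_psi * norm_rand();
          for (int t = 0; t < nT; ++t) {
            int h = year_specific ? t : 0;
            a[i + M * t] = mu_p[h] + sig_p[h] * norm_rand();
          }
          for (int t = 0; t < nTr; ++t) {
            int h = year_specific ? t : 0;
            c[i + M * t] = mu_g[h] + sig_g[h] * norm_rand();
            d[i + M * t] = mu_f[h] + sig_f[h] * norm_rand();
          }
          continue;
        }
        // b0 (initial occupancy intercept)
        {
          int n1 = 0;
          for (int j = 0; j < J; ++j) n1 += z[yidx(i, j, 0)];
          double cur = b0[i], prop = cur + psd[0] * norm_rand();
          double pc = ilogit_c(cur), pp = ilogit_c(prop);
          double ll = n1 * (std::log(pp) - std::log(pc)) +
                      (J - n1) * (std::log1p(-pp) - std::log1p(-pc));
          double lpr = (R::dnorm(prop, mu_psi, sig_psi, 1) -
                        R::dnorm(cur, mu_psi, sig_psi, 1));
          ++att[0];
          if (std::log(unif_rand()) < ll + lpr) { b0[i] = prop; ++acc[0]; }
        }
        // a[i, t] (detection intercepts)
        for (int t = 0; t < nT; ++t) {
          int h = year_specific ? t : 0;
          long sy = 0, sk = 0;
          for (int j = 0; j < J; ++j)
            if (z[yidx(i, j, t)]) { sy += Y[yidx(i, j, t)]; sk += K(j, t); }
          double cur = a[i + M * t], prop = cur + psd[1] * norm_rand();
          double ll = 0.0;
          if (sk > 0) {
            double pc = ilogit_c(cur), pp = ilogit_c(prop);
            ll = sy * (std::log(pp) - std::log(pc)) +
                 (sk - sy) * (std::log1p(-pp) - std::log1p(-pc));
          }
          double lpr = R::dnorm(prop, mu_p[h], sig_p[h], 1) -
                       R::dnorm(cur, mu_p[h], sig_p[h], 1);
          ++att[1];
          if (std::log(unif_rand()) < ll + lpr) { a[i + M * t] = prop; ++acc[1]; }
        }
        // c (colonization) and d (persistence) per transition
        for (int t = 0; t < nTr; ++t) {
          int h = year_specific ? t : 0;
          int n0 = 0, n0c = 0, n1 = 0, n1p = 0;
          for (int j = 0; j < J; ++j) {
            if (z[yidx(i, j, t)]) { ++n1; n1p += z[yidx(i, j, t + 1)]; }
            else                  { ++n0; n0c += z[yidx(i, j, t + 1)]; }
          }
          { // gamma
            double cur = c[i + M * t], prop = cur + psd[2] * norm_rand();
            double ll = 0.0;
            if (n0 > 0) {
              double gc = ilogit_c(cur), gp = ilogit_c(prop);
              ll = n0c * (std::log(gp) - std::log(gc)) +
                   (n0 - n0c) * (std::log1p(-gp) - std::log1p(-gc));
            }
            double lpr = R::dnorm(prop, mu_g[h], sig_g[h], 1) -
                         R::dnorm(cur, mu_g[h], sig_g[h], 1);
            ++att[2];
            if (std::log(unif_rand()) < ll + lpr) { c[i + M * t] = prop; ++acc[2]; }
          }
          { // phi
            double cur = d[i + M * t], prop = cur + psd[3] * norm_rand();
            double ll = 0.0;
            if (n1 > 0) {
              double fc = ilogit_c(cur), fp = ilogit_c(prop);
              ll = n1p * (std::log(fp) - std::log(fc)) +
                   (n1 - n1p) * (std::log1p(-fp) - std::log1p(-fc));
            }
            double lpr = R::dnorm(prop, mu_f[h], sig_f[h], 1) -
                         R::dnorm(cur, mu_f[h], sig_f[h], 1);
            ++att[3];
            if (std::log(unif_rand()) < ll + lpr) { d[i + M * t] = prop; ++acc[3]; }
          }
        }
      }

      // --- 4. hyperparameters -------------------------------------------
      {
        std::vector<double> e(b0.begin(), b0.end());
        update_hyper(e, mu_prior_sd, sigma_max, mu_psi, sig_psi);
      }
      for (int h = 0; h < nHp; ++h) {
        std::vector<double> e;
        for (int t = 0; t < nT; ++t)
          if (!year_specific || t == h)
            for (int i = 0; i < M; ++i) e.push_back(a[i + M * t]);
        update_hyper(e, mu_prior_sd, sigma_max, mu_p[h], sig_p[h]);
      }
      for (int h = 0; h < nHt; ++h) {
        std::vector<double> eg, ef;
        for (int t = 0; t < nTr; ++t)
          if (!year_specific || t == h)
            for (int i = 0; i < M; ++i) {
              eg.push_back(c[i + M * t]);
              ef.push_back(d[i + M * t]);
            }
        update_hyper(eg, mu_prior_sd, sigma_max, mu_g[h], sig_g[h]);
        update_hyper(ef, mu_prior_sd, sigma_max, mu_f[h], sig_f[h]);
      }

      // --- adaptation during burn-in ------------------------------------
      if (iter <= n_burnin && iter % 50 == 0) {
        for (int f = 0; f < 4; ++f) {
          if (att[f] > 0) {
            double rate = (double)acc[f] / (double)att[f];
            psd[f] *= std::exp(0.66 * (rate - 0.38));
            psd[f] = std::min(std::max(psd[f], 0.01), 10.0);
          }
          acc[f] = 0; att[f] = 0;
        }
      }
    }

    // --- 5. save ---------------------------------------------------------
    if (iter > n_burnin && (iter - n_burnin) % thin == 0) {
      dOmega[save_at] = Omega;
      int N = 0;
      for (int i = 0; i < M; ++i) { N += omega[i]; dOmegaI(save_at, i) = omega[i]; }
      dN[save_at] = N;
      for (int t = 0; t < T; ++t) {
        int r = 0;
        for (int i = 0; i < M; ++i) {
          if (!omega[i]) continue;
          for (int j = 0; j < J; ++j)
            if (z[yidx(i, j, t)]) { ++r; break; }
        }
        dRich(save_at, t) = r;
      }
      int col = 0;
      dHyper(save_at, col++) = mu_psi; dHyper(save_at, col++) = sig_psi;
      for (int h = 0; h < nHp; ++h) { dHyper(save_at, col++) = mu_p[h]; dHyper(save_at, col++) = sig_p[h]; }
      for (int h = 0; h < nHt; ++h) { dHyper(save_at, col++) = mu_g[h]; dHyper(save_at, col++) = sig_g[h]; }
      for (int h = 0; h < nHt; ++h) { dHyper(save_at, col++) = mu_f[h]; dHyper(save_at, col++) = sig_f[h]; }
      if (save_effects) {
        for (int i = 0; i < M; ++i) dB0(save_at, i) = b0[i];
        for (int q = 0; q < M * nT; ++q) dA(save_at, q) = a[q];
        for (int q = 0; q < M * nTr; ++q) { dC(save_at, q) = c[q]; dD(save_at, q) = d[q]; }
      }
      if (save_z)
        for (int q = 0; q < M * J * T; ++q) dZ(save_at, q) = z[q];
      ++save_at;
    }
  }

  List out = List::create(
      _["Omega"] = dOmega, _["N"] = dN, _["richness"] = dRich,
      _["omega"] = dOmegaI, _["hyper"] = dHyper,
      _["proposal_sd"] = NumericVector(psd, psd + 4));
  if (save_effects) {
    out["b0"] = dB0; out["a"] = dA; out["c"] = dC; out["d"] = dD;
  }
  if (save_z) out["z"] = dZ;
  return out;
}

// Single-species dynamic occupancy: scalar initial occupancy psi1 and
// per-transition persistence/colonization with Uniform(0,1) priors
// (conjugate Beta updates given the latent states); detection has
// site-level random logit intercepts a_j ~ N(alpha0, sigma_a0^2) updated
// by random-walk Metropolis with the usual conjugate/slice hyper update.
// [[Rcpp::export]]
List species_mcmc_cpp(IntegerMatrix y, IntegerMatrix K,
                      int n_iter, int n_burnin, int thin,
                      double mu_prior_sd, double sigma_max,
                      double proposal_sd_init) {
  const int J = y.nrow(), T = y.ncol(), nTr = T - 1;
  std::vector<double> a(J, 0.0);
  double psi1 = 0.5, alpha0 = 0.0, sig_a = 1.0;
  std::vector<double> phi_v(std::max(nTr, 1), 0.5),
      gam_v(std::max(nTr, 1), 0.2);
  std::vector<int> z(J * T, 1);

  double psd = proposal_sd_init;
  long acc = 0, att = 0;

  const int n_save = (n_iter - n_burnin) / thin;
  if (n_save <= 0) stop("no post-burn-in draws: check n_iter/n_burnin/thin");
  const int npar = 3 + 2 * std::max(nTr, 0);
  NumericMatrix draws(n_save, npar);
  NumericMatrix dZocc(n_save, T); // fraction of sites occupied (for checks)

  std::vector<double> emis0(T), emis1(T);
  int zbuf[16];
  int save_at = 0;

  for (int iter = 1; iter <= n_iter; ++iter) {
    // 1. latent states by FFBS per site
    for (int j = 0; j < J; ++j) {
      double p_j = ilogit_c(a[j]);
      for (int t = 0; t < T; ++t) {
        int yy = y(j, t), k = K(j, t);
        emis0[t] = (yy == 0) ? 1.0 : 0.0;
        emis1[t] = std::pow(p_j, (double)yy) * std::pow(1.0 - p_j, (double)(k - yy));
      }
      ffbs_chain(T, emis0.data(), emis1.data(), psi1, phi_v.data(),
                 gam_v.data(), zbuf);
      for (int t = 0; t < T; ++t) z[j + J * t] = zbuf[t];
    }
    // 2. psi1 | z (conjugate Beta under Uniform(0,1))
    {
      int s1 = 0;
      for (int j = 0; j < J; ++j) s1 += z[j];
      psi1 = R::rbeta(1.0 + s1, 1.0 + (J - s1));
    }
    // 3. dynamics | z (conjugate Beta per transition)
    for (int t = 0; t < nTr; ++t) {
      int n0 = 0, n0c = 0, n1 = 0, n1p = 0;
      for (int j = 0; j < J; ++j) {
        if (z[j + J * t]) { ++n1; n1p += z[j + J * (t + 1)]; }
        else             { ++n0; n0c += z[j + J * (t + 1)]; }
      }
      gam_v[t] = R::rbeta(1.0 + n0c, 1.0 + (n0 - n0c));
      phi_v[t] = R::rbeta(1.0 + n1p, 1.0 + (n1 - n1p));
    }
    // 4. site detection intercepts (binomial over occupied seasons)
    for (int j = 0; j < J; ++j) {
      long sy = 0, sk = 0;
      for (int t = 0; t < T; ++t)
        if (z[j + J * t]) { sy += y(j, t); sk += K(j, t); }
      double cur = a[j], prop = cur + psd * norm_rand();
      double ll = 0.0;
      if (sk > 0) {
        double pc = ilogit_c(cur), pp = ilogit_c(prop);
        ll = sy * (std::log(pp) - std::log(pc)) +
             (sk - sy) * (std::log1p(-pp) - std::log1p(-pc));
      }
      double lpr = R::dnorm(prop, alpha0, sig_a, 1) - R::dnorm(cur, alpha0, sig_a, 1);
      ++att;
      if (std::log(unif_rand()) < ll + lpr) { a[j] = prop; ++acc; }
    }
    // 5. detection hyperparameters
    update_hyper(a, mu_prior_sd, sigma_max, alpha0, sig_a);
    // adaptation during burn-in
    if (iter <= n_burnin && iter % 50 == 0 && att > 0) {
      double rate = (double)acc / (double)att;
      psd *= std::exp(0.66 * (rate - 0.38));
      psd = std::min(std::max(psd, 0.01), 10.0);
      acc = 0; att = 0;
    }
    // save
    if (iter > n_burnin && (iter - n_burnin) % thin == 0) {
      int col = 0;
      draws(save_at, col++) = psi1;
      draws(save_at, col++) = alpha0; draws(save_at, col++) = sig_a;
      for (int t = 0; t < nTr; ++t) draws(save_at, col++) = gam_v[t];
      for (int t = 0; t < nTr; ++t) draws(save_at, col++) = phi_v[t];
      for (int t = 0; t < T; ++t) {
        int r = 0;
        for (int j = 0; j < J; ++j) r += z[j + J * t];
        dZocc(save_at, t) = (double)r / J;
      }
      ++save_at;
    }
  }
  return List::create(_["draws"] = draws, _["z_occ"] = dZocc,
                      _["proposal_sd"] = psd);
}
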