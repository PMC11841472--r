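// Stochastic mean-field variational inference for the hierarchical
// multidimensional nominal categories model.
//
// Latent variables: Theta (S x D), A (D x IC), b (IC), plus unconstrained
// surrogates u (D) and v (1) mapped to the positive prior scales alpha_d and
// beta via the softplus bijection.  The variational family is a fully
// factorized normal over all of these; the ELBO is estimated with
// reparameterized Monte-Carlo samples of the log joint plus the closed-form
// Gaussian entropy, and maximized with Adam under a decaying learning-rate
// schedule.

#include <RcppArmadillo.h>
#include <random>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double softplus(double x) {
  return x > 30.0 ? x : std::log1p(std::exp(x));
}
static inline double sigmoid(double x) {
  return x >= 0.0 ? 1.0 / (1.0 + std::exp(-x))
                  : std::exp(x) / (1.0 + std::exp(x));
}
// log sigmoid, stable
static inline double log_sigmoid(double x) {
  return x >= 0.0 ? -std::log1p(std::exp(-x)) : x - std::log1p(std::exp(x));
}

// [[Rcpp::export]]
Rcpp::List svi_fit_cpp(const Rcpp::IntegerMatrix R_, const int C, const int D,
                       const double hc_a, const double hc_b,
                       const arma::mat& th_mu0, const arma::mat& a_mu0,
                       const arma::vec& b_mu0, const arma::vec& u_mu0,
                       const double v_mu0, const double init_sd,
                       const int n_steps, const double lr_peak,
                       const std::string schedule, const int n_mc,
                       const int seed) {
  const int S = R_.nrow(), I = R_.ncol(), IC = I * C;
  const int n_th = S * D, n_a = D * IC, n_b = IC, n_u = D;
  const int n_scalar = n_th + n_a + n_b + n_u + 1;
  const int n_par = 2 * n_scalar;

  // packed parameter vector: [mu block | omega block], omega = log sd
  vec par(n_par, fill::zeros), grad(n_par, fill::zeros);
  const int o_th = 0, o_a = n_th, o_b = n_th + n_a, o_u = n_th + n_a + n_b,
            o_v = n_th + n_a + n_b + n_u;
  // aliases into the mu block
  mat th_mu(par.memptr() + o_th, S, D, false, true);
  mat a_mu(par.memptr() + o_a, D, IC, false, true);
  vec b_mu(par.memptr() + o_b, IC, false, true);
  vec u_mu(par.memptr() + o_u, D, false, true);
  th_mu = th_mu0; a_mu = a_mu0; b_mu = b_mu0; u_mu = u_mu0;
  par(o_v) = v_mu0;
  par.subvec(n_scalar, n_par - 1).fill(std::log(init_sd));
  vec om = par.subvec(n_scalar, n_par - 1);  // copy; refreshed each step

  // Adam state
  vec adam_m(n_par, fill::zeros), adam_v(n_par, fill::zeros);
  const double b1 = 0.9, b2 = 0.999, adam_eps = 1e-8;

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> N01(0.0, 1.0);

  // workspaces
  mat z_th(S, D), e_th(S, D), a_z(D, IC), e_a(D, IC), T(S, IC);
  vec b_z(IC), e_b(IC), u_z(D), e_u(D);
  mat g_th(S, D), g_a(D, IC);
  vec g_b(IC), g_u(D);
  vec elbo_trace(n_steps);

  const double LOG2PI = std::log(2.0 * M_PI);
  const double ent_const = 0.5 * n_scalar * (LOG2PI + 1.0);

  for (int step = 0; step < n_steps; ++step) {
    double frac = static_cast<double>(step) / n_steps;
    double lr;
    if (schedule == "cosine")      lr = 0.5 * lr_peak * (1.0 + std::cos(M_PI * frac));
    else if (schedule == "constant") lr = lr_peak;
    else                           lr = lr_peak * (1.0 - frac);

    om = par.subvec(n_scalar, n_par - 1);
    vec sd_all = exp(om);
    mat th_sd(sd_all.memptr() + o_th, S, D, false, true);
    mat a_sd(sd_all.memptr() + o_a, D, IC, false, true);
    vec b_sd(sd_all.memptr() + o_b, IC, false, true);
    vec u_sd(sd_all.memptr() + o_u, D, false, true);
    double v_sd = sd_all(o_v);

    grad.zeros();
    double elbo_logp = 0.0;

    for (int mc = 0; mc < n_mc; ++mc) {
      // --- reparameterized sample of every latent scalar ---
      for (int j = 0; j < n_th; ++j) e_th(j) = N01(rng);
      for (int j = 0; j < n_a; ++j) e_a(j) = N01(rng);
      for (int j = 0; j < n_b; ++j) e_b(j) = N01(rng);
      for (int j = 0; j < n_u; ++j) e_u(j) = N01(rng);
      double e_v = N01(rng);
      z_th = th_mu + th_sd % e_th;
      a_z = a_mu + a_sd % e_a;
      b_z = b_mu + b_sd % e_b;
      u_z = u_mu + u_sd % e_u;
      double v_z = par(o_v) + v_sd * e_v;

      vec alpha(D);
      for (int d = 0; d < D; ++d) alpha(d) = softplus(u_z(d));
      double beta = softplus(v_z);

      // --- likelihood: tendencies, then a single fused pass per item doing
      // stable softmax, log-likelihood and G = Y - P in place (the array is
      // large; minimizing sweeps over it dominates the step cost) ---
      T = z_th * a_z;
      T.each_row() += b_z.t();
      double loglik = 0.0;
      std::vector<double*> colp(C);
      std::vector<double> v(C);
      for (int i = 0; i < I; ++i) {
        for (int c = 0; c < C; ++c) colp[c] = T.colptr(i * C + c);
        const int* rcol = &R_(0, i);
        for (int s = 0; s < S; ++s) {
          double mx = colp[0][s];
          for (int c = 1; c < C; ++c) if (colp[c][s] > mx) mx = colp[c][s];
          double sum = 0.0;
          for (int c = 0; c < C; ++c) { v[c] = std::exp(colp[c][s] - mx); sum += v[c]; }
          const int r = rcol[s];
          if (r > 0) {
            const double inv = 1.0 / sum;
            loglik += std::log(v[r - 1] * inv);
            for (int c = 0; c < C; ++c) colp[c][s] = -v[c] * inv;  // -P
            colp[r - 1][s] += 1.0;                                 // G = Y - P
          } else {
            for (int c = 0; c < C; ++c) colp[c][s] = 0.0;  // missing
          }
        }
      }

      // --- gradients of the log joint wrt sampled latents ---
      g_th = T * a_z.t() - z_th;                 // likelihood + N(0,1) prior
      g_a = z_th.t() * T;
      double logp_prior = -0.5 * dot(z_th, z_th) - 0.5 * n_th * LOG2PI;
      for (int d = 0; d < D; ++d) {
        double al = alpha(d), al2 = al * al;
        double ssq = dot(a_z.row(d), a_z.row(d));
        g_a.row(d) -= a_z.row(d) / al2;
        double dl_dalpha = -IC / al + ssq / (al2 * al)
                           - 2.0 * al / (hc_a * hc_a + al2);
        double sg = sigmoid(u_z(d));
        g_u(d) = dl_dalpha * sg + (1.0 - sg);
        logp_prior += -IC * std::log(al) - 0.5 * ssq / al2 - 0.5 * IC * LOG2PI
                      + std::log(2.0 / (M_PI * hc_a)) - std::log1p(al2 / (hc_a * hc_a))
                      + log_sigmoid(u_z(d));
      }
      {
        double be = beta, be2 = be * be;
        double ssqb = dot(b_z, b_z);
        g_b = sum(T, 0).t() - b_z / be2;
        double dl_dbeta = -IC / be + ssqb / (be2 * be)
                          - 2.0 * be / (hc_b * hc_b + be2);
        double sg = sigmoid(v_z);
        double g_v = dl_dbeta * sg + (1.0 - sg);
        logp_prior += -IC * std::log(be) - 0.5 * ssqb / be2 - 0.5 * IC * LOG2PI
                      + std::log(2.0 / (M_PI * hc_b)) - std::log1p(be2 / (hc_b * hc_b))
                      + log_sigmoid(v_z);

        // --- accumulate packed gradient ---
        double* g = grad.memptr();
        const double* gt = g_th.memptr();
        const double* et = e_th.memptr();
        const double* sdp = sd_all.memptr();
        for (int j = 0; j < n_th; ++j) {
          g[o_th + j] += gt[j];
          g[n_scalar + o_th + j] += gt[j] * et[j] * sdp[o_th + j];
        }
        const double* ga = g_a.memptr(); const double* ea = e_a.memptr();
        for (int j = 0; j < n_a; ++j) {
          g[o_a + j] += ga[j];
          g[n_scalar + o_a + j] += ga[j] * ea[j] * sdp[o_a + j];
        }
        for (int j = 0; j < n_b; ++j) {
          g[o_b + j] += g_b(j);
          g[n_scalar + o_b + j] += g_b(j) * e_b(j) * sdp[o_b + j];
        }
        for (int j = 0; j < n_u; ++j) {
          g[o_u + j] += g_u(j);
          g[n_scalar + o_u + j] += g_u(j) * e_u(j) * sdp[o_u + j];
        }
        g[o_v] += g_v;
        g[n_scalar + o_v] += g_v * e_v * v_sd;
      }
      elbo_logp += loglik + logp_prior;
    }

    grad /= n_mc;
    // entropy gradient: dH/d omega = 1 for every scalar
    grad.subvec(n_scalar, n_par - 1) += 1.0;
    double elbo = elbo_logp / n_mc + accu(om) + ent_const;
    elbo_trace(step) = elbo;
    if (!std::isfinite(elbo))
      Rcpp::stop("non-finite ELBO at step %d (learning rate %g)", step + 1, lr);

    // --- Adam ascent ---
    double bc1 = 1.0 - std::pow(b1, step + 1), bc2 = 1.0 - std::pow(b2, step + 1);
    double* p = par.memptr(); double* g = grad.memptr();
    double* am = adam_m.memptr(); double* av = adam_v.memptr();
    for (int j = 0; j < n_par; ++j) {
      am[j] = b1 * am[j] + (1.0 - b1) * g[j];
      av[j] = b2 * av[j] + (1.0 - b2) * g[j] * g[j];
      p[j] += lr * (am[j] / bc1) / (std::sqrt(av[j] / bc2) + adam_eps);
    }
    if (step % 512 == 0) Rcpp::checkUserInterrupt();
  }

  vec om_f = par.subvec(n_scalar, n_par - 1);
  vec sd_f = exp(om_f);
  return Rcpp::List::create(
    Rcpp::Named("theta_mu") = mat(par.memptr() + o_th, S, D),
    Rcpp::Named("theta_sd") = mat(sd_f.memptr() + o_th, S, D),
    Rcpp::Named("a_mu") = mat(par.memptr() + o_a, D, IC),
    Rcpp::Named("a_sd") = mat(sd_f.memptr() + o_a, D, IC),
    Rcpp::Named("b_mu") = vec(par.memptr() + o_b, IC),
    Rcpp::Named("b_sd") = vec(sd_f.memptr() + o_b, IC),
    Rcpp::Named("u_mu") = vec(par.memptr() + o_u, D),
    Rcpp::Named("u_sd") = vec(sd_f.memptr() + o_u, D),
    Rcpp::Named("v_mu") = par(o_v),
    Rcpp::Named("v_sd") = sd_f(o_v),
    Rcpp::Named("elbo") = elbo_trace);
}
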