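// Conjugate Gibbs sampler for the hierarchical multivariate-normal model of
// the five speech-rating series. Each (subject, item) observation is a
// 5-vector drawn from N(mu_s, Sigma_{s,c}) where the condition c (positive
// vs neutral feedback) selects the subject-level covariance, the y3
// component of mu_s is fixed (the judges' mean is experimenter-controlled),
// and the remaining four means are partially pooled across subjects.
//
// Conjugate structure:
//   P_{s,c} = Sigma_{s,c}^{-1} ~ Wishart(nu0, (nu0 * Lambda_c)^{-1})
//     so E[P_{s,c}] = Lambda_c^{-1}: Lambda_c is a group-level covariance
//     scale shared by all subjects in condition c (partial pooling).
//   Lambda_c ~ Wishart(a0, B0)
//   mu_{s,free} ~ N(eta, diag(sigma^2)); eta_j ~ N(m0, v0);
//   sigma_j^2 ~ Inv-Gamma(s_shape, s_rate)
//
// Observations labelled 2 ("zero prediction error", PE-split model only)
// use a covariance built from the element-wise average of the two
// conditions' tau and Omega; they inform the mean update but not the
// condition-specific Wishart updates (keeps every step exact).
//
// All randomness flows through R's RNG so results are reproducible with
// set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const int P = 5;

// Lower-triangular Bartlett factor draw: W = L A A' L' ~ Wishart(df, Scale)
// with Scale = L L'.
static mat rwishart(double df, const mat &scale_chol_lower) {
  mat A(P, P, fill::zeros);
  for (int i = 0; i < P; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  mat LA = scale_chol_lower * A;
  return LA * LA.t();
}

static mat chol_lower_safe(mat m) {
  mat L;
  double ridge = 0.0;
  for (int k = 0; k < 6; ++k) {
    if (chol(L, m + ridge * eye(P, P), "lower")) return L;
    ridge = (ridge == 0.0) ? 1e-10 : ridge * 100;
  }
  Rcpp::stop("Cholesky factorization failed (matrix not positive definite).");
  return L;
}

static mat chol_lower_safe_k(mat m, int k) {
  mat L;
  double ridge = 0.0;
  for (int t = 0; t < 6; ++t) {
    if (chol(L, m + ridge * eye(k, k), "lower")) return L;
    ridge = (ridge == 0.0) ? 1e-10 : ridge * 100;
  }
  Rcpp::stop("Cholesky factorization failed (matrix not positive definite).");
  return L;
}

// Sigma built from the element-wise average of the two conditions' tau and
// Omega (zero-PE observations in the PE-split model).
static mat averaged_sigma(const mat &sig_pos, const mat &sig_neu) {
  vec tau_pos = sqrt(sig_pos.diag());
  vec tau_neu = sqrt(sig_neu.diag());
  mat om_pos = sig_pos / (tau_pos * tau_pos.t());
  mat om_neu = sig_neu / (tau_neu * tau_neu.t());
  vec tau_avg = 0.5 * (tau_pos + tau_neu);
  mat om_avg = 0.5 * (om_pos + om_neu);
  return diagmat(tau_avg) * om_avg * diagmat(tau_avg);
}

// [[Rcpp::export]]
Rcpp::List gibbs_chain_cpp(const arma::mat &Y,
                           const arma::ivec &subj,  // 0-based subject index
                           const arma::ivec &lab,   // 0 neutral, 1 positive, 2 zero-PE
                           const arma::vec &mu3,    // fixed y3 mean per label
                           int S,
                           int n_warmup, int n_keep, int thin,
                           double nu0, double a0, const arma::mat &B0,
                           const arma::vec &m0, double v0,
                           double s_shape, double s_rate,
                           const arma::mat &Yeval,
                           const arma::ivec &subj_eval,
                           const arma::ivec &lab_eval,
                           bool compute_loglik) {
  const int n = Y.n_rows;
  const uvec free_idx = {0, 1, 3, 4};

  // sufficient statistics per subject x label
  cube Csl(P, P, S * 3, fill::zeros);
  mat sum_sl(P, S * 3, fill::zeros);
  ivec n_sl(S * 3, fill::zeros);
  for (int i = 0; i < n; ++i) {
    int g = subj(i) * 3 + lab(i);
    vec y = Y.row(i).t();
    Csl.slice(g) += y * y.t();
    sum_sl.col(g) += y;
    n_sl(g) += 1;
  }

  // initial values: empirical means, prior-mean covariances, chain jitter
  mat mu_free(4, S);
  for (int s = 0; s < S; ++s) {
    vec tot(P, fill::zeros);
    int cnt = 0;
    for (int l = 0; l < 3; ++l) {
      tot += sum_sl.col(s * 3 + l);
      cnt += n_sl(s * 3 + l);
    }
    vec m = (cnt > 0) ? vec(tot / cnt) : vec(P, fill::value(5.0));
    for (int j = 0; j < 4; ++j)
      mu_free(j, s) = m(free_idx(j)) + 0.2 * R::norm_rand();
  }
  mat Lambda[2];
  Lambda[0] = a0 * B0;
  Lambda[1] = a0 * B0;
  cube Pmat(P, P, S * 2);
  for (int s = 0; s < S; ++s)
    for (int c = 0; c < 2; ++c)
      Pmat.slice(s * 2 + c) = inv_sympd(Lambda[c]);
  vec eta = m0;
  vec sig2(4, fill::value(1.0));

  // eval-point grouping for pointwise log-likelihood
  const int n_eval = compute_loglik ? Yeval.n_rows : 0;

  // draw storage
  cube mu_draws(n_keep, S, 4);
  cube tau_draws[2] = {cube(n_keep, S, P), cube(n_keep, S, P)};
  cube omega_draws[2] = {cube(n_keep, S, 10), cube(n_keep, S, 10)};
  mat eta_draws(n_keep, 4);
  mat sig_draws(n_keep, 4);
  mat loglik_draws(compute_loglik ? n_keep : 0, n_eval);

  const int total_iter = n_warmup + n_keep * thin;
  int kept = 0;

  // upper-triangle cell order for omega storage
  int oi[10], oj[10], t = 0;
  for (int i = 0; i < P - 1; ++i)
    for (int j = i + 1; j < P; ++j) {
      oi[t] = i; oj[t] = j; ++t;
    }

  for (int iter = 0; iter < total_iter; ++iter) {
    // --- subject precision matrices ---
    for (int s = 0; s < S; ++s) {
      for (int c = 0; c < 2; ++c) {
        int g = s * 3 + c;
        int nsc = n_sl(g);
        vec mu_full(P);
        mu_full(0) = mu_free(0, s); mu_full(1) = mu_free(1, s);
        mu_full(2) = mu3(c);
        mu_full(3) = mu_free(2, s); mu_full(4) = mu_free(3, s);
        mat Ssc(P, P, fill::zeros);
        if (nsc > 0) {
          vec sy = sum_sl.col(g);
          Ssc = Csl.slice(g) - mu_full * sy.t() - sy * mu_full.t() +
            nsc * (mu_full * mu_full.t());
        }
        mat post_scale_inv = nu0 * Lambda[c] + Ssc;
        mat scale = inv_sympd((post_scale_inv + post_scale_inv.t()) / 2.0);
        Pmat.slice(s * 2 + c) =
          rwishart(nu0 + nsc, chol_lower_safe(scale));
      }
    }

    // --- group-level covariance scales ---
    for (int c = 0; c < 2; ++c) {
      mat acc = inv_sympd(B0);
      for (int s = 0; s < S; ++s) acc += nu0 * Pmat.slice(s * 2 + c);
      mat scale = inv_sympd((acc + acc.t()) / 2.0);
      Lambda[c] = rwishart(a0 + S * nu0, chol_lower_safe(scale));
    }

    // --- subject means (free components) ---
    for (int s = 0; s < S; ++s) {
      mat prec(4, 4, fill::zeros);
      prec.diag() = 1.0 / sig2;
      vec rhs = eta / sig2;
      for (int l = 0; l < 3; ++l) {
        int g = s * 3 + l;
        int nsl_ = n_sl(g);
        if (nsl_ == 0) continue;
        mat Pl;
        if (l < 2) {
          Pl = Pmat.slice(s * 2 + l);
        } else {
          mat sig_pos = inv_sympd(Pmat.slice(s * 2 + 1));
          mat sig_neu = inv_sympd(Pmat.slice(s * 2 + 0));
          Pl = inv_sympd(averaged_sigma(sig_pos, sig_neu));
        }
        vec adj = sum_sl.col(g);
        adj(2) -= nsl_ * mu3(l);
        vec pv = Pl * adj;
        prec += nsl_ * Pl.submat(free_idx, free_idx);
        rhs += pv.elem(free_idx);
      }
      mat cov = inv_sympd((prec + prec.t()) / 2.0);
      vec mean = cov * rhs;
      mat Lc = chol_lower_safe_k(cov, 4);
      vec z(4);
      for (int j = 0; j < 4; ++j) z(j) = R::norm_rand();
      mu_free.col(s) = mean + Lc * z;
    }

    // --- group-level mean hyperparameters ---
    for (int j = 0; j < 4; ++j) {
      double prec_post = S / sig2(j) + 1.0 / v0;
      double mean_post =
        (accu(mu_free.row(j)) / sig2(j) + m0(j) / v0) / prec_post;
      eta(j) = mean_post + R::norm_rand() / std::sqrt(prec_post);
      double ss = 0.0;
      for (int s = 0; s < S; ++s)
        ss += std::pow(mu_free(j, s) - eta(j), 2);
      double shape_post = s_shape + S / 2.0;
      double rate_post = s_rate + 0.5 * ss;
      sig2(j) = rate_post / R::rgamma(shape_post, 1.0);
    }

    // --- store ---
    if (iter >= n_warmup && (iter - n_warmup) % thin == 0) {
      for (int s = 0; s < S; ++s) {
        for (int j = 0; j < 4; ++j) mu_draws(kept, s, j) = mu_free(j, s);
        for (int c = 0; c < 2; ++c) {
          mat sig = inv_sympd(Pmat.slice(s * 2 + c));
          vec tau = sqrt(sig.diag());
          for (int j = 0; j < P; ++j) tau_draws[c](kept, s, j) = tau(j);
          for (int u = 0; u < 10; ++u)
            omega_draws[c](kept, s, u) =
              sig(oi[u], oj[u]) / (tau(oi[u]) * tau(oj[u]));
        }
      }
      for (int j = 0; j < 4; ++j) {
        eta_draws(kept, j) = eta(j);
        sig_draws(kept, j) = sig2(j);
      }

      if (compute_loglik && n_eval > 0) {
        // per-(subject, label) Cholesky factors for this draw
        for (int i = 0; i < n_eval; ++i) loglik_draws(kept, i) = NA_REAL;
        std::vector<mat> Lfac(S * 3);
        std::vector<bool> have(S * 3, false);
        for (int i = 0; i < n_eval; ++i) {
          int s = subj_eval(i), l = lab_eval(i);
          int g = s * 3 + l;
          if (!have[g]) {
            mat sig;
            if (l < 2) {
              sig = inv_sympd(Pmat.slice(s * 2 + l));
            } else {
              sig = averaged_sigma(inv_sympd(Pmat.slice(s * 2 + 1)),
                                   inv_sympd(Pmat.slice(s * 2 + 0)));
            }
            Lfac[g] = chol_lower_safe(sig);
            have[g] = true;
          }
          vec mu_full(P);
          mu_full(0) = mu_free(0, s); mu_full(1) = mu_free(1, s);
          mu_full(2) = mu3(l);
          mu_full(3) = mu_free(2, s); mu_full(4) = mu_free(3, s);
          vec d = Yeval.row(i).t() - mu_full;
          vec w = solve(trimatl(Lfac[g]), d);
          double logdet = 2.0 * accu(log(Lfac[g].diag()));
          loglik_draws(kept, i) =
            -0.5 * (P * std::log(2.0 * M_PI) + logdet + dot(w, w));
        }
      }
      ++kept;
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("mu") = mu_draws,
    Rcpp::Named("tau_neu") = tau_draws[0],
    Rcpp::Named("tau_pos") = tau_draws[1],
    Rcpp::Named("omega_neu") = omega_draws[0],
    Rcpp::Named("omega_pos") = omega_draws[1],
    Rcpp::Named("eta") = eta_draws,
    Rcpp::Named("sigma2") = sig_draws,
    Rcpp::Named("loglik") = loglik_draws);
}
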