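// Gibbs sampler for the mixed-effects location-scale model:
//   y_sit = alpha_si + gamma_s' z_it + e_sit,  e_sit ~ N(0, exp(omega_si))
//   eta_i = (alpha_i, omega_i) ~ MVN(B x_i, Psi)
// All conditionals are conjugate except omega (componentwise random-walk
// Metropolis with step sizes adapted during burn-in only).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static double rnorm1() { return R::rnorm(0.0, 1.0); }

// draw from Wishart(df, V) by Bartlett decomposition
static mat rwishart(double df, const mat &V) {
  int p = V.n_rows;
  mat L = chol(V, "lower");
  mat A(p, p, fill::zeros);
  for (int i = 0; i < p; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = rnorm1();
  }
  mat LA = L * A;
  return LA * LA.t();
}

// draw from N(P^{-1} h, P^{-1}) given precision P and linear term h
static vec rmvnorm_prec(const mat &P, const vec &h) {
  mat Rc = chol(symmatu(P));          // upper, P = Rc' Rc
  vec z(h.n_elem);
  for (uword j = 0; j < z.n_elem; ++j) z(j) = rnorm1();
  vec mu = solve(symmatu(P), h);
  return mu + solve(trimatu(Rc), z);
}

// [[Rcpp::export]]
List melsm_gibbs_chain(const arma::mat &X, List obs, int S, bool hetero,
                       arma::mat eta, arma::mat B, arma::mat gamma,
                       arma::mat Psi, arma::vec sig2,
                       int iter, int burn,
                       double coef_prec, const arma::mat &psi_scale,
                       double psi_df) {
  const int N = X.n_rows, K = X.n_cols, q = hetero ? 2 * S : S;
  const int kept = iter - burn;
  // unpack observation blocks: per outcome, person-sorted y/z with offsets
  std::vector<vec> ys(S);
  std::vector<mat> zs(S);
  std::vector<ivec> ptr(S);
  for (int s = 0; s < S; ++s) {
    List o = obs[s];
    ys[s] = as<vec>(o["y"]);
    zs[s] = as<mat>(o["z"]);
    ptr[s] = as<ivec>(o["ptr"]);
  }
  mat XtX = X.t() * X;

  mat step(N, S, fill::value(0.5));
  mat acc(N, S, fill::zeros), acc_tot(N, S, fill::zeros);
  int acc_n = 0, acc_tot_n = 0;

  mat B_draws(kept, q * K), gamma_draws(kept, 2 * S),
      psi_draws(kept, q * (q + 1) / 2);
  mat sig2_draws(hetero ? 1 : kept, S, fill::zeros);
  mat eta_sum(N, q, fill::zeros);

  for (int it = 0; it < iter; ++it) {
    mat Psi_inv = inv_sympd(symmatu(Psi));
    mat Vc_inv, W;
    if (hetero) {
      mat Paa = Psi.submat(0, 0, S - 1, S - 1);
      mat Pab = Psi.submat(0, S, S - 1, 2 * S - 1);
      mat Pbb = Psi.submat(S, S, 2 * S - 1, 2 * S - 1);
      W = Pab * inv_sympd(symmatu(Pbb));
      Vc_inv = inv_sympd(symmatu(Paa - W * Pab.t()));
    } else {
      Vc_inv = Psi_inv;
      W.zeros(S, S);
    }
    mat Mu = X * B.t();  // N x q prior means of eta

    // --- person-level latents ---
    for (int i = 0; i < N; ++i) {
      vec mu_i = Mu.row(i).t();
      // alpha block: conjugate normal
      vec m_a = mu_i.head(S);
      if (hetero) {
        vec eta_i = eta.row(i).t();
        m_a += W * (eta_i.tail(S) - mu_i.tail(S));
      }
      mat P = Vc_inv;
      vec h = Vc_inv * m_a;
      for (int s = 0; s < S; ++s) {
        double v_is = hetero ? std::exp(eta(i, S + s)) : sig2(s);
        double sum_r = 0.0;
        int a = ptr[s](i), b = ptr[s](i + 1);
        for (int r = a; r < b; ++r)
          sum_r += ys[s](r) - dot(gamma.row(s), zs[s].row(r));
        P(s, s) += (b - a) / v_is;
        h(s) += sum_r / v_is;
      }
      vec alpha_i = rmvnorm_prec(P, h);
      for (int s = 0; s < S; ++s) eta(i, s) = alpha_i(s);

      if (!hetero) continue;
      // omega block: componentwise Metropolis within Gibbs
      for (int s = 0; s < S; ++s) {
        int j = S + s;
        double lam = Psi_inv(j, j), cv = 1.0 / lam;
        double cm = mu_i(j);
        for (int l = 0; l < q; ++l)
          if (l != j) cm -= cv * Psi_inv(j, l) * (eta(i, l) - Mu(i, l));
        int a = ptr[s](i), b = ptr[s](i + 1);
        int n_is = b - a;
        if (n_is == 0) {
          eta(i, j) = cm + std::sqrt(cv) * rnorm1();
          continue;
        }
        double sse = 0.0;
        for (int r = a; r < b; ++r) {
          double e = ys[s](r) - eta(i, s) - dot(gamma.row(s), zs[s].row(r));
          sse += e * e;
        }
        double w0 = eta(i, j);
        double w1 = w0 + step(i, s) * rnorm1();
        if (w1 > 40.0) w1 = 40.0;
        if (w1 < -40.0) w1 = -40.0;
        double lp0 = -0.5 * (n_is * w0 + sse * std::exp(-w0)) -
                     0.5 * (w0 - cm) * (w0 - cm) / cv;
        double lp1 = -0.5 * (n_is * w1 + sse * std::exp(-w1)) -
                     0.5 * (w1 - cm) * (w1 - cm) / cv;
        if (std::log(R::runif(0.0, 1.0)) < lp1 - lp0) {
          eta(i, j) = w1;
          acc(i, s) += 1.0;
          acc_tot(i, s) += 1.0;
        }
      }
    }
    acc_n++; acc_tot_n++;
    // adapt omega step sizes during burn-in only
    if (hetero && it < burn && acc_n == 50) {
      for (int i = 0; i < N; ++i)
        for (int s = 0; s < S; ++s) {
          double rate = acc(i, s) / 50.0;
          if (rate > 0.5) step(i, s) *= 1.3;
          else if (rate < 0.25) step(i, s) /= 1.3;
        }
      acc.zeros(); acc_n = 0;
    }

    // --- within-level fixed effects ---
    for (int s = 0; s < S; ++s) {
      mat A = coef_prec * eye(2, 2);
      vec h(2, fill::zeros);
      for (int i = 0; i < N; ++i) {
        double v_is = hetero ? std::exp(eta(i, S + s)) : sig2(s);
        int a = ptr[s](i), b = ptr[s](i + 1);
        for (int r = a; r < b; ++r) {
          rowvec z = zs[s].row(r);
          A += z.t() * z / v_is;
          h += z.t() * (ys[s](r) - eta(i, s)) / v_is;
        }
      }
      gamma.row(s) = rmvnorm_prec(A, h).t();
    }

    // --- homoscedastic within variances (collapsed model only) ---
    if (!hetero) {
      for (int s = 0; s < S; ++s) {
        double sse = 0.0;
        int n_tot = ys[s].n_elem;
        for (int i = 0; i < N; ++i) {
          int a = ptr[s](i), b = ptr[s](i + 1);
          for (int r = a; r < b; ++r) {
            double e = ys[s](r) - eta(i, s) - dot(gamma.row(s), zs[s].row(r));
            sse += e * e;
          }
        }
        sig2(s) = 1.0 / R::rgamma(0.001 + n_tot / 2.0,
                                  1.0 / (0.001 + sse / 2.0));
      }
    }

    // --- between-level coefficients, vec(B) ~ N with Kronecker precision ---
    {
      mat P = kron(XtX, Psi_inv);
      P.diag() += coef_prec;
      vec rhs = vectorise(Psi_inv * eta.t() * X);
      B = reshape(rmvnorm_prec(P, rhs), q, K);
    }

    // --- between-level residual covariance ---
    {
      mat U = eta - X * B.t();
      mat SS = symmatu(psi_scale + U.t() * U);
      Psi = symmatu(inv_sympd(rwishart(psi_df + N, inv_sympd(SS))));
    }

    if (it >= burn) {
      int r = it - burn;
      B_draws.row(r) = vectorise(B).t();
      int c = 0;
      for (int s = 0; s < S; ++s) {
        gamma_draws(r, c++) = gamma(s, 0);
        gamma_draws(r, c++) = gamma(s, 1);
      }
      c = 0;
      for (int jj = 0; jj < q; ++jj)
        for (int ii = 0; ii <= jj; ++ii) psi_draws(r, c++) = Psi(ii, jj);
      if (!hetero) sig2_draws.row(r) = sig2.t();
      eta_sum += eta;
    }
  }
  return List::create(
      _["B"] = B_draws, _["gamma"] = gamma_draws, _["psi"] = psi_draws,
      _["sig2"] = sig2_draws, _["eta_mean"] = eta_sum / kept,
      _["accept"] = acc_tot / acc_tot_n, _["step"] = step);
}
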