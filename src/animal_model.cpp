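#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;

// ---------------------------------------------------------------------------
// Gibbs sampler for a d-trait (d = 1 or 2) animal model with optional
// probit-threshold traits:
//
//   y_ti = x_i' b_t + a_ti + u_{t,aq(i)} + g_{t,gen(i)} + e_ti
//
//   vec(a) ~ N(0, G (x) A),  u_k ~ N(0, AQ),  g_l ~ N(0, FG),  e_i ~ N(0, E)
//
// Binary traits are observed as 1(y_ti > 0); their latent liabilities are
// augmented, and the corresponding residual variance is fixed to 1 by
// parameter expansion (an unconstrained residual matrix is drawn, then the
// binary dimension of the whole state is rescaled).
//
// Breeding values are updated single-site over individuals (jointly over
// traits) using the sparse inverse of A in compressed-column form. The
// d <= 2 linear algebra in the hot loops is hand-rolled to avoid small-matrix
// allocations.
// ---------------------------------------------------------------------------

// standard normal truncated below at a (Robert 1995 for far tails)
static double rtnorm_lower(double a) {
  double z;
  if (a < 0.45) {
    do { z = norm_rand(); } while (z <= a);
  } else {
    const double alpha = 0.5 * (a + std::sqrt(a * a + 4.0));
    for (;;) {
      z = a + exp_rand() / alpha;
      const double rho = std::exp(-0.5 * (z - alpha) * (z - alpha));
      if (unif_rand() <= rho) break;
    }
  }
  return z;
}

// N(m, s^2) truncated to (0, inf) when pos, to (-inf, 0) otherwise
static double rtnorm_sign(double m, double s, bool pos) {
  if (pos) return m + s * rtnorm_lower(-m / s);
  return -(-m + s * rtnorm_lower(m / s));
}

// Wishart(df, S) via Bartlett decomposition (R RNG)
static mat rwishart(double df, const mat& S) {
  const int p = S.n_cols;
  mat L = arma::chol(S, "lower");
  mat T(p, p, arma::fill::zeros);
  for (int i = 0; i < p; ++i) {
    T(i, i) = std::sqrt(Rf_rchisq(df - i));
    for (int j = 0; j < i; ++j) T(i, j) = norm_rand();
  }
  mat LT = L * T;
  return LT * LT.t();
}

// inverse-Wishart(df, Psi)
static mat riwishart(double df, const mat& Psi) {
  return arma::inv_sympd(rwishart(df, arma::inv_sympd(Psi)));
}

// log inverse-Wishart(nu, Psi) density kernel at G, plus the Jacobian of the
// lower-Cholesky parameterization G = L L'
static double log_prior_chol(const mat& L, double nu, const mat& Psi) {
  const int d = L.n_rows;
  mat G = L * L.t();
  double logdet, sign;
  arma::log_det(logdet, sign, G);
  const double lp_iw = -0.5 * (nu + d + 1) * logdet -
                       0.5 * arma::trace(Psi * arma::inv_sympd(G));
  // Jacobian of G = L L' in the lower-Cholesky coordinates: 2^d prod l_ii^(d-i)
  // with i 0-based (the constant cancels in the Metropolis ratio)
  double lj = 0.0;
  for (int i = 0; i < d; ++i) lj += (d - i) * std::log(std::fabs(L(i, i)));
  return lp_iw + lj;
}

// sample from N(P^{-1} r, P^{-1}) given precision P and linear term r
static vec rmvnorm_prec(const mat& P, const vec& r) {
  mat U = arma::chol(P);                 // P = U'U
  vec mu = arma::solve(arma::trimatu(U), arma::solve(arma::trimatl(U.t()), r));
  vec z(P.n_cols);
  for (arma::uword i = 0; i < P.n_cols; ++i) z(i) = norm_rand();
  return mu + arma::solve(arma::trimatu(U), z);
}

// draw (x1, x2) ~ N(P^{-1} r, P^{-1}) for a 2x2 precision P (hand-rolled)
static inline void draw2_prec(double p11, double p12, double p22,
                              double r1, double r2,
                              double& x1, double& x2) {
  // lower Cholesky of P
  const double l11 = std::sqrt(p11);
  const double l21 = p12 / l11;
  const double l22 = std::sqrt(p22 - l21 * l21);
  // mean: solve L y = r, L' m = y
  const double y1 = r1 / l11;
  const double y2 = (r2 - l21 * y1) / l22;
  const double m2 = y2 / l22;
  const double m1 = (y1 - l21 * m2) / l11;
  // noise: solve L' e = z
  const double z1 = norm_rand(), z2 = norm_rand();
  const double e2 = z2 / l22;
  const double e1 = (z1 - l21 * e2) / l11;
  x1 = m1 + e1;
  x2 = m2 + e2;
}

// [[Rcpp::export]]
List animal_gibbs_cpp(
    const arma::mat& Y,              // n x d, binary traits coded 0/1, NA = missing
    const IntegerVector trait_type,  // 0 gaussian, 1 binary
    const arma::mat& X,              // n x p fixed-effect design (shared across traits)
    const IntegerVector ped_index,   // 0-based pedigree index per phenotype row
    const int n_ped,
    const IntegerVector ai_p,        // A-inverse, dgCMatrix slots (symmetric)
    const IntegerVector ai_i,
    const NumericVector ai_x,
    const IntegerVector aq,          // 0-based aquarium index per row, -1 if unused
    const int n_aq,
    const IntegerVector gen,         // 0-based generation index per row, -1 if unused
    const int n_gen,
    const double nu,
    const arma::mat& psi_g, const arma::mat& psi_e,
    const arma::mat& psi_aq, const arma::mat& psi_gen,
    const arma::mat& G0, const arma::mat& E0,
    const arma::mat& AQ0, const arma::mat& F0,
    const int n_iter, const int burnin, const int thin,
    const bool store_bv, const bool store_ranef,
    const double liability_bound) {

  const int n = Y.n_rows, d = Y.n_cols, p = X.n_cols;
  const bool use_aq = n_aq > 0, use_gen = n_gen > 0;
  const bool biv = d == 2;

  // observation mask and latent/imputed complete data
  arma::umat obs(n, d);
  mat Yl(n, d);
  for (int i = 0; i < n; ++i)
    for (int t = 0; t < d; ++t) {
      const double y = Y(i, t);
      obs(i, t) = std::isfinite(y) ? 1 : 0;
      if (!obs(i, t)) Yl(i, t) = 0.0;
      else Yl(i, t) = (trait_type[t] == 1) ? (y > 0.5 ? 0.7 : -0.7) : y;
    }

  // which pedigree member maps to which phenotype row (-1 = unphenotyped)
  std::vector<int> row_of(n_ped, -1);
  for (int i = 0; i < n; ++i) row_of[ped_index[i]] = i;

  // state
  mat B(p, d, arma::fill::zeros);
  for (int t = 0; t < d; ++t) {
    double s = 0; int m = 0;
    for (int i = 0; i < n; ++i) if (obs(i, t)) { s += Yl(i, t); ++m; }
    B(0, t) = m > 0 ? s / m : 0.0;   // column 1 of X is the intercept
  }
  mat a(n_ped, d, arma::fill::zeros);
  mat u(std::max(n_aq, 1), d, arma::fill::zeros);
  mat g(std::max(n_gen, 1), d, arma::fill::zeros);
  mat G = G0, E = E0, AQ = AQ0, FG = F0;

  // residuals of the complete data
  mat R = Yl - X * B;
  const mat XtX = X.t() * X;

  // group row indices by aquarium / generation
  std::vector<std::vector<int>> aq_rows(std::max(n_aq, 1)),
      gen_rows(std::max(n_gen, 1));
  if (use_aq) for (int i = 0; i < n; ++i) aq_rows[aq[i]].push_back(i);
  if (use_gen) for (int i = 0; i < n; ++i) gen_rows[gen[i]].push_back(i);

  // storage
  const int n_store = (n_iter - burnin + thin - 1) / thin;
  arma::cube Gs(d, d, n_store), Es(d, d, n_store), AQs(d, d, n_store),
      Fs(d, d, n_store), Bs(p, d, n_store);
  arma::cube As, Us;
  if (store_bv) As.set_size(n_ped, d, n_store);
  if (store_ranef && use_aq) Us.set_size(n_aq, d, n_store);
  int stored = 0, n_diverged = 0;

  const double ridge = 1e-10;

  for (int it = 0; it < n_iter; ++it) {
    // 2x2 (or 1x1) inverses as scalars for the hot loops
    double ei11, ei12 = 0.0, ei22 = 0.0;
    double gi11, gi12 = 0.0, gi22 = 0.0;
    if (biv) {
      const double de = E(0, 0) * E(1, 1) - E(0, 1) * E(0, 1);
      ei11 = E(1, 1) / de; ei22 = E(0, 0) / de; ei12 = -E(0, 1) / de;
      const double dg = G(0, 0) * G(1, 1) - G(0, 1) * G(0, 1);
      gi11 = G(1, 1) / dg; gi22 = G(0, 0) / dg; gi12 = -G(0, 1) / dg;
    } else {
      ei11 = 1.0 / E(0, 0);
      gi11 = 1.0 / G(0, 0);
    }
    mat Einv(d, d);
    Einv(0, 0) = ei11;
    if (biv) { Einv(0, 1) = Einv(1, 0) = ei12; Einv(1, 1) = ei22; }

    // -- 1. latent liabilities and missing-data imputation ------------------
    for (int t = 0; t < d; ++t) {
      const bool binary = trait_type[t] == 1;
      double slope = 0.0, cvar = E(t, t);
      int o = -1;
      if (biv) {
        o = 1 - t;
        slope = E(t, o) / E(o, o);
        cvar = E(t, t) - E(t, o) * slope;
      }
      bool any_latent = binary;
      if (!binary) {
        for (int i = 0; i < n; ++i) if (!obs(i, t)) { any_latent = true; break; }
      }
      if (!any_latent) continue;
      const double csd = std::sqrt(std::max(cvar, 1e-12));
      for (int i = 0; i < n; ++i) {
        const bool ob = obs(i, t);
        if (!binary && ob) continue;            // gaussian observed: fixed
        const double loc = Yl(i, t) - R(i, t);  // current linear predictor
        const double cm = (o >= 0) ? slope * R(i, o) : 0.0;
        const double m = loc + cm;
        double draw;
        if (binary && ob) {
          draw = rtnorm_sign(m, csd, Y(i, t) > 0.5);
          if (std::fabs(draw) > liability_bound) { draw = m; ++n_diverged; }
        } else {
          draw = m + csd * norm_rand();
        }
        Yl(i, t) = draw;
        R(i, t) = draw - loc;
      }
    }

    // -- 2. fixed effects ----------------------------------------------------
    {
      mat W = R + X * B;                         // data minus random effects
      mat M(p * d, p * d);
      for (int t1 = 0; t1 < d; ++t1)
        for (int t2 = 0; t2 < d; ++t2)
          M.submat(t1 * p, t2 * p, t1 * p + p - 1, t2 * p + p - 1) =
              Einv(t1, t2) * XtX;
      M.diag() += ridge;
      mat rhsM = X.t() * W * Einv;               // p x d
      vec rhs = arma::vectorise(rhsM);
      vec bnew = rmvnorm_prec(M, rhs);
      B = arma::reshape(bnew, p, d);
      R = W - X * B;
    }

    // -- 3. breeding values (single-site over individuals) -------------------
    if (biv) {
      double* a1 = a.colptr(0);
      double* a2 = a.colptr(1);
      double* r1 = R.colptr(0);
      double* r2 = R.colptr(1);
      for (int j = 0; j < n_ped; ++j) {
        double s1 = 0.0, s2 = 0.0, aii = 0.0;
        for (int k = ai_p[j]; k < ai_p[j + 1]; ++k) {
          const int rr = ai_i[k];
          if (rr == j) { aii = ai_x[k]; continue; }
          s1 += ai_x[k] * a1[rr];
          s2 += ai_x[k] * a2[rr];
        }
        double p11 = aii * gi11, p12 = aii * gi12, p22 = aii * gi22;
        double q1 = -(gi11 * s1 + gi12 * s2);
        double q2 = -(gi12 * s1 + gi22 * s2);
        const int i = row_of[j];
        if (i >= 0) {
          const double w1 = r1[i] + a1[j], w2 = r2[i] + a2[j];
          p11 += ei11; p12 += ei12; p22 += ei22;
          q1 += ei11 * w1 + ei12 * w2;
          q2 += ei12 * w1 + ei22 * w2;
        }
        double n1, n2;
        draw2_prec(p11 + ridge, p12, p22 + ridge, q1, q2, n1, n2);
        if (i >= 0) { r1[i] -= (n1 - a1[j]); r2[i] -= (n2 - a2[j]); }
        a1[j] = n1; a2[j] = n2;
      }
    } else {
      double* a1 = a.colptr(0);
      double* r1 = R.colptr(0);
      for (int j = 0; j < n_ped; ++j) {
        double s1 = 0.0, aii = 0.0;
        for (int k = ai_p[j]; k < ai_p[j + 1]; ++k) {
          const int rr = ai_i[k];
          if (rr == j) { aii = ai_x[k]; continue; }
          s1 += ai_x[k] * a1[rr];
        }
        double prec = aii * gi11 + ridge;
        double q1 = -gi11 * s1;
        const int i = row_of[j];
        if (i >= 0) {
          prec += ei11;
          q1 += ei11 * (r1[i] + a1[j]);
        }
        const double sdv = 1.0 / std::sqrt(prec);
        const double n1 = q1 / prec + sdv * norm_rand();
        if (i >= 0) r1[i] -= (n1 - a1[j]);
        a1[j] = n1;
      }
    }

    // -- 4. aquarium effects --------------------------------------------------
    if (use_aq) {
      const mat AQinv = arma::inv_sympd(AQ);
      for (int k = 0; k < n_aq; ++k) {
        const int nk = aq_rows[k].size();
        if (biv) {
          double w1 = 0.0, w2 = 0.0;
          for (int idx : aq_rows[k]) { w1 += R(idx, 0); w2 += R(idx, 1); }
          w1 += nk * u(k, 0); w2 += nk * u(k, 1);
          const double p11 = AQinv(0, 0) + nk * ei11 + ridge;
          const double p12 = AQinv(0, 1) + nk * ei12;
          const double p22 = AQinv(1, 1) + nk * ei22 + ridge;
          double n1, n2;
          draw2_prec(p11, p12, p22, ei11 * w1 + ei12 * w2,
                     ei12 * w1 + ei22 * w2, n1, n2);
          const double d1 = n1 - u(k, 0), d2 = n2 - u(k, 1);
          for (int idx : aq_rows[k]) { R(idx, 0) -= d1; R(idx, 1) -= d2; }
          u(k, 0) = n1; u(k, 1) = n2;
        } else {
          double w1 = 0.0;
          for (int idx : aq_rows[k]) w1 += R(idx, 0);
          w1 += nk * u(k, 0);
          const double prec = AQinv(0, 0) + nk * ei11 + ridge;
          const double n1 = ei11 * w1 / prec + norm_rand() / std::sqrt(prec);
          const double d1 = n1 - u(k, 0);
          for (int idx : aq_rows[k]) R(idx, 0) -= d1;
          u(k, 0) = n1;
        }
      }
      AQ = riwishart(nu + n_aq, psi_aq + u.t() * u);
    }

    // -- 5. generation effects ------------------------------------------------
    if (use_gen) {
      const mat FGinv = arma::inv_sympd(FG);
      for (int l = 0; l < n_gen; ++l) {
        const int nl = gen_rows[l].size();
        if (biv) {
          double w1 = 0.0, w2 = 0.0;
          for (int idx : gen_rows[l]) { w1 += R(idx, 0); w2 += R(idx, 1); }
          w1 += nl * g(l, 0); w2 += nl * g(l, 1);
          const double p11 = FGinv(0, 0) + nl * ei11 + ridge;
          const double p12 = FGinv(0, 1) + nl * ei12;
          const double p22 = FGinv(1, 1) + nl * ei22 + ridge;
          double n1, n2;
          draw2_prec(p11, p12, p22, ei11 * w1 + ei12 * w2,
                     ei12 * w1 + ei22 * w2, n1, n2);
          const double d1 = n1 - g(l, 0), d2 = n2 - g(l, 1);
          for (int idx : gen_rows[l]) { R(idx, 0) -= d1; R(idx, 1) -= d2; }
          g(l, 0) = n1; g(l, 1) = n2;
        } else {
          double w1 = 0.0;
          for (int idx : gen_rows[l]) w1 += R(idx, 0);
          w1 += nl * g(l, 0);
          const double prec = FGinv(0, 0) + nl * ei11 + ridge;
          const double n1 = ei11 * w1 / prec + norm_rand() / std::sqrt(prec);
          const double d1 = n1 - g(l, 0);
          for (int idx : gen_rows[l]) R(idx, 0) -= d1;
          g(l, 0) = n1;
        }
      }
      FG = riwishart(nu + n_gen, psi_gen + g.t() * g);
    }

    // -- 6. genetic covariance ------------------------------------------------
    {
      mat Sa(d, d, arma::fill::zeros);
      if (biv) {
        const double* a1 = a.colptr(0);
        const double* a2 = a.colptr(1);
        double sa11 = 0.0, sa12 = 0.0, sa22 = 0.0;
        for (int j = 0; j < n_ped; ++j) {
          const double aj1 = a1[j], aj2 = a2[j];
          for (int k = ai_p[j]; k < ai_p[j + 1]; ++k) {
            const int rr = ai_i[k];
            const double x = ai_x[k];
            sa11 += x * a1[rr] * aj1;
            sa12 += x * a1[rr] * aj2;
            sa22 += x * a2[rr] * aj2;
          }
        }
        Sa(0, 0) = sa11; Sa(1, 1) = sa22;
        Sa(0, 1) = Sa(1, 0) = sa12;   // symmetric by construction of A-inverse
      } else {
        const double* a1 = a.colptr(0);
        double sa11 = 0.0;
        for (int j = 0; j < n_ped; ++j)
          for (int k = ai_p[j]; k < ai_p[j + 1]; ++k)
            sa11 += ai_x[k] * a1[ai_i[k]] * a1[j];
        Sa(0, 0) = sa11;
      }
      G = riwishart(nu + n_ped, psi_g + Sa);
    }

    // -- 6b. ancillarity-sufficiency interweaving on (G, a) ------------------
    // Re-draw the lower-Cholesky factor of G in the non-centered ("whitened")
    // parameterization a = A~ L', where the genetic scale is informed directly
    // by the phenotypes: independence Metropolis-Hastings with the
    // likelihood-exact Gaussian as proposal, corrected by the IW prior and
    // the Cholesky Jacobian. This move transfers variance between G and E in
    // one step, which the single-site updates cannot, and is what keeps
    // mixing acceptable when G and E are weakly identified.
    {
      mat L(d, d, arma::fill::zeros);
      bool ok = true;
      try { L = arma::chol(G, "lower"); } catch (...) { ok = false; }
      if (ok) for (int t = 0; t < d; ++t) if (L(t, t) < 1e-8) ok = false;
      if (ok && biv) {
        const double l11 = L(0, 0), l21 = L(1, 0), l22 = L(1, 1);
        std::vector<double> at1(n_ped), at2(n_ped);
        const double* a1 = a.colptr(0);
        const double* a2 = a.colptr(1);
        for (int j = 0; j < n_ped; ++j) {
          at1[j] = a1[j] / l11;
          at2[j] = (a2[j] - l21 * at1[j]) / l22;
        }
        mat P(3, 3, arma::fill::zeros);
        vec q(3, arma::fill::zeros);
        for (int i = 0; i < n; ++i) {
          const int j = ped_index[i];
          const double t1 = at1[j], t2 = at2[j];
          const double w1 = R(i, 0) + a1[j], w2 = R(i, 1) + a2[j];
          P(0, 0) += ei11 * t1 * t1;
          P(0, 1) += ei12 * t1 * t1;
          P(0, 2) += ei12 * t1 * t2;
          P(1, 1) += ei22 * t1 * t1;
          P(1, 2) += ei22 * t1 * t2;
          P(2, 2) += ei22 * t2 * t2;
          q(0) += (ei11 * w1 + ei12 * w2) * t1;
          q(1) += (ei12 * w1 + ei22 * w2) * t1;
          q(2) += (ei12 * w1 + ei22 * w2) * t2;
        }
        P(1, 0) = P(0, 1); P(2, 0) = P(0, 2); P(2, 1) = P(1, 2);
        P.diag() += 1e-10;
        vec lam = rmvnorm_prec(P, q);
        if (std::fabs(lam(0)) > 1e-10 && std::fabs(lam(2)) > 1e-10) {
          mat Lstar(2, 2, arma::fill::zeros);
          Lstar(0, 0) = lam(0); Lstar(1, 0) = lam(1); Lstar(1, 1) = lam(2);
          const double lr = log_prior_chol(Lstar, nu, psi_g) -
                            log_prior_chol(L, nu, psi_g);
          if (std::log(unif_rand()) < lr) {
            double* a1w = a.colptr(0);
            double* a2w = a.colptr(1);
            for (int j = 0; j < n_ped; ++j) {
              const double na1 = lam(0) * at1[j];
              const double na2 = lam(1) * at1[j] + lam(2) * at2[j];
              const int i = row_of[j];
              if (i >= 0) {
                R(i, 0) -= (na1 - a1w[j]);
                R(i, 1) -= (na2 - a2w[j]);
              }
              a1w[j] = na1; a2w[j] = na2;
            }
            G = Lstar * Lstar.t();
          }
        }
      } else if (ok) {
        const double l11 = L(0, 0);
        const double* a1 = a.colptr(0);
        double Ps = 1e-10, qs = 0.0;
        for (int i = 0; i < n; ++i) {
          const int j = ped_index[i];
          const double t1 = a1[j] / l11;
          Ps += ei11 * t1 * t1;
          qs += ei11 * (R(i, 0) + a1[j]) * t1;
        }
        const double lam = qs / Ps + norm_rand() / std::sqrt(Ps);
        if (std::fabs(lam) > 1e-10) {
          mat Lstar(1, 1); Lstar(0, 0) = lam;
          const double lr = log_prior_chol(Lstar, nu, psi_g) -
                            log_prior_chol(L, nu, psi_g);
          if (std::log(unif_rand()) < lr) {
            const double scale = lam / l11;
            double* a1w = a.colptr(0);
            for (int j = 0; j < n_ped; ++j) {
              const double na1 = scale * a1w[j];
              const int i = row_of[j];
              if (i >= 0) R(i, 0) -= (na1 - a1w[j]);
              a1w[j] = na1;
            }
            G(0, 0) = lam * lam;
          }
        }
      }
    }

    // -- 7. residual covariance, with binary dimensions re-fixed to 1 --------
    {
      mat SE = R.t() * R;
      mat Estar = riwishart(nu + n, psi_e + SE);
      for (int t = 0; t < d; ++t) {
        if (trait_type[t] != 1) continue;
        const double c = Estar(t, t);
        const double sc = std::sqrt(c);
        // rescale the binary dimension of the whole state
        Yl.col(t) /= sc; R.col(t) /= sc; B.col(t) /= sc;
        a.col(t) /= sc; u.col(t) /= sc; g.col(t) /= sc;
        for (int t2 = 0; t2 < d; ++t2) {
          if (t2 == t) continue;
          G(t, t2) /= sc; G(t2, t) /= sc;
          AQ(t, t2) /= sc; AQ(t2, t) /= sc;
          FG(t, t2) /= sc; FG(t2, t) /= sc;
          Estar(t, t2) /= sc; Estar(t2, t) /= sc;
        }
        G(t, t) /= c; AQ(t, t) /= c; FG(t, t) /= c;
        Estar(t, t) = 1.0;
      }
      E = Estar;
    }

    // -- 8. store -------------------------------------------------------------
    if (it >= burnin && ((it - burnin) % thin == 0) && stored < n_store) {
      Gs.slice(stored) = G; Es.slice(stored) = E;
      AQs.slice(stored) = AQ; Fs.slice(stored) = FG;
      Bs.slice(stored) = B;
      if (store_bv) As.slice(stored) = a;
      if (store_ranef && use_aq) Us.slice(stored) = u;
      ++stored;
    }
    if ((it & 255) == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(
      _["G"] = Gs, _["E"] = Es, _["AQ"] = AQs, _["FG"] = Fs, _["B"] = Bs,
      _["n_stored"] = stored, _["n_diverged"] = n_diverged);
  if (store_bv) out["BV"] = As;
  if (store_ranef && use_aq) out["U"] = Us;
  return out;
}
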