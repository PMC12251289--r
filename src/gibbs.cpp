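// Hybrid Gibbs sampler core.  Dense 2Nw x 2Nw Cholesky per draw; kept in
// C++ to avoid the allocation churn of an R-level loop at Nw ~ 10^3.
// Uses R's RNG so runs are reproducible under set.seed().

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static double beta_logpost(double b, const vec& r2, const vec& s2,
                           double theta_b, double phi_b) {
  vec lam = 1.0 / b + s2;
  return -0.5 * accu(log(lam)) - 0.5 * accu(r2 / lam)
         + (theta_b - 1.0) * std::log(b) - phi_b * b;
}

// numerical inverse-transform draw from p(beta | t, uh) on a log grid
static double sample_beta_grid(double beta_init, const vec& r2, const vec& s2,
                               double theta_b, double phi_b, int ngrid) {
  double centre = std::log(beta_init);
  for (int attempt = 0; attempt < 3; ++attempt) {
    vec coarse = linspace<vec>(centre - 8.0 * M_LN10, centre + 8.0 * M_LN10, 81);
    uword best = 0; double bestv = -datum::inf;
    for (uword i = 0; i < coarse.n_elem; ++i) {
      double v = beta_logpost(std::exp(coarse(i)), r2, s2, theta_b, phi_b);
      if (v > bestv) { bestv = v; best = i; }
    }
    centre = coarse(best);
    if (best != 0 && best != coarse.n_elem - 1) break;
  }
  double half = 4.0 * M_LN10;
  vec grid_l, lv;
  for (int attempt = 0; attempt < 2; ++attempt) {
    grid_l = linspace<vec>(centre - half, centre + half, ngrid);
    lv.set_size(ngrid);
    for (int i = 0; i < ngrid; ++i)
      lv(i) = beta_logpost(std::exp(grid_l(i)), r2, s2, theta_b, phi_b);
    vec dens = exp(lv - lv.max());
    if (dens(0) <= 1e-3 && dens(ngrid - 1) <= 1e-3) break;
    half = 6.0 * M_LN10;
  }
  vec beta = exp(grid_l);
  vec dens = exp(lv - lv.max());
  vec cdf(ngrid, fill::zeros);
  for (int i = 1; i < ngrid; ++i)
    cdf(i) = cdf(i - 1) + 0.5 * (dens(i) + dens(i - 1)) * (beta(i) - beta(i - 1));
  double tot = cdf(ngrid - 1);
  if (!std::isfinite(tot) || tot <= 0.0)
    Rcpp::stop("degenerate beta conditional");
  double u = unif_rand() * tot;
  int lo = 0;
  while (lo < ngrid - 2 && cdf(lo + 1) < u) ++lo;
  double c0 = cdf(lo), c1 = cdf(lo + 1);
  double w = (c1 > c0) ? (u - c0) / (c1 - c0) : 0.5;
  return beta(lo) + w * (beta(lo + 1) - beta(lo));
}

// [[Rcpp::export]]
Rcpp::List gibbs_chain(const arma::mat& M, const arma::mat& P,
                       const arma::vec& uh, const arma::vec& sigma2,
                       double theta_a, double phi_a,
                       double theta_b, double phi_b,
                       double alpha0, double beta0,
                       int n_draws, int burn_in, int beta_grid_n,
                       bool fix_alpha, bool fix_beta) {
  const int n = M.n_rows;
  const int nw = n / 2;
  const int kept = n_draws - burn_in;
  Rcpp::RNGScope rng;

  double alpha = alpha0, beta = beta0;
  vec t(n, fill::zeros), z(n), w(n), b(n), y(n), m(n);
  mat Mw(n, n), A(n, n), R(n, n);
  mat draws(kept, n);
  vec alpha_chain(n_draws), beta_chain(n_draws);

  for (int it = 0; it < n_draws; ++it) {
    // --- t | alpha, beta ---
    w = 1.0 / (1.0 / beta + sigma2);
    Mw = M.each_col() % sqrt(w);
    A = Mw.t() * Mw;
    A += alpha * P;
    if (!chol(R, A))
      Rcpp::stop("posterior precision not positive definite (iteration %d)", it + 1);
    b = M.t() * (w % uh);
    y = solve(trimatl(R.t()), b);
    m = solve(trimatu(R), y);
    for (int i = 0; i < n; ++i) z(i) = norm_rand();
    t = m + solve(trimatu(R), z);
    if (!t.is_finite())
      Rcpp::stop("divergent chain: non-finite traction draw (iteration %d)", it + 1);

    // --- alpha | t ---
    if (!fix_alpha) {
      double rate = 0.5 * dot(t, P * t) + phi_a;
      alpha = R::rgamma(nw + theta_a, 1.0 / rate);
    }

    // --- beta | t ---
    if (!fix_beta) {
      vec r = uh - M * t;
      vec r2 = square(r);
      beta = sample_beta_grid(beta, r2, sigma2, theta_b, phi_b, beta_grid_n);
    }

    alpha_chain(it) = alpha;
    beta_chain(it) = beta;
    if (it >= burn_in) draws.row(it - burn_in) = t.t();
    if (it % 16 == 0) Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(Rcpp::Named("draws") = draws,
                            Rcpp::Named("alpha") = alpha_chain,
                            Rcpp::Named("beta") = beta_chain);
}
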