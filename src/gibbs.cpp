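#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Hierarchically centred Gaussian CAR regression, one Gibbs chain.
//
//   y_i ~ N(X_i beta + s_i + sum_k gamma_k[cell_k(i)], s2u)
//   s   ~ ICAR(s2s): s_i | s_-i ~ N(mean of neighbours, s2s / L_i)
//   gamma_k[c] ~ N(0, gvar_k) exchangeably within interaction block k
//
// Priors: beta ~ N(0, beta_prior_var I); all precisions ~ Gamma(shape, rate).
// Adjacency is passed in CSR form (0-based): adj holds the concatenated
// neighbour lists, adj_start[i] the offset of node i's list, nnbr[i] = L_i.
// zcell is an n x K matrix of 0-based interaction cell indices; ncell[k]
// counts the observed cells of block k.  Islands (L_i = 0) have s_i pinned
// to zero and are excluded from the sum-to-zero recentring and the s2s
// update.  Uses R's RNG throughout so set.seed() on the R side makes chains
// reproducible.
// [[Rcpp::export]]
List gibbs_car_chain(const arma::vec& y, const arma::mat& X,
                     const arma::ivec& adj, const arma::ivec& adj_start,
                     const arma::ivec& nnbr,
                     const arma::imat& zcell, const arma::ivec& ncell,
                     int n_iter, int n_burn,
                     double beta_prior_var,
                     double prec_shape, double prec_rate,
                     const arma::vec& beta_init,
                     double s2u_init, double s2s_init, double gvar_init,
                     bool spatial, bool fix_s2u, bool fix_s2s) {
  const int n = y.n_elem;
  const int p = X.n_cols;
  const int K = ncell.n_elem;
  const double VAR_FLOOR = 1e-12;

  arma::mat XtX = X.t() * X;
  arma::vec beta = beta_init;
  arma::vec s(n, arma::fill::zeros);
  double s2u = s2u_init, s2s = s2s_init;

  std::vector<arma::vec> gamma(K);
  arma::vec gvar(std::max(K, 1));
  int n_cells_total = 0;
  for (int k = 0; k < K; ++k) {
    gamma[k] = arma::vec(ncell[k], arma::fill::zeros);
    gvar[k] = gvar_init;
    n_cells_total += ncell[k];
  }
  arma::vec gsum(n, arma::fill::zeros);

  // non-island bookkeeping
  arma::uvec noni = arma::find(nnbr > 0);
  const int n_ni = noni.n_elem;

  const int n_keep = n_iter - n_burn;
  arma::mat beta_draws(n_keep, p);
  arma::mat s_draws(n_keep, spatial ? n : 0);
  arma::vec s2u_draws(n_keep), s2s_draws(n_keep), vars_draws(n_keep);
  arma::mat gvar_draws(n_keep, K);
  arma::mat gamma_draws(n_keep, n_cells_total);
  int n_floored = 0;

  arma::vec z(p), xb(n);

  for (int it = 0; it < n_iter; ++it) {
    // --- beta | rest: Gaussian full conditional ---
    arma::vec resid = y - s - gsum;
    arma::mat A = XtX / s2u;
    A.diag() += 1.0 / beta_prior_var;
    arma::vec b = X.t() * resid / s2u;
    arma::mat R = arma::chol(A);            // upper triangular
    arma::vec mu = arma::solve(A, b, arma::solve_opts::likely_sympd);
    for (int j = 0; j < p; ++j) z[j] = R::norm_rand();
    beta = mu + arma::solve(arma::trimatu(R), z);
    xb = X * beta;

    // --- spatial effects, sequential single-site updates ---
    if (spatial) {
      for (int i = 0; i < n; ++i) {
        const int L = nnbr[i];
        if (L == 0) { s[i] = 0.0; continue; }
        double snbr = 0.0;
        const int a0 = adj_start[i];
        for (int j = 0; j < L; ++j) snbr += s[adj[a0 + j]];
        const double prec = L / s2s + 1.0 / s2u;
        const double m = (snbr / s2s + (y[i] - xb[i] - gsum[i]) / s2u) / prec;
        s[i] = m + R::norm_rand() / std::sqrt(prec);
      }
      // sum-to-zero identification over non-islands
      if (n_ni > 0) {
        double mbar = 0.0;
        for (int u = 0; u < n_ni; ++u) mbar += s[noni[u]];
        mbar /= n_ni;
        for (int u = 0; u < n_ni; ++u) s[noni[u]] -= mbar;
      }
    }

    // --- interaction blocks ---
    for (int k = 0; k < K; ++k) {
      for (int i = 0; i < n; ++i) gsum[i] -= gamma[k][zcell(i, k)];
      arma::vec csum(ncell[k], arma::fill::zeros);
      arma::ivec ccnt(ncell[k], arma::fill::zeros);
      for (int i = 0; i < n; ++i) {
        const int c = zcell(i, k);
        csum[c] += y[i] - xb[i] - s[i] - gsum[i];
        ccnt[c] += 1;
      }
      double ssq = 0.0;
      for (int c = 0; c < ncell[k]; ++c) {
        if (ccnt[c] > 0) {
          const double prec = ccnt[c] / s2u + 1.0 / gvar[k];
          const double m = (csum[c] / s2u) / prec;
          gamma[k][c] = m + R::norm_rand() / std::sqrt(prec);
        } else {
          gamma[k][c] = R::norm_rand() * std::sqrt(gvar[k]);
        }
        ssq += gamma[k][c] * gamma[k][c];
      }
      gvar[k] = 1.0 / R::rgamma(prec_shape + 0.5 * ncell[k],
                                1.0 / (prec_rate + 0.5 * ssq));
      if (gvar[k] < VAR_FLOOR) { gvar[k] = VAR_FLOOR; ++n_floored; }
      for (int i = 0; i < n; ++i) gsum[i] += gamma[k][zcell(i, k)];
    }

    // --- IID residual variance ---
    if (!fix_s2u) {
      arma::vec e = y - xb - s - gsum;
      s2u = 1.0 / R::rgamma(prec_shape + 0.5 * n,
                            1.0 / (prec_rate + 0.5 * arma::dot(e, e)));
      if (s2u < VAR_FLOOR) { s2u = VAR_FLOOR; ++n_floored; }
    }

    // --- spatial conditional variance (pairwise-difference quadratic) ---
    if (spatial && !fix_s2s) {
      double quad = 0.0;
      for (int i = 0; i < n; ++i) {
        const int a0 = adj_start[i];
        for (int j = 0; j < nnbr[i]; ++j) {
          const double d = s[i] - s[adj[a0 + j]];
          quad += d * d;
        }
      }
      quad *= 0.5;  // each unordered pair counted twice above
      s2s = 1.0 / R::rgamma(prec_shape + 0.5 * (n_ni - 1),
                            1.0 / (prec_rate + 0.5 * quad));
      if (s2s < VAR_FLOOR) { s2s = VAR_FLOOR; ++n_floored; }
    }

    if (!beta.is_finite() || !std::isfinite(s2u) || !std::isfinite(s2s))
      stop("divergent draws at iteration %d (s2u=%g, s2s=%g)", it + 1, s2u, s2s);

    // --- store ---
    if (it >= n_burn) {
      const int r = it - n_burn;
      beta_draws.row(r) = beta.t();
      if (spatial) s_draws.row(r) = s.t();
      s2u_draws[r] = s2u;
      s2s_draws[r] = s2s;
      // empirical marginal variance of s across counties, this draw
      vars_draws[r] = (n > 1) ? arma::var(s) : 0.0;
      int off = 0;
      for (int k = 0; k < K; ++k) {
        gvar_draws(r, k) = gvar[k];
        for (int c = 0; c < ncell[k]; ++c) gamma_draws(r, off + c) = gamma[k][c];
        off += ncell[k];
      }
    }
  }

  return List::create(
    _["beta"] = beta_draws, _["s"] = s_draws,
    _["sigma2_u"] = s2u_draws, _["sigma2_s"] = s2s_draws,
    _["var_s"] = vars_draws,
    _["interaction_var"] = gvar_draws, _["interaction_effects"] = gamma_draws,
    _["n_floored"] = n_floored);
}

// Gibbs sampling of the intrinsic CAR prior itself (no data), with
// sum-to-zero recentring after every sweep.  Returns the retained draws'
// running mean and second-moment matrix, for comparison against numerical
// integration of the pairwise-difference density on small graphs.
// [[Rcpp::export]]
List icar_gibbs_moments(const arma::ivec& adj, const arma::ivec& adj_start,
                        const arma::ivec& nnbr, double sigma2,
                        int n_iter, int n_burn, int thin = 1) {
  const int n = nnbr.n_elem;
  arma::vec s(n, arma::fill::zeros);
  arma::vec msum(n, arma::fill::zeros);
  arma::mat m2(n, n, arma::fill::zeros);
  int kept = 0;
  for (int it = 0; it < n_iter; ++it) {
    for (int sweep = 0; sweep < thin; ++sweep) {
      for (int i = 0; i < n; ++i) {
        const int L = nnbr[i];
        if (L == 0) { s[i] = 0.0; continue; }
        double snbr = 0.0;
        const int a0 = adj_start[i];
        for (int j = 0; j < L; ++j) snbr += s[adj[a0 + j]];
        s[i] = snbr / L + R::norm_rand() * std::sqrt(sigma2 / L);
      }
      s -= arma::mean(s);
    }
    if (it >= n_burn) {
      msum += s;
      m2 += s * s.t();
      ++kept;
    }
  }
  return List::create(_["mean"] = msum / kept, _["second_moment"] = m2 / kept,
                      _["n_draws"] = kept);
}
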