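// Sparse inverse covariance estimation with elementwise penalties.
//
// The inner solver is the block coordinate-descent ("graphical lasso")
// algorithm generalised to a full penalty matrix Rho (diagonal never
// penalised).  Non-convex arctangent penalisation is handled one level up by
// local linear approximation (LLA): the L1 solution at lambda initialises a
// short sequence of weighted-L1 solves whose element weights are the atan
// penalty derivative evaluated at the current iterate.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// One weighted graphical-lasso solve.
// W and B are warm-start state (working covariance and regression
// coefficients); both are updated in place.  Returns convergence flag.
//
// The inner lasso uses active-set coordinate descent: after a full sweep the
// iteration cycles over the nonzero coordinates only, with a closing full
// sweep to verify optimality — the standard strategy for sparse fits.
// One weighted graphical-lasso solve. ThetaWarm (may be null) provides a
// consistent warm start: W = ThetaWarm^{-1}, B_kj = -ThetaWarm_kj/ThetaWarm_jj.
// Carrying a stale working covariance across penalty changes instead makes
// the block algorithm lose primal consistency and diverge to indefinite
// iterates, so warm starts are always rebuilt from a positive-definite Theta.
static bool wglasso_solve(const mat& S, const mat& Rho, const mat* ThetaWarm,
                          mat& B, mat& Theta, double tol, int maxit) {
  const uword p = S.n_rows;
  mat W;
  bool warmed = false;
  if (ThetaWarm != nullptr && ThetaWarm->is_finite()) {
    if (inv_sympd(W, symmatu(*ThetaWarm))) {
      const mat& T = *ThetaWarm;
      for (uword j = 0; j < p; ++j) {
        for (uword k = 0; k < p; ++k) {
          B(k, j) = (k == j) ? 0.0 : -T(k, j) / T(j, j);
        }
      }
      warmed = true;
    }
  }
  if (!warmed) {
    W = S;
    B.zeros();
  }
  W.diag() = S.diag();   // diagonal unpenalised
  // absolute convergence threshold scaled by mean off-diagonal magnitude
  double offmean = 0.0;
  if (p > 1) {
    offmean = (accu(abs(S)) - accu(abs(S.diag()))) / double(p * (p - 1));
  }
  double thr = tol * std::max(offmean, 1e-8);
  bool converged = false;

  vec wb(p);
  std::vector<uword> active;
  active.reserve(p);

  for (int it = 0; it < maxit; ++it) {
    double dmax = 0.0;
    for (uword j = 0; j < p; ++j) {
      double* bj = B.colptr(j);
      const double* sj = S.colptr(j);
      const double* rj = Rho.colptr(j);
      // wb_k = sum_{l != j} W(k,l) b_l  (B(j,j) = 0 keeps l=j out)
      wb = W * B.col(j);

      // one coordinate-descent pass over `coords`; returns max |delta b|
      auto cd_pass = [&](const uword* coords, uword m) {
        double dpass = 0.0;
        for (uword t = 0; t < m; ++t) {
          uword k = coords[t];
          double z = sj[k] - wb(k) + W(k, k) * bj[k];
          double r = rj[k];
          double bnew = 0.0;
          if (z > r)       bnew = (z - r) / W(k, k);
          else if (z < -r) bnew = (z + r) / W(k, k);
          double d = bnew - bj[k];
          if (d != 0.0) {
            wb += d * W.col(k);
            bj[k] = bnew;
            if (std::abs(d) > dpass) dpass = std::abs(d);
          }
        }
        return dpass;
      };

      std::vector<uword> full;
      full.reserve(p - 1);
      for (uword k = 0; k < p; ++k) if (k != j) full.push_back(k);

      // bounded per-column budget: a handful of full/active cycles per outer
      // sweep; full-precision column solves are not required for the outer
      // fixed point, and unbounded inner loops blow up on ill-conditioned
      // (singular-S, small-lambda) subproblems
      for (int cycle = 0; cycle < 3; ++cycle) {
        double d0 = cd_pass(full.data(), full.size());
        if (!std::isfinite(d0) || std::abs(bj[full[0]]) > 1e8) break;  // diverged
        if (d0 < 0.1 * thr) break;
        active.clear();
        for (uword k = 0; k < p; ++k) if (k != j && bj[k] != 0.0) active.push_back(k);
        for (int inner = 0; inner < 50; ++inner) {
          if (active.empty()) break;
          if (cd_pass(active.data(), active.size()) < 0.1 * thr) break;
        }
      }

      // wb now equals W11 * b on the off-j coordinates
      for (uword k = 0; k < p; ++k) {
        if (k == j) continue;
        double d = std::abs(wb(k) - W(k, j));
        if (d > dmax) dmax = d;
        W(k, j) = wb(k);
        W(j, k) = wb(k);
      }
      bj[j] = 0.0;
    }
    if (dmax < thr) { converged = true; break; }
  }

  // recover Theta from (W, B)
  Theta.set_size(p, p);
  for (uword j = 0; j < p; ++j) {
    double s = 0.0;
    for (uword k = 0; k < p; ++k) if (k != j) s += W(k, j) * B(k, j);
    double t22 = 1.0 / (W(j, j) - s);
    Theta(j, j) = t22;
    for (uword k = 0; k < p; ++k) if (k != j) Theta(k, j) = -B(k, j) * t22;
  }
  Theta = 0.5 * (Theta + Theta.t());
  return converged;
}

static double atan_deriv(double theta, double lambda, double gamma) {
  return lambda * (gamma + 2.0 / M_PI) * gamma / (gamma * gamma + theta * theta);
}

// partial correlations from a precision matrix, with hard zero threshold
static mat partial_from_precision(const mat& Theta, double edge_tol) {
  vec d = sqrt(Theta.diag());
  mat P = -Theta;
  P.each_col() /= d;
  P.each_row() /= d.t();
  P.diag().ones();
  for (uword j = 0; j < P.n_cols; ++j)
    for (uword i = 0; i < P.n_rows; ++i)
      if (i != j && std::abs(P(i, j)) < edge_tol) P(i, j) = 0.0;
  return P;
}

// [[Rcpp::export(name = ".cpp_ggm_path")]]
Rcpp::List cpp_ggm_path(const arma::mat& S, int n, const arma::vec& lambdas,
                        double gamma, int lla_max, double lla_tol,
                        double glasso_tol, int glasso_maxit,
                        double edge_tol, int bic_stop) {
  const uword p = S.n_rows;
  const uword nl = lambdas.n_elem;

  vec bic(nl, fill::value(datum::nan));
  vec nedges(nl, fill::value(datum::nan));
  ivec conv(nl, fill::zeros);

  mat B(p, p, fill::zeros);          // coefficient workspace
  mat ThetaL1Prev;                   // L1 warm-start chain along the grid
  bool haveL1Prev = false;
  mat bestTheta, bestPartial;
  double bestBic = datum::inf;
  int bestIdx = -1;

  int consecutive_bad = 0;

  for (uword i = 0; i < nl; ++i) {
    double lambda = lambdas(i);
    mat Theta(p, p, fill::zeros);
    bool converged = true;   // inner solves reached their tolerance
    bool valid = true;       // iterate is finite and positive definite

    // with a (near-)singular S the small-lambda tail of the grid diverges;
    // after two consecutive non-PD fits the remaining smaller lambdas are
    // marked invalid without solving
    if (consecutive_bad >= 2 && lambda >= 1e-14) {
      bic(i) = datum::inf;
      nedges(i) = datum::nan;
      conv(i) = 0;
      continue;
    }

    if (lambda < 1e-14) {
      // unpenalised limit: direct inversion (with escalating jitter)
      mat Sj = S;
      double ridge = 0.0;
      bool done = false;
      for (int t = 0; t < 8 && !done; ++t) {
        done = inv_sympd(Theta, Sj);
        if (!done) {
          ridge = (ridge == 0.0) ? 1e-8 : ridge * 10.0;
          Sj = S + ridge * eye(p, p);
        }
      }
      if (!done) Rcpp::stop("input matrix is numerically singular even after ridge jitter");
    } else {
      mat RhoL1 = lambda * (ones(p, p) - eye(p, p));
      converged = wglasso_solve(S, RhoL1, haveL1Prev ? &ThetaL1Prev : nullptr,
                                B, Theta, glasso_tol, glasso_maxit);

      mat cholL1;
      if (!Theta.is_finite() || !chol(cholL1, symmatu(Theta))) {
        valid = false;   // broken (diverged) iterate: skip LLA entirely
        haveL1Prev = false;
      } else {
        ThetaL1Prev = Theta;   // chain the L1 solutions down the grid
        haveL1Prev = true;
      }

      if (valid && lla_max > 0) {
        for (int t = 0; t < lla_max; ++t) {
          mat Rho(p, p, fill::zeros);
          for (uword jj = 0; jj < p; ++jj)
            for (uword ii = 0; ii < p; ++ii)
              if (ii != jj) Rho(ii, jj) = atan_deriv(Theta(ii, jj), lambda, gamma);
          // cold start: warm-starting across penalty reweightings destabilises
          // the block algorithm even with a consistency-rebuilt state
          mat ThetaNew;
          converged = wglasso_solve(S, Rho, nullptr, B, ThetaNew,
                                    glasso_tol, glasso_maxit);
          if (!ThetaNew.is_finite()) { valid = false; break; }
          double dmax = abs(ThetaNew - Theta).max();
          Theta = ThetaNew;
          if (dmax < lla_tol) { converged = true; break; }
        }
      }
    }

    mat P = partial_from_precision(Theta, edge_tol);
    // propagate hard zeros back into the precision estimate
    for (uword jj = 0; jj < p; ++jj)
      for (uword ii = 0; ii < p; ++ii)
        if (ii != jj && P(ii, jj) == 0.0) Theta(ii, jj) = 0.0;

    double ne = 0;
    for (uword jj = 1; jj < p; ++jj)
      for (uword ii = 0; ii < jj; ++ii)
        if (P(ii, jj) != 0.0) ne += 1;

    // BIC candidacy requires a positive-definite estimate (Cholesky check);
    // with a singular input S the small-lambda end of the grid can diverge.
    // Merely-unconverged iterates keep their BIC (the last iterate stands,
    // flagged), only invalid ones are excluded.
    double b;
    mat R;
    if (!valid || !Theta.is_finite() || !chol(R, symmatu(Theta))) {
      b = datum::inf;
      valid = false;
    } else {
      double ldet = 2.0 * accu(log(R.diag()));
      double ll = 0.5 * double(n) * (ldet - accu(S % Theta));
      b = -2.0 * ll + ne * std::log(double(n));
    }

    bic(i) = b;
    nedges(i) = ne;
    conv(i) = (valid && converged) ? 1 : 0;
    consecutive_bad = valid ? 0 : consecutive_bad + 1;

    // strict < keeps the earlier (larger-lambda, sparser) fit on ties
    if (b < bestBic) {
      bestBic = b;
      bestIdx = int(i);
      bestTheta = Theta;
      bestPartial = P;
    }

    // optional early exit once the BIC has stopped improving for a while
    // (used inside permutation loops; the remaining entries stay NaN)
    if (bic_stop > 0 && bestIdx >= 0 &&
        int(i) - bestIdx >= bic_stop) break;
  }

  if (bestIdx < 0) Rcpp::stop("no lambda on the grid produced a positive-definite estimate");

  return Rcpp::List::create(
    Rcpp::Named("precision") = bestTheta,
    Rcpp::Named("partial") = bestPartial,
    Rcpp::Named("best_index") = bestIdx + 1,
    Rcpp::Named("lambda") = Rcpp::NumericVector(lambdas.begin(), lambdas.end()),
    Rcpp::Named("bic") = Rcpp::NumericVector(bic.begin(), bic.end()),
    Rcpp::Named("n_edges") = Rcpp::NumericVector(nedges.begin(), nedges.end()),
    Rcpp::Named("converged") = Rcpp::IntegerVector(conv.begin(), conv.end()));
}
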