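#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// S_Het for each row of Tmat: maximum over a threshold grid of
//   S_Hom = (u' Corr_S^-1 t_S)^2 / (u' Corr_S^-1 u),  u = 1/w,
// where S = { j : |t_j| > tau }.  An empty `taus` means the adaptive grid
// {0} U {|t_j|} of each row, whose subsets are exactly the prefixes of the
// statistics sorted by decreasing |t| (cut at tie boundaries).  That case
// is the Monte-Carlo hot path and is evaluated with an incrementally grown
// Cholesky factor: appending one statistic costs O(m^2), and with
// z_t = L^-1 t, z_u = L^-1 u the statistic is (z_u . z_t)^2 / (z_u . z_u).
// [[Rcpp::export]]
arma::vec shet_stat_kernel(const arma::mat& Tmat, const arma::mat& Corr,
                           const arma::vec& w, const arma::vec& taus) {
  const arma::uword n = Tmat.n_rows, M = Tmat.n_cols;
  if (Corr.n_rows != M || w.n_elem != M)
    Rcpp::stop("dimension mismatch between statistics, Corr and w");
  const arma::vec u_all = 1.0 / w;
  arma::vec out(n);

  if (taus.n_elem > 0) {               // fixed user grid: generic path
    for (arma::uword i = 0; i < n; ++i) {
      arma::vec t = Tmat.row(i).t();
      arma::vec a = arma::abs(t);
      double best = -arma::datum::inf;
      for (arma::uword k = 0; k < taus.n_elem; ++k) {
        arma::uvec sel = arma::find(a > taus[k]);
        if (sel.n_elem == 0) continue;
        arma::mat X;
        arma::mat rhs = arma::join_rows(t.elem(sel), u_all.elem(sel));
        if (!arma::solve(X, Corr.submat(sel, sel), rhs,
                         arma::solve_opts::likely_sympd))
          Rcpp::stop("singular correlation sub-block in SHet");
        double num = arma::dot(u_all.elem(sel), X.col(0));
        double den = arma::dot(u_all.elem(sel), X.col(1));
        best = std::max(best, num * num / den);
      }
      if (!std::isfinite(best))
        Rcpp::stop("empty selection at every SHet threshold");
      out[i] = best;
    }
    return out;
  }

  arma::mat L(M, M);
  arma::vec zt(M), zu(M);
  for (arma::uword i = 0; i < n; ++i) {
    arma::rowvec t = Tmat.row(i);
    arma::vec a = arma::abs(t.t());
    arma::uvec ord = arma::sort_index(a, "descend");
    double best = -arma::datum::inf, st = 0.0, su = 0.0;
    for (arma::uword m = 0; m < M; ++m) {
      const arma::uword jm = ord[m];
      // forward-substitute the new row of the Cholesky factor
      double diag = Corr(jm, jm);
      for (arma::uword r = 0; r < m; ++r) {
        double y = Corr(ord[r], jm);
        for (arma::uword k = 0; k < r; ++k) y -= L(r, k) * L(m, k);
        y /= L(r, r);
        L(m, r) = y;
        diag -= y * y;
      }
      if (diag < 1e-12)
        Rcpp::stop("singular correlation sub-block in SHet");
      L(m, m) = std::sqrt(diag);
      double vt = t[jm], vu = u_all[jm];
      for (arma::uword k = 0; k < m; ++k) {
        vt -= L(m, k) * zt[k];
        vu -= L(m, k) * zu[k];
      }
      zt[m] = vt / L(m, m);
      zu[m] = vu / L(m, m);
      st += zu[m] * zt[m];
      su += zu[m] * zu[m];
      // prefix of size m+1 corresponds to a threshold only at a strict
      // drop in |t| (ties extend the prefix); |t| = 0 is never selected
      bool boundary = (m + 1 < M) ? (a[jm] > a[ord[m + 1]]) : (a[jm] > 0);
      if (boundary && a[jm] > 0)
        best = std::max(best, st * st / su);
    }
    if (!std::isfinite(best))
      Rcpp::stop("empty selection at every SHet threshold");
    out[i] = best;
  }
  return out;
}
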