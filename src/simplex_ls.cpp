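#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Lawson-Hanson active-set NNLS: minimise ||A x - b|| subject to x >= 0.
// The designs passed in have at most p+2 rows, so the passive set stays
// small and the inner least-squares solves are cheap.
static vec nnls(const mat& A, const vec& b, double tol) {
  const uword m = A.n_cols;
  vec x(m, fill::zeros);
  std::vector<bool> passive(m, false);
  vec w = A.t() * (b - A * x);
  const uword max_outer = 3 * m + 30;
  uword outer = 0;
  while (outer++ < max_outer) {
    // pick the most violated dual among the active (zero) variables
    double wmax = -datum::inf;
    sword jmax = -1;
    for (uword j = 0; j < m; ++j) {
      if (!passive[j] && w(j) > wmax) { wmax = w(j); jmax = j; }
    }
    if (jmax < 0 || wmax <= tol) break;
    passive[(uword)jmax] = true;

    for (uword inner = 0; inner < max_outer; ++inner) {
      uvec P(m);
      uword np = 0;
      for (uword j = 0; j < m; ++j) if (passive[j]) P(np++) = j;
      P.resize(np);
      mat Ap = A.cols(P);
      vec z;
      bool ok = solve(z, Ap, b);
      if (!ok) z = pinv(Ap) * b;
      if (np > 0 && z.min() > 0) {
        x.zeros();
        x.elem(P) = z;
        break;
      }
      // step back along the segment to the first zero crossing
      double alpha = datum::inf;
      for (uword t = 0; t < np; ++t) {
        if (z(t) <= 0) {
          double xt = x(P(t));
          double a = xt / (xt - z(t));
          if (a < alpha) alpha = a;
        }
      }
      if (!std::isfinite(alpha)) alpha = 0.0;
      vec xp = x.elem(P);
      xp += alpha * (z - xp);
      x.zeros();
      x.elem(P) = xp;
      for (uword t = 0; t < np; ++t) {
        if (x(P(t)) <= tol) { passive[P(t)] = false; x(P(t)) = 0.0; }
      }
    }
    w = A.t() * (b - A * x);
  }
  return x;
}

// Rows of W solve min ||t_r - w' P||^2 subject to w >= 0, sum(w) = 1,
// via the standard large-penalty augmentation of the NNLS system
// (an extra equation M * sum(w) = M), followed by exact renormalisation.
// P: m x p candidate points; T: r x p targets. Returns r x m.
// [[Rcpp::export]]
arma::mat simplex_weights_cpp(const arma::mat& P, const arma::mat& T,
                              double penalty, double tol) {
  const uword m = P.n_rows, p = P.n_cols, r = T.n_rows;
  mat A(p + 1, m);
  A.rows(0, p - 1) = P.t();
  A.row(p).fill(penalty);
  mat W(r, m, fill::zeros);
  vec b(p + 1);
  for (uword i = 0; i < r; ++i) {
    b.subvec(0, p - 1) = T.row(i).t();
    b(p) = penalty;
    vec w = nnls(A, b, tol);
    double s = accu(w);
    if (s <= 0) {
      // degenerate target: fall back to nearest single candidate
      vec d(m);
      for (uword j = 0; j < m; ++j)
        d(j) = accu(square(P.row(j) - T.row(i)));
      w.zeros();
      w(d.index_min()) = 1.0;
      s = 1.0;
    }
    W.row(i) = w.t() / s;
  }
  return W;
}
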