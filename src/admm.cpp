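#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Elementwise soft-thresholding with per-coordinate thresholds.
static inline vec soft_vec(const vec& v, const vec& t) {
  return sign(v) % max(abs(v) - t, zeros<vec>(v.n_elem));
}

// ADMM for  min (1/2)||Ax - b||^2 + lambda ||penalize % z||_1
//           s.t. Cx = d, x - z = 0
// over a decreasing lambda sequence with warm starts. The quadratic
// x-update factorization depends only on rho, so it is cached and
// recomputed only when rho changes along the path: directly on
// E'E + rho I (m x m) when m <= rows(E), otherwise via the matrix
// inversion lemma on I + E E'/rho (rows(E) x rows(E)), where E stacks A
// and sqrt(rho) C. When rho changes, the scaled duals u = y/rho are
// rescaled so the underlying multipliers y carry over.
//
// For an unconstrained (plain lasso) solve the caller passes C = 0, d = 0 and
// constrained = false; the C-row of E and the constraint residual then vanish
// identically and the updates reduce to the standard lasso ADMM.
// [[Rcpp::export]]
Rcpp::List admm_path_cpp(const arma::mat& A,
                         const arma::vec& b,
                         const arma::vec& Cvec,
                         const double d,
                         const arma::vec& penalize,
                         const arma::vec& lambdas,
                         const arma::vec& rhos,
                         const double eps_abs,
                         const double eps_rel,
                         const int max_iter,
                         const arma::vec& x0,
                         const arma::vec& z0,
                         const double u1_0,
                         const arma::vec& u2_0,
                         const bool constrained) {
  const uword n = A.n_rows, m = A.n_cols, L = lambdas.n_elem;
  const uword nE = n + (constrained ? 1 : 0);
  const double nB = static_cast<double>(m) + (constrained ? 1.0 : 0.0);

  mat E(nE, m);
  E.rows(0, n - 1) = A;

  const vec Atb = A.t() * b;
  const bool lemma = nE < m;

  mat R; // upper-triangular Cholesky factor, cached per rho
  double rho = datum::nan;

  vec x = x0, z = z0, u2 = u2_0;
  double u1 = u1_0;

  mat X(m, L), Z(m, L), U2(m, L);
  vec U1(L), r_out(L), s_out(L), epri_out(L), edual_out(L);
  ivec iters(L), conv(L);

  for (uword l = 0; l < L; ++l) {
    const double lambda = lambdas(l);
    if (l == 0 || rhos(l) != rho) {
      if (l > 0) { // rescale scaled duals to the new rho
        const double ratio = rho / rhos(l);
        u1 *= ratio; u2 *= ratio;
      }
      rho = rhos(l);
      if (constrained) E.row(n) = std::sqrt(rho) * Cvec.t();
      if (lemma) {
        R = chol(eye<mat>(nE, nE) + (E * E.t()) / rho);
      } else {
        R = chol(E.t() * E + rho * eye<mat>(m, m));
      }
    }
    const vec thr = (lambda / rho) * penalize;
    double r_norm = datum::inf, s_norm = datum::inf;
    double eps_pri = 0.0, eps_dual = 0.0;
    int it = 0, ok = 0;

    for (it = 1; it <= max_iter; ++it) {
      // x-update
      vec q = Atb + rho * (z - u2);
      if (constrained) q += rho * Cvec * (d - u1);
      if (lemma) {
        const vec Eq = E * q;
        const vec w = solve(trimatu(R), solve(trimatl(R.t()), Eq));
        x = q / rho - E.t() * w / (rho * rho);
      } else {
        x = solve(trimatu(R), solve(trimatl(R.t()), q));
      }

      // z-update (soft threshold; unpenalized coordinates pass through)
      const vec z_old = z;
      z = soft_vec(x + u2, thr);

      // scaled dual update
      const double cres = constrained ? dot(Cvec, x) - d : 0.0;
      if (constrained) u1 += cres;
      u2 += x - z;

      // residuals and tolerances; B stacks C (if any) on the identity, so
      // ||Bx|| = sqrt(||x||^2 + (Cx)^2) and r = (Cx - d, x - z)
      r_norm = std::sqrt(cres * cres + accu(square(x - z)));
      s_norm = rho * norm(z - z_old, 2);
      const double Cx = constrained ? dot(Cvec, x) : 0.0;
      const double norm_Bx = std::sqrt(accu(square(x)) + Cx * Cx);
      eps_pri = std::sqrt(nB) * eps_abs +
        eps_rel * std::max(norm_Bx, std::max(norm(z, 2), std::abs(d)));
      const vec Bt_u = constrained ? vec(Cvec * u1 + u2) : u2;
      eps_dual = std::sqrt(static_cast<double>(m)) * eps_abs +
        eps_rel * rho * norm(Bt_u, 2);

      if (r_norm <= eps_pri && s_norm <= eps_dual) { ok = 1; break; }
    }
    if (it > max_iter) it = max_iter;

    X.col(l) = x; Z.col(l) = z; U2.col(l) = u2; U1(l) = u1;
    r_out(l) = r_norm; s_out(l) = s_norm;
    epri_out(l) = eps_pri; edual_out(l) = eps_dual;
    iters(l) = it; conv(l) = ok;
  }

  return Rcpp::List::create(
    Rcpp::Named("x") = X, Rcpp::Named("z") = Z,
    Rcpp::Named("u1") = U1, Rcpp::Named("u2") = U2,
    Rcpp::Named("iterations") = iters, Rcpp::Named("converged") = conv,
    Rcpp::Named("primal_residual") = r_out, Rcpp::Named("dual_residual") = s_out,
    Rcpp::Named("eps_pri") = epri_out, Rcpp::Named("eps_dual") = edual_out,
    Rcpp::Named("lemma_branch") = lemma);
}
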