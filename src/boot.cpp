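// Wild bootstrap inner loop for the rank quadratic forms.
// Everything here mirrors the R estimators exactly (the R side is the
// reference in the test suite); C++ is used only because B bootstrap
// replicates per dataset times thousands of simulated datasets make the
// replicate loop the hot path.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// spectral pseudoinverse with relative eigenvalue tolerance
static mat pinv_sym(const mat& M, double tol) {
  vec ev;
  mat V;
  eig_sym(ev, V, symmatu(M));
  double mx = ev.n_elem ? abs(ev).max() : 0.0;
  vec inv(ev.n_elem, fill::zeros);
  if (mx > 0)
    for (uword i = 0; i < ev.n_elem; ++i)
      if (std::abs(ev(i)) > tol * mx) inv(i) = 1.0 / ev(i);
  return V * diagmat(inv) * V.t();
}

// Per-replicate statistics for the wild bootstrap.
//
// Z_list: per group n_i x d centered ranks (0 at unobserved entries)
// L_list: per group n_i x d observation masks (0/1)
// W_list: per group n_i x B weight matrices (one weight per subject/replicate)
// C, T:   contrast matrix (r x ad) and its projection (ad x ad)
// N:      total observed count; n_total: total subjects
// Returns B x 3 matrix of (WTS*, ATS*, MATS*) plus the count of ATS
// replicates with tr(T V*) <= 0 (whose ATS* is set to 0).
// [[Rcpp::export]]
Rcpp::List boot_stats_cpp(Rcpp::List Z_list, Rcpp::List L_list,
                          Rcpp::List W_list, const arma::mat& C,
                          const arma::mat& T, double N, double n_total,
                          double tol) {
  const int a = Z_list.size();
  std::vector<mat> Z(a), L(a), W(a);
  std::vector<vec> lamdot(a);
  std::vector<mat> Delta(a);
  int d = 0, B = 0;
  for (int i = 0; i < a; ++i) {
    Z[i] = Rcpp::as<mat>(Z_list[i]);
    L[i] = Rcpp::as<mat>(L_list[i]);
    W[i] = Rcpp::as<mat>(W_list[i]);
    d = Z[i].n_cols;
    B = W[i].n_cols;
    lamdot[i] = sum(L[i], 0).t();
    Delta[i] = L[i].t() * L[i];
  }
  const int ad = a * d;
  mat stats(B, 3, fill::zeros);
  int n_degenerate = 0;

  vec pstar(ad);
  mat Vstar(ad, ad);
  for (int b = 0; b < B; ++b) {
    pstar.zeros();
    Vstar.zeros();
    for (int i = 0; i < a; ++i) {
      const double n_i = Z[i].n_rows;
      mat Zs = Z[i].each_col() % W[i].col(b);  // zero stays zero at lambda=0
      vec colsum = sum(Zs, 0).t();             // = sum over observed
      vec zbar = colsum / lamdot[i];
      for (int j = 0; j < d; ++j) pstar(i * d + j) = zbar(j) / N;
      // centered columns, re-masked so unobserved entries contribute nothing
      mat Zc = Zs;
      Zc.each_row() -= zbar.t();
      Zc %= L[i];
      const double scale = n_total / n_i;
      for (int j = 0; j < d; ++j) {
        double vjj = n_i * dot(Zc.col(j), Zc.col(j)) /
                     (N * N * lamdot[i](j) * (lamdot[i](j) - 1.0));
        Vstar(i * d + j, i * d + j) = scale * vjj;
        for (int jp = j + 1; jp < d; ++jp) {
          double den = N * N * ((lamdot[i](j) - 1.0) * (lamdot[i](jp) - 1.0) +
                                Delta[i](j, jp) - 1.0);
          if (den > 0) {
            double v = n_i * dot(Zc.col(j), Zc.col(jp)) / den;
            Vstar(i * d + j, i * d + jp) = scale * v;
            Vstar(i * d + jp, i * d + j) = scale * v;
          }
        }
      }
    }
    vec Cp = C * pstar;
    // WTS*
    mat Mw = C * Vstar * C.t();
    stats(b, 0) = n_total * dot(Cp, pinv_sym(Mw, tol) * Cp);
    // ATS*
    double tr1 = accu(T % Vstar);  // = trace(T Vstar), both symmetric
    if (tr1 > 0) {
      stats(b, 1) = n_total * dot(pstar, T * pstar) / tr1;
    } else {
      stats(b, 1) = 0.0;
      ++n_degenerate;
    }
    // MATS*
    mat Md = C * diagmat(Vstar.diag()) * C.t();
    stats(b, 2) = n_total * dot(Cp, pinv_sym(Md, tol) * Cp);
  }
  return Rcpp::List::create(Rcpp::Named("stats") = stats,
                            Rcpp::Named("n_degenerate") = n_degenerate);
}
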