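#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// F statistic of the genotype dummy block D added to y ~ [C, m_b], for
// each candidate mediator column m_b of M. Used for the observed and the
// within-genotype-class surrogate datasets of the CIT equivalence
// component, where only the mediator column changes between fits.
//
// Computed by the Frisch-Waugh-Lovell decomposition: y, D and every
// mediator column are residualized on C once (a single least-squares
// solve); per column only the 1-dimensional projection on the mediator
// residual and a d x d solve remain.
// [[Rcpp::export]]
arma::vec citFstatsC(const arma::vec& y, const arma::mat& C,
                     const arma::mat& D, const arma::mat& M) {
  const uword n = y.n_elem;
  const uword B = M.n_cols;
  const uword d = D.n_cols;

  mat Z = join_rows(join_rows(y, D), M);
  mat R = Z - C * solve(C, Z);
  vec yt = R.col(0);
  mat Dt = R.cols(1, d);
  mat Mt = R.cols(d + 1, d + B);

  const double df2 = double(n) - double(C.n_cols + 1 + d);
  vec out(B);
  for (uword b = 0; b < B; ++b) {
    vec mb = Mt.col(b);
    double mm = dot(mb, mb);
    vec y2 = yt;
    mat D2 = Dt;
    if (mm > 1e-12) {
      y2 -= mb * (dot(mb, yt) / mm);
      D2 -= mb * ((mb.t() * Dt) / mm);
    }
    double rss0 = dot(y2, y2);
    vec Dty = D2.t() * y2;
    vec sol = solve(D2.t() * D2, Dty);
    double rss1 = rss0 - dot(Dty, sol);
    out(b) = ((rss0 - rss1) / double(d)) / (rss1 / df2);
  }
  return out;
}

// Observed F (first element) followed by B surrogate F statistics where
// the mediator is permuted within the genotype classes given by
// classIdx (1-based index vectors). Permutations use R's RNG stream, so
// results are reproducible under set.seed().
// [[Rcpp::export]]
arma::vec citP4C(const arma::vec& y, const arma::mat& C,
                 const arma::mat& D, const arma::vec& m,
                 const Rcpp::List& classIdx, const int B) {
  const uword n = y.n_elem;
  mat M(n, B + 1);
  M.col(0) = m;
  for (int b = 1; b <= B; ++b) {
    vec col = m;
    for (int k = 0; k < classIdx.size(); ++k) {
      Rcpp::IntegerVector idx = classIdx[k];
      const int ni = idx.size();
      for (int i = ni - 1; i > 0; --i) {
        int j = int(R::unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(col(idx[i] - 1), col(idx[j] - 1));
      }
    }
    M.col(b) = col;
  }
  return citFstatsC(y, C, D, M);
}
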