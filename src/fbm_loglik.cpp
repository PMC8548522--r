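#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Joint covariance of anchored FBM increments for K particles sharing one
// substrate process. All pairwise |time - time|, |time - anchor| and
// |anchor - anchor| values were pooled into one vector V on the R side, so a
// parameter evaluation only needs length(V) pow() calls per exponent instead
// of O(n^2). Index matrices are 1-based (R convention).
//
// Particle block k (anchor a_k):
//   Cov[x(t_i)-x(a_k), x(t_j)-x(a_k)] = D_k (|t_i-a_k|^a + |t_j-a_k|^a - |t_i-t_j|^a)
// Substrate term for rows i (block k) and j (block l):
//   Cov[R(t_i)-R(a_k), R(t_j)-R(a_l)]
//     = D_R (|t_i-a_l|^a + |t_j-a_k|^a - |t_i-t_j|^a - |a_k-a_l|^a)
static void build_cov(arma::mat &C,
                      const IntegerVector &blk,
                      const NumericVector &V,
                      const IntegerMatrix &ILAG,
                      const IntegerMatrix &IA,
                      const IntegerMatrix &IAA,
                      const NumericVector &D,
                      const NumericVector &A,
                      double DR, double aR, bool useR) {
  const int n = ILAG.nrow();
  const int K = IA.ncol();
  const int m = V.size();
  std::vector<double> vp(m);

  C.zeros(n, n);

  // contiguous row range of each block (blk assumed sorted)
  std::vector<int> bs(K, n), be(K, -1);
  for (int i = 0; i < n; ++i) {
    int k = blk[i] - 1;
    if (i < bs[k]) bs[k] = i;
    if (i > be[k]) be[k] = i;
  }

  for (int k = 0; k < K; ++k) {
    const double Dk = D[k], al = A[k];
    for (int u = 0; u < m; ++u) vp[u] = std::pow(V[u], al);
    for (int j = bs[k]; j <= be[k]; ++j) {
      const double pj = vp[IA(j, k) - 1];
      for (int i = bs[k]; i <= j; ++i) {
        const double v = Dk * (vp[IA(i, k) - 1] + pj - vp[ILAG(i, j) - 1]);
        C(i, j) += v;
      }
    }
  }

  if (useR) {
    for (int u = 0; u < m; ++u) vp[u] = std::pow(V[u], aR);
    for (int j = 0; j < n; ++j) {
      const int l = blk[j] - 1;
      for (int i = 0; i <= j; ++i) {
        const int k = blk[i] - 1;
        const double v = DR * (vp[IA(i, l) - 1] + vp[IA(j, k) - 1] -
                               vp[ILAG(i, j) - 1] - vp[IAA(k, l) - 1]);
        C(i, j) += v;
      }
    }
  }

  C = arma::symmatu(C);
}

// [[Rcpp::export(name = ".cppJointCov")]]
arma::mat cpp_joint_cov(IntegerVector blk, NumericVector V,
                        IntegerMatrix ILAG, IntegerMatrix IA, IntegerMatrix IAA,
                        NumericVector D, NumericVector A,
                        double DR, double aR, bool useR) {
  arma::mat C;
  build_cov(C, blk, V, ILAG, IA, IAA, D, A, DR, aR, useR);
  return C;
}

// Multivariate normal log-likelihood of the stacked anchored displacements,
// dimensions independent and sharing the covariance up to per-dimension
// localization-error diagonals. MU is K x d (per particle, per dimension).
// Returns -Inf when the jittered covariance is not positive definite.
// [[Rcpp::export(name = ".cppJointLogLik")]]
double cpp_joint_loglik(const arma::mat &Y, const arma::mat &SIG2,
                        IntegerVector blk, NumericVector V,
                        IntegerMatrix ILAG, IntegerMatrix IA, IntegerMatrix IAA,
                        NumericVector D, NumericVector A,
                        double DR, double aR, bool useR,
                        const arma::mat &MU) {
  const int n = Y.n_rows, d = Y.n_cols;
  arma::mat C;
  build_cov(C, blk, V, ILAG, IA, IAA, D, A, DR, aR, useR);

  arma::mat Yc(n, d);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < d; ++j) Yc(i, j) = Y(i, j) - MU(blk[i] - 1, j);

  // one Cholesky when every dimension carries the same noise diagonal
  bool shared = true;
  for (int j = 1; j < d && shared; ++j)
    if (arma::any(SIG2.col(j) != SIG2.col(0))) shared = false;

  const double l2pi = std::log(2.0 * M_PI);
  double ll = 0.0;
  arma::mat R;
  for (int j = 0; j < d; ++j) {
    if (j == 0 || !shared) {
      arma::mat Cj = C;
      Cj.diag() += SIG2.col(shared ? 0 : j);
      Cj.diag() += 1e-10 * Cj.diag().max();
      if (!arma::chol(R, Cj)) return R_NegInf;
    }
    arma::vec z = arma::solve(arma::trimatl(R.t()), Yc.col(j));
    ll += -0.5 * arma::dot(z, z) - arma::accu(arma::log(R.diag())) -
          0.5 * n * l2pi;
  }
  return ll;
}
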