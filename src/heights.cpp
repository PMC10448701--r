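// Sampled simplex-height profiles from a squared-distance matrix.
//
// For a tested dimension n, the apex height of point i over a base of n+1
// sampled points is obtained from bordered Cayley-Menger determinants:
// writing CM_base for the (n+2)x(n+2) Cayley-Menger matrix of the base and
// b = (1, d^2(i, p_1), ..., d^2(i, p_{n+1}))' for the bordered column of the
// apex, the determinant identity det(CM_full) = det(CM_base) * (0 - b'CM_base^{-1}b)
// gives h^2 = |det CM_full| / (2 |det CM_base|) = |b' CM_base^{-1} b| / 2,
// so each draw costs one LU factorisation of CM_base and two triangular solves.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Sample k distinct indices uniformly from {0,...,N-1} \ {skip} into the
// first k slots of pool (a permutation of that set), via partial Fisher-Yates
// driven by R's RNG so that set.seed() governs reproducibility.
static void sample_partners(arma::uvec &pool, int k) {
  const int M = pool.n_elem;
  for (int t = 0; t < k; ++t) {
    int r = t + (int)(unif_rand() * (M - t));
    if (r >= M) r = M - 1; // guard against unif_rand() == 1.0
    std::swap(pool[t], pool[r]);
  }
}

// [[Rcpp::export]]
List cpp_height_profile(const arma::mat &D2, const arma::ivec &dims, int S,
                        int max_retry, double degen_tol) {
  const int N = D2.n_rows;
  const int K = dims.n_elem;

  arma::mat med(N, K, arma::fill::zeros);
  arma::imat degen(N, K, arma::fill::zeros);
  long neg_sq = 0; // draws with a sign-anomalous Cayley-Menger determinant

  arma::uvec pool(N - 1);
  std::vector<double> hs(S);

  for (int a = 0; a < K; ++a) {
    const int n = dims[a];     // tested dimension
    const int m = n + 1;       // base vertex count (base simplex has dim n)
    const int q = m + 1;       // Cayley-Menger matrix size for the base

    arma::mat A(q, q);
    arma::vec b(q), z(q);
    arma::mat L, U, P;

    for (int i = 0; i < N; ++i) {
      // pool <- {0..N-1} \ {i}
      for (int j = 0, t = 0; j < N; ++j) if (j != i) pool[t++] = j;

      long degen_i = 0;
      for (int s = 0; s < S; ++s) {
        double h = -1.0;
        for (int r = 0; r <= max_retry; ++r) {
          sample_partners(pool, m);

          A(0, 0) = 0.0;
          double maxA = 1.0;
          for (int u = 0; u < m; ++u) {
            A(0, u + 1) = 1.0;
            A(u + 1, 0) = 1.0;
            A(u + 1, u + 1) = 0.0;
            b[u + 1] = D2(i, pool[u]);
            for (int v = u + 1; v < m; ++v) {
              const double d2 = D2(pool[u], pool[v]);
              A(u + 1, v + 1) = d2;
              A(v + 1, u + 1) = d2;
              if (d2 > maxA) maxA = d2;
            }
          }
          b[0] = 1.0;

          if (!arma::lu(L, U, P, A)) { ++degen_i; continue; }
          // Rank-deficiency test: a flat base shows an LU pivot collapsing
          // to round-off level relative to the matrix scale, while bases
          // with genuine (even noise-level) extent keep all pivots well
          // above it.
          double minpiv = std::abs(U(0, 0));
          for (int u = 1; u < q; ++u) {
            minpiv = std::min(minpiv, std::abs(U(u, u)));
          }
          if (minpiv < degen_tol * maxA) { ++degen_i; continue; }

          // forward/back substitution for A z = b with PA = LU
          z = P * b;
          for (int u = 0; u < q; ++u) {
            double acc = z[u];
            for (int v = 0; v < u; ++v) acc -= L(u, v) * z[v];
            z[u] = acc / L(u, u);
          }
          for (int u = q - 1; u >= 0; --u) {
            double acc = z[u];
            for (int v = u + 1; v < q; ++v) acc -= U(u, v) * z[v];
            z[u] = acc / U(u, u);
          }
          const double qd = arma::dot(b, z);
          if (qd < 0.0) ++neg_sq; // non-Euclidean input or round-off
          h = std::sqrt(std::abs(qd) / 2.0);
          break;
        }
        if (h < 0.0 || degen_i > 50L * S) {
          stop("height profile: point %d at tested dimension %d exceeded the "
               "degenerate-simplex retry budget (pathological distance matrix?)",
               i + 1, n);
        }
        hs[s] = h;
      }
      degen(i, a) = (int)degen_i;

      // median; even S averages the two central order statistics
      std::nth_element(hs.begin(), hs.begin() + S / 2, hs.begin() + S);
      double md = hs[S / 2];
      if (S % 2 == 0) {
        std::nth_element(hs.begin(), hs.begin() + S / 2 - 1, hs.begin() + S / 2);
        md = 0.5 * (md + hs[S / 2 - 1]);
      }
      med(i, a) = md;
    }
    checkUserInterrupt();
  }

  return List::create(_["median_heights"] = med,
                      _["degenerate_counts"] = degen,
                      _["n_negative_sq"] = (double)neg_sq);
}
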