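// Exact t-SNE: Gaussian input affinities calibrated to a target perplexity by
// per-point binary search, Student-t output affinities, gradient descent with
// early exaggeration, momentum and adaptive per-coordinate gains. O(n^2) per
// iteration with hand-fused loops; intended for the ~10^3-10^4 events of a
// dyad recording.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat squared_distances(const mat& X) {
  vec sq = sum(square(X), 1);
  mat D = -2.0 * (X * X.t());
  D.each_col() += sq;
  D.each_row() += sq.t();
  D.diag().zeros();
  D.elem(find(D < 0)).zeros();
  return D;
}

// Row-stochastic conditional affinities at the requested perplexity.
static mat conditional_p(const mat& D, double perplexity) {
  const uword n = D.n_rows;
  const double logU = std::log(perplexity);
  mat P(n, n, fill::zeros);
  for (uword i = 0; i < n; ++i) {
    double betamin = -datum::inf, betamax = datum::inf, beta = 1.0;
    rowvec Di = D.row(i);
    rowvec Pi(n);
    for (int iter = 0; iter < 64; ++iter) {
      double sumP = 0.0, sumDP = 0.0;
      for (uword j = 0; j < n; ++j) {
        double p = (j == i) ? 0.0 : std::exp(-Di(j) * beta);
        Pi(j) = p;
        sumP += p;
        sumDP += Di(j) * p;
      }
      if (sumP <= 0) sumP = datum::eps;
      double H = std::log(sumP) + beta * sumDP / sumP;
      Pi /= sumP;
      double diff = H - logU;
      if (std::fabs(diff) < 1e-5) break;
      if (diff > 0) {
        betamin = beta;
        beta = std::isinf(betamax) ? beta * 2.0 : (beta + betamax) / 2.0;
      } else {
        betamax = beta;
        beta = std::isinf(betamin) ? beta / 2.0 : (beta + betamin) / 2.0;
      }
    }
    P.row(i) = Pi;
  }
  return P;
}

// [[Rcpp::export(name = ".tsne_cpp")]]
arma::mat tsne_cpp(const arma::mat& X, const arma::mat& Y0, double perplexity,
                   int n_iter, int exaggeration_iter, double exaggeration,
                   double eta) {
  const uword n = X.n_rows;
  mat P = conditional_p(squared_distances(X), perplexity);
  P = (P + P.t()) / (2.0 * n);
  P.elem(find(P < 1e-12)).fill(1e-12);
  P *= exaggeration;

  mat Y = Y0;
  mat dY(n, 2, fill::zeros), iY(n, 2, fill::zeros), gains(n, 2, fill::ones);
  mat Q(n, n, fill::zeros);
  double momentum = 0.5;

  for (int iter = 0; iter < n_iter; ++iter) {
    // Student-t kernel q_ij (unnormalized) and its sum Z
    double Z = 0.0;
    const double* y0 = Y.colptr(0);
    const double* y1 = Y.colptr(1);
    for (uword i = 0; i < n; ++i) {
      const double yi0 = y0[i], yi1 = y1[i];
      double* Qcol = Q.colptr(i);
      for (uword j = i + 1; j < n; ++j) {
        const double d0 = yi0 - y0[j], d1 = yi1 - y1[j];
        const double q = 1.0 / (1.0 + d0 * d0 + d1 * d1);
        Qcol[j] = q;
        Q.at(i, j) = q;         // mirror for contiguous reads below
        Z += 2.0 * q;
      }
      Qcol[i] = 0.0;
    }
    if (Z < datum::eps) Z = datum::eps;
    const double invZ = 1.0 / Z;

    // gradient: 4 * sum_j (p_ij - q_ij/Z) * q_ij * (y_i - y_j)
    for (uword i = 0; i < n; ++i) {
      const double yi0 = y0[i], yi1 = y1[i];
      double g0 = 0.0, g1 = 0.0;
      const double* Pcol = P.colptr(i);   // P symmetric: column i == row i
      const double* Qcol = Q.colptr(i);
      for (uword j = 0; j < n; ++j) {
        const double q = Qcol[j];
        const double coef = (Pcol[j] - q * invZ) * q;
        g0 += coef * (yi0 - y0[j]);
        g1 += coef * (yi1 - y1[j]);
      }
      dY(i, 0) = 4.0 * g0;
      dY(i, 1) = 4.0 * g1;
    }

    for (uword i = 0; i < n; ++i) {
      for (uword k = 0; k < 2; ++k) {
        const bool same = (dY(i, k) > 0) == (iY(i, k) > 0);
        double g = same ? gains(i, k) * 0.8 : gains(i, k) + 0.2;
        if (g < 0.01) g = 0.01;
        gains(i, k) = g;
        iY(i, k) = momentum * iY(i, k) - eta * g * dY(i, k);
        Y(i, k) += iY(i, k);
      }
    }
    Y.each_row() -= mean(Y, 0);

    if (iter + 1 == exaggeration_iter) { P /= exaggeration; momentum = 0.8; }
  }
  return Y;
}
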