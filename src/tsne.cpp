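// Exact t-SNE on a precomputed dissimilarity matrix.
// Input affinities p_{j|i} are Gaussian kernels on squared dissimilarities,
// with per-point bandwidths calibrated by bisection to a target perplexity
// (Shannon entropy 2^H = perplexity); the joint P is the symmetrized,
// normalized conditional matrix. The embedding minimizes KL(P || Q) with
// Student-t (df = 1) low-dimensional kernels by gradient descent with
// momentum, gain adaptation and early exaggeration.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat joint_p(const mat& D, double perplexity, double tol = 1e-5) {
  const uword N = D.n_rows;
  mat S = square(D);
  mat P(N, N, fill::zeros);
  const double logU = std::log(perplexity);
  for (uword i = 0; i < N; ++i) {
    double beta = 1.0, betamin = -datum::inf, betamax = datum::inf;
    rowvec Si = S.row(i);
    Si(i) = 0;                               // self term zeroed below
    rowvec Pi;
    for (int iter = 0; iter < 64; ++iter) {
      Pi = exp(-beta * Si);
      Pi(i) = 0;                             // exclude self
      double sumP = accu(Pi);
      if (sumP <= 0) sumP = datum::eps;
      double H = std::log(sumP) + beta * accu(Si % Pi) / sumP;
      Pi /= sumP;
      double diff = H - logU;
      if (std::abs(diff) < tol) break;
      if (diff > 0) {                        // entropy too high: sharpen
        betamin = beta;
        beta = std::isfinite(betamax) ? (beta + betamax) / 2 : beta * 2;
      } else {
        betamax = beta;
        beta = std::isfinite(betamin) ? (beta + betamin) / 2 : beta / 2;
      }
    }
    Pi(i) = 0;
    P.row(i) = Pi;
  }
  P = (P + P.t());
  P /= accu(P);
  P.transform([](double v) { return v < 1e-12 ? 1e-12 : v; });
  P.diag().zeros();
  return P;
}

static double kl_divergence(const mat& P, const mat& Y) {
  const uword N = Y.n_rows;
  mat sq = sum(square(Y), 1) * ones<rowvec>(N);
  mat num = 1.0 / (1.0 + sq + sq.t() - 2.0 * Y * Y.t());
  num.diag().zeros();
  mat Q = num / accu(num);
  Q.transform([](double v) { return v < 1e-12 ? 1e-12 : v; });
  double kl = 0.0;
  for (uword i = 0; i < N; ++i)
    for (uword j = 0; j < N; ++j)
      if (i != j) kl += P(i, j) * std::log(P(i, j) / Q(i, j));
  return kl;
}

// [[Rcpp::export(name = ".tsne_cpp")]]
Rcpp::List tsne_cpp(const arma::mat& D, arma::mat Y, double perplexity,
                    int max_iter, double eta, double exaggeration,
                    int exagg_iter) {
  const uword N = D.n_rows;
  mat P = joint_p(D, perplexity);
  const double kl0 = kl_divergence(P, Y);

  mat dY(N, 2, fill::zeros), iY(N, 2, fill::zeros), gains(N, 2, fill::ones);
  const double min_gain = 0.01;
  std::vector<double> num((size_t)N * N);
  for (int iter = 0; iter < max_iter; ++iter) {
    double ex = iter < exagg_iter ? exaggeration : 1.0;
    // Student-t kernels and their normalizer, lower triangle only
    double sum_num = 0.0;
    for (uword i = 0; i < N; ++i) {
      const double yi0 = Y(i, 0), yi1 = Y(i, 1);
      for (uword j = 0; j < i; ++j) {
        double d0 = yi0 - Y(j, 0), d1 = yi1 - Y(j, 1);
        double q = 1.0 / (1.0 + d0 * d0 + d1 * d1);
        num[i * N + j] = q;
        sum_num += 2.0 * q;
      }
    }
    const double inv_sum = 1.0 / std::max(sum_num, 1e-12);
    dY.zeros();
    for (uword i = 0; i < N; ++i) {
      const double yi0 = Y(i, 0), yi1 = Y(i, 1);
      double g0 = 0.0, g1 = 0.0;
      for (uword j = 0; j < i; ++j) {
        double q = num[i * N + j];
        double Qij = q * inv_sum;
        if (Qij < 1e-12) Qij = 1e-12;
        double mult = (ex * P(i, j) - Qij) * q;
        double d0 = yi0 - Y(j, 0), d1 = yi1 - Y(j, 1);
        g0 += mult * d0;           // force on i from j
        g1 += mult * d1;
        dY(j, 0) -= 4.0 * mult * d0;  // equal and opposite on j
        dY(j, 1) -= 4.0 * mult * d1;
      }
      dY(i, 0) += 4.0 * g0;
      dY(i, 1) += 4.0 * g1;
    }
    double momentum = iter < 250 ? 0.5 : 0.8;
    umat same = (dY > 0) == (iY > 0);
    gains = gains % (0.8 * conv_to<mat>::from(same) +
                     1.0 * conv_to<mat>::from(1 - same)) +
            0.2 * conv_to<mat>::from(1 - same);
    gains.transform([min_gain](double v) { return v < min_gain ? min_gain : v; });
    iY = momentum * iY - eta * (gains % dY);
    Y += iY;
    Y.each_row() -= mean(Y, 0);
    if (iter % 50 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("Y") = Y,
                            Rcpp::Named("kl_initial") = kl0,
                            Rcpp::Named("kl_final") = kl_divergence(P, Y));
}
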