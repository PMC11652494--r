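#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact t-SNE (no Barnes-Hut approximation). The self-calibration buffer is
// bounded at 1,500 samples, so the O(n^2) gradient is tractable; exactness
// keeps the embedding deterministic given R's RNG state. Pairwise tables
// are held in single precision: they are re-derived every iteration and
// only steer a 3-D layout used for clustering, so float rounding is
// irrelevant while halving memory traffic of the O(n^2) passes.

static void input_similarities(const NumericMatrix &X, double perplexity,
                               std::vector<float> &P) {
  const int n = X.nrow(), d = X.ncol();
  std::vector<double> D((size_t)n * n, 0.0);
  std::vector<double> xi(d);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < d; ++k) xi[k] = X(i, k);
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = xi[k] - X(j, k);
        s += diff * diff;
      }
      D[(size_t)i * n + j] = s;
      D[(size_t)j * n + i] = s;
    }
  }

  const double logU = std::log(perplexity);
  std::vector<double> row(n);
  for (int i = 0; i < n; ++i) {
    double beta = 1.0, betamin = -1.0, betamax = -1.0;
    double sumP = 0.0;
    const double *Di = &D[(size_t)i * n];
    for (int iter = 0; iter < 50; ++iter) {
      sumP = 0.0;
      double sumDP = 0.0;
      for (int j = 0; j < n; ++j) {
        if (j == i) { row[j] = 0.0; continue; }
        double pj = std::exp(-beta * Di[j]);
        row[j] = pj;
        sumP += pj;
        sumDP += Di[j] * pj;
      }
      if (sumP <= 0) sumP = 1e-300;
      double H = std::log(sumP) + beta * sumDP / sumP;
      double diff = H - logU;
      if (std::fabs(diff) < 1e-5) break;
      if (diff > 0) {
        betamin = beta;
        beta = (betamax < 0) ? beta * 2.0 : 0.5 * (beta + betamax);
      } else {
        betamax = beta;
        beta = (betamin < 0) ? beta / 2.0 : 0.5 * (beta + betamin);
      }
    }
    for (int j = 0; j < n; ++j)
      P[(size_t)i * n + j] = (float)(row[j] / sumP);
  }
}

// [[Rcpp::export]]
NumericMatrix tsne_cpp(NumericMatrix X, int out_dim, double perplexity,
                       int max_iter, double exaggeration, int exag_iter,
                       double eta, int momentum_switch) {
  const int n = X.nrow();
  std::vector<float> P((size_t)n * n, 0.0f);
  input_similarities(X, perplexity, P);

  // symmetrize, normalize to a joint distribution, apply early exaggeration
  double psum = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      float v = 0.5f * (P[(size_t)i * n + j] + P[(size_t)j * n + i]);
      P[(size_t)i * n + j] = v;
      P[(size_t)j * n + i] = v;
      psum += 2.0 * v;
    }
  if (psum <= 0) psum = 1e-300;
  float scale = (float)(exaggeration / psum);
  for (size_t t = 0; t < P.size(); ++t) {
    P[t] *= scale;
    if (P[t] < 1e-12f) P[t] = 1e-12f;
  }

  if (eta <= 0) eta = std::max(200.0, n / 12.0);

  std::vector<double> Y((size_t)n * out_dim), dY((size_t)n * out_dim, 0.0),
      iY((size_t)n * out_dim, 0.0), gains((size_t)n * out_dim, 1.0);
  for (size_t t = 0; t < Y.size(); ++t) Y[t] = norm_rand() * 1e-4;

  std::vector<float> num((size_t)n * n, 0.0f);
  for (int iter = 0; iter < max_iter; ++iter) {
    // pairwise Student-t kernel in the embedding
    double sumQ = 0.0;
    for (int i = 0; i < n; ++i) {
      const double *yi = &Y[(size_t)i * out_dim];
      float *numi = &num[(size_t)i * n];
      double rowQ = 0.0;
      for (int j = i + 1; j < n; ++j) {
        const double *yj = &Y[(size_t)j * out_dim];
        double s = 0.0;
        for (int k = 0; k < out_dim; ++k) {
          double diff = yi[k] - yj[k];
          s += diff * diff;
        }
        float q = (float)(1.0 / (1.0 + s));
        numi[j] = q;
        rowQ += q;
      }
      sumQ += rowQ;
    }
    sumQ *= 2.0;
    if (sumQ < 1e-300) sumQ = 1e-300;
    const float invQ = (float)(1.0 / sumQ);

    std::fill(dY.begin(), dY.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      double *gi = &dY[(size_t)i * out_dim];
      const double *yi = &Y[(size_t)i * out_dim];
      const float *numi = &num[(size_t)i * n];
      const float *Pi = &P[(size_t)i * n];
      for (int j = i + 1; j < n; ++j) {
        float q = numi[j];
        double mult = (double)((Pi[j] - q * invQ) * q);
        const double *yj = &Y[(size_t)j * out_dim];
        double *gj = &dY[(size_t)j * out_dim];
        for (int k = 0; k < out_dim; ++k) {
          double g = mult * (yi[k] - yj[k]);
          gi[k] += g;
          gj[k] -= g;
        }
      }
    }

    double momentum = (iter < momentum_switch) ? 0.5 : 0.8;
    for (size_t t = 0; t < Y.size(); ++t) {
      double g = 4.0 * dY[t];
      gains[t] = ((g > 0) == (iY[t] > 0)) ? gains[t] * 0.8 : gains[t] + 0.2;
      if (gains[t] < 0.01) gains[t] = 0.01;
      iY[t] = momentum * iY[t] - eta * gains[t] * g;
      Y[t] += iY[t];
    }
    // re-center
    for (int k = 0; k < out_dim; ++k) {
      double m = 0.0;
      for (int i = 0; i < n; ++i) m += Y[(size_t)i * out_dim + k];
      m /= n;
      for (int i = 0; i < n; ++i) Y[(size_t)i * out_dim + k] -= m;
    }

    if (iter + 1 == exag_iter) {
      float inv_ex = (float)(1.0 / exaggeration);
      for (size_t t = 0; t < P.size(); ++t) P[t] *= inv_ex;
    }
  }

  NumericMatrix out(n, out_dim);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < out_dim; ++k) out(i, k) = Y[(size_t)i * out_dim + k];
  return out;
}
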