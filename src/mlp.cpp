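// Minimal feed-forward network: p inputs -> H sigmoidal hidden units ->
// 1 linear output, trained by full-batch back-propagation with momentum and
// early stopping on a validation split. Deterministic given the initial
// weights and splits (all randomness is drawn on the R side).
//
// Weight layout (flat vector, length p*H + 2*H + 1):
//   W1[i + p*h]  input i -> hidden h      (i in 0..p-1, h in 0..H-1)
//   b1[h]        at offset p*H
//   w2[h]        hidden h -> output, at offset p*H + H
//   b2           last element

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double sigm(double x) { return 1.0 / (1.0 + std::exp(-x)); }

static double predict_one(const double* x, int stride, int p, int H,
                          const std::vector<double>& w) {
  const double* W1 = w.data();
  const double* b1 = w.data() + (size_t)p * H;
  const double* w2 = b1 + H;
  double out = w2[H];  // b2
  for (int h = 0; h < H; ++h) {
    double a = b1[h];
    const double* col = W1 + (size_t)p * h;
    for (int i = 0; i < p; ++i) a += x[(size_t)i * stride] * col[i];
    out += sigm(a) * w2[h];
  }
  return out;
}

static double mse_on(const NumericMatrix& X, const NumericVector& y,
                     const IntegerVector& idx, int p, int H,
                     const std::vector<double>& w) {
  if (idx.size() == 0) return NA_REAL;
  double s = 0.0;
  for (int k = 0; k < idx.size(); ++k) {
    int r = idx[k] - 1;
    double e = predict_one(&X(r, 0), X.nrow(), p, H, w) - y[r];
    s += e * e;
  }
  return s / idx.size();
}

// [[Rcpp::export]]
NumericVector mlp_predict_cpp(NumericMatrix X, NumericVector w, int hidden) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> wv(w.begin(), w.end());
  NumericVector out(n);
  for (int s = 0; s < n; ++s)
    out[s] = predict_one(&X(s, 0), n, p, hidden, wv);
  return out;
}

// [[Rcpp::export]]
List mlp_train_cpp(NumericMatrix X, NumericVector y, IntegerVector train,
                   IntegerVector val, NumericVector w0, int hidden, double lr,
                   double momentum, int max_epochs, int patience) {
  const int p = X.ncol(), H = hidden, n = X.nrow();
  const int ntr = train.size();
  const size_t nw = w0.size();
  std::vector<double> w(w0.begin(), w0.end()), vel(nw, 0.0), grad(nw, 0.0);
  std::vector<double> best(w), z(H);
  double best_val = mse_on(X, y, val, p, H, w);
  int best_epoch = 0, epoch = 0;
  for (epoch = 1; epoch <= max_epochs; ++epoch) {
    std::fill(grad.begin(), grad.end(), 0.0);
    double* gW1 = grad.data();
    double* gb1 = grad.data() + (size_t)p * H;
    double* gw2 = gb1 + H;
    const double* W1 = w.data();
    const double* b1 = w.data() + (size_t)p * H;
    const double* w2 = b1 + H;
    for (int k = 0; k < ntr; ++k) {
      int s = train[k] - 1;
      double out = w2[H];
      for (int h = 0; h < H; ++h) {
        double a = b1[h];
        const double* col = W1 + (size_t)p * h;
        for (int i = 0; i < p; ++i) a += X(s, i) * col[i];
        z[h] = sigm(a);
        out += z[h] * w2[h];
      }
      double delta = 2.0 * (out - y[s]) / ntr;
      gw2[H] += delta;
      for (int h = 0; h < H; ++h) {
        gw2[h] += delta * z[h];
        double dz = delta * w2[h] * z[h] * (1.0 - z[h]);
        gb1[h] += dz;
        double* gcol = gW1 + (size_t)p * h;
        for (int i = 0; i < p; ++i) gcol[i] += dz * X(s, i);
      }
    }
    for (size_t j = 0; j < nw; ++j) {
      vel[j] = momentum * vel[j] - lr * grad[j];
      w[j] += vel[j];
    }
    double vm = mse_on(X, y, val, p, H, w);
    if (vm < best_val - 1e-12) {
      best_val = vm;
      best = w;
      best_epoch = epoch;
    } else if (epoch - best_epoch >= patience) {
      break;
    }
  }
  (void)n;
  return List::create(_["weights"] = NumericVector(best.begin(), best.end()),
                      _["val_mse"] = best_val, _["epochs"] = epoch);
}
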