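#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Small feed-forward network d -> h1 -> h2 -> 1 with tanh hidden activations
// and a sigmoid (or identity) output, trained by (stochastic) gradient
// descent with momentum on the squared-error loss.  The training loop lives
// in C++ because the default regime updates the weights once per pattern:
// n * epochs updates of a tiny network, which is pure loop overhead in R.

static inline double sigmoidc(double z) { return 1.0 / (1.0 + std::exp(-z)); }

struct Net {
  int d, h1, h2;
  std::vector<double> W1, b1, W2, b2, W3;
  double b3;

  Net(const List& w) {
    NumericMatrix W1m = w["W1"], W2m = w["W2"];
    NumericVector b1v = w["b1"], b2v = w["b2"], W3v = w["W3"];
    d = W1m.nrow(); h1 = W1m.ncol(); h2 = W2m.ncol();
    W1.assign(W1m.begin(), W1m.end());
    W2.assign(W2m.begin(), W2m.end());
    W3.assign(W3v.begin(), W3v.end());
    b1.assign(b1v.begin(), b1v.end());
    b2.assign(b2v.begin(), b2v.end());
    b3 = as<double>(w["b3"]);
  }

  List to_list() const {
    NumericMatrix W1m(d, h1), W2m(h1, h2);
    std::copy(W1.begin(), W1.end(), W1m.begin());
    std::copy(W2.begin(), W2.end(), W2m.begin());
    return List::create(_["W1"] = W1m, _["b1"] = NumericVector(b1.begin(), b1.end()),
                        _["W2"] = W2m, _["b2"] = NumericVector(b2.begin(), b2.end()),
                        _["W3"] = NumericVector(W3.begin(), W3.end()),
                        _["b3"] = b3);
  }

  // forward pass for row i of X (n x d, column-major); fills a1 (h1), a2 (h2)
  double forward(const double* X, int n, int i, bool sigmoid_out,
                 double* a1, double* a2) const {
    for (int j = 0; j < h1; ++j) {
      double z = b1[j];
      for (int k = 0; k < d; ++k) z += X[k * n + i] * W1[j * d + k];
      a1[j] = std::tanh(z);
    }
    for (int j = 0; j < h2; ++j) {
      double z = b2[j];
      for (int k = 0; k < h1; ++k) z += a1[k] * W2[j * h1 + k];
      a2[j] = std::tanh(z);
    }
    double z = b3;
    for (int k = 0; k < h2; ++k) z += a2[k] * W3[k];
    return sigmoid_out ? sigmoidc(z) : z;
  }
};

// mean squared error over all rows
static double full_mse(const Net& net, const double* X, const double* y,
                       int n, bool sigmoid_out) {
  std::vector<double> a1(net.h1), a2(net.h2);
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    double p = net.forward(X, n, i, sigmoid_out, a1.data(), a2.data());
    double e = p - y[i];
    s += e * e;
  }
  return s / n;
}

// [[Rcpp::export]]
List ann_train_cpp(NumericMatrix X, NumericVector y, List init,
                   double lr, double momentum, int epochs,
                   bool online, bool sigmoid_out, bool trace) {
  const int n = X.nrow();
  Net net(init);
  const int d = net.d, h1 = net.h1, h2 = net.h2;
  if (X.ncol() != d) stop("input dimension does not match the network");

  std::vector<double> vW1(d * h1, 0.0), vb1(h1, 0.0);
  std::vector<double> vW2(h1 * h2, 0.0), vb2(h2, 0.0);
  std::vector<double> vW3(h2, 0.0); double vb3 = 0.0;

  std::vector<double> a1(h1), a2(h2), d1(h1), d2(h2);
  std::vector<double> gW1(d * h1), gb1(h1), gW2(h1 * h2), gb2(h2), gW3(h2);
  double gb3;

  NumericVector loss_trace(trace ? epochs : 0);
  const double* Xp = X.begin();
  const double* yp = y.begin();

  for (int ep = 0; ep < epochs; ++ep) {
    if (!online) {
      std::fill(gW1.begin(), gW1.end(), 0.0); std::fill(gb1.begin(), gb1.end(), 0.0);
      std::fill(gW2.begin(), gW2.end(), 0.0); std::fill(gb2.begin(), gb2.end(), 0.0);
      std::fill(gW3.begin(), gW3.end(), 0.0); gb3 = 0.0;
    }
    for (int i = 0; i < n; ++i) {
      double p = net.forward(Xp, n, i, sigmoid_out, a1.data(), a2.data());
      double e = p - yp[i];
      double d3 = sigmoid_out ? e * p * (1.0 - p) : e;
      // hidden deltas
      for (int j = 0; j < h2; ++j)
        d2[j] = net.W3[j] * d3 * (1.0 - a2[j] * a2[j]);
      for (int j = 0; j < h1; ++j) {
        double s = 0.0;
        for (int k = 0; k < h2; ++k) s += net.W2[k * h1 + j] * d2[k];
        d1[j] = s * (1.0 - a1[j] * a1[j]);
      }
      if (online) {
        // per-pattern update with momentum
        for (int k = 0; k < h2; ++k) {
          vW3[k] = momentum * vW3[k] - lr * a2[k] * d3;
          net.W3[k] += vW3[k];
        }
        vb3 = momentum * vb3 - lr * d3; net.b3 += vb3;
        for (int j = 0; j < h2; ++j) {
          for (int k = 0; k < h1; ++k) {
            int idx = j * h1 + k;
            vW2[idx] = momentum * vW2[idx] - lr * a1[k] * d2[j];
            net.W2[idx] += vW2[idx];
          }
          vb2[j] = momentum * vb2[j] - lr * d2[j]; net.b2[j] += vb2[j];
        }
        for (int j = 0; j < h1; ++j) {
          for (int k = 0; k < d; ++k) {
            int idx = j * d + k;
            vW1[idx] = momentum * vW1[idx] - lr * Xp[k * n + i] * d1[j];
            net.W1[idx] += vW1[idx];
          }
          vb1[j] = momentum * vb1[j] - lr * d1[j]; net.b1[j] += vb1[j];
        }
      } else {
        for (int k = 0; k < h2; ++k) gW3[k] += a2[k] * d3;
        gb3 += d3;
        for (int j = 0; j < h2; ++j) {
          for (int k = 0; k < h1; ++k) gW2[j * h1 + k] += a1[k] * d2[j];
          gb2[j] += d2[j];
        }
        for (int j = 0; j < h1; ++j) {
          for (int k = 0; k < d; ++k) gW1[j * d + k] += Xp[k * n + i] * d1[j];
          gb1[j] += d1[j];
        }
      }
    }
    if (!online) {
      const double inv_n = 1.0 / n;
      for (int k = 0; k < h2; ++k) {
        vW3[k] = momentum * vW3[k] - lr * gW3[k] * inv_n; net.W3[k] += vW3[k];
      }
      vb3 = momentum * vb3 - lr * gb3 * inv_n; net.b3 += vb3;
      for (size_t k = 0; k < vW2.size(); ++k) {
        vW2[k] = momentum * vW2[k] - lr * gW2[k] * inv_n; net.W2[k] += vW2[k];
      }
      for (int j = 0; j < h2; ++j) {
        vb2[j] = momentum * vb2[j] - lr * gb2[j] * inv_n; net.b2[j] += vb2[j];
      }
      for (size_t k = 0; k < vW1.size(); ++k) {
        vW1[k] = momentum * vW1[k] - lr * gW1[k] * inv_n; net.W1[k] += vW1[k];
      }
      for (int j = 0; j < h1; ++j) {
        vb1[j] = momentum * vb1[j] - lr * gb1[j] * inv_n; net.b1[j] += vb1[j];
      }
    }
    if (trace) {
      double L = full_mse(net, Xp, yp, n, sigmoid_out);
      if (!std::isfinite(L))
        stop("training loss became non-finite at epoch %d; reduce the learning rate", ep + 1);
      loss_trace[ep] = L;
    } else if (ep == epochs - 1 || (ep % 50) == 49) {
      if (!std::isfinite(net.b3))
        stop("training diverged (non-finite weights); reduce the learning rate");
    }
  }

  // fitted values from the final weights
  NumericVector fitted(n);
  for (int i = 0; i < n; ++i)
    fitted[i] = net.forward(Xp, n, i, sigmoid_out, a1.data(), a2.data());

  return List::create(_["weights"] = net.to_list(), _["fitted"] = fitted,
                      _["loss_trace"] = loss_trace);
}

// [[Rcpp::export]]
NumericVector ann_forward_cpp(NumericMatrix X, List weights, bool sigmoid_out) {
  Net net(weights);
  if (X.ncol() != net.d) stop("input dimension does not match the network");
  const int n = X.nrow();
  std::vector<double> a1(net.h1), a2(net.h2);
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = net.forward(X.begin(), n, i, sigmoid_out, a1.data(), a2.data());
  return out;
}
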