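#include <Rcpp.h>
using namespace Rcpp;

// Single sigmoid unit trained on mean cross-entropy by full-batch gradient
// descent with a bold-driver step size (deterministic; zero init; convex
// loss). Training halts on whichever fires first:
//   (1) validation error rises for `patience` successive epochs -> return
//       the weights at minimum validation error,
//   (2) gradient infinity-norm < grad_tol,
//   (3) max_epochs reached.

static double xent(const NumericMatrix& X, const IntegerVector& y,
                   const std::vector<double>& w, double b) {
  const double eps = 1e-12;
  double loss = 0.0;
  int n = X.nrow(), p = X.ncol();
  for (int i = 0; i < n; ++i) {
    double z = b;
    for (int j = 0; j < p; ++j) z += X(i, j) * w[j];
    double pr = 1.0 / (1.0 + std::exp(-z));
    pr = std::min(1.0 - eps, std::max(eps, pr));
    loss += y[i] ? -std::log(pr) : -std::log(1.0 - pr);
  }
  return loss / n;
}

// [[Rcpp::export(name = ".train_logistic_unit")]]
List train_logistic_unit(NumericMatrix X, IntegerVector y,
                         NumericMatrix Xval, IntegerVector yval,
                         int max_epochs, int patience, double grad_tol,
                         double lr0) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> w(p, 0.0), best_w(p, 0.0), grad(p);
  double b = 0.0, best_b = 0.0, gb;
  double lr = lr0;
  double prev_loss = R_PosInf;
  double best_val = R_PosInf, prev_val = R_PosInf;
  int rising = 0;
  int epoch = 0;
  std::string reason = "max_epochs";

  for (epoch = 1; epoch <= max_epochs; ++epoch) {
    // gradient of mean cross-entropy
    std::fill(grad.begin(), grad.end(), 0.0);
    gb = 0.0;
    double loss = 0.0;
    const double eps = 1e-12;
    for (int i = 0; i < n; ++i) {
      double z = b;
      for (int j = 0; j < p; ++j) z += X(i, j) * w[j];
      double pr = 1.0 / (1.0 + std::exp(-z));
      double e = pr - (double)y[i];
      for (int j = 0; j < p; ++j) grad[j] += e * X(i, j);
      gb += e;
      double pc = std::min(1.0 - eps, std::max(eps, pr));
      loss += y[i] ? -std::log(pc) : -std::log(1.0 - pc);
    }
    loss /= n;
    double gmax = std::abs(gb / n);
    for (int j = 0; j < p; ++j)
      gmax = std::max(gmax, std::abs(grad[j] / n));
    if (gmax < grad_tol) { reason = "gradient"; break; }

    // bold driver: shrink step on loss increase, grow slowly otherwise
    if (loss > prev_loss) lr *= 0.5; else lr *= 1.05;
    prev_loss = loss;
    for (int j = 0; j < p; ++j) w[j] -= lr * grad[j] / n;
    b -= lr * gb / n;

    double vloss = xent(Xval, yval, w, b);
    if (vloss < best_val) { best_val = vloss; best_w = w; best_b = b; }
    if (vloss > prev_val) ++rising; else rising = 0;
    prev_val = vloss;
    if (rising >= patience) { reason = "patience"; break; }
  }
  if (reason == "patience") { w = best_w; b = best_b; }
  return List::create(_["weights"] = NumericVector(w.begin(), w.end()),
                      _["bias"] = b,
                      _["epochs"] = std::min(epoch, max_epochs),
                      _["stop_reason"] = reason,
                      _["val_error"] = best_val);
}

// Sigmoid outputs for a weight vector (used by predict and the decoding
// drivers; kept in C++ so the per-repeat loops stay cheap).
// [[Rcpp::export(name = ".sigmoid_scores")]]
NumericVector sigmoid_scores(NumericMatrix X, NumericVector w, double b) {
  int n = X.nrow(), p = X.ncol();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double z = b;
    for (int j = 0; j < p; ++j) z += X(i, j) * w[j];
    out[i] = 1.0 / (1.0 + std::exp(-z));
  }
  return out;
}
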