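#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Stochastic gradient descent for the regularized factorization R ~ X Y^T
// over the observed lower-triangular entries.  One epoch visits the
// observed entries (i > j) in fixed row-major order; within one entry
// update the residual e_ij is computed once and both the row x_i and the
// row y_j updates use the pre-update coordinate values:
//   e_ij = r_ij - sum_k x_ik y_jk
//   x_ik <- x_ik + alpha (2 e_ij y_jk - beta x_ik)
//   y_jk <- y_jk + alpha (2 e_ij x_ik - beta y_jk)
// The per-epoch total error E is the sum of e_ij^2 accumulated during the
// pass; training stops when E < tol or after max_iter epochs.
// [[Rcpp::export]]
List mf_train_cpp(NumericMatrix X0, NumericMatrix Y0, NumericMatrix R,
                  LogicalMatrix obs, double alpha, double beta,
                  int max_iter, double tol) {
  NumericMatrix X = clone(X0);
  NumericMatrix Y = clone(Y0);
  const int N = R.nrow();
  const int K = X.ncol();

  std::vector<int> ri, rj;
  for (int i = 1; i < N; ++i)
    for (int j = 0; j < i; ++j)
      if (obs(i, j)) { ri.push_back(i); rj.push_back(j); }
  if (ri.empty()) stop("no observed off-diagonal entries");

  std::vector<double> trace;
  trace.reserve(std::min(max_iter, 100000));
  for (int epoch = 0; epoch < max_iter; ++epoch) {
    double E = 0.0;
    for (size_t t = 0; t < ri.size(); ++t) {
      const int i = ri[t], j = rj[t];
      double rhat = 0.0;
      for (int k = 0; k < K; ++k) rhat += X(i, k) * Y(j, k);
      const double e = R(i, j) - rhat;
      for (int k = 0; k < K; ++k) {
        const double xk = X(i, k), yk = Y(j, k);
        X(i, k) = xk + alpha * (2.0 * e * yk - beta * xk);
        Y(j, k) = yk + alpha * (2.0 * e * xk - beta * yk);
      }
      E += e * e;
    }
    trace.push_back(E);
    if (!std::isfinite(E) || E > 1e12)
      stop("matrix factorization diverged (E = %g at epoch %d); "
           "rescale the matrix or lower alpha", E, epoch + 1);
    if (E < tol) break;
  }
  return List::create(_["X"] = X, _["Y"] = Y,
                      _["error_trace"] = NumericVector(trace.begin(), trace.end()));
}
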