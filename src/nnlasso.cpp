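#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for the non-negative lasso
//   min 0.5 * ||y - X b||^2 + lam * sum(b),  b >= 0
// on the precomputed Gram matrix G = X'X and q = X'y. The gradient vector
// v = G b is maintained incrementally, so a full sweep costs O(p) per
// active coordinate update. Columns with zero norm keep weight zero.
//
// [[Rcpp::export(name = ".nnlasso_cd")]]
List nnlasso_cd(NumericMatrix G, NumericVector q, double yty, double lam,
                int max_sweeps, double tol) {
  const int p = G.ncol();
  NumericVector b(p), v(p);
  NumericVector h = NumericVector(p);
  for (int c = 0; c < p; ++c) h[c] = G(c, c);
  std::vector<double> trace;
  trace.reserve(64);
  bool converged = false;
  int sweeps = 0;
  while (sweeps < max_sweeps) {
    ++sweeps;
    double delta = 0.0;
    for (int c = 0; c < p; ++c) {
      if (h[c] <= 0.0) continue;
      double g = q[c] - v[c] + h[c] * b[c];
      double b_new = (g - lam) / h[c];
      if (b_new < 0.0) b_new = 0.0;
      double d = b_new - b[c];
      if (d != 0.0) {
        for (int k = 0; k < p; ++k) v[k] += G(k, c) * d;
        b[c] = b_new;
        double ad = d < 0 ? -d : d;
        if (ad > delta) delta = ad;
      }
    }
    double quad = 0.0, lin = 0.0, l1 = 0.0;
    for (int c = 0; c < p; ++c) {
      quad += b[c] * v[c];
      lin += q[c] * b[c];
      l1 += b[c];
    }
    trace.push_back(0.5 * (yty - 2.0 * lin + quad) + lam * l1);
    if (delta < tol) {
      converged = true;
      break;
    }
  }
  return List::create(_["b"] = b, _["objective_trace"] = wrap(trace),
                      _["sweeps"] = sweeps, _["converged"] = converged);
}
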