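#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Relaxed disjunctive-normal-form path loss and its derivative structure.
//
// For a root-to-leaf path with region scores f_1..f_n in [0,1], the
// disjuncts are "exactly node j is selected" (j = 1..n) plus the
// all-negated empty selection:
//   P_j = f_j * prod_{k != j} (1 - f_k),   P_0 = prod_k (1 - f_k)
//   F   = 1 - prod_{j = 0..n} (1 - P_j)
// F equals the at-most-one-per-path indicator at binary scores.
//
// For the gradient of the unsupervised loss ||1 - F||^2 / (2 s^2) with
// respect to the classifier weights, dF_i/dw = sum_m c_{i,m} df_m/dw, so it
// suffices to accumulate per-region scalars
//   coef_r = sum_{paths i} (1 - F_i) * c_{i, r}.
// All products are over factors in [0, 1]; underflow to 0 is the correct
// limit, so plain prefix/suffix products are numerically safe.
//
// f: scores per region (length R); paths: list of 1-based index vectors.
// [[Rcpp::export]]
List path_loss_terms(NumericVector f, List paths, bool want_coef) {
  const int npath = paths.size();
  const int nreg = f.size();
  NumericVector F(npath);
  NumericVector coef(want_coef ? nreg : 0);

  std::vector<double> u, pre, suf, P, Q, vpre, vsuf, A, c;
  for (int i = 0; i < npath; ++i) {
    IntegerVector idx = paths[i];
    const int n = idx.size();
    u.assign(n, 0.0);
    for (int k = 0; k < n; ++k) {
      const int r = idx[k] - 1;
      if (r < 0 || r >= nreg) stop("path index out of range");
      u[k] = 1.0 - f[r];
    }
    // prefix/suffix products of u; pre[k] = u_0..u_{k-1}, suf[k] = u_k..u_{n-1}
    pre.assign(n + 1, 1.0);
    suf.assign(n + 1, 1.0);
    for (int k = 0; k < n; ++k) pre[k + 1] = pre[k] * u[k];
    for (int k = n - 1; k >= 0; --k) suf[k] = suf[k + 1] * u[k];

    // disjunct products: P[0] empty selection, P[1..n] single selections
    P.assign(n + 1, 0.0);
    Q.assign(n, 0.0);  // Q[m] = prod_{k != m} u_k
    P[0] = pre[n];
    for (int m = 0; m < n; ++m) {
      Q[m] = pre[m] * suf[m + 1];
      const int r = idx[m] - 1;
      P[m + 1] = f[r] * Q[m];
    }

    // v_j = 1 - P_j; leave-one-out products A_j = prod_{r != j} v_r
    const int nd = n + 1;
    vpre.assign(nd + 1, 1.0);
    vsuf.assign(nd + 1, 1.0);
    for (int j = 0; j < nd; ++j) vpre[j + 1] = vpre[j] * (1.0 - P[j]);
    for (int j = nd - 1; j >= 0; --j) vsuf[j] = vsuf[j + 1] * (1.0 - P[j]);
    const double Fi = 1.0 - vpre[nd];
    F[i] = Fi;
    if (!want_coef) continue;

    A.assign(nd, 0.0);
    for (int j = 0; j < nd; ++j) A[j] = vpre[j] * vsuf[j + 1];

    // c_m = dF/df_m = (A_{m+1} - A_0) * Q_m
    //       - sum_{j != m, j >= 1} A_j f_j * prod_{k != j, m} u_k
    c.assign(n, 0.0);
    for (int m = 0; m < n; ++m)
      c[m] = (A[m + 1] - A[0]) * Q[m];
    for (int m = 0; m < n; ++m) {
      double mid = 1.0;  // prod of u over the exclusive range (j, m)
      for (int j = m - 1; j >= 0; --j) {
        const double Qjm = pre[j] * mid * suf[m + 1];
        c[m] -= A[j + 1] * f[idx[j] - 1] * Qjm;
        mid *= u[j];
      }
      mid = 1.0;
      for (int j = m + 1; j < n; ++j) {
        const double Qjm = pre[m] * mid * suf[j + 1];
        c[m] -= A[j + 1] * f[idx[j] - 1] * Qjm;
        mid *= u[j];
      }
    }
    const double wi = 1.0 - Fi;
    for (int m = 0; m < n; ++m) coef[idx[m] - 1] += wi * c[m];
  }

  if (want_coef) return List::create(_["F"] = F, _["coef"] = coef);
  return List::create(_["F"] = F);
}
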