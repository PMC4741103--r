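#include <Rcpp.h>
using namespace Rcpp;

// Activities of K local views against the first nW prototype columns of W.
// A[j,k] = max(0, 1 - mean_i |W[i,j] - V[i,k]|); W may have spare capacity
// columns beyond nW, which are ignored (no copy of the prototype bank).
// [[Rcpp::export]]
NumericMatrix vf_activity_cpp(NumericMatrix W, int nW, NumericMatrix V) {
  const int D = V.nrow(), K = V.ncol();
  if (nW < 0 || nW > W.ncol())
    stop("invalid active prototype count");
  if (nW > 0 && W.nrow() != D)
    stop("view length does not match prototype length");
  NumericMatrix A(nW, K);
  for (int k = 0; k < K; ++k) {
    const double *vk = &V(0, k);
    for (int j = 0; j < nW; ++j) {
      const double *wj = &W(0, j);
      double s = 0.0;
      for (int i = 0; i < D; ++i) s += std::fabs(wj[i] - vk[i]);
      double a = 1.0 - s / D;
      A(j, k) = a > 0.0 ? a : 0.0;
    }
  }
  return A;
}

// One incremental-learning step for a single view. Mutates W in place:
// either recruits a new prototype into column nW (caller guarantees spare
// capacity and increments its own count) or averages the winner column
// W[,k] += eps*(view - W[,k])*(1 - a_k). Ties at the max go to the smallest
// index. Returns the 1-based winner, the recruitment flag, and the activity
// vector over the (possibly grown) bank, with a freshly recruited neuron at
// activity 1.
// [[Rcpp::export]]
List vf_learn_cpp(NumericMatrix W, int nW, NumericVector view,
                  double gamma, double eps) {
  const int D = view.size();
  if (nW > 0 && W.nrow() != D)
    stop("view length does not match prototype length");
  for (int i = 0; i < D; ++i)
    if (!R_finite(view[i])) stop("non-finite view entries");
  NumericVector act(nW);
  int win = -1;
  double best = -1.0;
  for (int j = 0; j < nW; ++j) {
    const double *wj = &W(0, j);
    double s = 0.0;
    for (int i = 0; i < D; ++i) s += std::fabs(wj[i] - view[i]);
    double a = 1.0 - s / D;
    if (a < 0.0) a = 0.0;
    act[j] = a;
    if (a > best) { best = a; win = j; }
  }
  const bool recruit = (nW == 0) || (best < gamma);
  const double bestPre = nW == 0 ? 0.0 : best;  // familiarity before learning
  if (recruit) {
    if (nW >= W.ncol()) stop("prototype bank has no spare capacity");
    for (int i = 0; i < D; ++i) W(i, nW) = view[i];
    NumericVector act2(nW + 1);
    for (int j = 0; j < nW; ++j) act2[j] = act[j];
    act2[nW] = 1.0;
    return List::create(_["winner"] = nW + 1, _["recruited"] = true,
                        _["best_pre"] = bestPre, _["activities"] = act2);
  }
  const double coef = eps * (1.0 - best);
  for (int i = 0; i < D; ++i) W(i, win) += coef * (view[i] - W(i, win));
  return List::create(_["winner"] = win + 1, _["recruited"] = false,
                      _["best_pre"] = bestPre, _["activities"] = act);
}
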