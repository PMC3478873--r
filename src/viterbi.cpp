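#include <Rcpp.h>
using namespace Rcpp;

// Generic max-product (Viterbi) decoder over an expanded state graph.
//
// The graph is given as per-state predecessor lists in compressed form:
// predecessors of expanded state j are pred_idx[pred_ptr[j] .. pred_ptr[j+1]-1]
// (0-based expanded ids) with log transition weights pred_logw at the same
// positions. Emissions are looked up through state_of, which maps each
// expanded state to its base state (0-based row of log_emis). Ties are broken
// deterministically: predecessor lists are iterated in ascending expanded-id
// order and only a strict improvement replaces the incumbent, so the lowest
// index wins.
// [[Rcpp::export]]
List viterbi_core(NumericVector log_init,
                  IntegerVector pred_ptr,
                  IntegerVector pred_idx,
                  NumericVector pred_logw,
                  IntegerVector state_of,
                  NumericMatrix log_emis,
                  IntegerVector obs,
                  LogicalVector final_ok) {
  const int n = log_init.size();
  const R_xlen_t T = obs.size();
  if (T == 0)
    return List::create(_["path"] = IntegerVector(0),
                        _["logp"] = R_NegInf);

  std::vector<double> cur(n), nxt(n);
  IntegerMatrix bp(n, T);  // backpointers; column 0 unused

  for (int j = 0; j < n; ++j)
    cur[j] = log_init[j] + log_emis(state_of[j], obs[0]);

  for (R_xlen_t t = 1; t < T; ++t) {
    for (int j = 0; j < n; ++j) {
      double best = R_NegInf;
      int arg = -1;
      for (int k = pred_ptr[j]; k < pred_ptr[j + 1]; ++k) {
        const double s = cur[pred_idx[k]] + pred_logw[k];
        if (s > best) { best = s; arg = pred_idx[k]; }
      }
      nxt[j] = (arg < 0 || best == R_NegInf)
                 ? R_NegInf
                 : best + log_emis(state_of[j], obs[t]);
      bp(j, t) = arg;
    }
    std::swap(cur, nxt);
  }

  double best = R_NegInf;
  int last = -1;
  for (int j = 0; j < n; ++j)
    if (final_ok[j] && cur[j] > best) { best = cur[j]; last = j; }

  if (last < 0)
    return List::create(_["path"] = IntegerVector(0),
                        _["logp"] = R_NegInf);

  IntegerVector path(T);
  path[T - 1] = last;
  for (R_xlen_t t = T - 1; t > 0; --t)
    path[t - 1] = bp(path[t], t);
  for (R_xlen_t t = 0; t < T; ++t) path[t] += 1;  // 1-based for R

  return List::create(_["path"] = path, _["logp"] = best);
}
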