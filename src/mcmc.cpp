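#include <Rcpp.h>
using namespace Rcpp;

// Slot-based Metropolis-Hastings sampler for the mixture decomposition of
// a copying vector. State: integer slot counts n[s] summing to n_slots;
// beta_s = n_s / n_slots. Log posterior: sum_j cx_j log(sum_s beta_s M_js)
// plus a truncated-Poisson prior on the number of active sources, uniform
// over source subsets and over slot compositions.
//
// Moves (probability 1/2 each):
//  A) move one slot from a random nonzero source to a random other source
//     (Hastings ratio corrects for the changing number of nonzero sources)
//  B) relabel: transfer all slots of a random active source to a random
//     inactive source (symmetric proposal).
// Proposals creating more than t_eligible active sources are rejected.

static double log_lik(const NumericVector& cx, const NumericMatrix& M,
                      const IntegerVector& n, int n_slots) {
  const int J = cx.size(), S = n.size();
  double ll = 0.0;
  for (int j = 0; j < J; ++j) {
    if (cx[j] <= 0) continue;
    double p = 0.0;
    for (int s = 0; s < S; ++s)
      if (n[s] > 0) p += (double)n[s] * M(j, s);
    p /= (double)n_slots;
    if (p <= 0) return R_NegInf;
    ll += cx[j] * std::log(p);
  }
  return ll;
}

// [[Rcpp::export]]
List mixture_chain_cpp(NumericVector cx, NumericMatrix M, int n_slots,
                       int t_eligible, double t_expected, int n_iter,
                       int burn_in, int thin, IntegerVector init) {
  const int S = M.ncol();
  IntegerVector n = clone(init);

  // log prior by active-source count (truncation constant drops out)
  std::vector<double> lprior(t_eligible + 1, R_NegInf);
  for (int a = 1; a <= t_eligible; ++a)
    lprior[a] = a * std::log(t_expected) - lgamma(a + 1.0) -
      Rf_lchoose((double)S, (double)a) -
      Rf_lchoose((double)n_slots - 1.0, (double)a - 1.0);

  int active = 0;
  for (int s = 0; s < S; ++s) if (n[s] > 0) ++active;
  double ll = log_lik(cx, M, n, n_slots);
  double lp = ll + lprior[active];

  int n_keep = (n_iter - burn_in) / thin;
  NumericMatrix out(n_keep, S);
  int kept = 0;
  long accepted = 0;

  for (int it = 1; it <= n_iter; ++it) {
    double u = unif_rand();
    if (u < 0.5) {
      // slot move
      int m1 = active;                        // sources with >= 1 slot
      int pick = (int)(unif_rand() * m1);
      int i = -1;
      for (int s = 0; s < S; ++s) if (n[s] > 0 && --pick < 0) { i = s; break; }
      int j = (int)(unif_rand() * (S - 1));
      if (j >= i) ++j;
      int new_active = active - (n[i] == 1 ? 1 : 0) + (n[j] == 0 ? 1 : 0);
      if (new_active >= 1 && new_active <= t_eligible) {
        n[i]--; n[j]++;
        double ll_new = log_lik(cx, M, n, n_slots);
        double lp_new = ll_new + lprior[new_active];
        int m1_new = new_active < active ? m1 - 1 :
                     (new_active > active ? m1 + 1 : m1);
        // note m1 tracks nonzero counts = active
        double la = lp_new - lp + std::log((double)m1) -
          std::log((double)m1_new);
        if (std::log(unif_rand()) < la) {
          lp = lp_new; active = new_active; ++accepted;
        } else {
          n[i]++; n[j]--;
        }
      }
    } else {
      // relabel move
      if (active < S) {
        int pick = (int)(unif_rand() * active);
        int i = -1;
        for (int s = 0; s < S; ++s) if (n[s] > 0 && --pick < 0) { i = s; break; }
        pick = (int)(unif_rand() * (S - active));
        int j = -1;
        for (int s = 0; s < S; ++s) if (n[s] == 0 && --pick < 0) { j = s; break; }
        int ni = n[i];
        n[j] = ni; n[i] = 0;
        double ll_new = log_lik(cx, M, n, n_slots);
        double lp_new = ll_new + lprior[active];
        if (std::log(unif_rand()) < lp_new - lp) {
          lp = lp_new; ++accepted;
        } else {
          n[i] = ni; n[j] = 0;
        }
      }
    }
    if (it > burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      for (int s = 0; s < S; ++s)
        out(kept, s) = (double)n[s] / (double)n_slots;
      ++kept;
    }
  }
  return List::create(_["samples"] = out,
                      _["acceptance_rate"] = (double)accepted / n_iter);
}
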