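#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for the haplotype-copying HMM on one chromosome.
// donorsT: K_all x L donor haplotype matrix (transposed: a site is a
// contiguous column); target: length-L 0/1 alleles; use: 0-based rows of
// donorsT forming the donor set (leave-own-out handled by omission);
// rho: per-gap switch probabilities (L-1); w: per-site cM weights;
// mu: mismatch emission probability. Emissions (1-mu / mu) are computed
// on the fly. Returns expected chunk lengths/counts per used donor, the
// log-likelihood, expected mismatch count and per-gap expected switch
// probabilities.
// [[Rcpp::export]]
List paint_fb_cpp(IntegerMatrix donorsT, IntegerVector target,
                  IntegerVector use, NumericVector rho, NumericVector w,
                  double mu) {
  const int L = target.size(), K = use.size();
  const double e_match = 1.0 - mu, e_mism = mu;
  NumericMatrix ahat(K, L);            // column t contiguous
  NumericVector cc(L);
  const int* dT = INTEGER(donorsT);
  const int nAll = donorsT.nrow();
  std::vector<int> uk(use.begin(), use.end());

  double s = 0.0;
  {
    const int* col = dT;               // site 0
    for (int k = 0; k < K; ++k) {
      double e = (col[uk[k]] == target[0]) ? e_match : e_mism;
      ahat(k, 0) = e;
      s += e;
    }
  }
  cc[0] = s / K;
  for (int k = 0; k < K; ++k) ahat(k, 0) /= s;
  for (int t = 1; t < L; ++t) {
    const double r = rho[t - 1], stay = 1.0 - r, base = r / K;
    const int* col = dT + (R_xlen_t)t * nAll;
    const int tg = target[t];
    double tot = 0.0;
    for (int k = 0; k < K; ++k) {
      double e = (col[uk[k]] == tg) ? e_match : e_mism;
      double a = e * (stay * ahat(k, t - 1) + base);
      ahat(k, t) = a;
      tot += a;
    }
    cc[t] = tot;
    for (int k = 0; k < K; ++k) ahat(k, t) /= tot;
  }

  std::vector<double> bprev(K, 1.0), bcur(K);
  NumericVector lengths(K), counts(K), switch_e(std::max(L - 1, 0));
  double mism_exp = 0.0;
  {
    const int* col = dT + (R_xlen_t)(L - 1) * nAll;
    for (int k = 0; k < K; ++k) {
      double g = ahat(k, L - 1);
      lengths[k] += g * w[L - 1];
      if (col[uk[k]] != target[L - 1]) mism_exp += g;
    }
  }
  for (int t = L - 2; t >= 0; --t) {
    const double r = rho[t];
    const int* coln = dT + (R_xlen_t)(t + 1) * nAll;
    const int* colt = dT + (R_xlen_t)t * nAll;
    const int tgn = target[t + 1], tgt_ = target[t];
    double sv = 0.0;
    for (int k = 0; k < K; ++k) {
      double e = (coln[uk[k]] == tgn) ? e_match : e_mism;
      bcur[k] = e * bprev[k];           // temp: v
      sv += bcur[k];
    }
    const double inv_c = 1.0 / cc[t + 1], base = r / K;
    switch_e[t] = base * sv * inv_c;
    for (int k = 0; k < K; ++k) {
      double v = bcur[k];
      double b = ((1.0 - r) * v + base * sv) * inv_c;
      counts[k] += base * v * (1.0 - ahat(k, t)) * inv_c;
      double g = ahat(k, t) * b;
      lengths[k] += g * w[t];
      if (colt[uk[k]] != tgt_) mism_exp += g;
      bcur[k] = b;
    }
    std::swap(bprev, bcur);
  }
  for (int k = 0; k < K; ++k) counts[k] += ahat(k, 0) * bprev[k];
  double ll = 0.0;
  for (int t = 0; t < L; ++t) ll += std::log(cc[t]);
  return List::create(_["lengths"] = lengths, _["counts"] = counts,
                      _["loglik"] = ll, _["mismatch_exp"] = mism_exp,
                      _["switch_e"] = switch_e);
}

// Forward-backward for the 3-state diploid local-ancestry HMM on one
// chromosome. E: L x 3 emissions; d: per-gap distances in Morgans;
// g: switch intensity per Morgan; q: stationary European probability.
// Returns the L x 3 posterior matrix and the log-likelihood.
// [[Rcpp::export]]
List diploid_fb_cpp(NumericMatrix E, NumericVector d, double g, double q) {
  const int L = E.nrow();
  NumericMatrix ahat(L, 3), A(3 * std::max(L - 1, 0), 3);
  NumericVector cc(L);
  double init[3] = {(1 - q) * (1 - q), 2 * q * (1 - q), q * q};
  double tot = 0.0;
  for (int z = 0; z < 3; ++z) { ahat(0, z) = init[z] * E(0, z); tot += ahat(0, z); }
  cc[0] = tot;
  for (int z = 0; z < 3; ++z) ahat(0, z) /= tot;
  for (int t = 0; t < L - 1; ++t) {
    const double r = 1.0 - std::exp(-g * d[t]);
    const double hEE = 1 - r + r * q, hEI = r * (1 - q);
    const double hIE = r * q, hII = 1 - r + r * (1 - q);
    const int o = 3 * t;
    A(o + 0, 0) = hII * hII; A(o + 0, 1) = 2 * hIE * hII; A(o + 0, 2) = hIE * hIE;
    A(o + 1, 0) = hEI * hII; A(o + 1, 1) = hEE * hII + hEI * hIE;
    A(o + 1, 2) = hEE * hIE;
    A(o + 2, 0) = hEI * hEI; A(o + 2, 1) = 2 * hEE * hEI; A(o + 2, 2) = hEE * hEE;
    tot = 0.0;
    double a[3];
    for (int z2 = 0; z2 < 3; ++z2) {
      a[z2] = 0.0;
      for (int z1 = 0; z1 < 3; ++z1) a[z2] += ahat(t, z1) * A(o + z1, z2);
      a[z2] *= E(t + 1, z2);
      tot += a[z2];
    }
    cc[t + 1] = tot;
    for (int z = 0; z < 3; ++z) ahat(t + 1, z) = a[z] / tot;
  }
  NumericMatrix gam(L, 3);
  double bprev[3] = {1.0, 1.0, 1.0}, bcur[3];
  for (int z = 0; z < 3; ++z) gam(L - 1, z) = ahat(L - 1, z);
  for (int t = L - 2; t >= 0; --t) {
    const int o = 3 * t;
    for (int z1 = 0; z1 < 3; ++z1) {
      double b = 0.0;
      for (int z2 = 0; z2 < 3; ++z2)
        b += A(o + z1, z2) * E(t + 1, z2) * bprev[z2];
      bcur[z1] = b / cc[t + 1];
      gam(t, z1) = ahat(t, z1) * bcur[z1];
    }
    for (int z = 0; z < 3; ++z) bprev[z] = bcur[z];
  }
  double ll = 0.0;
  for (int t = 0; t < L; ++t) ll += std::log(cc[t]);
  return List::create(_["gamma"] = gam, _["loglik"] = ll);
}
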