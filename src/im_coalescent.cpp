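// Structured-coalescent core for the two-population isolation-with-
// migration model, infinite sites.  Time is in mutational units
// (1/mu generations): pair-coalescence rate 2/theta_j within population
// j, per-lineage backward migration rate m_j, mutation rate 1 per
// lineage per unit branch length.  Uses R's RNG so set.seed() governs
// reproducibility.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// For every mutation, record the number of descendant sample copies in
// population 1 (c1) and population 2 (c2).
// [[Rcpp::export(name = ".sim_im_counts_cpp")]]
List sim_im_counts_cpp(int n1, int n2, double theta1, double theta2,
                       double thetaA, double tSplit, double m1, double m2) {
  if (n1 + n2 < 2) stop("need >= 2 sampled lineages");
  if (theta1 <= 0 || theta2 <= 0 || thetaA <= 0)
    stop("theta parameters must be positive");
  int n = n1 + n2;
  std::vector<int> a1(n), a2(n), pop(n);
  for (int i = 0; i < n; ++i) {
    a1[i] = i < n1 ? 1 : 0;
    a2[i] = i < n1 ? 0 : 1;
    pop[i] = i < n1 ? 1 : 2;
  }
  bool merged = tSplit <= 0.0;
  if (merged) for (int i = 0; i < n; ++i) pop[i] = 0;
  double time = 0.0;
  std::vector<int> mc1, mc2;
  mc1.reserve(256); mc2.reserve(256);

  int k = n;
  auto drop_muts = [&](double dt) {
    if (dt <= 0.0) return;
    int nm = (int) R::rpois(k * dt);
    for (int s = 0; s < nm; ++s) {
      int idx = (int) (unif_rand() * k);
      if (idx >= k) idx = k - 1;
      mc1.push_back(a1[idx]);
      mc2.push_back(a2[idx]);
    }
  };
  // draw two distinct indices in [0, kk)
  auto draw_pair = [](int kk, int &i1, int &i2) {
    i1 = (int) (unif_rand() * kk); if (i1 >= kk) i1 = kk - 1;
    i2 = (int) (unif_rand() * (kk - 1)); if (i2 >= kk - 1) i2 = kk - 2;
    if (i2 >= i1) ++i2;
  };

  while (k > 1) {
    if (!merged) {
      int k1 = 0, k2 = 0;
      for (int i = 0; i < k; ++i) (pop[i] == 1 ? k1 : k2)++;
      double rc1 = k1 * (k1 - 1) / theta1;
      double rc2 = k2 * (k2 - 1) / theta2;
      double rm1 = k1 * m1, rm2 = k2 * m2;
      double tot = rc1 + rc2 + rm1 + rm2;
      double dt = tot > 0 ? exp_rand() / tot : R_PosInf;
      if (time + dt >= tSplit) {
        drop_muts(tSplit - time);
        time = tSplit;
        for (int i = 0; i < k; ++i) pop[i] = 0;
        merged = true;
        continue;
      }
      drop_muts(dt);
      time += dt;
      double u = unif_rand() * tot;
      if (u < rc1 || u < rc1 + rc2) {
        int target = u < rc1 ? 1 : 2;
        int kk = target == 1 ? k1 : k2;
        int i1, i2;
        draw_pair(kk, i1, i2);
        // map population-relative to absolute indices
        int seen = 0, ai = -1, bi = -1;
        for (int i = 0; i < k; ++i) {
          if (pop[i] == target) {
            if (seen == i1) ai = i;
            if (seen == i2) bi = i;
            ++seen;
          }
        }
        a1[ai] += a1[bi]; a2[ai] += a2[bi];
        a1[bi] = a1[k - 1]; a2[bi] = a2[k - 1]; pop[bi] = pop[k - 1];
        --k;
      } else if (u < rc1 + rc2 + rm1) {
        int pick = (int) (unif_rand() * k1);
        int seen = 0;
        for (int i = 0; i < k; ++i) {
          if (pop[i] == 1) {
            if (seen == pick) { pop[i] = 2; break; }
            ++seen;
          }
        }
      } else {
        int pick = (int) (unif_rand() * k2);
        int seen = 0;
        for (int i = 0; i < k; ++i) {
          if (pop[i] == 2) {
            if (seen == pick) { pop[i] = 1; break; }
            ++seen;
          }
        }
      }
    } else {
      double dt = exp_rand() / (k * (k - 1) / thetaA);
      drop_muts(dt);
      time += dt;
      int i1, i2;
      draw_pair(k, i1, i2);
      a1[i1] += a1[i2]; a2[i1] += a2[i2];
      a1[i2] = a1[k - 1]; a2[i2] = a2[k - 1]; pop[i2] = pop[k - 1];
      --k;
    }
  }
  return List::create(_["c1"] = IntegerVector(mc1.begin(), mc1.end()),
                      _["c2"] = IntegerVector(mc2.begin(), mc2.end()));
}
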