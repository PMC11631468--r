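#include <Rcpp.h>
using namespace Rcpp;

// Structured-coalescent Gillespie sampler for a 2+2 sample under the full
// five-parameter IM model (unequal Ne, bidirectional migration), in natural
// units (sizes diploid, times in generations, migration rates per lineage per
// generation, backwards in time). Competing exponentials: each pair of
// lineages in population p coalesces at rate 1/(2*N_p); each lineage in A
// migrates to B at rate m_a; each lineage in B migrates to A at rate m_b.
// At time t all surviving lineages enter the ancestral population (size
// N_ab) and coalesce panmictically. Branch lengths are accumulated per branch
// type on the unrooted 4-leaf genealogy: a lineage whose descendant set is
// {a}, {a,b,b} contributes to tau_a; {b}, {a,a,b} to tau_b; {a,b} to tau_ab;
// {a,a} or {b,b} to tau_aa. External (a/b) branch time is also split by the
// population the lineage occupies, for mutation-rate-bias experiments.
//
// Uses R's RNG (seed via set.seed() in the calling R session).

static inline int branch_type(int na, int nb) {
  int tot = na + nb;
  if (tot >= 4) return -1;            // root
  if (na == 1 && nb == 0) return 0;   // a
  if (na == 0 && nb == 1) return 1;   // b
  if (na == 1 && nb == 1) return 2;   // ab
  if ((na == 2 && nb == 0) || (na == 0 && nb == 2)) return 3; // aa
  if (na == 2 && nb == 1) return 1;   // complement {b}
  if (na == 1 && nb == 2) return 0;   // complement {a}
  return -1;
}

// [[Rcpp::export(name = ".sample_genealogies_cpp")]]
NumericMatrix sample_genealogies_cpp(int n, double N_a, double N_b,
                                     double N_ab, double t, double m_a,
                                     double m_b) {
  NumericMatrix out(n, 11);
  colnames(out) = CharacterVector::create(
      "incongruent", "tau_a", "tau_b", "tau_aa", "tau_ab",
      "a_in_A", "a_in_B", "a_in_AB", "b_in_A", "b_in_B", "b_in_AB");
  RNGScope scope;

  for (int rep = 0; rep < n; ++rep) {
    int na[4] = {1, 1, 0, 0};
    int nb[4] = {0, 0, 1, 1};
    int pop[4] = {0, 0, 1, 1};  // 0 = A, 1 = B, 2 = AB
    int k = 4;
    double now = 0.0;
    bool split_done = (t <= 0.0);
    if (split_done) for (int i = 0; i < 4; ++i) pop[i] = 2;
    double tau[4] = {0, 0, 0, 0};
    double occ[2][3] = {{0, 0, 0}, {0, 0, 0}};
    int incongruent = -1;

    while (k > 1) {
      int cnt[3] = {0, 0, 0};
      for (int i = 0; i < k; ++i) cnt[pop[i]]++;
      double rate_coal[3];
      rate_coal[0] = cnt[0] * (cnt[0] - 1) / 2.0 / (2.0 * N_a);
      rate_coal[1] = cnt[1] * (cnt[1] - 1) / 2.0 / (2.0 * N_b);
      rate_coal[2] = cnt[2] * (cnt[2] - 1) / 2.0 / (2.0 * N_ab);
      double rate_mig_a = split_done ? 0.0 : cnt[0] * m_a;
      double rate_mig_b = split_done ? 0.0 : cnt[1] * m_b;
      double total = rate_coal[0] + rate_coal[1] + rate_coal[2] +
                     rate_mig_a + rate_mig_b;

      double dt;
      if (total <= 0.0) {
        if (split_done) stop("zero total rate after the split");
        dt = t - now;  // nothing can happen before the split
      } else {
        dt = exp_rand() / total;
      }

      if (!split_done && now + dt >= t) {
        double d = t - now;
        for (int i = 0; i < k; ++i) {
          int bt = branch_type(na[i], nb[i]);
          if (bt >= 0) tau[bt] += d;
          if (bt == 0) occ[0][pop[i]] += d;
          if (bt == 1) occ[1][pop[i]] += d;
        }
        now = t;
        split_done = true;
        for (int i = 0; i < k; ++i) pop[i] = 2;
        continue;
      }

      now += dt;
      for (int i = 0; i < k; ++i) {
        int bt = branch_type(na[i], nb[i]);
        if (bt >= 0) tau[bt] += dt;
        if (bt == 0) occ[0][pop[i]] += dt;
        if (bt == 1) occ[1][pop[i]] += dt;
      }

      double u = unif_rand() * total;
      int event_pop = -1;
      bool is_mig_a = false, is_mig_b = false;
      for (int p = 0; p < 3; ++p) {
        if (u < rate_coal[p]) { event_pop = p; break; }
        u -= rate_coal[p];
      }
      if (event_pop < 0) {
        if (u < rate_mig_a) is_mig_a = true;
        else is_mig_b = true;
      }

      if (is_mig_a || is_mig_b) {
        int from = is_mig_a ? 0 : 1, to = is_mig_a ? 1 : 0;
        int cntf = 0;
        for (int i = 0; i < k; ++i) if (pop[i] == from) cntf++;
        int pick = (int)(unif_rand() * cntf);
        if (pick >= cntf) pick = cntf - 1;
        for (int i = 0; i < k; ++i) {
          if (pop[i] == from && pick-- == 0) { pop[i] = to; break; }
        }
      } else {
        // coalesce a uniform random pair within event_pop
        int idx[4], m = 0;
        for (int i = 0; i < k; ++i) if (pop[i] == event_pop) idx[m++] = i;
        int npairs = m * (m - 1) / 2;
        int pick = (int)(unif_rand() * npairs);
        if (pick >= npairs) pick = npairs - 1;
        int i1 = -1, i2 = -1, c = 0;
        for (int x = 0; x < m - 1 && i1 < 0; ++x)
          for (int y = x + 1; y < m; ++y)
            if (c++ == pick) { i1 = idx[x]; i2 = idx[y]; break; }
        if (incongruent < 0)
          incongruent = (na[i1] + na[i2] == 1 && nb[i1] + nb[i2] == 1) ? 1 : 0;
        na[i1] += na[i2];
        nb[i1] += nb[i2];
        // drop lineage i2
        for (int i = i2; i < k - 1; ++i) {
          na[i] = na[i + 1]; nb[i] = nb[i + 1]; pop[i] = pop[i + 1];
        }
        --k;
      }
    }

    out(rep, 0) = incongruent;
    out(rep, 1) = tau[0];
    out(rep, 2) = tau[1];
    out(rep, 3) = tau[3];
    out(rep, 4) = tau[2];
    out(rep, 5) = occ[0][0];
    out(rep, 6) = occ[0][1];
    out(rep, 7) = occ[0][2];
    out(rep, 8) = occ[1][0];
    out(rep, 9) = occ[1][1];
    out(rep, 10) = occ[1][2];
  }
  return out;
}
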