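// Exact genotype-class count engine: one full generation (reproduction,
// mutation, merge, coupled Beverton-Holt viability selection) for the two
// competing populations. Uses the R RNG so set.seed() governs everything.
//
// Count layout mirrors the R array dim c(nC, 2, 2):
//   index = class + nC * sex + 2 * nC * origin,
// sex 0 = F, 1 = M; origin 0 = sexual, 1 = asexual.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Multinomial draw by conditional binomials; probs need not be normalized.
static void rmultinom_probs(int n, const std::vector<double>& probs,
                            std::vector<int>& out) {
  const int k = (int)probs.size();
  out.assign(k, 0);
  double ptot = 0.0;
  for (int i = 0; i < k; ++i) ptot += probs[i];
  for (int i = 0; i < k && n > 0; ++i) {
    if (probs[i] <= 0.0) continue;
    double p = probs[i] / ptot;
    int x = (p >= 1.0) ? n : (int)R::rbinom((double)n, p);
    out[i] = x;
    n -= x;
    ptot -= probs[i];
    if (ptot <= 0.0) { out[i] += n; n = 0; }
  }
}

struct Pool {
  // offspring counts: [class][sex] of sexual origin, plus all-female
  // asexual-origin clones per class
  std::vector<int> sexF, sexM, asexF;
  long total;
  Pool(int nC) : sexF(nC, 0), sexM(nC, 0), asexF(nC, 0), total(0) {}
};

static int broodSize(double b, int nMothers, bool poisson) {
  if (nMothers <= 0) return 0;
  if (poisson) return (int)R::rpois(b * nMothers);
  return (int)std::lround(b) * nMothers;
}

// One population's reproductive season into a newborn pool.
static void reproduce(const IntegerVector& counts, int nC, int L,
                      const IntegerMatrix& states, double alpha, double b,
                      bool poisson, Pool& pool) {
  std::vector<int> females(nC), males(nC);
  long totMales = 0;
  for (int c = 0; c < nC; ++c) {
    females[c] = counts[c] + counts[c + 2 * nC];          // F sexual + F asexual
    males[c] = counts[c + nC] + counts[c + 3 * nC];       // M slices
    totMales += males[c];
  }
  std::vector<double> maleW(nC);
  for (int c = 0; c < nC; ++c) maleW[c] = (double)males[c];

  std::vector<int> fathers(nC), kids(nC);
  std::vector<double> childProbs(nC);

  for (int m = 0; m < nC; ++m) {
    if (females[m] == 0) continue;
    int nAsex = (alpha >= 1.0) ? females[m]
              : (alpha <= 0.0) ? 0
              : (int)R::rbinom((double)females[m], alpha);
    int nSex = females[m] - nAsex;

    // gynogenesis: clonal all-female broods
    int nClones = broodSize(b, nAsex, poisson);
    pool.asexF[m] += nClones;
    pool.total += nClones;

    // sexual reproduction requires conspecific males
    if (nSex == 0 || totMales == 0) continue;
    rmultinom_probs(nSex, maleW, fathers);
    for (int f = 0; f < nC; ++f) {
      if (fathers[f] == 0) continue;
      int nKids = broodSize(b, fathers[f], poisson);
      if (nKids == 0) continue;
      // per-locus transmission probabilities for the pair (m, f)
      // child state prob at a locus: P(0), P(1), P(2) from parental states
      for (int k = 0; k < nC; ++k) {
        double pr = 1.0;
        for (int i = 0; i < L; ++i) {
          double pm = states(m, i) / 2.0, pf = states(f, i) / 2.0;
          int sc = states(k, i);
          double p = (sc == 0) ? (1.0 - pm) * (1.0 - pf)
                   : (sc == 1) ? pm + pf - 2.0 * pm * pf
                   : pm * pf;
          pr *= p;
          if (pr == 0.0) break;
        }
        childProbs[k] = pr;
      }
      rmultinom_probs(nKids, childProbs, kids);
      for (int k = 0; k < nC; ++k) {
        if (kids[k] == 0) continue;
        int kF = (int)R::rbinom((double)kids[k], 0.5);
        pool.sexF[k] += kF;
        pool.sexM[k] += kids[k] - kF;
        pool.total += kids[k];
      }
    }
  }
}

// Recurrent mutation on the newborn pool; returns the number of allele flips.
static int mutate(Pool& pool, int nC, int L, const IntegerMatrix& states,
                  double rate, bool perAllele) {
  if (rate <= 0.0 || pool.total == 0) return 0;
  double trials = perAllele ? (double)pool.total * 2.0 * L : (double)pool.total;
  int nFlips = (int)R::rbinom(trials, rate);
  for (int t = 0; t < nFlips; ++t) {
    // pick a newborn uniformly (cells: asexF, sexF, sexM per class)
    double u = R::unif_rand() * (double)pool.total;
    int cls = -1, cell = 0; // cell: 0 asexF, 1 sexF, 2 sexM
    double acc = 0.0;
    for (int c = 0; c < nC && cls < 0; ++c) {
      acc += pool.asexF[c];
      if (u < acc) { cls = c; cell = 0; break; }
      acc += pool.sexF[c];
      if (u < acc) { cls = c; cell = 1; break; }
      acc += pool.sexM[c];
      if (u < acc) { cls = c; cell = 2; break; }
    }
    if (cls < 0) cls = nC - 1, cell = (pool.sexM[nC - 1] > 0) ? 2 : (pool.sexF[nC - 1] > 0 ? 1 : 0);
    int locus = (int)(R::unif_rand() * L);
    if (locus >= L) locus = L - 1;
    int s = states(cls, locus);
    // flip one of the two alleles: hom -> het; het -> either hom
    int snew = (s == 1) ? (R::unif_rand() < 0.5 ? 0 : 2) : 1;
    int delta = (snew - s); // -2..2, change class index by delta * 3^locus
    int pow3 = 1;
    for (int i = 0; i < locus; ++i) pow3 *= 3;
    int cls2 = cls + delta * pow3;
    std::vector<int>& arr = (cell == 0) ? pool.asexF : (cell == 1 ? pool.sexF : pool.sexM);
    if (arr[cls] > 0) { arr[cls] -= 1; arr[cls2] += 1; }
  }
  return nFlips;
}

static void mergePool(IntegerVector& counts, int nC, const Pool& pool) {
  for (int c = 0; c < nC; ++c) {
    counts[c] += pool.sexF[c];                 // F sexual
    counts[c + nC] += pool.sexM[c];            // M sexual
    counts[c + 2 * nC] += pool.asexF[c];       // F asexual
  }
}

// Beverton-Holt thinning of every cell; fit is nC x 2 (origin columns).
static void select(IntegerVector& counts, int nC, const NumericMatrix& fit,
                   double K0, double b, double phi, double Nadults) {
  for (int o = 0; o < 2; ++o) {
    for (int s = 0; s < 2; ++s) {
      for (int c = 0; c < nC; ++c) {
        int idx = c + nC * s + 2 * nC * o;
        int n = counts[idx];
        if (n == 0) continue;
        double K = fit(c, o) * K0;
        double p = (K > 0.0) ? 1.0 / (1.0 + b * phi * Nadults / K) : 0.0;
        counts[idx] = (p >= 1.0) ? n : (int)R::rbinom((double)n, p);
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_step_generation(IntegerVector counts1, IntegerVector counts2,
                         IntegerMatrix states, int L,
                         NumericMatrix fit1, NumericMatrix fit2,
                         double alpha1, double alpha2,
                         double b, double K0, double mutationRate,
                         bool poissonBrood, bool perAlleleMutation) {
  RNGScope scope;
  const int nC = states.nrow();
  IntegerVector c1 = clone(counts1), c2 = clone(counts2);

  // density terms from the combined ADULT census, before newborns merge
  double Nadults = 0.0, adultF = 0.0;
  for (int i = 0; i < 4 * nC; ++i) { Nadults += c1[i] + c2[i]; }
  for (int o = 0; o < 2; ++o)
    for (int c = 0; c < nC; ++c)
      adultF += c1[c + 2 * nC * o] + c2[c + 2 * nC * o];
  double phi = (Nadults > 0.0) ? adultF / Nadults : 0.0;

  Pool pool1(nC), pool2(nC);
  reproduce(c1, nC, L, states, alpha1, b, poissonBrood, pool1);
  reproduce(c2, nC, L, states, alpha2, b, poissonBrood, pool2);

  int nMut = 0;
  nMut += mutate(pool1, nC, L, states, mutationRate, perAlleleMutation);
  nMut += mutate(pool2, nC, L, states, mutationRate, perAlleleMutation);

  mergePool(c1, nC, pool1);
  mergePool(c2, nC, pool2);

  select(c1, nC, fit1, K0, b, phi, Nadults);
  select(c2, nC, fit2, K0, b, phi, Nadults);

  return List::create(_["counts1"] = c1, _["counts2"] = c2,
                      _["mutations"] = nMut,
                      _["offspring1"] = (double)pool1.total,
                      _["offspring2"] = (double)pool2.total);
}
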