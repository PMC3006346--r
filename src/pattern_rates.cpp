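#include <Rcpp.h>
using namespace Rcpp;

// Monte-Carlo expected polarized site-pattern rates under the
// five-taxon multispecies coalescent.
//
// Samples: F_1 F_2 S_1 S_2 A_1 A_2 M_1 M_2 O (tip bits 0..8).
// Time axis and branch lengths are in mutation units, so the expected
// per-bp rate of a pattern equals the expected summed length of
// genealogy branches on which a single mutation would produce that
// pattern. Patterns are polarized on the mastodon: a branch whose
// descendant set includes the outgroup is folded onto its complement.
// The returned 81-vector is indexed by
//   idx = nF + 3*nS + 9*nA + 27*nM
// with nX the derived-allele copy count in taxon X (0..2); idx 0 (no
// derived elephantid allele) cannot occur and stays 0.
//
// Uses R's RNG stream, so set.seed() before the call makes the result
// reproducible (the common-random-numbers device of the fitter).

// population codes: 0=F 1=S 2=A 3=M 4=O 5=FS 6=AM 7=LE 8=root
static const int NPOP = 9;

// [[Rcpp::export]]
NumericVector msc_pattern_rates_cpp(NumericVector tau, NumericVector theta,
                                    int n_reps) {
  // tau: (fs, am, le, root); theta: (f, s, a, m, fs, am, le, root)
  if (tau.size() != 4 || theta.size() != 8)
    stop("tau must have 4 and theta 8 entries");
  double th[NPOP];
  th[0] = theta[0]; th[1] = theta[1]; th[2] = theta[2]; th[3] = theta[3];
  th[4] = 1.0; // outgroup pop never holds 2 lineages
  th[5] = theta[4]; th[6] = theta[5]; th[7] = theta[6]; th[8] = theta[7];
  for (int p = 0; p < NPOP; ++p)
    if (!(th[p] > 0)) stop("theta must be positive");

  // merge events sorted by time: (time, fromA, fromB, to)
  struct Ev { double t; int a, b, to; };
  Ev ev[4] = {{tau[0], 0, 1, 5},   // FS
              {tau[1], 2, 3, 6},   // AM
              {tau[2], 5, 6, 7},   // LE
              {tau[3], 7, 4, 8}};  // root
  if (ev[0].t > ev[1].t) std::swap(ev[0], ev[1]);
  if (!(ev[1].t < ev[2].t && ev[2].t < ev[3].t))
    stop("split times must satisfy tau_FS, tau_AM < tau_LE < tau_root");

  NumericVector rates(81);
  int mask[9], popof[9];
  double birth[9];

  for (int rep = 0; rep < n_reps; ++rep) {
    int n = 9;
    for (int i = 0; i < 8; ++i) { mask[i] = 1 << i; popof[i] = i / 2; birth[i] = 0.0; }
    mask[8] = 1 << 8; popof[8] = 4; birth[8] = 0.0;
    double t = 0.0;
    for (int e = 0; e <= 4 && n > 1; ++e) {
      double t_end = (e < 4) ? ev[e].t : R_PosInf;
      while (n > 1) {
        // per-population lineage counts
        int k[NPOP] = {0};
        for (int i = 0; i < n; ++i) k[popof[i]]++;
        double rate[NPOP], total = 0.0;
        for (int p = 0; p < NPOP; ++p) {
          rate[p] = (k[p] > 1) ? k[p] * (k[p] - 1) / th[p] : 0.0;
          total += rate[p];
        }
        if (total <= 0.0) { t = t_end; break; }
        double w = exp_rand() / total;
        if (t + w >= t_end) { t = t_end; break; }
        t += w;
        // choose population, then an unordered pair within it
        double u = unif_rand() * total; int p = 0, last_pos = -1;
        for (p = 0; p < NPOP; ++p) {
          if (rate[p] <= 0.0) continue;
          last_pos = p;
          if (u <= rate[p]) break;
          u -= rate[p];
        }
        if (p == NPOP) p = last_pos; // fp rounding guard
        int i1 = -1, i2 = -1;
        int r1 = (int)(unif_rand() * k[p]); if (r1 == k[p]) r1--;
        int r2 = (int)(unif_rand() * (k[p] - 1)); if (r2 == k[p] - 1) r2--;
        if (r2 >= r1) r2++;
        int seen = 0;
        for (int i = 0; i < n; ++i) if (popof[i] == p) {
          if (seen == r1) i1 = i;
          if (seen == r2) i2 = i;
          seen++;
        }
        // record the two child branches
        for (int c = 0; c < 2; ++c) {
          int ci = c == 0 ? i1 : i2;
          int m = mask[ci];
          double len = t - birth[ci];
          if (m & (1 << 8)) m = (~m) & 0x1FF; // fold onto non-outgroup side
          int nF = ((m >> 0) & 1) + ((m >> 1) & 1);
          int nS = ((m >> 2) & 1) + ((m >> 3) & 1);
          int nA = ((m >> 4) & 1) + ((m >> 5) & 1);
          int nM = ((m >> 6) & 1) + ((m >> 7) & 1);
          int idx = nF + 3 * nS + 9 * nA + 27 * nM;
          rates[idx] += len;
        }
        // merge: keep i1 as the parent, drop i2
        mask[i1] |= mask[i2];
        birth[i1] = t;
        mask[i2] = mask[n - 1]; popof[i2] = popof[n - 1]; birth[i2] = birth[n - 1];
        n--;
      }
      if (e < 4) {
        for (int i = 0; i < n; ++i)
          if (popof[i] == ev[e].a || popof[i] == ev[e].b) popof[i] = ev[e].to;
      }
    }
  }
  for (int i = 0; i < 81; ++i) rates[i] /= n_reps;
  return rates;
}
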