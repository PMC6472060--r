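#include <Rcpp.h>
#include <algorithm>
#include <cstring>
using namespace Rcpp;

// Haplotype matrices are stored loci x individuals (column = one haplotype /
// one individual) so that gamete construction reads and writes contiguous
// memory. All randomness goes through R's RNG so that set.seed() governs
// everything.

// Gamete formation: per chromosome, crossover count ~ Poisson(map length in
// Morgans), breakpoint positions uniform on [0, length), no interference;
// the starting haplotype is chosen with probability 1/2 and the copied strand
// switches at each breakpoint.
//
// hapA, hapB:  L x N integer matrices (columns are individuals)
// parents:     1-based column indices, one per gamete
// chromStart:  0-based first-locus index per chromosome (length C)
// chromEnd:    0-based one-past-last locus index per chromosome
// locusPos:    genetic position in Morgans, within-chromosome
// chromLen:    chromosome lengths in Morgans
// Copy one gamete from parental strands a/b: per chromosome, Poisson
// crossovers, uniform breakpoints, fair-coin start strand; alleles are
// copied segment-wise (memcpy between successive breakpoints).
template <typename T>
static void make_one_gamete(const T* a, const T* b, T* dst,
                            const int C,
                            const int* chromStart, const int* chromEnd,
                            const double* locusPos, const double* chromLen,
                            std::vector<double>& bp) {
  for (int c = 0; c < C; ++c) {
    const int ncx = (int) R::rpois(chromLen[c]);
    bp.resize(ncx);
    for (int k = 0; k < ncx; ++k) bp[k] = unif_rand() * chromLen[c];
    std::sort(bp.begin(), bp.end());
    int state = (unif_rand() < 0.5) ? 0 : 1;  // 0 = strand a, 1 = strand b
    int l = chromStart[c];
    const int end = chromEnd[c];
    for (int k = 0; k <= ncx && l < end; ++k) {
      // first locus index at or beyond breakpoint k (end of this segment)
      int segEnd = end;
      if (k < ncx) {
        segEnd = (int) (std::lower_bound(locusPos + l, locusPos + end, bp[k])
                        - locusPos);
      }
      const T* src = state ? b : a;
      if (segEnd > l)
        std::memcpy(dst + l, src + l, (size_t) (segEnd - l) * sizeof(T));
      l = segEnd;
      state ^= 1;
    }
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_make_gametes(const IntegerMatrix& hapA,
                               const IntegerMatrix& hapB,
                               const IntegerVector& parents,
                               const IntegerVector& chromStart,
                               const IntegerVector& chromEnd,
                               const NumericVector& locusPos,
                               const NumericVector& chromLen) {
  const int L = hapA.nrow();
  const int G = parents.size();
  const int C = chromLen.size();
  IntegerMatrix out(L, G);
  std::vector<double> bp;

  for (int g = 0; g < G; ++g) {
    const int p = parents[g] - 1;
    make_one_gamete(&hapA(0, p), &hapB(0, p), &out(0, g), C,
                    &chromStart[0], &chromEnd[0], &locusPos[0], &chromLen[0],
                    bp);
  }
  return out;
}

// Forward Wright-Fisher burn-in at locus resolution for founder
// generation: starts from an all-wild-type haploid pool, and each
// generation g (g >= 1) draws 2 * popSizes[g] gametes by meiosis from
// random diploid parents of the previous generation (consecutive column
// pairs form diploids), then applies one-way 0 -> 1 mutation at rate mu
// per gamete per locus (as a binomial event count placed uniformly over
// cells). popSizes[0] is the initial diploid size. Returns the final
// haploid pool, L x 2*popSizes[last].
// [[Rcpp::export]]
IntegerMatrix cpp_wf_burnin(const int nLoci,
                            const IntegerVector& chromStart,
                            const IntegerVector& chromEnd,
                            const NumericVector& locusPos,
                            const NumericVector& chromLen,
                            const IntegerVector& popSizes,
                            const double mu) {
  const int C = chromLen.size();
  std::vector<uint8_t> cur((size_t) nLoci * 2 * popSizes[0], 0);
  std::vector<uint8_t> nxt;
  std::vector<double> bp;
  int nDip = popSizes[0];

  for (int g = 1; g < popSizes.size(); ++g) {
    const int nGam = 2 * popSizes[g];
    nxt.assign((size_t) nLoci * nGam, 0);
    for (int j = 0; j < nGam; ++j) {
      const int p = (int) (unif_rand() * nDip);
      const uint8_t* a = &cur[(size_t) nLoci * (2 * p)];
      const uint8_t* b = &cur[(size_t) nLoci * (2 * p + 1)];
      make_one_gamete(a, b, &nxt[(size_t) nLoci * j], C,
                      &chromStart[0], &chromEnd[0], &locusPos[0],
                      &chromLen[0], bp);
    }
    if (mu > 0) {
      const double nCells = (double) nLoci * nGam;
      const int nev = (int) R::rbinom(nCells, mu);
      for (int e = 0; e < nev; ++e)
        nxt[(size_t) (unif_rand() * nCells)] = 1;
    }
    cur.swap(nxt);
    nDip = popSizes[g];
  }

  IntegerMatrix out(nLoci, 2 * nDip);
  std::copy(cur.begin(), cur.end(), out.begin());
  return out;
}

// Multiplicative fitness w = prod over fitness loci of {1, 1-h*s, 1-s} for
// dosage {0, 1, 2}. Plain product in the order of the locus vector; exact
// zeros (lethal homozygotes) are handled naturally.
//
// rows: 0-based row (locus) indices of the fitness loci.
// [[Rcpp::export]]
NumericVector cpp_fitness(const IntegerMatrix& hapA,
                          const IntegerMatrix& hapB,
                          const IntegerVector& rows,
                          const NumericVector& s,
                          const double h) {
  const int N = hapA.ncol();
  const int M = rows.size();
  NumericVector w(N);
  for (int j = 0; j < N; ++j) {
    const int* a = &hapA(0, j);
    const int* b = &hapB(0, j);
    double wj = 1.0;
    for (int i = 0; i < M; ++i) {
      const int l = rows[i];
      const int d = a[l] + b[l];
      if (d == 1)      wj *= 1.0 - h * s[i];
      else if (d == 2) wj *= 1.0 - s[i];
    }
    w[j] = wj;
  }
  return w;
}

// True breeding value: sum over QTL of a_i * dosage_i.
// [[Rcpp::export]]
NumericVector cpp_breeding_value(const IntegerMatrix& hapA,
                                 const IntegerMatrix& hapB,
                                 const IntegerVector& rows,
                                 const NumericVector& eff) {
  const int N = hapA.ncol();
  const int M = rows.size();
  NumericVector bv(N);
  for (int j = 0; j < N; ++j) {
    const int* a = &hapA(0, j);
    const int* b = &hapB(0, j);
    double x = 0.0;
    for (int i = 0; i < M; ++i) {
      const int l = rows[i];
      x += eff[i] * (a[l] + b[l]);
    }
    bv[j] = x;
  }
  return bv;
}

// Allele dosage (0/1/2) at a set of loci: returns M x N integer matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_dosage(const IntegerMatrix& hapA,
                         const IntegerMatrix& hapB,
                         const IntegerVector& rows) {
  const int N = hapA.ncol();
  const int M = rows.size();
  IntegerMatrix out(M, N);
  for (int j = 0; j < N; ++j) {
    const int* a = &hapA(0, j);
    const int* b = &hapB(0, j);
    for (int i = 0; i < M; ++i) {
      const int l = rows[i];
      out(i, j) = a[l] + b[l];
    }
  }
  return out;
}

// Derived-allele count per locus over all haplotype columns of two matrices.
// [[Rcpp::export]]
NumericVector cpp_allele_counts(const IntegerMatrix& hapA,
                                const IntegerMatrix& hapB) {
  const int L = hapA.nrow();
  const int N = hapA.ncol();
  NumericVector cnt(L);
  for (int j = 0; j < N; ++j) {
    const int* a = &hapA(0, j);
    const int* b = &hapB(0, j);
    for (int l = 0; l < L; ++l) cnt[l] += a[l] + b[l];
  }
  return cnt;
}
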