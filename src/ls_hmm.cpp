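// Diploid Li-Stephens haplotype-copying HMM: forward-backward genotype
// posteriors for target individuals typed on a subset of loci, conditioning
// on a panel of reference haplotypes.
//
// State space: ordered pairs of reference haplotypes (H^2 states).  Each
// haplotype switches template with probability s_l between loci (after a
// switch the new template is uniform over all H haplotypes, including the
// current one).  Emission: per-allele error epsilon, so the observed
// genotype code is the sum of two independently mis-read alleles.
// The two-haplotype transition factorizes, so each update is O(H^2).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// emission probability of observed code g given template dosage class,
// returned as a 3-vector over dosage d = 0,1,2
static inline vec emissionByDosage(int g, double eps) {
  vec e(3);
  if (g < 0) { e.fill(1.0); return e; }
  // q = P(read coded allele) for allele 0 and 1
  const double q0 = eps, q1 = 1.0 - eps;
  auto pg = [&](double qa, double qb) {
    switch (g) {
      case 0: return (1 - qa) * (1 - qb);
      case 1: return qa * (1 - qb) + (1 - qa) * qb;
      default: return qa * qb;
    }
  };
  e[0] = pg(q0, q0);
  e[1] = pg(q1, q0);
  e[2] = pg(q1, q1);
  return e;
}

// one factorized transition step: given normalized state matrix F (H x H),
// return T' F T with T = (1-s) I + (s/H) J
static inline mat transitionStep(const mat& F, double s, int H) {
  const double a = 1.0 - s, b = s / H;
  vec r = sum(F, 1);   // over second haplotype -> length H (rows)
  rowvec c = sum(F, 0);
  double tot = accu(F);
  return a * a * F + a * b * (repmat(r, 1, H) + repmat(c, H, 1)) +
         b * b * tot;
}

// [[Rcpp::export(name = ".lsDiploidPosterior")]]
arma::cube lsImputeMatrix(const arma::imat& refHaps,      // H x L, alleles 0/1
                          const arma::imat& obs,          // n x L, -1 missing
                          const arma::vec& switchProb,    // length L, [0] unused
                          double eps) {
  const int H = refHaps.n_rows, L = refHaps.n_cols, n = obs.n_rows;
  if (H < 2) Rcpp::stop("need at least 2 reference haplotypes");
  if ((int)switchProb.n_elem != L) Rcpp::stop("switchProb length mismatch");

  // dosage class of each ordered haplotype pair at each locus is
  // refHaps(j,l) + refHaps(k,l); build per-locus emission matrices lazily
  cube post(n, L, 3);
  cube Fstore(H, H, L);

  for (int ind = 0; ind < n; ++ind) {
    // forward
    mat F(H, H);
    for (int l = 0; l < L; ++l) {
      vec e = emissionByDosage(obs(ind, l), eps);
      if (l == 0) F.fill(1.0 / (H * H));
      else F = transitionStep(F, switchProb[l], H);
      for (int j = 0; j < H; ++j)
        for (int k = 0; k < H; ++k)
          F(j, k) *= e[refHaps(j, l) + refHaps(k, l)];
      double tot = accu(F);
      if (tot <= 0) Rcpp::stop("zero-probability observation at locus %d", l + 1);
      F /= tot;
      Fstore.slice(l) = F;
    }
    // backward + combine
    mat B(H, H, fill::ones);
    for (int l = L - 1; l >= 0; --l) {
      mat FB = Fstore.slice(l) % B;
      double tot = accu(FB);
      vec p(3, fill::zeros);
      for (int j = 0; j < H; ++j)
        for (int k = 0; k < H; ++k)
          p[refHaps(j, l) + refHaps(k, l)] += FB(j, k);
      p /= tot;
      for (int d = 0; d < 3; ++d) post(ind, l, d) = p[d];
      if (l > 0) {
        vec e = emissionByDosage(obs(ind, l), eps);
        mat G = B;
        for (int j = 0; j < H; ++j)
          for (int k = 0; k < H; ++k)
            G(j, k) *= e[refHaps(j, l) + refHaps(k, l)];
        B = transitionStep(G, switchProb[l], H);
        B /= accu(B);
      }
    }
  }
  return post;
}
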