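#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Extended haplotype homozygosity walk away from a core SNP, one direction.
//
// H: haplotypes x SNPs 0/1 matrix for ONE chromosome, polarized
// (0 = ancestral, 1 = derived). Carriers of `allele` at `core` are tracked
// as identity groups; at each flanking SNP the groups split on the new
// allele and EHH = sum_g C(n_g,2) / C(n,2). The walk records each visited
// flank and stops after the first flank with EHH < limit, at a physical
// gap above maxGap, or at the chromosome edge (the latter two flagged as
// truncation). The one-sided iHH accumulates trapezoids of EHH against bp
// starting from EHH = 1 at the core.
struct SideWalk {
  std::vector<int> idx;        // 0-based flank SNP indices, in walk order
  std::vector<double> ehh;
  double ihh = 0.0;
  bool truncated = false;
};

static SideWalk walk_side(const IntegerMatrix &H, int core, int allele,
                          const NumericVector &pos, double limit,
                          double maxGap, int dir) {
  SideWalk out;
  const int nHap = H.nrow(), nSnp = H.ncol();
  std::vector<int> carriers;
  for (int h = 0; h < nHap; ++h)
    if (H(h, core) == allele) carriers.push_back(h);
  const int n = (int)carriers.size();
  if (n < 2) { out.truncated = true; return out; }
  const double pairsTot = 0.5 * n * (n - 1);

  std::vector<int> grp(n, 0);
  int nGroups = 1;
  double ehhPrev = 1.0, posPrev = pos[core];

  for (int j = core + dir; j >= 0 && j < nSnp; j += dir) {
    double gap = std::abs(pos[j] - posPrev);
    if (gap > maxGap) { out.truncated = true; return out; }
    // split groups on the allele at j
    std::vector<int> remap(2 * nGroups, -1);
    int nNew = 0;
    std::vector<int> count;
    for (int i = 0; i < n; ++i) {
      int key = 2 * grp[i] + H(carriers[i], j);
      if (remap[key] < 0) { remap[key] = nNew++; count.push_back(0); }
      grp[i] = remap[key];
      count[grp[i]] += 1;
    }
    nGroups = nNew;
    double pairs = 0.0;
    for (int c : count) pairs += 0.5 * (double)c * (c - 1);
    double ehh = pairs / pairsTot;
    out.idx.push_back(j);
    out.ehh.push_back(ehh);
    out.ihh += gap * 0.5 * (ehhPrev + ehh);
    if (ehh < limit) return out;          // clean stop at cutoff crossing
    ehhPrev = ehh;
    posPrev = pos[j];
  }
  out.truncated = true;                   // ran off the chromosome edge
  return out;
}

// [[Rcpp::export(name = ".ehh_profile_cpp")]]
List ehh_profile_cpp(const IntegerMatrix &H, int core1, int allele,
                     const NumericVector &pos, double limit, double maxGap) {
  int core = core1 - 1;
  SideWalk L = walk_side(H, core, allele, pos, limit, maxGap, -1);
  SideWalk R = walk_side(H, core, allele, pos, limit, maxGap, +1);
  int n = 0;
  for (int h = 0; h < H.nrow(); ++h) if (H(h, core) == allele) ++n;
  return List::create(
    _["n_carriers"] = n,
    _["left_idx"] = wrap(L.idx), _["left_ehh"] = wrap(L.ehh),
    _["left_ihh"] = L.ihh, _["left_truncated"] = L.truncated,
    _["right_idx"] = wrap(R.idx), _["right_ehh"] = wrap(R.ehh),
    _["right_ihh"] = R.ihh, _["right_truncated"] = R.truncated);
}

// Genome-scan of unstandardized iHS ingredients over every core SNP of one
// chromosome. Cores with derived frequency outside [minFreq, maxFreq],
// with an allele class carried by < 2 haplotypes, or with any truncated
// side-walk (edge/gap policy: discard) get NA. reason: 0 ok, 1 frequency,
// 2 carriers, 3 truncated.
// [[Rcpp::export(name = ".ihs_scan_cpp")]]
DataFrame ihs_scan_cpp(const IntegerMatrix &H, const NumericVector &pos,
                       double limit, double maxGap, double minFreq,
                       double maxFreq) {
  const int nSnp = H.ncol(), nHap = H.nrow();
  NumericVector ihhA(nSnp, NA_REAL), ihhD(nSnp, NA_REAL),
      freqD(nSnp), lnRatio(nSnp, NA_REAL);
  IntegerVector reason(nSnp, 0);
  for (int j = 0; j < nSnp; ++j) {
    int nd = 0;
    for (int h = 0; h < nHap; ++h) nd += H(h, j);
    double p = (double)nd / nHap;
    freqD[j] = p;
    if (p < minFreq || p > maxFreq) { reason[j] = 1; continue; }
    if (nd < 2 || nHap - nd < 2) { reason[j] = 2; continue; }
    SideWalk aL = walk_side(H, j, 0, pos, limit, maxGap, -1);
    if (aL.truncated) { reason[j] = 3; continue; }
    SideWalk aR = walk_side(H, j, 0, pos, limit, maxGap, +1);
    if (aR.truncated) { reason[j] = 3; continue; }
    SideWalk dL = walk_side(H, j, 1, pos, limit, maxGap, -1);
    if (dL.truncated) { reason[j] = 3; continue; }
    SideWalk dR = walk_side(H, j, 1, pos, limit, maxGap, +1);
    if (dR.truncated) { reason[j] = 3; continue; }
    ihhA[j] = aL.ihh + aR.ihh;
    ihhD[j] = dL.ihh + dR.ihh;
    if (ihhA[j] > 0 && ihhD[j] > 0)
      lnRatio[j] = std::log(ihhA[j] / ihhD[j]);
    else reason[j] = 3;
  }
  return DataFrame::create(
    _["freq_derived"] = freqD, _["ihh_a"] = ihhA, _["ihh_d"] = ihhD,
    _["ln_ratio"] = lnRatio, _["reason"] = reason);
}
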