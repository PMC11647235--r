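---
title: "Methods: diversity, homozygosity and haplotype-based selection scans in popgenscan"
author: "popgenscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, homozygosity and haplotype-based selection scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`popgenscan` implements the downstream analysis stack used in livestock
conservation genomics on diploid SNP panels: quality control, diversity
indices, runs of homozygosity (ROH) and genomic inbreeding, population
structure (PCA and an admixture model), and an iHS selection scan with
candidate-gene annotation. This vignette records the models, the
parameters that matter, and the design decisions taken where the
conventions of the field leave room.

# Data model and conventions

Genotypes are held in a `GenotypeMatrix` (samples x variants ALT-dosages
0/1/2, `NA` for missing; biallelic SNPs only, positions strictly
increasing within chromosome) and phased data in a `HaplotypeSet`
(2 haplotypes per sample, strictly binary: EHH statistics are undefined
on missing data, so phasing/imputation is an input requirement, not a
package stage). All coordinates are 1-based inclusive, the VCF/GTF
convention; window arithmetic converts to half-open intervals only at
the tiling boundary. Missing calls are a sentinel (`NA`), never a third
allele value, which keeps every frequency computation branch-free.
Chromosome labels are opaque strings; the default autosome set is
`"1".."30"`.

iHS needs each site polarized into ancestral/derived alleles. Array and
resequencing panels rarely ship outgroup polarization, so two modes are
provided and recorded per site: `major_ancestral` (default; the sample
major allele is taken as ancestral, the usual fallback when no outgroup
is available) and `ref_ancestral` (keep the VCF REF coding, appropriate
when the reference is a credible proxy for the ancestral state or when a
generator knows the truth). The choice flips signs of individual iHS
values but not the two-sided outlier scan.

# Quality control

`filterGenotypes()` applies, in a fixed and reported order: samples with
more than 10% missing genotypes, then variants with call rate below 99%,
then variants with MAF below 1% (frequencies recomputed on the retained
samples, from non-missing calls only). The thresholds are the
conventional array-QC trio and are all exposed. The fixed order makes
the filter deterministic and idempotent — rerunning it on its own output
removes nothing, which the tests assert by re-scan.

# Diversity and inbreeding

Per population and variant: observed heterozygosity Ho is the
heterozygote fraction among non-missing calls; expected heterozygosity
is the uncorrected population value $He = 2p(1-p)$; $MAF = \min(p, 1-p)$.
Population summaries are means, SDs and medians across variants.

Two genomic inbreeding coefficients are computed:

* $F_{ROH}$: summed ROH length over the SNP-covered genome length.
  The denominator is configuration, not data: the shipped default is
  100,100,000 bp, the value used with the turkey panel this workflow
  targets, but it should be set to the SNP-covered autosome span of the
  assembly at hand (for synthetic data, the simulated span). It is kept
  configurable rather than derived from the input because array panels
  under-cover chromosome ends and the analyst, not the file, knows the
  intended span.
* $F_{HOM} = (O - E)/(L - E)$ with $O$ the observed homozygous count,
  $L$ the typed SNPs of the sample and
  $E = \sum_j [1 - 2p_j(1-p_j)\,2N_j/(2N_j-1)]$ the count expected under
  Hardy–Weinberg with the usual small-sample correction. The identity
  defines the coefficient; the estimator of $E$ is the conventional one
  behind standard tooling. He deliberately stays uncorrected while $E$
  is corrected: the former is a population descriptive, the latter a
  null expectation for a finite sample. Sites informative in fewer than
  two samples are excluded from $O$, $E$ and $L$ alike (keeping them in
  $O$ only could push the coefficient above 1).

# Runs of homozygosity

`detectROH()` reproduces the PLINK-style scanning-window algorithm with
the parameter set `--homozyg-kb 1000 --homozyg-window-snp 100
--homozyg-window-het 1 --homozyg-window-missing 2
--homozyg-window-threshold 0.05 --homozyg-snp 100 --homozyg-density 100
--homozyg-gap 1000` as defaults: a window of 100 SNPs is homozygous if
it holds at most 1 heterozygous and 2 missing calls; a SNP qualifies
when at least 5% of the windows covering it are homozygous; maximal
qualifying stretches, split at gaps above 1 Mb, are kept when at least
1 Mb long, 100 SNPs deep and no sparser than 100 kb/SNP.

Dialect choices, stated because PLINK leaves them implicit:

* only windows containing the full SNP count are scored (no truncated
  edge windows);
* a qualifying SNP need not itself be homozygous — qualification is
  purely the covering-window vote, which is the documented definition
  and the contract the brute-force test oracle enumerates;
* segment length is inclusive of both endpoint SNPs
  (`end - start + 1`), consistent with 1-based inclusive coordinates;
* the density filter applies to the final segment, not per window.

Length classes are half-open, `[0,2) [2,4) [4,8) [8,16) [16,Inf)` Mb, so
a 4.0 Mb segment counts as "4-8"; the five classes partition the
segments exhaustively, matching the usual summary-table layout.

# Population structure

`pcaGenotypes()` mean-imputes missing calls per variant, centers at
$2p$, and by default applies Patterson scaling ($/\sqrt{p(1-p)}$), the
standard normalization for genotype PCA; plain centering is available
since array studies differ here and the choice is not always stated.
Coordinates come from the SVD of the scaled matrix and are checked
against a dense covariance eigendecomposition in the tests at 1e-8.

The admixture model is the binomial mixture: genotype $g_{ij}$ is
binomial(2) in $\sum_k q_{ik} f_{kj}$, with $Q$ the ancestry fractions
and $F$ the ancestral allele frequencies.
`fitAdmixture()` maximizes the log-likelihood by plain EM rather than a
quasi-Newton block relaxation: slower, but exactly specified, and its
monotone-ascent property is a testable contract (the trace is asserted
non-decreasing on every fitted run). Initialization draws Q rows from
Dirichlet(1) and F from seeded perturbed pooled frequencies; five
restarts keep the best likelihood. Q and F are clipped to
$[10^{-6}, 1-10^{-6}]$ to keep the likelihood finite; missing genotypes
carry zero weight.

`cvAdmixture()` selects K by entry-masking cross-validation: a random
1/folds of the observed genotype entries is held out, the model refitted,
and held-out entries scored by binomial deviance under the predicted
dosage; the K minimizing the mean CV error is flagged. Masks that would
empty a variant are redrawn. Masking entries (rather than whole samples)
matches the hold-out style of the established CV procedure for this
model. The conventional full-scale range is K = 2..16; the range is
configuration.

# iHS selection scan

For a core SNP, EHH at flanking SNP $x$ is the probability that two
random haplotypes carrying the same core allele are identical over
$[core..x]$, computed by identity-group splitting
($\sum_g \binom{n_g}{2} / \binom{n}{2}$). iHH is the trapezoid integral
of the EHH decay against physical distance, both directions summed,
walked until EHH drops below 0.05, a gap exceeds 200 kb, or the
chromosome ends. The first flank below the cutoff is included, so the
integral covers the crossing; gap- or edge-truncated cores are discarded
rather than integrated short, the conservative convention of the
haplotype-scan literature (both the cutoff and gap are configurable).
Cores with derived frequency outside [0.05, 0.95] or with fewer than two
carriers per allele class are skipped and the reason recorded. The
compiled core keeps a 50k-SNP genome scan in seconds; a direct
pair-enumeration oracle in the tests pins the definition down to 1e-10.

The unstandardized score $\ln(iHH_A/iHH_D)$ is standardized within
derived-allele-frequency bins (20 equal-width bins on (0,1); bins with
fewer than 10 usable SNPs merge into their nearest occupied neighbour)
so that allele-frequency dependence of haplotype length cancels; within
every retained bin the standardized iHS has mean 0 and SD 1 by
construction, asserted to 1e-9. The two-sided transform is
$piHS = -\log_{10}[1 - 2|\Phi(iHS) - 0.5|]$, i.e. the $-\log_{10}$
two-sided normal tail, so $piHS(\pm 1.96) \approx 1.301$.

The outlier scan tiles each chromosome with 1 Mb windows stepping
500 kb, anchored at position 0, trailing partial window retained; the
statistic is the window's maximum |iHS|; empty windows are dropped.
Significant windows are those reaching the empirical top-1% threshold —
the `ceiling(0.01 n)`-th largest statistic, ties included. The tie rule
matters: with a 500 kb step every interior SNP lies in two windows, so
the extreme SNP always ties two windows exactly, and a hard count cut
would drop one of them by storage order. Overlapping significant windows
merge into candidate regions (the headline artifact); SNPs with
piHS > 4 are reported separately, since both outputs are conventional
and they answer different questions. Group-wise scans (e.g. local vs
commercial vs heritage populations) are configuration: iHS is
standardized within each group independently.

Candidate regions intersect gene annotation via 1 bp minimum overlap on
1-based inclusive intervals, strand ignored (the `intersectBed`
default); only GTF `gene` records with biotype `protein_coding` and a
`gene_name` are considered, duplicates collapsed to their spanning
interval.

# Synthetic data generator

`simulatePopulations()` is first-class, tested code: it emulates the
data structure the analyses assume, with planted truth for recovery
testing.

* Ancestral allele frequencies are U-shaped (Beta(0.25, 0.25), clipped
  to [0.02, 0.98]), the qualitative shape of site-frequency spectra.
* Population divergence is a truncated-normal drift of the ancestral
  frequency per population, SD 0.2 by default — strong isolation, the
  regime of small closed populations, giving PCA/admixture-separable
  groups.
* Background LD comes from a founder-copying step: each haplotype is a
  mosaic of 8 population founders, switching founder with probability
  0.05 per SNP (mean copied stretch 20 SNPs). This produces local
  haplotype sharing and realistic EHH decay at desk scale with exactly
  specified behaviour, in place of a coalescent simulator.
* Hard sweeps are planted by making a `targetFreq` fraction of
  haplotypes carry the derived allele at a focal SNP and copy one
  template over a fixed span — the classic high-frequency long-shared
  haplotype that iHS detects.
* Autozygosity is planted per individual by overwriting haplotype 2
  with haplotype 1 over tracts (2–8 Mb) laid out to total exactly a
  fraction phi of the genome; tract boundaries go into the truth record.
* Genotype missingness is applied at rate 0.002 (array-like, consistent
  with a 99% call-rate regime); haplotypes stay complete.

All randomness flows through one mandatory seed; identical configs are
byte-identical down to the written VCF.

What the generator does **not** emulate: demographic history and
recombination-map heterogeneity, ascertainment bias of array content,
genotyping error, soft sweeps, and LD beyond the founder-mosaic scale.
Passing recovery tests therefore demonstrates that the statistics
measure what they claim on data with planted signal of the stated form —
not that any particular real panel meets these assumptions.

# Pipeline

`runPipeline()` executes qc → diversity → ROH → inbreeding → PCA →
admixture (optional) → per-group iHS → annotation from one `runConfig()`
(or YAML). Every stage records parameter hashes and input/output
checksums in `manifest.json`; a rerun skips stages whose parameters and
outputs are unchanged and whose upstream stages were not recomputed, so
deleting one output recomputes exactly that stage and its dependents.
All tables are TSV with a commented parameter header; a failing stage
aborts with its name after persisting the manifest.

# Test and verification scale

The verification suite runs entirely on generated data, sized for a
single CPU: oracle equivalence on 100 random haplotype instances (up to
20 haplotypes x 50 SNPs) and 20 random ROH samples (3–5k SNPs);
F_ROH recovery at phi = 0.1/0.3/0.6 with 30 individuals on 2 x 25 Mb
chromosomes at 200 SNPs/Mb; an F_HOM null on 50 samples x 10k SNPs;
sweep recovery over 20 replicates of 20 samples on a 10 Mb chromosome
(~2,000 SNPs, derived frequency 0.8, 1 Mb span); a neutral
false-positive control on 50k SNPs; and admixture K-recovery over 10
replicates of 3 x 15 samples x 300 SNPs. `scripts/acceptance.R` recomputes
the same quantities from scratch under a caller-supplied seed.

# Known limitations

* The EM optimizer is not ADMIXTURE's accelerated block relaxation;
  at hundreds of thousands of SNPs it is slow. The model and CV scheme
  are the same.
* ROH detection approximates PLINK's behaviour at chromosome edges
  (full windows only); counts can differ marginally from PLINK near
  chromosome ends.
* No ROH-island/consensus-region analysis, no cross-population
  statistics (XP-EHH, Rsb), no Hardy–Weinberg or LD-pruning filters.
* Polarization without an outgroup (`major_ancestral`) misorients truly
  derived-major sites; the |iHS| outlier scan is insensitive to this,
  but signed per-site interpretation is not.
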