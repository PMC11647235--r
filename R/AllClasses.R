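#' @import methods
#' @importFrom stats rnorm runif rbinom rbeta qnorm pnorm sd median setNames
#' @importFrom utils head tail write.table read.table
#' @useDynLib popgenscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

MISSING_CALL <- NA_integer_

# ---------------------------------------------------------------------------
# GenotypeMatrix
# ---------------------------------------------------------------------------

#' GenotypeMatrix: diploid SNP calls for a sample panel
#'
#' Samples x variants matrix of alternate-allele dosages (0, 1, 2) with
#' `NA` marking missing calls, together with per-variant chromosome,
#' 1-based position and REF/ALT alleles. Only biallelic SNPs are admitted;
#' positions must be strictly increasing within each chromosome.
#'
#' @slot calls integer matrix, samples x variants, entries in {0,1,2,NA}.
#' @slot chrom character vector of chromosome labels (opaque strings).
#' @slot pos integer vector of 1-based bp coordinates.
#' @slot refAllele,altAllele single-base allele strings per variant.
#'
#' @export
setClass("GenotypeMatrix",
  representation(
    calls = "matrix",
    chrom = "character",
    pos = "integer",
    refAllele = "character",
    altAllele = "character"
  )
)

validGenotypeMatrix <- function(object) {
  msg <- character()
  m <- ncol(object@calls)
  if (length(object@chrom) != m) msg <- c(msg, "chrom length != n_variants")
  if (length(object@pos) != m) msg <- c(msg, "pos length != n_variants")
  if (length(object@refAllele) != m) msg <- c(msg, "refAllele length != n_variants")
  if (length(object@altAllele) != m) msg <- c(msg, "altAllele length != n_variants")
  if (is.null(rownames(object@calls)))
    msg <- c(msg, "calls must carry sample ids as rownames")
  v <- object@calls[!is.na(object@calls)]
  if (length(v) && (any(v < 0L) || any(v > 2L)))
    msg <- c(msg, "calls must be in {0,1,2} or NA")
  if (m > 1L) {
    same <- object@chrom[-1L] == object@chrom[-m]
    if (any(same & object@pos[-1L] <= object@pos[-m]))
      msg <- c(msg, "positions must be strictly increasing within chromosome")
    if (anyDuplicated(rle(object@chrom)$values))
      msg <- c(msg, "chromosome blocks must be contiguous (records sorted by chrom,pos)")
  }
  bad <- !grepl("^[ACGT]$", object@refAllele) | !grepl("^[ACGT]$", object@altAllele)
  if (any(bad)) msg <- c(msg, "only biallelic single-base SNPs admitted")
  if (length(msg)) msg else TRUE
}
setValidity("GenotypeMatrix", validGenotypeMatrix)

#' Construct a GenotypeMatrix
#'
#' @param calls integer matrix (samples x variants) of alt-allele dosages,
#'   `NA` = missing; rownames are sample ids.
#' @param chrom,pos per-variant chromosome label and 1-based position.
#' @param refAllele,altAllele per-variant single-base alleles.
#' @return A [GenotypeMatrix-class] object.
#' @export
GenotypeMatrix <- function(calls, chrom, pos, refAllele, altAllele) {
  storage.mode(calls) <- "integer"
  new("GenotypeMatrix", calls = calls, chrom = as.character(chrom),
      pos = as.integer(pos), refAllele = as.character(refAllele),
      altAllele = as.character(altAllele))
}

# ---------------------------------------------------------------------------
# HaplotypeSet
# ---------------------------------------------------------------------------

#' HaplotypeSet: phased binary haplotypes
#'
#' 2 n_samples x n_variants binary matrix (0 = ancestral, 1 = derived once
#' polarized; 0 = REF, 1 = ALT as read from a phased VCF). Haplotype rows
#' `2i-1` and `2i` belong to sample `i`. No missing values are allowed:
#' EHH-based statistics require complete phased input.
#'
#' @slot haplotypes integer 0/1 matrix, 2*n_samples x n_variants.
#' @slot ancestralIsRef logical per variant: TRUE when the ancestral allele
#'   is the VCF REF allele under the recorded polarization.
#' @slot chrom,pos,refAllele,altAllele as in [GenotypeMatrix-class].
#'
#' @export
setClass("HaplotypeSet",
  representation(
    haplotypes = "matrix",
    ancestralIsRef = "logical",
    chrom = "character",
    pos = "integer",
    refAllele = "character",
    altAllele = "character"
  )
)

setValidity("HaplotypeSet", function(object) {
  msg <- character()
  m <- ncol(object@haplotypes)
  if (nrow(object@haplotypes) %% 2L != 0L)
    msg <- c(msg, "haplotype count must be even (two per sample)")
  if (anyNA(object@haplotypes) || !all(object@haplotypes %in% c(0L, 1L)))
    msg <- c(msg, "haplotypes must be strictly binary with no missing values")
  if (length(object@ancestralIsRef) != m)
    msg <- c(msg, "ancestralIsRef length != n_variants")
  for (s in c("chrom", "pos", "refAllele", "altAllele"))
    if (length(slot(object, s)) != m) msg <- c(msg, paste0(s, " length != n_variants"))
  if (m > 1L) {
    same <- object@chrom[-1L] == object@chrom[-m]
    if (any(same & object@pos[-1L] <= object@pos[-m]))
      msg <- c(msg, "positions must be strictly increasing within chromosome")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a HaplotypeSet
#'
#' @param haplotypes 0/1 integer matrix, two consecutive rows per sample;
#'   rownames of the odd rows (suffix stripped of `_1`/`_2`) give sample ids.
#' @param chrom,pos,refAllele,altAllele per-variant metadata.
#' @param ancestralIsRef logical per variant; default all TRUE (REF coded 0).
#' @return A [HaplotypeSet-class] object.
#' @export
HaplotypeSet <- function(haplotypes, chrom, pos, refAllele, altAllele,
                         ancestralIsRef = rep(TRUE, ncol(haplotypes))) {
  storage.mode(haplotypes) <- "integer"
  new("HaplotypeSet", haplotypes = haplotypes, chrom = as.character(chrom),
      pos = as.integer(pos), refAllele = as.character(refAllele),
      altAllele = as.character(altAllele), ancestralIsRef = ancestralIsRef)
}

# ---------------------------------------------------------------------------
# PopulationMap
# ---------------------------------------------------------------------------

#' PopulationMap: sample-to-population assignment
#'
#' @slot pop named character vector; names are sample ids, values population
#'   codes. Every sample has exactly one population.
#' @export
setClass("PopulationMap", representation(pop = "character"))

setValidity("PopulationMap", function(object) {
  msg <- character()
  if (is.null(names(object@pop)) || any(!nzchar(names(object@pop))))
    msg <- c(msg, "every entry must be named by a sample id")
  if (anyDuplicated(names(object@pop)))
    msg <- c(msg, "a sample may appear only once")
  if (any(!nzchar(object@pop)) || anyNA(object@pop))
    msg <- c(msg, "population codes must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Construct a PopulationMap
#' @param pop named character vector (names = sample ids, values = population
#'   codes), or a two-column data.frame (sample_id, population).
#' @return A [PopulationMap-class] object.
#' @export
PopulationMap <- function(pop) {
  if (is.data.frame(pop)) {
    stopifnot(ncol(pop) >= 2L)
    pop <- setNames(as.character(pop[[2L]]), as.character(pop[[1L]]))
  }
  new("PopulationMap", pop = pop)
}

# ---------------------------------------------------------------------------
# QCReport / ROHParams / PCAResult / AncestryFit
# ---------------------------------------------------------------------------

#' QCReport: bookkeeping of the genotype quality-control filters
#' @slot nVariantsIn,nRemovedCallRate,nRemovedMAF,nSamplesRemovedMissing,nVariantsOut integer counters.
#' @slot thresholds named numeric: min_call_rate, min_maf, max_sample_missing.
#' @export
setClass("QCReport",
  representation(
    nVariantsIn = "integer", nRemovedCallRate = "integer",
    nRemovedMAF = "integer", nSamplesRemovedMissing = "integer",
    nVariantsOut = "integer", thresholds = "numeric"
  )
)

setValidity("QCReport", function(object) {
  msg <- character()
  if (object@nVariantsOut !=
      object@nVariantsIn - object@nRemovedCallRate - object@nRemovedMAF)
    msg <- c(msg, "variant counts do not balance")
  if (any(object@thresholds < 0) || any(object@thresholds > 1))
    msg <- c(msg, "thresholds must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' ROHParams: PLINK-style run-of-homozygosity detection parameters
#'
#' Defaults mirror the PLINK flags `--homozyg-kb 1000 --homozyg-window-snp 100
#' --homozyg-window-het 1 --homozyg-window-missing 2
#' --homozyg-window-threshold 0.05 --homozyg-snp 100 --homozyg-density 100
#' --homozyg-gap 1000`.
#'
#' @slot minKb minimum segment length (kb).
#' @slot windowSnp scanning window size in SNPs.
#' @slot windowHet,windowMissing maximum heterozygous / missing calls for a
#'   window to count as homozygous.
#' @slot windowThreshold minimum fraction of homozygous windows covering a
#'   SNP for it to qualify.
#' @slot minSnp minimum SNPs in a retained segment.
#' @slot maxDensityKbPerSnp maximum kb per SNP in a retained segment.
#' @slot maxGapKb split candidate runs at inter-SNP gaps above this (kb).
#' @export
setClass("ROHParams",
  representation(
    minKb = "numeric", windowSnp = "integer", windowHet = "integer",
    windowMissing = "integer", windowThreshold = "numeric",
    minSnp = "integer", maxDensityKbPerSnp = "numeric", maxGapKb = "numeric"
  ),
  prototype(
    minKb = 1000, windowSnp = 100L, windowHet = 1L, windowMissing = 2L,
    windowThreshold = 0.05, minSnp = 100L, maxDensityKbPerSnp = 100,
    maxGapKb = 1000
  )
)

setValidity("ROHParams", function(object) {
  vals <- c(object@minKb, object@windowSnp, object@windowHet + 1L,
            object@windowMissing + 1L, object@minSnp,
            object@maxDensityKbPerSnp, object@maxGapKb)
  if (any(vals <= 0)) return("parameters must be positive")
  if (object@windowThreshold <= 0 || object@windowThreshold > 1)
    return("windowThreshold must lie in (0,1]")
  TRUE
})

#' Construct ROHParams
#' @param minKb,windowSnp,windowHet,windowMissing,windowThreshold,minSnp,maxDensityKbPerSnp,maxGapKb
#'   see [ROHParams-class]; defaults are the PLINK parameter set above.
#' @return An [ROHParams-class] object.
#' @export
ROHParams <- function(minKb = 1000, windowSnp = 100L, windowHet = 1L,
                      windowMissing = 2L, windowThreshold = 0.05,
                      minSnp = 100L, maxDensityKbPerSnp = 100,
                      maxGapKb = 1000) {
  new("ROHParams", minKb = minKb, windowSnp = as.integer(windowSnp),
      windowHet = as.integer(windowHet),
      windowMissing = as.integer(windowMissing),
      windowThreshold = windowThreshold, minSnp = as.integer(minSnp),
      maxDensityKbPerSnp = maxDensityKbPerSnp, maxGapKb = maxGapKb)
}

#' PCAResult: principal components of a genotype matrix
#' @slot coordinates samples x components score matrix.
#' @slot explainedVarianceFraction per-component fraction of total variance.
#' @slot scaling "patterson" or "center".
#' @export
setClass("PCAResult",
  representation(coordinates = "matrix",
                 explainedVarianceFraction = "numeric",
                 scaling = "character")
)

setValidity("PCAResult", function(object) {
  if (ncol(object@coordinates) != length(object@explainedVarianceFraction))
    return("one explained fraction per component required")
  if (any(object@explainedVarianceFraction < -1e-12))
    return("explained fractions must be non-negative")
  if (sum(object@explainedVarianceFraction) > 1 + 1e-8)
    return("explained fractions must sum to at most 1")
  TRUE
})

#' AncestryFit: admixture model fit for one K
#'
#' The model: each individual i draws its two allele copies at SNP j from K
#' ancestral populations with proportions `Q[i, ]`; population k carries the
#' derived/ALT allele at frequency `F[k, j]`; the genotype is binomial with
#' success probability `sum_k Q[i,k] F[k,j]`.
#'
#' @slot K number of ancestral populations.
#' @slot Q samples x K ancestry proportions (rows sum to 1).
#' @slot F K x variants ancestral allele frequencies in [0,1].
#' @slot loglikTrace log-likelihood after each EM iteration (non-decreasing).
#' @slot cvError mean masked-genotype binomial deviance (NA unless from CV).
#' @export
setClass("AncestryFit",
  representation(K = "integer", Q = "matrix", F = "matrix",
                 loglikTrace = "numeric", cvError = "numeric")
)

setValidity("AncestryFit", function(object) {
  msg <- character()
  if (ncol(object@Q) != object@K || nrow(object@F) != object@K)
    msg <- c(msg, "Q/F dimensions inconsistent with K")
  if (any(object@Q < -1e-9) || any(abs(rowSums(object@Q) - 1) > 1e-6))
    msg <- c(msg, "Q rows must be non-negative and sum to 1")
  if (any(object@F < -1e-9) || any(object@F > 1 + 1e-9))
    msg <- c(msg, "F entries must lie in [0,1]")
  if (length(object@loglikTrace) > 1L &&
      any(diff(object@loglikTrace) < -1e-6 * abs(object@loglikTrace[1L])))
    msg <- c(msg, "log-likelihood trace must be non-decreasing")
  if (length(msg)) msg else TRUE
})
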