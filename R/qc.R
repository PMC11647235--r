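# Variant- and sample-level genotype quality control.

# Alt-allele frequency per variant over non-missing calls; NaN where no calls.
altFreq <- function(calls) {
  colSums(calls, na.rm = TRUE) / (2 * colSums(!is.na(calls)))
}

#' Genotype quality control
#'
#' Applies, in this fixed order: (1) drop samples whose missing-genotype
#' fraction exceeds `maxSampleMissing`; (2) drop variants whose call rate
#' over the retained samples is below `minCallRate`; (3) drop variants whose
#' minor allele frequency, computed over the retained samples' non-missing
#' calls, is below `minMAF`. Defaults reproduce the conventional array QC of
#' a 99% call rate, 1% MAF and 10% sample missingness. The fixed order is
#' recorded in the report; filtering is idempotent.
#'
#' @param g a [GenotypeMatrix-class].
#' @param minCallRate minimum variant call rate in [0,1].
#' @param minMAF minimum minor allele frequency in [0,1].
#' @param maxSampleMissing maximum per-sample missing fraction in [0,1].
#' @return list with `genotypes` (filtered [GenotypeMatrix-class]) and
#'   `report` (a [QCReport-class]).
#' @export
filterGenotypes <- function(g, minCallRate = 0.99, minMAF = 0.01,
                            maxSampleMissing = 0.10) {
  stopifnot(is(g, "GenotypeMatrix"))
  if (nSamples(g) == 0L || nVariants(g) == 0L) stop("empty genotype matrix")
  calls <- g@calls
  nIn <- ncol(calls)

  sampleMiss <- rowMeans(is.na(calls))
  dropSample <- sampleMiss > maxSampleMissing
  if (all(dropSample)) stop("all samples removed by missingness filter")
  if (any(dropSample))
    message("filterGenotypes: removed ", sum(dropSample),
            " sample(s) with missing fraction > ", maxSampleMissing)
  calls <- calls[!dropSample, , drop = FALSE]

  callRate <- colMeans(!is.na(calls))
  dropCR <- callRate < minCallRate

  p <- altFreq(calls)
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  dropMAF <- !dropCR & maf < minMAF

  keep <- !(dropCR | dropMAF)
  if (!any(keep)) stop("all variants removed by QC filters")

  report <- new("QCReport",
    nVariantsIn = nIn,
    nRemovedCallRate = sum(dropCR),
    nRemovedMAF = sum(dropMAF),
    nSamplesRemovedMissing = sum(dropSample),
    nVariantsOut = sum(keep),
    thresholds = c(min_call_rate = minCallRate, min_maf = minMAF,
                   max_sample_missing = maxSampleMissing))

  out <- GenotypeMatrix(calls[, keep, drop = FALSE], g@chrom[keep],
                        g@pos[keep], g@refAllele[keep], g@altAllele[keep])
  list(genotypes = out, report = report)
}
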