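# Accessor generics and methods; slot access stays internal to the package.

#' @name accessors
#' @title Accessors for popgenscan containers
#' @description Accessor functions for [GenotypeMatrix-class],
#'   [HaplotypeSet-class], [PopulationMap-class], [PCAResult-class] and
#'   [AncestryFit-class] objects.
#' @param x,object a popgenscan container.
#' @return The requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))
#' @rdname accessors
#' @export
setGeneric("chromosomes", function(x) standardGeneric("chromosomes"))
#' @rdname accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))
#' @rdname accessors
#' @export
setGeneric("refAllele", function(x) standardGeneric("refAllele"))
#' @rdname accessors
#' @export
setGeneric("altAllele", function(x) standardGeneric("altAllele"))
#' @rdname accessors
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))
#' @rdname accessors
#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))
#' @rdname accessors
#' @export
setGeneric("ancestralIsRef", function(x) standardGeneric("ancestralIsRef"))
#' @rdname accessors
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname accessors
#' @export
setMethod("sampleIDs", "GenotypeMatrix", function(x) rownames(x@calls))
#' @rdname accessors
#' @export
setMethod("nSamples", "GenotypeMatrix", function(x) nrow(x@calls))
#' @rdname accessors
#' @export
setMethod("nVariants", "GenotypeMatrix", function(x) ncol(x@calls))
#' @rdname accessors
#' @export
setMethod("chromosomes", "GenotypeMatrix", function(x) x@chrom)
#' @rdname accessors
#' @export
setMethod("positions", "GenotypeMatrix", function(x) x@pos)
#' @rdname accessors
#' @export
setMethod("refAllele", "GenotypeMatrix", function(x) x@refAllele)
#' @rdname accessors
#' @export
setMethod("altAllele", "GenotypeMatrix", function(x) x@altAllele)
#' @rdname accessors
#' @export
setMethod("genotypeCalls", "GenotypeMatrix", function(x) x@calls)

#' @rdname accessors
#' @export
setMethod("sampleIDs", "HaplotypeSet", function(x) {
  ids <- rownames(x@haplotypes)[seq(1L, nrow(x@haplotypes), by = 2L)]
  sub("_[12]$", "", ids)
})
#' @rdname accessors
#' @export
setMethod("nSamples", "HaplotypeSet", function(x) nrow(x@haplotypes) %/% 2L)
#' @rdname accessors
#' @export
setMethod("nVariants", "HaplotypeSet", function(x) ncol(x@haplotypes))
#' @rdname accessors
#' @export
setMethod("chromosomes", "HaplotypeSet", function(x) x@chrom)
#' @rdname accessors
#' @export
setMethod("positions", "HaplotypeSet", function(x) x@pos)
#' @rdname accessors
#' @export
setMethod("refAllele", "HaplotypeSet", function(x) x@refAllele)
#' @rdname accessors
#' @export
setMethod("altAllele", "HaplotypeSet", function(x) x@altAllele)
#' @rdname accessors
#' @export
setMethod("haplotypes", "HaplotypeSet", function(x) x@haplotypes)
#' @rdname accessors
#' @export
setMethod("ancestralIsRef", "HaplotypeSet", function(x) x@ancestralIsRef)

#' @rdname accessors
#' @export
setMethod("sampleIDs", "PopulationMap", function(x) names(x@pop))
#' @rdname accessors
#' @export
setMethod("populations", "PopulationMap", function(x) x@pop)

#' @rdname accessors
#' @export
setGeneric("pcaCoordinates", function(x) standardGeneric("pcaCoordinates"))
#' @rdname accessors
#' @export
setMethod("pcaCoordinates", "PCAResult", function(x) x@coordinates)
#' @rdname accessors
#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))
#' @rdname accessors
#' @export
setMethod("explainedVariance", "PCAResult", function(x) x@explainedVarianceFraction)

#' @rdname accessors
#' @export
setGeneric("ancestryQ", function(x) standardGeneric("ancestryQ"))
#' @rdname accessors
#' @export
setMethod("ancestryQ", "AncestryFit", function(x) x@Q)
#' @rdname accessors
#' @export
setGeneric("ancestryF", function(x) standardGeneric("ancestryF"))
#' @rdname accessors
#' @export
setMethod("ancestryF", "AncestryFit", function(x) x@F)
#' @rdname accessors
#' @export
setGeneric("loglikTrace", function(x) standardGeneric("loglikTrace"))
#' @rdname accessors
#' @export
setMethod("loglikTrace", "AncestryFit", function(x) x@loglikTrace)
#' @rdname accessors
#' @export
setGeneric("cvError", function(x) standardGeneric("cvError"))
#' @rdname accessors
#' @export
setMethod("cvError", "AncestryFit", function(x) x@cvError)

#' @rdname accessors
#' @export
setGeneric("qcThresholds", function(x) standardGeneric("qcThresholds"))
#' @rdname accessors
#' @export
setMethod("qcThresholds", "QCReport", function(x) x@thresholds)

#' QC counters as a one-row data.frame
#' @param x a [QCReport-class].
#' @return data.frame with the filter counters.
#' @export
qcCounts <- function(x) {
  stopifnot(is(x, "QCReport"))
  data.frame(
    n_variants_in = x@nVariantsIn,
    n_samples_removed_missing = x@nSamplesRemovedMissing,
    n_removed_callrate = x@nRemovedCallRate,
    n_removed_maf = x@nRemovedMAF,
    n_variants_out = x@nVariantsOut
  )
}

# -- subsetting -------------------------------------------------------------

#' @describeIn accessors subset samples (i) and/or variants (j).
#' @param i,j sample and variant indices.
#' @param drop ignored.
#' @param ... ignored.
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@calls))
  if (missing(j)) j <- seq_len(ncol(x@calls))
  GenotypeMatrix(x@calls[i, j, drop = FALSE], x@chrom[j], x@pos[j],
                 x@refAllele[j], x@altAllele[j])
})

#' @describeIn accessors subset samples (i) and/or variants (j); sample
#'   subsetting keeps both haplotypes of each selected sample.
#' @export
setMethod("[", "HaplotypeSet", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@haplotypes) %/% 2L)
  if (missing(j)) j <- seq_len(ncol(x@haplotypes))
  if (is.character(i)) i <- match(i, sampleIDs(x))
  if (is.logical(i)) i <- which(i)
  hrows <- as.vector(rbind(2L * i - 1L, 2L * i))
  HaplotypeSet(x@haplotypes[hrows, j, drop = FALSE], x@chrom[j], x@pos[j],
               x@refAllele[j], x@altAllele[j], x@ancestralIsRef[j])
})

# -- show -------------------------------------------------------------------

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@calls), "samples x",
      ncol(object@calls), "variants on",
      length(unique(object@chrom)), "chromosome(s);",
      sum(is.na(object@calls)), "missing calls\n")
})

setMethod("show", "HaplotypeSet", function(object) {
  cat("HaplotypeSet:", nrow(object@haplotypes), "haplotypes (",
      nrow(object@haplotypes) %/% 2L, "samples) x",
      ncol(object@haplotypes), "variants;",
      sum(!object@ancestralIsRef), "sites polarized ALT-ancestral\n")
})

setMethod("show", "PopulationMap", function(object) {
  tab <- table(object@pop)
  cat("PopulationMap:", length(object@pop), "samples in", length(tab),
      "populations (", paste(names(tab), tab, sep = ":", collapse = ", "),
      ")\n")
})

setMethod("show", "QCReport", function(object) {
  cat("QCReport:", object@nVariantsIn, "variants in ->",
      object@nVariantsOut, "out;",
      object@nSamplesRemovedMissing, "samples removed,",
      object@nRemovedCallRate, "variants failed call rate,",
      object@nRemovedMAF, "failed MAF\n")
})

setMethod("show", "ROHParams", function(object) {
  cat(sprintf(
    "ROHParams: min %g kb, window %d SNPs (het<=%d, missing<=%d, thr %g), min %d SNPs, density <=%g kb/SNP, gap <=%g kb\n",
    object@minKb, object@windowSnp, object@windowHet, object@windowMissing,
    object@windowThreshold, object@minSnp, object@maxDensityKbPerSnp,
    object@maxGapKb))
})

setMethod("show", "PCAResult", function(object) {
  ev <- object@explainedVarianceFraction
  cat("PCAResult:", nrow(object@coordinates), "samples x",
      ncol(object@coordinates), "components (", object@scaling,
      "scaling); PC1", sprintf("%.2f%%", 100 * ev[1L]), "of variance\n")
})

setMethod("show", "AncestryFit", function(object) {
  cat("AncestryFit: K =", object@K, ";", nrow(object@Q), "samples,",
      ncol(object@F), "variants; final loglik",
      sprintf("%.2f", tail(object@loglikTrace, 1L)),
      if (!is.na(object@cvError)) sprintf("; CV error %.4f", object@cvError)
      else "", "\n")
})
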