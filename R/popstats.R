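# Per-population diversity indices and genomic inbreeding coefficients.

#' Per-population diversity indices
#'
#' For each population and variant: observed heterozygosity Ho is the
#' heterozygote fraction among non-missing calls; expected heterozygosity
#' He = 2p(1-p) with p the within-population sample ALT-allele frequency
#' (uncorrected population value); MAF = min(p, 1-p). The population value
#' of each index is its mean across variants; the SD across variants and
#' the median are reported alongside. Variants with no non-missing call in
#' a population are excluded from that population's summary.
#'
#' @param g a [GenotypeMatrix-class].
#' @param pops a [PopulationMap-class] covering all samples of `g`.
#' @return data.frame, one row per population: `population`, `n_samples`,
#'   then mean/sd/median of `ho`, `he`, `maf`.
#' @export
diversityTable <- function(g, pops) {
  stopifnot(is(g, "GenotypeMatrix"), is(pops, "PopulationMap"))
  popv <- populations(pops)[sampleIDs(g)]
  if (anyNA(popv)) stop("samples missing from the population map: ",
                        paste(sampleIDs(g)[is.na(popv)], collapse = ", "))
  out <- lapply(sort(unique(popv)), function(pp) {
    calls <- g@calls[popv == pp, , drop = FALSE]
    nObs <- colSums(!is.na(calls))
    if (all(nObs == 0L))
      stop("population ", pp, " has no non-missing calls")
    use <- nObs > 0L
    calls <- calls[, use, drop = FALSE]
    nObs <- nObs[use]
    ho <- colSums(calls == 1L, na.rm = TRUE) / nObs
    p <- colSums(calls, na.rm = TRUE) / (2 * nObs)
    he <- 2 * p * (1 - p)
    maf <- pmin(p, 1 - p)
    data.frame(
      population = pp, n_samples = sum(popv == pp),
      ho_mean = mean(ho), ho_sd = sd(ho), ho_median = median(ho),
      he_mean = mean(he), he_sd = sd(he), he_median = median(he),
      maf_mean = mean(maf), maf_sd = sd(maf), maf_median = median(maf))
  })
  do.call(rbind, out)
}

#' Excess-homozygosity inbreeding coefficient F_HOM
#'
#' Per sample, F_HOM = (O - E) / (L - E): O is the observed count of
#' homozygous genotypes over the sample's non-missing autosomal SNPs, L the
#' number of those SNPs, and E the homozygote count expected by chance,
#' `E = sum_j [1 - 2 p_j (1 - p_j) * 2N_j / (2N_j - 1)]` with p_j the
#' ALT-allele frequency over all samples and N_j the number of informative
#' samples at site j (the 2N/(2N-1) factor is the usual small-sample
#' correction of expected heterozygosity). Sites informative in a single
#' sample only are excluded from O, E and L with a log note.
#'
#' @param g a [GenotypeMatrix-class] (the full analysis set; allele
#'   frequencies are computed over all its samples).
#' @return named numeric vector of per-sample F_HOM values (negative values
#'   indicate fewer homozygotes than expected).
#' @export
fHom <- function(g) {
  stopifnot(is(g, "GenotypeMatrix"))
  calls <- g@calls
  nInf <- colSums(!is.na(calls))
  drop <- nInf <= 1L
  if (any(drop)) {
    message("fHom: excluded ", sum(drop),
            " site(s) informative in <2 samples")
    calls <- calls[, !drop, drop = FALSE]
    nInf <- nInf[!drop]
  }
  if (!ncol(calls)) stop("no usable sites for fHom")
  p <- colSums(calls, na.rm = TRUE) / (2 * nInf)
  eSite <- 1 - 2 * p * (1 - p) * (2 * nInf) / (2 * nInf - 1)
  obs <- !is.na(calls)
  O <- rowSums(calls == 0L | calls == 2L, na.rm = TRUE)
  E <- as.vector(obs %*% eSite)
  L <- rowSums(obs)
  fHomIdentity(O, E, L)
}

#' @describeIn fHom the defining identity `(O - E) / (L - E)` on observed
#'   (`O`) and expected (`E`) homozygote counts over `L` typed SNPs.
#' @param O,E,L observed homozygotes, expected homozygotes, typed SNPs.
#' @export
fHomIdentity <- function(O, E, L) (O - E) / (L - E)

#' Genomic inbreeding coefficient F_ROH
#'
#' Ratio of the summed length of a sample's ROH segments to the SNP-covered
#' genome length. `genomeLengthBp` is a configuration value: conventionally
#' the summed span of SNP-covered autosomes of the assembly in use; for
#' synthetic genomes, the simulated SNP-covered span.
#'
#' @param roh data.frame of ROH segments as returned by [detectROH()]
#'   (columns `sample_id`, `start_bp`, `end_bp`, `length_bp`); segments of
#'   one sample must not overlap.
#' @param genomeLengthBp positive denominator in bp.
#' @param samples optional character vector of sample ids to report
#'   (samples without segments get 0).
#' @return named numeric vector of per-sample F_ROH in [0,1].
#' @export
fRoh <- function(roh, genomeLengthBp, samples = NULL) {
  stopifnot(genomeLengthBp > 0)
  if (nrow(roh) && any(roh$length_bp < 0)) stop("negative-length ROH segment")
  sums <- if (nrow(roh))
    tapply(as.numeric(roh$length_bp), roh$sample_id, sum) else numeric()
  if (is.null(samples)) samples <- names(sums)
  f <- setNames(as.numeric(sums[samples]), samples)
  f[is.na(f)] <- 0
  if (any(f > genomeLengthBp)) {
    warning("summed ROH length exceeds genomeLengthBp; F_ROH clipped at 1")
    f <- pmin(f, genomeLengthBp)
  }
  f / genomeLengthBp
}

#' Per-sample and per-population inbreeding table
#'
#' Combines [fRoh()] and [fHom()] into the conventional per-population
#' summary (mean +/- SD of each coefficient).
#'
#' @param g a [GenotypeMatrix-class].
#' @param pops a [PopulationMap-class].
#' @param roh ROH segments from [detectROH()].
#' @param genomeLengthBp denominator for F_ROH (see [fRoh()]).
#' @return list with `per_sample` (sample, population, f_roh, f_hom) and
#'   `per_population` (mean/sd of both) data.frames.
#' @export
inbreedingTable <- function(g, pops, roh, genomeLengthBp) {
  fr <- fRoh(roh, genomeLengthBp, samples = sampleIDs(g))
  fh <- fHom(g)
  popv <- populations(pops)[sampleIDs(g)]
  per <- data.frame(sample_id = sampleIDs(g), population = popv,
                    f_roh = fr[sampleIDs(g)], f_hom = fh[sampleIDs(g)],
                    row.names = NULL)
  agg <- do.call(rbind, lapply(split(per, per$population), function(d)
    data.frame(population = d$population[1L], n = nrow(d),
               f_roh_mean = mean(d$f_roh), f_roh_sd = sd(d$f_roh),
               f_hom_mean = mean(d$f_hom), f_hom_sd = sd(d$f_hom))))
  rownames(agg) <- NULL
  list(per_sample = per, per_population = agg)
}
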