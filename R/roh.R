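# PLINK-style sliding-window detection of runs of homozygosity.

ROH_CLASS_BREAKS <- c(0, 2, 4, 8, 16, Inf)     # Mb, half-open [a, b)
ROH_CLASS_LABELS <- c("<2", "2-4", "4-8", "8-16", ">16")

#' Length class of an ROH segment
#'
#' Half-open classes `[0,2) [2,4) [4,8) [8,16) [16,Inf)` Mb; a segment on a
#' boundary belongs to the upper class.
#' @param lengthBp segment length(s) in bp.
#' @return factor with levels `<2`, `2-4`, `4-8`, `8-16`, `>16`.
#' @export
rohClass <- function(lengthBp) {
  cut(lengthBp / 1e6, breaks = ROH_CLASS_BREAKS, labels = ROH_CLASS_LABELS,
      right = FALSE, include.lowest = TRUE)
}

# Qualifying-SNP mask for one sample on one chromosome.
# A scanning window of `w` consecutive SNPs is homozygous when it holds at
# most windowHet heterozygous and windowMissing missing calls; a SNP
# qualifies when >= windowThreshold of the full windows covering it are
# homozygous. Windows truncated at chromosome ends are not scored.
rohQualifyingSnps <- function(v, params) {
  L <- length(v)
  w <- params@windowSnp
  if (L < w) return(NULL)
  het <- as.integer(!is.na(v) & v == 1L)
  mis <- as.integer(is.na(v))
  cs <- function(x, k) {
    cc <- c(0L, cumsum(x))
    cc[(k + 1L):(L + 1L)] - cc[1L:(L - k + 1L)]
  }
  q <- (cs(het, w) <= params@windowHet) & (cs(mis, w) <= params@windowMissing)
  nW <- L - w + 1L
  cq <- c(0L, cumsum(as.integer(q)))
  i <- seq_len(L)
  lo <- pmax(1L, i - w + 1L)
  hi <- pmin(i, nW)
  nHom <- cq[hi + 1L] - cq[lo]
  nCov <- hi - lo + 1L
  nHom / nCov >= params@windowThreshold
}

# Candidate index ranges: maximal stretches of qualifying SNPs, split at
# physical gaps above maxGapKb.
rohCandidateRanges <- function(hit, pos, params) {
  if (!any(hit)) return(NULL)
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    idx <- i0:i1
    if (length(idx) > 1L) {
      gaps <- diff(pos[idx]) > params@maxGapKb * 1000
      brk <- c(0L, which(gaps), length(idx))
    } else brk <- c(0L, 1L)
    for (b in seq_len(length(brk) - 1L))
      out[[length(out) + 1L]] <- idx[(brk[b] + 1L):brk[b + 1L]]
  }
  out
}

#' Detect runs of homozygosity
#'
#' Per sample and chromosome: slide a window of `windowSnp` SNPs; a window
#' is homozygous if it contains at most `windowHet` heterozygous and
#' `windowMissing` missing calls; a SNP qualifies when the fraction of
#' homozygous windows covering it reaches `windowThreshold`; maximal
#' stretches of qualifying SNPs become candidate segments, split where the
#' gap between consecutive SNPs exceeds `maxGapKb`; candidates are retained
#' when they span at least `minKb` kb, contain at least `minSnp` SNPs and
#' have density at most `maxDensityKbPerSnp` kb per SNP. Segment length is
#' inclusive of both endpoint SNPs (`end - start + 1`).
#'
#' @param g a [GenotypeMatrix-class] with variants sorted by position.
#' @param params an [ROHParams-class]; defaults are the conventional
#'   array-data PLINK parameter set.
#' @return data.frame of segments: `sample_id`, `chrom`, `start_bp`,
#'   `end_bp`, `n_snps`, `length_bp`, `class` (see [rohClass()]).
#' @export
detectROH <- function(g, params = ROHParams()) {
  stopifnot(is(g, "GenotypeMatrix"), is(params, "ROHParams"))
  validObject(params)
  segs <- list()
  chromLevels <- rle(g@chrom)$values
  skipped <- character()
  for (ch in chromLevels) {
    j <- which(g@chrom == ch)
    if (length(j) < params@windowSnp) { skipped <- c(skipped, ch); next }
    pos <- g@pos[j]
    for (s in sampleIDs(g)) {
      hit <- rohQualifyingSnps(g@calls[s, j], params)
      for (idx in rohCandidateRanges(hit, pos, params)) {
        startBp <- pos[idx[1L]]; endBp <- pos[idx[length(idx)]]
        n <- length(idx)
        len <- endBp - startBp + 1L
        if (len >= params@minKb * 1000 && n >= params@minSnp &&
            len / n <= params@maxDensityKbPerSnp * 1000)
          segs[[length(segs) + 1L]] <- data.frame(
            sample_id = s, chrom = ch, start_bp = startBp, end_bp = endBp,
            n_snps = n, length_bp = len)
      }
    }
  }
  if (length(skipped))
    message("detectROH: chromosome(s) with fewer than ", params@windowSnp,
            " SNPs skipped: ", paste(skipped, collapse = ", "))
  if (!length(segs))
    return(data.frame(sample_id = character(), chrom = character(),
                      start_bp = integer(), end_bp = integer(),
                      n_snps = integer(), length_bp = integer(),
                      class = rohClass(numeric())))
  out <- do.call(rbind, segs)
  out$class <- rohClass(out$length_bp)
  out
}

#' Per-population ROH summary
#'
#' Class-wise segment counts per population plus, per population: total
#' segment count, mean segment length (Mb), mean per-individual segment
#' count and mean per-individual summed ROH length (Mb). Individuals of the
#' population map without any segment contribute zeros to the
#' per-individual means.
#'
#' @param roh segments from [detectROH()].
#' @param pops a [PopulationMap-class].
#' @return list with `class_counts` (population x class matrix, plus Total
#'   column) and `summary` data.frame.
#' @export
summarizeROH <- function(roh, pops) {
  stopifnot(is(pops, "PopulationMap"))
  popv <- populations(pops)
  pnames <- sort(unique(popv))
  cc <- matrix(0L, nrow = length(pnames), ncol = length(ROH_CLASS_LABELS),
               dimnames = list(pnames, ROH_CLASS_LABELS))
  summ <- data.frame(population = pnames, n_segments = 0L,
                     mean_length_mb = NA_real_,
                     mean_n_per_individual = 0,
                     mean_sum_mb_per_individual = 0)
  if (nrow(roh)) {
    segPop <- popv[roh$sample_id]
    if (anyNA(segPop)) stop("ROH sample missing from population map")
    t0 <- table(factor(segPop, levels = pnames),
                factor(roh$class, levels = ROH_CLASS_LABELS))
    cc[] <- as.integer(t0)
    for (k in seq_along(pnames)) {
      d <- roh[segPop == pnames[k], , drop = FALSE]
      ids <- names(popv)[popv == pnames[k]]
      summ$n_segments[k] <- nrow(d)
      summ$mean_length_mb[k] <- if (nrow(d)) mean(d$length_bp) / 1e6 else NA_real_
      perN <- table(factor(d$sample_id, levels = ids))
      perSum <- tapply(as.numeric(d$length_bp),
                       factor(d$sample_id, levels = ids), sum,
                       default = 0)
      summ$mean_n_per_individual[k] <- mean(perN)
      summ$mean_sum_mb_per_individual[k] <- mean(perSum) / 1e6
    }
  }
  list(class_counts = cbind(cc, Total = rowSums(cc)), summary = summ)
}
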