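# iHS selection scan: EHH profiles, integrated haplotype homozygosity,
# frequency-bin standardization, p-value transform and the overlapping
# 1 Mb / 500 kb window outlier scan.

chromBlock <- function(h, core) {
  ch <- h@chrom[core]
  j <- which(h@chrom == ch)
  list(chrom = ch, cols = j, core = match(core, j))
}

#' Extended haplotype homozygosity profile around a core SNP
#'
#' EHH at flanking SNP x is the probability that two random haplotypes
#' carrying `allele` at the core are identical over the whole interval
#' [core..x]: `sum_g C(n_g,2) / C(n,2)` over identity groups g. The profile
#' is 1 at the core and non-increasing with distance; the walk stops after
#' the first flank where EHH drops below `limit`, at a physical gap above
#' `maxGapBp`, or at the chromosome edge (the latter two recorded as
#' truncation).
#'
#' @param h a polarized [HaplotypeSet-class] (0 = ancestral, 1 = derived;
#'   see [polarize()]).
#' @param core variant index of the core SNP.
#' @param allele `"ancestral"` or `"derived"`.
#' @param limit EHH cutoff terminating the walk.
#' @param maxGapBp maximum tolerated gap between consecutive SNPs (bp).
#' @return list of class `EHHProfile`: `core_pos`, `allele`, `n_carriers`,
#'   `left`/`right` data.frames (pos, ehh, ordered outward from the core),
#'   `left_truncated`/`right_truncated`, and one-sided `left_ihh` /
#'   `right_ihh` trapezoid areas (bp).
#' @export
ehh <- function(h, core, allele = c("derived", "ancestral"), limit = 0.05,
                maxGapBp = 200000) {
  allele <- match.arg(allele)
  stopifnot(is(h, "HaplotypeSet"))
  blk <- chromBlock(h, core)
  H <- h@haplotypes[, blk$cols, drop = FALSE]
  a <- if (allele == "derived") 1L else 0L
  nCar <- sum(H[, blk$core] == a)
  if (nCar < 2L)
    stop("EHH profile undefined: ", allele, " allele at ", blk$chrom, ":",
         h@pos[core], " carried by ", nCar, " haplotype(s)")
  prof <- .ehh_profile_cpp(H, blk$core, a, as.numeric(h@pos[blk$cols]),
                           limit, maxGapBp)
  pos <- h@pos[blk$cols]
  structure(list(
    chrom = blk$chrom, core_pos = pos[blk$core], allele = allele,
    n_carriers = prof$n_carriers, limit = limit,
    left = data.frame(pos = pos[prof$left_idx + 1L], ehh = prof$left_ehh),
    right = data.frame(pos = pos[prof$right_idx + 1L], ehh = prof$right_ehh),
    left_truncated = prof$left_truncated,
    right_truncated = prof$right_truncated,
    left_ihh = prof$left_ihh, right_ihh = prof$right_ihh),
    class = "EHHProfile")
}

#' Integrated EHH (iHH) of a profile
#'
#' Trapezoid integral of EHH against bp position on each side of the core
#' (starting from EHH = 1 at the core), both directions summed; integration
#' stops where the profile itself stopped (the cutoff crossing). Units bp.
#' Edge-truncated profiles are integrable but the genome scan discards
#' their cores (see [ihsScan()]).
#'
#' @param profile an `EHHProfile` from [ehh()].
#' @return total area in bp.
#' @export
ihh <- function(profile) {
  stopifnot(inherits(profile, "EHHProfile"))
  trapz <- function(side) {
    if (!nrow(side)) return(0)
    x <- c(profile$core_pos, side$pos)
    y <- c(1, side$ehh)
    sum(abs(diff(x)) * (head(y, -1) + tail(y, -1)) / 2)
  }
  trapz(profile$left) + trapz(profile$right)
}

#' Genome-wide unstandardized iHS scan
#'
#' For every core SNP computes iHH for the ancestral and derived allele
#' classes and the log-ratio `ln(iHH_A / iHH_D)`. Cores are skipped (NA,
#' with a reason code) when the derived frequency falls outside
#' `[minDerivedFreq, 1 - minDerivedFreq]`, when an allele class has fewer
#' than 2 carrier haplotypes, or when any side-walk is truncated by the
#' chromosome edge or a gap above `maxGapBp` (edge policy: discard).
#'
#' @param h a polarized [HaplotypeSet-class].
#' @param limit,maxGapBp EHH walk parameters (see [ehh()]).
#' @param minDerivedFreq minimum derived-allele frequency for a core.
#' @return data.frame per SNP: `chrom`, `pos`, `freq_derived`, `ihh_a`,
#'   `ihh_d`, `ln_ratio` (NA where skipped), `reason` (`ok`, `frequency`,
#'   `carriers`, `truncated`).
#' @export
ihsScan <- function(h, limit = 0.05, maxGapBp = 200000,
                    minDerivedFreq = 0.05) {
  stopifnot(is(h, "HaplotypeSet"))
  out <- lapply(rle(h@chrom)$values, function(ch) {
    j <- which(h@chrom == ch)
    d <- .ihs_scan_cpp(h@haplotypes[, j, drop = FALSE],
                       as.numeric(h@pos[j]), limit, maxGapBp,
                       minDerivedFreq, 1 - minDerivedFreq)
    cbind(data.frame(chrom = ch, pos = h@pos[j]), d)
  })
  res <- do.call(rbind, out)
  res$reason <- c("ok", "frequency", "carriers", "truncated")[res$reason + 1L]
  nSkip <- sum(res$reason != "ok")
  if (nSkip) message("ihsScan: ", nSkip, " of ", nrow(res),
                     " cores skipped (frequency/carriers/truncation)")
  res
}

#' piHS: two-sided p-value transform of standardized iHS
#'
#' `piHS = -log10[1 - 2 |Phi(iHS) - 0.5|]`, with Phi the standard normal
#' CDF; equivalently `-log10` of the two-sided normal tail probability.
#' Symmetric in the sign of iHS; 0 at iHS = 0.
#'
#' @param ihs standardized iHS value(s).
#' @return piHS value(s), >= 0.
#' @export
pihs <- function(ihs) {
  -log10(2 * pnorm(abs(ihs), lower.tail = FALSE))
}

#' Standardize iHS within derived-allele-frequency bins
#'
#' `iHS = (ln(iHH_A/iHH_D) - E_p[.]) / SD_p[.]` where the expectation and
#' SD are taken within the core's derived-frequency bin p: `nBins`
#' equal-width bins on (0,1), bins holding fewer than `minBin` usable SNPs
#' merged with their nearest neighbor (logged). Adds `piHS` (see [pihs()]).
#'
#' @param scan data.frame from [ihsScan()] (or any table with columns
#'   `freq_derived` and `ln_ratio`).
#' @param nBins number of equal-width frequency bins.
#' @param minBin minimum SNPs per retained bin.
#' @return the input with columns `freq_bin`, `ihs`, `pihs` added
#'   (NA where `ln_ratio` is NA).
#' @export
standardizeIHS <- function(scan, nBins = 20L, minBin = 10L) {
  stopifnot(all(c("freq_derived", "ln_ratio") %in% names(scan)))
  usable <- !is.na(scan$ln_ratio)
  bin <- pmin(pmax(ceiling(scan$freq_derived * nBins), 1L), nBins)
  # merge under-filled bins with their nearest occupied neighbor
  counts <- tabulate(bin[usable], nBins)
  merged <- seq_len(nBins)          # merged[b]: group label of original bin b
  repeat {
    eff <- vapply(split(counts, merged), sum, 0)
    small <- names(eff)[eff > 0 & eff < minBin]
    if (!length(small)) break
    b <- as.integer(small[1L])
    occ <- setdiff(as.integer(names(eff)[eff > 0]), b)
    if (!length(occ)) break         # a single under-filled group remains
    nb <- occ[which.min(abs(occ - b))]
    message("standardizeIHS: merging frequency bin ", b, " into bin ", nb,
            " (", eff[as.character(b)], " SNPs < ", minBin, ")")
    merged[merged == b] <- nb
  }
  binEff <- merged[bin]
  scan$freq_bin <- binEff
  scan$ihs <- NA_real_
  for (b in unique(binEff[usable])) {
    sel <- usable & binEff == b
    mu <- mean(scan$ln_ratio[sel])
    sdv <- sd(scan$ln_ratio[sel])
    if (!is.finite(sdv) || sdv == 0)
      stop("zero iHS standard deviation in frequency bin ", b)
    scan$ihs[sel] <- (scan$ln_ratio[sel] - mu) / sdv
  }
  scan$pihs <- pihs(scan$ihs)
  scan
}

#' Overlapping-window outlier scan
#'
#' Tiles each chromosome with `windowBp` windows stepping `stepBp`
#' (anchored at position 0; the trailing partial window is retained), takes
#' the maximum |iHS| among the window's SNPs as the test statistic, drops
#' windows without a usable SNP, flags as significant every window whose
#' statistic reaches the empirical top-`topFraction` threshold (the
#' `ceiling(topFraction * n)`-th largest value; ties at the threshold are
#' all kept — overlapping windows sharing the extreme SNP tie exactly),
#' and merges
#' overlapping significant windows into candidate regions. SNPs with
#' `piHS > snpThreshold` are reported separately.
#'
#' @param scan standardized table from [standardizeIHS()].
#' @param windowBp,stepBp window length and step (bp).
#' @param topFraction fraction of windows called significant.
#' @param snpThreshold per-SNP piHS threshold.
#' @return list of class `WindowScan`: `windows` (chrom, start_bp, end_bp,
#'   n_snps, max_abs_ihs), `threshold` (lowest significant statistic),
#'   `significant`, `regions` (merged candidate regions, 1-based
#'   inclusive), `snp_significant`.
#' @export
windowScan <- function(scan, windowBp = 1e6, stepBp = 5e5,
                       topFraction = 0.01, snpThreshold = 4.0) {
  stopifnot(all(c("chrom", "pos", "ihs", "pihs") %in% names(scan)))
  wins <- list()
  for (ch in unique(scan$chrom)) {
    d <- scan[scan$chrom == ch, ]
    if (!any(!is.na(d$ihs))) {
      message("windowScan: no usable SNP on chromosome ", ch, "; skipped")
      next
    }
    chromEnd <- max(d$pos)
    nWin <- if (chromEnd <= windowBp) 1L else
      ceiling((chromEnd - windowBp) / stepBp) + 1L
    starts <- (seq_len(nWin) - 1L) * stepBp
    for (s in starts) {
      inWin <- d$pos >= s + 1 & d$pos <= s + windowBp & !is.na(d$ihs)
      if (!any(inWin)) next
      wins[[length(wins) + 1L]] <- data.frame(
        chrom = ch, start_bp = s + 1, end_bp = s + windowBp,
        n_snps = sum(inWin), max_abs_ihs = max(abs(d$ihs[inWin])))
    }
  }
  if (!length(wins)) stop("windowScan: no non-empty window")
  windows <- do.call(rbind, wins)
  nSig <- ceiling(topFraction * nrow(windows))
  ord <- order(windows$max_abs_ihs, decreasing = TRUE)
  threshold <- windows$max_abs_ihs[ord[nSig]]
  # all windows at or above the empirical threshold are significant: a SNP
  # shared by two overlapping windows ties them, and both fall in the top
  # fraction of the empirical distribution
  sig <- windows[windows$max_abs_ihs >= threshold, ]

  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    sig$chrom, IRanges::IRanges(sig$start_bp, sig$end_bp)))
  regions <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start_bp = GenomicRanges::start(gr), end_bp = GenomicRanges::end(gr))

  structure(list(
    windows = windows, threshold = threshold, significant = sig,
    regions = regions,
    snp_significant = scan[!is.na(scan$pihs) & scan$pihs > snpThreshold, ],
    params = list(window_bp = windowBp, step_bp = stepBp,
                  top_fraction = topFraction,
                  snp_threshold = snpThreshold)),
    class = "WindowScan")
}
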