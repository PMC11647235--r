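# Seeded generator of phased multi-population genotype data with planted
# population structure, autozygosity and hard sweeps. This is the test
# substrate for every analysis module: drifted populations are
# PCA/admixture-separable, planted tracts create F_ROH signal, planted
# sweeps create iHS signal.

truncNorm <- function(mu, sdv, lo, hi) {
  # exact truncated-normal draw via inverse CDF; vectorized over mu
  u <- runif(length(mu), pnorm(lo, mu, sdv), pnorm(hi, mu, sdv))
  qnorm(u, mu, sdv)
}

#' Simulation configuration
#'
#' Defaults describe the study conditions the generator emulates: several
#' strongly isolated populations (allele-frequency drift SD 0.2 around a
#' U-shaped ancestral spectrum), array-like SNP density, background LD from
#' a founder-copying step, and array-like missingness.
#'
#' @param nPops number of populations.
#' @param samplesPerPop diploid individuals per population.
#' @param nChrom number of chromosomes.
#' @param chromLengthBp chromosome length (bp); recycled over chromosomes.
#' @param snpDensity SNPs per Mb.
#' @param divergenceDrift SD of the truncated-normal per-population
#'   allele-frequency drift around the ancestral frequency.
#' @param sweeps list of sweep specs: `list(pop=, chrom=, positionBp=,
#'   targetFreq=, spanBp=)` (see [plantSweep()]).
#' @param autozygosity list of autozygosity specs: `list(pop=, phi=)`
#'   (see [plantAutozygosity()]).
#' @param missingRate per-genotype missing probability (haplotypes stay
#'   complete; missingness applies to the emitted genotype matrix).
#' @param ldFounders per-population founder-haplotype pool size for the
#'   copying step.
#' @param ldSwitchRate per-SNP probability of switching founder while
#'   copying (mean copied stretch = 1/rate SNPs).
#' @param seed mandatory integer seed; all randomness flows through it.
#' @return list of class `SimConfig`.
#' @export
simConfig <- function(nPops = 3L, samplesPerPop = 20L, nChrom = 2L,
                      chromLengthBp = 25e6, snpDensity = 100,
                      divergenceDrift = 0.2, sweeps = list(),
                      autozygosity = list(), missingRate = 0.002,
                      ldFounders = 8L, ldSwitchRate = 0.05, seed) {
  if (missing(seed)) stop("simConfig: seed is mandatory")
  chromLengthBp <- rep_len(chromLengthBp, nChrom)
  cfg <- list(nPops = as.integer(nPops),
              samplesPerPop = as.integer(samplesPerPop),
              nChrom = as.integer(nChrom), chromLengthBp = chromLengthBp,
              snpDensity = snpDensity, divergenceDrift = divergenceDrift,
              sweeps = sweeps, autozygosity = autozygosity,
              missingRate = missingRate, ldFounders = as.integer(ldFounders),
              ldSwitchRate = ldSwitchRate, seed = as.integer(seed))
  stopifnot(cfg$missingRate >= 0, cfg$missingRate <= 1,
            cfg$divergenceDrift >= 0, cfg$ldSwitchRate > 0,
            cfg$snpDensity > 0, all(cfg$chromLengthBp > 0))
  for (sw in cfg$sweeps) {
    stopifnot(sw$targetFreq > 0.5, sw$targetFreq <= 0.95)
    len <- cfg$chromLengthBp[match(sw$chrom, as.character(seq_len(nChrom)))]
    if (sw$positionBp - sw$spanBp / 2 < 1 ||
        sw$positionBp + sw$spanBp / 2 > len)
      stop("sweep span exceeds chromosome ", sw$chrom)
  }
  for (az in cfg$autozygosity)
    stopifnot(az$phi >= 0, az$phi <= 1)
  structure(cfg, class = "SimConfig")
}

#' Index of the variant nearest a genomic position
#' @param h a [HaplotypeSet-class] or [GenotypeMatrix-class].
#' @param chrom chromosome label.
#' @param posBp position in bp.
#' @return integer variant index (into the full variant set).
#' @export
variantIndex <- function(h, chrom, posBp) {
  j <- which(chromosomes(h) == chrom)
  if (!length(j)) stop("no variants on chromosome ", chrom)
  j[which.min(abs(positions(h)[j] - posBp))]
}

#' Plant a hard selective sweep
#'
#' A fraction `targetFreq` of the haplotypes (optionally restricted to
#' `samples`) is made to carry the ALT allele at the SNP nearest
#' `positionBp` and copies one template haplotype over the whole
#' `spanBp` window around it: the classic hard-sweep signature of a
#' high-frequency derived allele on a long shared haplotype. Haplotypes
#' outside the span are unmodified.
#'
#' @param h a [HaplotypeSet-class] in REF/ALT coding.
#' @param chrom,positionBp focal locus.
#' @param targetFreq target derived (ALT) frequency in (0.5, 0.95].
#' @param spanBp length of the shared carrier haplotype (bp, centered on
#'   the focal SNP).
#' @param samples optional sample ids whose haplotypes participate.
#' @return the modified [HaplotypeSet-class].
#' @export
plantSweep <- function(h, chrom, positionBp, targetFreq, spanBp,
                       samples = NULL) {
  stopifnot(is(h, "HaplotypeSet"), targetFreq > 0.5, targetFreq <= 0.95)
  jChrom <- which(h@chrom == chrom)
  span <- jChrom[h@pos[jChrom] >= positionBp - spanBp / 2 &
                 h@pos[jChrom] <= positionBp + spanBp / 2]
  if (!length(span)) stop("sweep span contains zero SNPs")
  focal <- variantIndex(h, chrom, positionBp)
  if (is.null(samples)) samples <- sampleIDs(h)
  si <- match(samples, sampleIDs(h))
  hrows <- as.vector(rbind(2L * si - 1L, 2L * si))
  nCar <- round(targetFreq * length(hrows))
  carriers <- sample(hrows, nCar)
  H <- h@haplotypes
  template <- H[carriers[1L], span]
  template[span == focal] <- 1L
  H[carriers, span] <- rep(template, each = nCar)
  H[setdiff(hrows, carriers), focal] <- 0L
  HaplotypeSet(H, h@chrom, h@pos, h@refAllele, h@altAllele,
               h@ancestralIsRef)
}

#' Plant autozygous tracts
#'
#' For each targeted individual, contiguous tracts totaling fraction `phi`
#' of the genome have haplotype 2 overwritten by haplotype 1 (both allele
#' copies descend from one parental haplotype), creating true runs of
#' homozygosity with F_ROH = `phi` against the simulated genome length.
#'
#' @param h a [HaplotypeSet-class].
#' @param samples sample ids to make autozygous.
#' @param phi target autozygous genome fraction in [0,1].
#' @param chromLengthBp named (by chromosome) vector of chromosome lengths
#'   in bp; their sum is the genome length `phi` refers to.
#' @param minTractBp,maxTractBp tract length range (bp); the final tract is
#'   trimmed so the per-individual total matches `phi` exactly.
#' @return list: `haplotypes` (modified [HaplotypeSet-class]) and `tracts`
#'   (data.frame sample_id, chrom, start_bp, end_bp).
#' @export
plantAutozygosity <- function(h, samples, phi, chromLengthBp,
                              minTractBp = 2e6, maxTractBp = 8e6) {
  stopifnot(is(h, "HaplotypeSet"), phi >= 0, phi <= 1)
  H <- h@haplotypes
  chromNames <- names(chromLengthBp)
  tracts <- list()
  genomeBp <- sum(chromLengthBp)
  offsets <- cumsum(c(0, as.numeric(chromLengthBp)))
  for (s in samples) {
    if (phi == 0) next
    si <- match(s, sampleIDs(h))
    target <- phi * genomeBp
    # draw tract lengths summing exactly to the target (the last tract is
    # trimmed and may fall below minTractBp), then spread the non-autozygous
    # remainder over the k+1 gaps and lay tracts along the concatenated
    # genome, splitting at chromosome boundaries
    lens <- numeric()
    while (sum(lens) < target) {
      l <- runif(1, min(minTractBp, target), maxTractBp)
      if (sum(lens) + l > target) l <- target - sum(lens)
      lens <- c(lens, l)
    }
    k <- length(lens)
    w <- runif(k + 1L)
    gaps <- (genomeBp - target) * w / sum(w)
    starts <- cumsum(gaps)[seq_len(k)] +
      c(0, cumsum(lens))[seq_len(k)]                         # 0-based, [s,e)
    ends <- starts + lens
    for (t in seq_len(k)) {
      for (ci in seq_along(chromNames)) {
        s0 <- max(starts[t], offsets[ci]); e0 <- min(ends[t], offsets[ci + 1L])
        if (e0 - s0 < 1) next
        a <- floor(s0 - offsets[ci]) + 1   # 1-based inclusive on chromosome
        b <- floor(e0 - offsets[ci])
        ch <- chromNames[ci]
        j <- which(h@chrom == ch & h@pos >= a & h@pos <= b)
        H[2L * si, j] <- H[2L * si - 1L, j]
        tracts[[length(tracts) + 1L]] <- data.frame(
          sample_id = s, chrom = ch, start_bp = a, end_bp = b)
      }
    }
  }
  tracts <- if (length(tracts)) do.call(rbind, tracts) else
    data.frame(sample_id = character(), chrom = character(),
               start_bp = numeric(), end_bp = numeric())
  list(haplotypes = HaplotypeSet(H, h@chrom, h@pos, h@refAllele,
                                 h@altAllele, h@ancestralIsRef),
       tracts = tracts)
}

#' Simulate phased multi-population genotype data
#'
#' Ancestral allele frequencies are drawn from a U-shaped Beta(0.25, 0.25)
#' spectrum (clipped to [0.02, 0.98]); each population's frequencies drift
#' by a truncated normal of SD `divergenceDrift`; haplotypes are built by a
#' founder-copying step (each haplotype copies stretches, of mean length
#' `1/ldSwitchRate` SNPs, from a pool of `ldFounders` population founders
#' drawn site-wise), giving realistic local haplotype sharing; sweeps and
#' autozygous tracts are then planted per the config; finally genotype
#' calls are masked missing at `missingRate`. All randomness flows through
#' `cfg$seed`; identical configs give identical output.
#'
#' @param cfg a [simConfig()] object.
#' @return list: `haplotypes` ([HaplotypeSet-class], complete, phased,
#'   REF/ALT coded), `genotypes` ([GenotypeMatrix-class] with missingness),
#'   `pops` ([PopulationMap-class]), and `truth` (planted parameters:
#'   per-population frequencies, sweep focal indices and carriers implied,
#'   autozygous tracts, genome length, seed).
#' @export
simulatePopulations <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  chromNames <- as.character(seq_len(cfg$nChrom))
  nSnpChrom <- pmax(2L, round(cfg$snpDensity * cfg$chromLengthBp / 1e6))
  chrom <- rep(chromNames, nSnpChrom)
  pos <- unlist(lapply(seq_len(cfg$nChrom), function(k)
    sort(sample.int(cfg$chromLengthBp[k], nSnpChrom[k]))))
  m <- length(pos)
  ref <- sample(c("A", "C", "G", "T"), m, replace = TRUE)
  altOf <- c(A = "G", C = "T", G = "A", T = "C")
  alt <- unname(altOf[ref])

  pAnc <- pmin(pmax(rbeta(m, 0.25, 0.25), 0.02), 0.98)
  popNames <- paste0("POP", seq_len(cfg$nPops))
  pPop <- sapply(popNames, function(pp)
    if (cfg$divergenceDrift > 0)
      truncNorm(pAnc, cfg$divergenceDrift, 0.01, 0.99) else pAnc)

  nS <- cfg$samplesPerPop
  ids <- as.vector(vapply(popNames, function(pp)
    paste0(pp, "_S", sprintf("%02d", seq_len(nS))), character(nS)))
  popv <- setNames(rep(popNames, each = nS), ids)

  H <- matrix(0L, nrow = 2L * length(ids), ncol = m)
  rownames(H) <- paste0(rep(ids, each = 2L), "_", c(1L, 2L))
  for (pi in seq_along(popNames)) {
    founders <- matrix(rbinom(cfg$ldFounders * m, 1L, rep(pPop[, pi],
                                                          each = cfg$ldFounders)),
                       nrow = cfg$ldFounders)
    for (si in seq_len(nS)) {
      row0 <- 2L * ((pi - 1L) * nS + si - 1L)
      for (hh in 1:2) {
        # founder mosaic, switching independently within each chromosome
        seg <- cumsum(runif(m) < cfg$ldSwitchRate |
                        c(TRUE, chrom[-1L] != chrom[-m]))
        fseq <- sample.int(cfg$ldFounders, max(seg), replace = TRUE)
        H[row0 + hh, ] <- founders[cbind(fseq[seg], seq_len(m))]
      }
    }
  }

  h <- HaplotypeSet(H, chrom, pos, ref, alt)

  truthSweeps <- list()
  for (sw in cfg$sweeps) {
    inPop <- if (!is.null(sw$pop)) ids[popv == sw$pop] else ids
    h <- plantSweep(h, sw$chrom, sw$positionBp, sw$targetFreq, sw$spanBp,
                    samples = inPop)
    truthSweeps[[length(truthSweeps) + 1L]] <-
      c(sw, list(focal_index = variantIndex(h, sw$chrom, sw$positionBp)))
  }

  tracts <- data.frame(sample_id = character(), chrom = character(),
                       start_bp = numeric(), end_bp = numeric())
  chromLen <- setNames(cfg$chromLengthBp, chromNames)
  for (az in cfg$autozygosity) {
    res <- plantAutozygosity(h, ids[popv == az$pop], az$phi, chromLen)
    h <- res$haplotypes
    tracts <- rbind(tracts, res$tracts)
  }

  g <- collapseToGenotypes(h)
  calls <- genotypeCalls(g)
  if (cfg$missingRate > 0) {
    mask <- matrix(runif(length(calls)) < cfg$missingRate, nrow(calls))
    calls[mask] <- NA_integer_
    g <- GenotypeMatrix(calls, chrom, pos, ref, alt)
  }

  list(haplotypes = h, genotypes = g, pops = PopulationMap(popv),
       truth = list(pop_freq = pPop, pop_of = popv, sweeps = truthSweeps,
                    autozygous_tracts = tracts,
                    genome_length_bp = sum(cfg$chromLengthBp),
                    seed = cfg$seed))
}

#' Write a toy Ensembl-dialect GTF of genes tiled over chromosomes
#'
#' Deterministic annotation for exercising [loadGTF()] and
#' [intersectRegions()]: a gene every `geneEveryBp`, length `geneLengthBp`.
#' Every 10th gene is written as lincRNA and every 13th lacks a gene_name,
#' so the protein-coding/name filter has something to discard.
#'
#' @param chromLengthBp named vector of chromosome lengths (bp).
#' @param path output GTF path.
#' @param geneEveryBp,geneLengthBp tiling spacing and gene length.
#' @return `path`, invisibly.
#' @export
writeToyGTF <- function(chromLengthBp, path, geneEveryBp = 2e5,
                        geneLengthBp = 5e4) {
  lines <- c("#!genome-build toy-synthetic-1.0")
  k <- 0L
  for (ch in names(chromLengthBp)) {
    starts <- seq(1, chromLengthBp[[ch]] - geneLengthBp, by = geneEveryBp)
    for (s in starts) {
      k <- k + 1L
      biotype <- if (k %% 10L == 0L) "lincRNA" else "protein_coding"
      nameAttr <- if (k %% 13L == 0L) "" else
        sprintf(' gene_name "GENE%04d";', k)
      lines <- c(lines, sprintf(
        '%s\ttoy\tgene\t%d\t%d\t.\t+\t.\tgene_id "SYNG%08d";%s gene_biotype "%s";',
        ch, s, s + geneLengthBp - 1, k, nameAttr, biotype))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
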