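# Genotype I/O: VCF and population-map readers/writers, polarization,
# haplotype/genotype conversion. Coordinates are 1-based inclusive
# throughout; window arithmetic converts to half-open intervals at the
# boundary (see windowScan).

#' Default autosome set
#'
#' Chromosome labels treated as autosomes by default, "1".."30". Chromosome
#' labels are otherwise opaque strings; supply your own set where the
#' assembly differs.
#' @return character vector of chromosome labels.
#' @export
defaultAutosomes <- function() as.character(1:30)

#' Read a VCF into a GenotypeMatrix or HaplotypeSet
#'
#' Multiallelic and non-SNP records are dropped with a logged count.
#' Records must be sorted by chromosome and position. With
#' `phasedRequired = TRUE` every genotype must carry the phased separator
#' `|` and no call may be missing; the result is a [HaplotypeSet-class]
#' coded 0 = REF, 1 = ALT (see [polarize()] for ancestral/derived coding).
#'
#' @param path path to a VCF 4.x file (plain or bgzipped).
#' @param phasedRequired logical; return phased haplotypes instead of
#'   genotype dosages.
#' @return A [GenotypeMatrix-class] or, when `phasedRequired`, a
#'   [HaplotypeSet-class].
#' @export
readVCF <- function(path, phasedRequired = FALSE) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  gt <- v@gt
  samples <- colnames(gt)[-1L]
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]

  snp <- grepl("^[ACGT]$", ref) & grepl("^[ACGT]$", alt)
  if (any(!snp))
    message("readVCF: dropped ", sum(!snp), " multiallelic/non-SNP record(s)")
  chrom <- chrom[snp]; pos <- pos[snp]; ref <- ref[snp]; alt <- alt[snp]
  gtm <- gt[snp, -1L, drop = FALSE]
  if (!length(pos)) stop("no biallelic SNP records in ", path)

  m <- length(pos)
  if (m > 1L) {
    same <- chrom[-1L] == chrom[-m]
    bad <- which(same & pos[-1L] <= pos[-m])
    if (length(bad))
      stop("VCF not sorted: record ", chrom[bad[1L] + 1L], ":",
           pos[bad[1L] + 1L], " follows ", chrom[bad[1L]], ":", pos[bad[1L]])
    if (anyDuplicated(rle(chrom)$values))
      stop("VCF not sorted: chromosome blocks interleaved")
  }

  # genotype field only (GT is the first sub-field by VCF spec); vcfR
  # reports fully missing genotypes as NA
  gtOnly <- matrix(sub(":.*$", "", gtm), nrow = m)

  if (phasedRequired) {
    unph <- is.na(gtOnly) | !grepl("^[01]\\|[01]$", gtOnly)
    if (any(unph)) {
      idx <- which(unph, arr.ind = TRUE)[1L, ]
      stop("phased input required but sample ", samples[idx[2L]],
           " at ", chrom[idx[1L]], ":", pos[idx[1L]],
           " has genotype '", gtOnly[idx[1L], idx[2L]], "'")
    }
    a1 <- matrix(as.integer(substr(gtOnly, 1L, 1L)), nrow = m)
    a2 <- matrix(as.integer(substr(gtOnly, 3L, 3L)), nrow = m)
    H <- matrix(0L, nrow = 2L * length(samples), ncol = m)
    H[seq(1L, nrow(H), 2L), ] <- t(a1)
    H[seq(2L, nrow(H), 2L), ] <- t(a2)
    rownames(H) <- paste0(rep(samples, each = 2L), "_", c(1L, 2L))
    return(HaplotypeSet(H, chrom, pos, ref, alt))
  }

  miss <- is.na(gtOnly) | gtOnly %in% c("./.", ".|.", ".")
  a1 <- suppressWarnings(as.integer(substr(gtOnly, 1L, 1L)))
  a2 <- suppressWarnings(as.integer(substr(gtOnly, 3L, 3L)))
  calls <- a1 + a2
  calls[miss] <- NA_integer_
  if (anyNA(calls[!miss]))
    stop("unparseable genotype field in ", path)
  calls <- matrix(calls, nrow = m)
  calls <- t(calls)
  rownames(calls) <- samples
  GenotypeMatrix(calls, chrom, pos, ref, alt)
}

#' Write a GenotypeMatrix or HaplotypeSet as VCF 4.2
#'
#' Plain-text VCF writer. Genotypes are written `0/1`-style (missing `./.`);
#' haplotypes are written phased (`0|1`). Round-trips through [readVCF()]
#' up to header provenance lines.
#'
#' @param x a [GenotypeMatrix-class] or [HaplotypeSet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeVCF <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##source=popgenscan-", as.character(utils::packageVersion("popgenscan")))),
             con)
  if (is(x, "HaplotypeSet")) {
    ids <- sampleIDs(x)
    H <- x@haplotypes
    i1 <- seq(1L, nrow(H), 2L)
    gtxt <- matrix(paste0(t(H[i1, , drop = FALSE]), "|",
                          t(H[i1 + 1L, , drop = FALSE])),
                   nrow = ncol(H))
  } else {
    ids <- sampleIDs(x)
    g <- t(x@calls)
    gtxt <- matrix(c("0/0", "0/1", "1/1")[g + 1L], nrow = nrow(g))
    gtxt[is.na(g)] <- "./."
  }
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", ids), collapse = "\t"), con)
  body <- cbind(x@chrom, x@pos, ".", x@refAllele, x@altAllele, ".", "PASS",
                ".", "GT", gtxt)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read / write a sample-to-population map (2-column TSV)
#'
#' @param path TSV with columns sample_id, population (no header required;
#'   a header line `sample_id<TAB>population` is tolerated). Lines starting
#'   with `#` are ignored.
#' @return A [PopulationMap-class].
#' @export
readPopulationMap <- function(path) {
  d <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                  colClasses = "character")
  if (nrow(d) && identical(tolower(d[1L, 1L]), "sample_id"))
    d <- d[-1L, , drop = FALSE]
  PopulationMap(d)
}

#' @rdname readPopulationMap
#' @param pops a [PopulationMap-class] to write.
#' @export
writePopulationMap <- function(pops, path) {
  write.table(data.frame(sample_id = names(pops@pop), population = pops@pop),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Polarize haplotypes into ancestral (0) / derived (1) coding
#'
#' iHS requires each site to be polarized. Two conventions are provided:
#' `ref_ancestral` keeps the VCF REF allele as ancestral (coding unchanged),
#' `major_ancestral` (default) takes the sample-major allele as ancestral,
#' flipping sites where the ALT allele is the majority. The choice is
#' recorded per site in `ancestralIsRef`.
#'
#' @param h a [HaplotypeSet-class].
#' @param mode `"major_ancestral"` or `"ref_ancestral"`.
#' @return A [HaplotypeSet-class] with 0 = ancestral, 1 = derived.
#' @export
polarize <- function(h, mode = c("major_ancestral", "ref_ancestral")) {
  mode <- match.arg(mode)
  stopifnot(is(h, "HaplotypeSet"))
  H <- h@haplotypes
  # restore REF/ALT coding first so polarize() is not state-dependent
  H[, !h@ancestralIsRef] <- 1L - H[, !h@ancestralIsRef, drop = FALSE]
  if (mode == "ref_ancestral") {
    flip <- rep(FALSE, ncol(H))
  } else {
    altFreq <- colMeans(H)
    flip <- altFreq > 0.5
  }
  H[, flip] <- 1L - H[, flip, drop = FALSE]
  HaplotypeSet(H, h@chrom, h@pos, h@refAllele, h@altAllele,
               ancestralIsRef = !flip)
}

#' Collapse phased haplotypes to genotype dosages
#'
#' Sums each sample's two haplotypes in the VCF REF/ALT coding (undoing any
#' polarization), so the result matches the source [GenotypeMatrix-class]
#' at every non-missing entry.
#'
#' @param h a [HaplotypeSet-class].
#' @return A [GenotypeMatrix-class] with no missing calls.
#' @export
collapseToGenotypes <- function(h) {
  stopifnot(is(h, "HaplotypeSet"))
  H <- h@haplotypes
  H[, !h@ancestralIsRef] <- 1L - H[, !h@ancestralIsRef, drop = FALSE]
  i1 <- seq(1L, nrow(H), 2L)
  calls <- H[i1, , drop = FALSE] + H[i1 + 1L, , drop = FALSE]
  rownames(calls) <- sampleIDs(h)
  GenotypeMatrix(calls, h@chrom, h@pos, h@refAllele, h@altAllele)
}

#' Per-site derived allele frequency of a polarized HaplotypeSet
#' @param h a [HaplotypeSet-class] (polarized; 1 = derived).
#' @return numeric vector of derived-allele frequencies.
#' @export
derivedAlleleFrequency <- function(h) {
  stopifnot(is(h, "HaplotypeSet"))
  colMeans(h@haplotypes)
}

# Write a result table as TSV with '# key=value' parameter header lines.
writeResultTSV <- function(d, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(params))
    writeLines(paste0("# ", k, "=", paste(params[[k]], collapse = ",")), con)
  suppressWarnings(
    write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE))
  invisible(path)
}
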