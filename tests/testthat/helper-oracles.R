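# Independent oracles: brute-force re-derivations of each statistic from
# its definition, kept free of the implementation's code paths.

# ---- EHH / iHH / iHS oracle (direct pair enumeration, naive trapezoid) ----

oracleEHHSide <- function(H, core, allele, pos, limit, maxGap, dir) {
  carriers <- which(H[, core] == allele)
  n <- length(carriers)
  if (n < 2L)
    return(list(idx = integer(), ehh = numeric(), ihh = 0, truncated = TRUE))
  pr <- t(combn(carriers, 2L))
  alive <- rep(TRUE, nrow(pr))          # pair still identical over [core..x]
  idx <- integer(); ehhv <- numeric(); area <- 0
  prevPos <- pos[core]; prevEhh <- 1; truncated <- FALSE
  j <- core + dir
  repeat {
    if (j < 1L || j > ncol(H)) { truncated <- TRUE; break }
    gap <- abs(pos[j] - prevPos)
    if (gap > maxGap) { truncated <- TRUE; break }
    alive <- alive & (H[pr[, 1L], j] == H[pr[, 2L], j])
    e <- sum(alive) / nrow(pr)
    idx <- c(idx, j); ehhv <- c(ehhv, e)
    area <- area + gap * 0.5 * (prevEhh + e)
    if (e < limit) break
    prevEhh <- e; prevPos <- pos[j]; j <- j + dir
  }
  list(idx = idx, ehh = ehhv, ihh = area, truncated = truncated)
}

oracleIHS <- function(H, pos, limit = 0.05, maxGap = 200000,
                      minFreq = 0.05) {
  m <- ncol(H)
  out <- data.frame(freq_derived = colMeans(H), ihh_a = NA_real_,
                    ihh_d = NA_real_, ln_ratio = NA_real_)
  for (j in seq_len(m)) {
    p <- out$freq_derived[j]
    if (p < minFreq || p > 1 - minFreq) next
    if (sum(H[, j]) < 2L || sum(1L - H[, j]) < 2L) next
    sides <- list(
      oracleEHHSide(H, j, 0L, pos, limit, maxGap, -1L),
      oracleEHHSide(H, j, 0L, pos, limit, maxGap, +1L),
      oracleEHHSide(H, j, 1L, pos, limit, maxGap, -1L),
      oracleEHHSide(H, j, 1L, pos, limit, maxGap, +1L))
    if (any(vapply(sides, `[[`, TRUE, "truncated"))) next
    out$ihh_a[j] <- sides[[1L]]$ihh + sides[[2L]]$ihh
    out$ihh_d[j] <- sides[[3L]]$ihh + sides[[4L]]$ihh
    if (out$ihh_a[j] > 0 && out$ihh_d[j] > 0)
      out$ln_ratio[j] <- log(out$ihh_a[j] / out$ihh_d[j])
  }
  out
}

# ---- ROH oracle (windowed qualification enumerated from the definition) ----

oracleROHOneSample <- function(v, pos, params) {
  L <- length(v)
  w <- params@windowSnp
  if (L < w) return(NULL)
  nW <- L - w + 1L
  homWin <- logical(nW)
  for (k in seq_len(nW)) {
    win <- v[k:(k + w - 1L)]
    homWin[k] <- sum(win == 1L, na.rm = TRUE) <= params@windowHet &&
      sum(is.na(win)) <= params@windowMissing
  }
  hit <- logical(L)
  for (i in seq_len(L)) {
    ks <- max(1L, i - w + 1L):min(i, nW)
    hit[i] <- mean(homWin[ks]) >= params@windowThreshold
  }
  segs <- NULL
  i <- 1L
  while (i <= L) {
    if (!hit[i]) { i <- i + 1L; next }
    j <- i
    while (j < L && hit[j + 1L] &&
           pos[j + 1L] - pos[j] <= params@maxGapKb * 1000) j <- j + 1L
    len <- pos[j] - pos[i] + 1L
    n <- j - i + 1L
    if (len >= params@minKb * 1000 && n >= params@minSnp &&
        len / n <= params@maxDensityKbPerSnp * 1000)
      segs <- rbind(segs, data.frame(start_bp = pos[i], end_bp = pos[j],
                                     n_snps = n, length_bp = len))
    i <- j + 1L
  }
  segs
}

oracleROH <- function(g, params) {
  out <- NULL
  for (ch in unique(chromosomes(g))) {
    j <- which(chromosomes(g) == ch)
    for (s in sampleIDs(g)) {
      segs <- oracleROHOneSample(genotypeCalls(g)[s, j], positions(g)[j],
                                 params)
      if (!is.null(segs))
        out <- rbind(out, cbind(data.frame(sample_id = s, chrom = ch), segs))
    }
  }
  out
}

# ---- naive interval intersection -----------------------------------------

oracleIntersect <- function(regions, genes) {
  hits <- NULL
  for (i in seq_len(nrow(regions))) for (k in seq_len(nrow(genes))) {
    if (regions$chrom[i] == genes$chrom[k] &&
        regions$start_bp[i] <= genes$end_bp[k] &&
        regions$end_bp[i] >= genes$start_bp[k])
      hits <- rbind(hits, data.frame(region_id = i,
                                     gene_id = genes$gene_id[k]))
  }
  hits
}

# ---- misc helpers ---------------------------------------------------------

# mean silhouette along one coordinate for a two-group labelling
silhouette1d <- function(x, grp) {
  s <- vapply(seq_along(x), function(i) {
    own <- x[grp == grp[i]]; other <- x[grp != grp[i]]
    a <- if (length(own) > 1L) sum(abs(x[i] - own)) / (length(own) - 1L) else 0
    b <- mean(abs(x[i] - other))
    (b - a) / max(a, b)
  }, 0)
  mean(s)
}

# random GenotypeMatrix for property tests
randomGenotypes <- function(n, m, missRate = 0.02, nChrom = 1L) {
  calls <- matrix(sample(0:2, n * m, replace = TRUE), n)
  calls[matrix(runif(n * m) < missRate, n)] <- NA_integer_
  rownames(calls) <- sprintf("S%03d", seq_len(n))
  chrom <- sort(rep_len(as.character(seq_len(nChrom)), m))
  pos <- unlist(lapply(split(seq_len(m), chrom), function(j)
    sort(sample.int(1e6, length(j)))), use.names = FALSE)
  GenotypeMatrix(calls, chrom, pos, rep("A", m), rep("G", m))
}

# write a VCF from explicit body lines (for malformed/edge-case fixtures)
writeVcfLines <- function(bodyLines, samples, path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    bodyLines), path)
  path
}
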