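# Fixture: a chromosome whose background is heterozygous everywhere with a
# planted homozygous tract, so qualification is fully determined by the
# window definition.
tractGenotypes <- function(nBefore, nTract, nAfter, spacingBp,
                           hetVal = 1L, homVal = 0L) {
  v <- c(rep(hetVal, nBefore), rep(homVal, nTract), rep(hetVal, nAfter))
  m <- length(v)
  calls <- matrix(v, nrow = 1, dimnames = list("S01", NULL))
  GenotypeMatrix(calls, rep("1", m), as.integer(seq_len(m)) * spacingBp,
                 rep("A", m), rep("G", m))
}

test_that("an all-heterozygous individual yields no segments", {
  g <- tractGenotypes(0, 0, 400, 8000L)  # 400 het SNPs
  expect_identical(nrow(detectROH(g)), 0L)
})

test_that("a 150-SNP homozygous tract at 8 kb spacing gives one short-class segment", {
  g <- tractGenotypes(150, 150, 150, 8000L)
  segs <- detectROH(g)
  expect_equal(nrow(segs), 1L)
  expect_equal(as.character(segs$class), "<2")
  expect_gte(segs$n_snps, 100L)
  expect_gte(segs$length_bp, 1e6)
  # and the same tract squeezed under 1 Mb fails the length threshold
  g2 <- tractGenotypes(150, 150, 150, 6000L)   # 149 * 6 kb = 894 kb span
  expect_identical(nrow(detectROH(g2)), 0L)
})

test_that("detected segments agree with the brute-force window-definition oracle", {
  params <- ROHParams(minKb = 300, windowSnp = 25L, windowHet = 1L,
                      windowMissing = 2L, windowThreshold = 0.05,
                      minSnp = 25L, maxDensityKbPerSnp = 100, maxGapKb = 250)
  set.seed(17)
  for (rep in 1:6) {
    n <- 4L; m <- 1500L
    # block structure: alternate stretches of near-homozygosity and noise
    calls <- matrix(NA_integer_, n, m)
    for (i in seq_len(n)) {
      state <- sample(c(0L, 1L), 30, replace = TRUE)
      lens <- as.vector(rmultinom(1, m, rep(1, 30)))
      v <- rep(state, lens)[seq_len(m)]
      hom <- sample(c(0L, 2L), m, replace = TRUE)
      het <- sample(0:2, m, replace = TRUE, prob = c(0.2, 0.6, 0.2))
      calls[i, ] <- ifelse(v == 0L, hom, het)
      calls[i, runif(m) < 0.01] <- NA_integer_
    }
    rownames(calls) <- sprintf("S%02d", seq_len(n))
    pos <- sort(sample.int(12e6, m))
    g <- GenotypeMatrix(calls, rep("1", m), pos, rep("A", m), rep("C", m))
    got <- detectROH(g, params)
    want <- oracleROH(g, params)
    if (is.null(want)) {
      expect_identical(nrow(got), 0L)
    } else {
      got <- got[order(got$sample_id, got$start_bp), ]
      want <- want[order(want$sample_id, want$start_bp), ]
      expect_equal(got[, c("sample_id", "start_bp", "end_bp", "n_snps",
                           "length_bp")],
                   want[, c("sample_id", "start_bp", "end_bp", "n_snps",
                            "length_bp")],
                   ignore_attr = TRUE)
    }
  }
})

test_that("segments never overlap, pass all retention filters, and shrink with minKb", {
  cfg <- simConfig(nPops = 1, samplesPerPop = 10, nChrom = 2,
                   chromLengthBp = 25e6, snpDensity = 200, seed = 55,
                   autozygosity = list(list(pop = "POP1", phi = 0.35)))
  sim <- simulatePopulations(cfg)
  p <- ROHParams()
  segs <- detectROH(sim$genotypes, p)
  expect_gt(nrow(segs), 0L)
  expect_true(all(segs$length_bp == segs$end_bp - segs$start_bp + 1))
  expect_true(all(segs$length_bp >= p@minKb * 1000))
  expect_true(all(segs$n_snps >= p@minSnp))
  expect_true(all(segs$length_bp / segs$n_snps <= p@maxDensityKbPerSnp * 1000))
  for (key in split(segs, paste(segs$sample_id, segs$chrom))) {
    if (nrow(key) < 2) next
    key <- key[order(key$start_bp), ]
    expect_true(all(key$start_bp[-1] > key$end_bp[-nrow(key)]))
  }
  # monotonicity in the length threshold
  strict <- detectROH(sim$genotypes, ROHParams(minKb = 4000))
  expect_lte(nrow(strict), nrow(segs))
  expect_true(all(paste(strict$sample_id, strict$start_bp) %in%
                  paste(segs$sample_id, segs$start_bp)))
})

test_that("chromosomes with fewer SNPs than the window yield no calls, with a log", {
  g <- tractGenotypes(0, 50, 0, 10000L)    # 50 hom SNPs < windowSnp = 100
  expect_message(segs <- detectROH(g), "skipped")
  expect_identical(nrow(segs), 0L)
})

test_that("class binning is half-open and the summary does its arithmetic", {
  expect_equal(as.character(rohClass(c(1.5e6, 2e6, 3.9999e6, 4e6, 16e6, 17e6))),
               c("<2", "2-4", "2-4", "4-8", ">16", ">16"))
  pm <- PopulationMap(c(S1 = "P1"))
  segs <- data.frame(sample_id = c("S1", "S1"), chrom = "1",
                     start_bp = c(1, 4e6), end_bp = c(1.5e6, 7e6 - 1),
                     n_snps = c(200L, 350L),
                     length_bp = c(1.5e6, 3.0e6))
  segs$class <- rohClass(segs$length_bp)
  s <- summarizeROH(segs, pm)
  expect_equal(s$class_counts["P1", "<2"], 1)
  expect_equal(s$class_counts["P1", "2-4"], 1)
  expect_equal(s$class_counts["P1", "Total"], 2)
  expect_equal(s$summary$mean_length_mb, 2.25)
  expect_equal(s$summary$mean_sum_mb_per_individual, 4.5)
  expect_equal(s$summary$mean_n_per_individual, 2)
  # empty input: all-zero table
  s0 <- summarizeROH(segs[0, ], pm)
  expect_true(all(s0$class_counts == 0))
})
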