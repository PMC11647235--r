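mkHaps <- function(H, posBp, chrom = rep("1", ncol(H))) {
  stopifnot(nrow(H) %% 2 == 0)
  rownames(H) <- paste0(rep(sprintf("S%02d", seq_len(nrow(H) / 2)),
                            each = 2), "_", 1:2)
  HaplotypeSet(H, chrom, as.integer(posBp), rep("A", ncol(H)),
               rep("G", ncol(H)))
}

test_that("EHH pair-counting matches the defining hand examples", {
  # 4 derived carriers + 2 ancestral at the core (col 2)
  core <- 2L
  base <- cbind(c(0L,0L,0L,0L,0L,0L), c(1L,1L,1L,1L,0L,0L),
                c(0L,0L,0L,0L,0L,0L))
  pos <- c(1000, 2000, 3000)

  h1 <- mkHaps(base, pos)                       # carriers identical
  p1 <- ehh(h1, core, "derived")
  expect_equal(p1$right$ehh, 1)
  expect_equal(p1$left$ehh, 1)

  split2 <- base; split2[, 3] <- c(0L,0L,1L,1L,0L,0L)  # two identical pairs
  p2 <- ehh(mkHaps(split2, pos), core, "derived")
  expect_equal(p2$right$ehh, (1 + 1) / choose(4, 2))   # = 1/3

  # all four carriers distinct by col 3 + col 1 patterns: EHH right = 0 needs
  # 4 distinct values in one column -> impossible for binary; use two steps
  dist4 <- base
  dist4[, 3] <- c(0L,1L,0L,1L,0L,0L)
  p3 <- ehh(mkHaps(dist4, pos), core, "derived")
  expect_equal(p3$right$ehh[1], 1/3)            # {1,3} and {2,4} pairs

  expect_error(ehh(mkHaps(base, pos), 1L, "derived"),
               "undefined|carried")  # core col 1 has zero derived carriers
})

test_that("EHH profiles are non-increasing and start at 1", {
  sim <- simulatePopulations(simConfig(nPops = 1, samplesPerPop = 10,
                                       nChrom = 1, chromLengthBp = 2e6,
                                       snpDensity = 100, seed = 77))
  h <- polarize(sim$haplotypes)
  set.seed(1)
  for (core in sample(which(derivedAlleleFrequency(h) > 0.2 &
                            derivedAlleleFrequency(h) < 0.8), 15)) {
    for (al in c("derived", "ancestral")) {
      p <- ehh(h, core, al)
      expect_true(all(diff(c(1, p$right$ehh)) <= 1e-12))
      expect_true(all(diff(c(1, p$left$ehh)) <= 1e-12))
      expect_true(all(p$right$ehh >= 0 & p$right$ehh <= 1))
    }
  }
})

test_that("iHH integrates the trapezoid examples", {
  prof <- structure(list(
    chrom = "1", core_pos = 1, allele = "derived", n_carriers = 4,
    limit = 0.05,
    left = data.frame(pos = numeric(), ehh = numeric()),
    right = data.frame(pos = c(10001, 20001), ehh = c(0.5, 0.05)),
    left_truncated = FALSE, right_truncated = FALSE,
    left_ihh = 0, right_ihh = 10250), class = "EHHProfile")
  expect_equal(ihh(prof), 10250)                 # 7500 + 2750

  rect <- prof
  rect$right <- data.frame(pos = 50001, ehh = 1)
  expect_equal(ihh(rect), 50000)                 # constant EHH = 1

  sym <- prof
  sym$left <- data.frame(pos = c(-9999, -19999), ehh = c(0.5, 0.05))
  expect_equal(ihh(sym), 2 * 10250)              # symmetric profiles add
})

test_that("EHH, iHH and unstandardized iHS match the pair-enumeration oracle", {
  set.seed(23)
  for (rep in 1:25) {
    nHap <- 2 * sample(4:10, 1)
    m <- sample(20:50, 1)
    p <- runif(m, 0.1, 0.9)
    H <- matrix(rbinom(nHap * m, 1, rep(p, each = nHap)), nHap)
    pos <- sort(sample.int(5e5, m))
    h <- mkHaps(H, pos)
    got <- suppressMessages(ihsScan(h))
    want <- oracleIHS(H, pos)
    expect_equal(got$ihh_a, want$ihh_a, tolerance = 1e-12)
    expect_equal(got$ihh_d, want$ihh_d, tolerance = 1e-12)
    expect_equal(got$ln_ratio, want$ln_ratio, tolerance = 1e-12)
    # spot-check EHH values through the profile interface
    j <- which(!is.na(want$ln_ratio))
    if (length(j)) {
      core <- j[1]
      pr <- ehh(h, core, "derived")
      or <- oracleEHHSide(H, core, 1L, pos, 0.05, 200000, +1L)
      expect_equal(pr$right$ehh, or$ehh, tolerance = 1e-12)
      expect_equal(pr$right_ihh, or$ihh, tolerance = 1e-12)
    }
  }
})

test_that("piHS transform matches the normal CDF and is symmetric", {
  expect_equal(pihs(0), 0)
  expect_equal(pihs(1.96), -log10(1 - 2 * abs(pnorm(1.96) - 0.5)))
  expect_equal(pihs(1.96), 1.301, tolerance = 1e-3)
  x <- c(0.3, 1.1, 2.7, 4.2)
  expect_equal(pihs(-x), pihs(x))
  expect_true(all(pihs(rnorm(100)) >= 0))
})

test_that("standardization centres and scales every frequency bin", {
  set.seed(41)
  scan <- data.frame(chrom = "1", pos = sort(sample.int(5e7, 4000)),
                     freq_derived = runif(4000, 0.05, 0.95),
                     ln_ratio = rnorm(4000, 0.3, 0.8))
  scan$ln_ratio[sample(4000, 50)] <- NA
  std <- suppressMessages(standardizeIHS(scan))
  ok <- !is.na(std$ihs)
  for (b in unique(std$freq_bin[ok])) {
    v <- std$ihs[ok & std$freq_bin == b]
    expect_lt(abs(mean(v)), 1e-9)
    expect_lt(abs(sd(v) - 1), 1e-9)
  }
  # an under-filled bin merges with its nearest occupied neighbour
  scan2 <- scan[scan$freq_derived > 0.3, ]
  tiny <- data.frame(chrom = "1", pos = 11:15, freq_derived = 0.07,
                     ln_ratio = rnorm(5))
  expect_message(std2 <- standardizeIHS(rbind(tiny, scan2)), "merging")
  expect_equal(length(unique(std2$freq_bin[std2$freq_derived == 0.07])), 1L)
  # constant ln_ratio in a bin is an error naming the bin
  scan3 <- data.frame(chrom = "1", pos = 1:40, freq_derived = 0.52,
                      ln_ratio = 1)
  expect_error(standardizeIHS(scan3), "bin")
})

test_that("window tiling, top-fraction selection and merging follow the contract", {
  # 2.2 Mb chromosome, SNPs throughout -> windows at 0, 0.5, 1.0, 1.5 Mb
  set.seed(2)
  scan <- data.frame(chrom = "1", pos = sort(sample.int(2.2e6, 500)),
                     freq_derived = 0.5, ln_ratio = NA)
  scan$ihs <- rnorm(500); scan$pihs <- pihs(scan$ihs)
  ws <- windowScan(scan)
  expect_equal(nrow(ws$windows), 4L)
  expect_equal(ws$windows$start_bp, c(0, 0.5e6, 1e6, 1.5e6) + 1)

  # 400 non-empty windows, top 1% -> ceil(0.01 * 400) = 4 significant.
  # SNPs sit in one block per Mb, so interior blocks feed two overlapping
  # windows (tied statistics) and the first block of a chromosome feeds one.
  mkBlock <- function(chrom, mb, stat)
    data.frame(chrom = chrom, pos = mb * 1e6 + c(1e5, 3e5),
               ihs = stat, pihs = pihs(stat))
  blocks <- rbind(
    do.call(rbind, lapply(0:99, function(k)
      mkBlock("1", k, 0.5 + k * 0.01))),
    do.call(rbind, lapply(0:99, function(k)
      mkBlock("2", k, if (k == 50) 8 else 1 + k * 0.01))),
    mkBlock("3", 0, 10), mkBlock("4", 0, 9),
    mkBlock("5", 0, 0.2), mkBlock("6", 0, 0.3))
  ws2 <- windowScan(blocks)
  # blocks at the two ends of a chromosome feed one window each, interior
  # blocks feed two: 198 + 198 + 4 singleton chromosomes
  expect_equal(nrow(ws2$windows), 400L)
  expect_equal(nrow(ws2$significant), 4L)
  expect_setequal(round(ws2$significant$max_abs_ihs), c(10, 9, 8, 8))
  expect_true(all(ws2$significant$max_abs_ihs >= ws2$threshold))

  # overlapping significant windows merge into one region
  scan3 <- data.frame(chrom = "1", pos = seq(5e4, 1e7, by = 5e4))
  scan3$ihs <- 0.1
  scan3$ihs[scan3$pos > 1.5e6 & scan3$pos < 2.0e6] <- 6   # hot stretch
  scan3$pihs <- pihs(scan3$ihs)
  ws3 <- windowScan(scan3, topFraction = 0.06)
  expect_true(any(ws3$significant$start_bp == 1e6 + 1) &&
              any(ws3$significant$start_bp == 1.5e6 + 1))
  expect_equal(nrow(ws3$regions), 1L)
  expect_equal(ws3$regions$start_bp, 1e6 + 1)
  expect_equal(ws3$regions$end_bp, 2.5e6)
})

test_that("per-SNP significance respects the piHS threshold", {
  scan <- data.frame(chrom = "1", pos = seq(1e5, 5e6, by = 1e5))
  scan$ihs <- 0.2; scan$ihs[c(3, 17)] <- c(5.2, -6.1)
  scan$pihs <- pihs(scan$ihs)
  ws <- windowScan(scan, topFraction = 0.05, snpThreshold = 4)
  expect_equal(ws$snp_significant$pos, scan$pos[c(3, 17)])
})
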