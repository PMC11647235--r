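mkGeno1 <- function(calls, chrom = NULL) {
  m <- ncol(calls)
  rownames(calls) <- sprintf("S%02d", seq_len(nrow(calls)))
  GenotypeMatrix(calls, if (is.null(chrom)) rep("1", m) else chrom,
                 seq_len(m) * 1000L, rep("A", m), rep("G", m))
}

test_that("diversity indices match hand counts and symmetric cases", {
  # one population, 4 samples, 3 sites:
  #  site 1: genotypes {0,1,1,2} -> Ho = 0.5, p = 0.5, He = 0.5, MAF = 0.5
  #  site 2: monomorphic          -> Ho = He = MAF = 0
  #  site 3: {2,2,1,1}            -> Ho = 0.5, p = 0.75, He = 0.375, MAF = .25
  calls <- cbind(c(0L,1L,1L,2L), rep(0L, 4), c(2L,2L,1L,1L))
  g <- mkGeno1(calls)
  pm <- PopulationMap(setNames(rep("P1", 4), sampleIDs(g)))
  d <- diversityTable(g, pm)
  expect_equal(d$ho_mean, mean(c(0.5, 0, 0.5)))
  expect_equal(d$he_mean, mean(c(0.5, 0, 0.375)))
  expect_equal(d$maf_mean, mean(c(0.5, 0, 0.25)))
  expect_equal(d$ho_median, 0.5)
  expect_equal(d$he_median, 0.375)
  expect_true(all(d$he_mean <= 0.5))
})

test_that("He equals brute-force expected heterozygosity at every site", {
  set.seed(8)
  g <- randomGenotypes(30, 80, missRate = 0.05)
  pm <- PopulationMap(setNames(rep(c("A", "B"), 15), sampleIDs(g)))
  d <- diversityTable(g, pm)
  for (pp in c("A", "B")) {
    calls <- genotypeCalls(g)[populations(pm)[sampleIDs(g)] == pp, ]
    he <- apply(calls, 2, function(v) {
      v <- v[!is.na(v)]
      p <- sum(v) / (2 * length(v))
      2 * p * (1 - p)
    })
    expect_equal(d$he_mean[d$population == pp], mean(he), tolerance = 1e-12)
    expect_equal(d$maf_mean[d$population == pp],
                 mean(apply(calls, 2, function(v) {
                   v <- v[!is.na(v)]
                   p <- sum(v) / (2 * length(v)); min(p, 1 - p)
                 })), tolerance = 1e-12)
  }
})

test_that("diversity errors on a population with no informative calls", {
  calls <- rbind(c(0L, 1L), c(NA_integer_, NA_integer_))
  g <- mkGeno1(calls)
  pm <- PopulationMap(setNames(c("A", "B"), sampleIDs(g)))
  expect_error(diversityTable(g, pm), "population B")
})

test_that("fHom matches its defining identity and an independent oracle", {
  expect_equal(fHomIdentity(80, 60, 100), 0.5)
  expect_equal(fHomIdentity(60, 60, 100), 0)       # O = E
  expect_equal(fHomIdentity(100, 60, 100), 1)      # O = L

  set.seed(31)
  g <- randomGenotypes(20, 60, missRate = 0.05)
  fh <- suppressMessages(fHom(g))
  calls <- genotypeCalls(g)
  nInf <- colSums(!is.na(calls))
  use <- nInf > 1L
  pj <- colSums(calls[, use], na.rm = TRUE) / (2 * nInf[use])
  ej <- 1 - 2 * pj * (1 - pj) * 2 * nInf[use] / (2 * nInf[use] - 1)
  for (s in sampleIDs(g)) {
    v <- calls[s, use]
    obs <- !is.na(v)
    O <- sum(v[obs] %in% c(0L, 2L))
    E <- sum(ej[obs]); L <- sum(obs)
    expect_equal(unname(fh[s]), (O - E) / (L - E), tolerance = 1e-12)
  }
  # fully homozygous sample has F_HOM = 1 exactly
  calls2 <- calls
  calls2[1, ] <- ifelse(is.na(calls2[1, ]), NA_integer_, 0L)
  fh2 <- suppressMessages(fHom(mkGeno1(calls2)))
  expect_equal(unname(fh2[1]), 1)
})

test_that("fRoh is the summed-length ratio with clipping and error handling", {
  roh <- data.frame(sample_id = c("a", "a", "b"),
                    chrom = "1",
                    start_bp = c(1, 100, 1),
                    end_bp = c(30, 140, 50),
                    length_bp = c(25e6, 25.05e6, 5e6))
  f <- fRoh(roh, genomeLengthBp = 100100000, samples = c("a", "b", "c"))
  expect_equal(unname(f["a"]), 50050000 / 100100000)  # = 0.5
  expect_equal(unname(f["b"]), 5e6 / 100100000)
  expect_equal(unname(f["c"]), 0)                     # no ROH -> 0
  full <- data.frame(sample_id = "a", length_bp = 100100000)
  expect_equal(unname(fRoh(full, 100100000)["a"]), 1) # exact full coverage
  expect_warning(fc <- fRoh(data.frame(sample_id = "a", length_bp = 2e8),
                            1e8), "clipped")
  expect_equal(unname(fc["a"]), 1)
  expect_error(fRoh(data.frame(sample_id = "a", length_bp = -5), 1e8),
               "negative")
})

test_that("planted autozygosity is recovered by detectROH + fRoh", {
  phi <- 0.4
  cfg <- simConfig(nPops = 1, samplesPerPop = 12, nChrom = 2,
                   chromLengthBp = 25e6, snpDensity = 200, seed = 99,
                   missingRate = 0.002,
                   autozygosity = list(list(pop = "POP1", phi = phi)))
  sim <- simulatePopulations(cfg)
  segs <- detectROH(sim$genotypes)
  f <- fRoh(segs, sim$truth$genome_length_bp,
            samples = sampleIDs(sim$genotypes))
  expect_lt(abs(mean(f) - phi), 0.02)
  # truth tracts themselves integrate to phi
  tr <- sim$truth$autozygous_tracts
  perSample <- tapply(tr$end_bp - tr$start_bp + 1, tr$sample_id, sum)
  expect_equal(as.numeric(perSample) / sim$truth$genome_length_bp,
               rep(phi, 12), tolerance = 1e-6)
})

test_that("F_HOM is centred at zero in a Hardy-Weinberg population", {
  sim <- simulatePopulations(simConfig(nPops = 1, samplesPerPop = 50,
                                       nChrom = 1, chromLengthBp = 20e6,
                                       snpDensity = 150, seed = 12,
                                       missingRate = 0.01))
  fh <- fHom(sim$genotypes)
  expect_lt(abs(mean(fh)), 0.02)
})

test_that("inbreedingTable aggregates per population", {
  sim <- simulatePopulations(simConfig(nPops = 2, samplesPerPop = 6,
                                       nChrom = 1, chromLengthBp = 25e6,
                                       snpDensity = 150, seed = 4,
                                       autozygosity = list(
                                         list(pop = "POP2", phi = 0.3))))
  segs <- detectROH(sim$genotypes)
  tb <- inbreedingTable(sim$genotypes, sim$pops, segs,
                        sim$truth$genome_length_bp)
  expect_equal(nrow(tb$per_sample), 12L)
  expect_equal(sort(tb$per_population$population), c("POP1", "POP2"))
  expect_gt(tb$per_population$f_roh_mean[tb$per_population$population == "POP2"],
            tb$per_population$f_roh_mean[tb$per_population$population == "POP1"])
  expect_true(all(tb$per_sample$f_roh >= 0 & tb$per_sample$f_roh <= 1))
})
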