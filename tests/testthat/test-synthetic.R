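test_that("the generator is seed-deterministic down to the written VCF", {
  cfg <- simConfig(nPops = 2, samplesPerPop = 6, nChrom = 2,
                   chromLengthBp = 1e6, snpDensity = 100,
                   missingRate = 0.02, seed = 123,
                   sweeps = list(list(pop = "POP1", chrom = "1",
                                      positionBp = 5e5, targetFreq = 0.8,
                                      spanBp = 2e5)))
  f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
  writeVCF(simulatePopulations(cfg)$genotypes, f1)
  writeVCF(simulatePopulations(cfg)$genotypes, f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed changes the data
  cfg2 <- cfg; cfg2$seed <- 124L
  f3 <- tempfile(fileext = ".vcf")
  writeVCF(simulatePopulations(cfg2)$genotypes, f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("generator outputs satisfy the container invariants", {
  sim <- simulatePopulations(simConfig(nPops = 3, samplesPerPop = 5,
                                       nChrom = 2, chromLengthBp = 8e5,
                                       snpDensity = 120, seed = 2,
                                       missingRate = 0.05))
  expect_true(validObject(sim$haplotypes))
  expect_true(validObject(sim$genotypes))
  expect_true(validObject(sim$pops))
  expect_identical(sampleIDs(sim$genotypes), sampleIDs(sim$haplotypes))
  expect_identical(sort(sampleIDs(sim$pops)), sort(sampleIDs(sim$genotypes)))
})

test_that("missingness hits its target rate within binomial tolerance", {
  sim <- simulatePopulations(simConfig(nPops = 1, samplesPerPop = 25,
                                       nChrom = 2, chromLengthBp = 20e6,
                                       snpDensity = 100, seed = 9,
                                       missingRate = 0.05))
  calls <- genotypeCalls(sim$genotypes)
  expect_gte(length(calls), 1e5)
  expect_lt(abs(mean(is.na(calls)) - 0.05), 0.005)
})

test_that("zero drift leaves no systematic between-population differentiation", {
  sim <- simulatePopulations(simConfig(nPops = 3, samplesPerPop = 20,
                                       nChrom = 1, chromLengthBp = 5e6,
                                       snpDensity = 100, seed = 10,
                                       divergenceDrift = 0, missingRate = 0))
  pv <- populations(sim$pops)[sampleIDs(sim$genotypes)]
  calls <- genotypeCalls(sim$genotypes)
  pf <- sapply(unique(pv), function(pp)
    colMeans(calls[pv == pp, ]) / 2)
  # mean between-population variance at a site is at the binomial
  # sampling level (pq/2n per pop plus founder-pool noise), far below
  # what the default drift SD of 0.2 produces
  expect_lt(mean(apply(pf, 1, var)), 0.02)
  simD <- simulatePopulations(simConfig(nPops = 3, samplesPerPop = 20,
                                        nChrom = 1, chromLengthBp = 5e6,
                                        snpDensity = 100, seed = 10,
                                        missingRate = 0))
  callsD <- genotypeCalls(simD$genotypes)
  pfD <- sapply(unique(pv), function(pp) colMeans(callsD[pv == pp, ]) / 2)
  expect_gt(mean(apply(pfD, 1, var)), 3 * mean(apply(pf, 1, var)))
})

test_that("plantSweep builds the hard-sweep haplotype structure it promises", {
  set.seed(31)
  sim <- simulatePopulations(simConfig(nPops = 1, samplesPerPop = 10,
                                       nChrom = 1, chromLengthBp = 5e6,
                                       snpDensity = 100, seed = 31,
                                       missingRate = 0))
  h <- plantSweep(sim$haplotypes, "1", 2.5e6, targetFreq = 0.8,
                  spanBp = 1e6)
  focal <- variantIndex(h, "1", 2.5e6)
  H <- haplotypes(h)
  expect_equal(sum(H[, focal]), round(0.8 * 20))       # 16 of 20 carriers
  span <- which(positions(h) >= 2e6 & positions(h) <= 3e6)
  carriers <- which(H[, focal] == 1L)
  expect_true(all(apply(H[carriers, span], 2, function(col)
    length(unique(col)) == 1L)))                       # identical over span
  # EHH for the derived allele is 1 across the span
  hp <- polarize(h, "ref_ancestral")
  pr <- ehh(hp, focal, "derived")
  inSpan <- pr$right$pos <= 3e6
  expect_true(all(pr$right$ehh[inSpan] == 1))
  # extended derived homozygosity makes ln(iHH_A / iHH_D) negative
  sc <- suppressMessages(ihsScan(hp))
  expect_lt(sc$ln_ratio[focal], 0)
  # infeasible spans are rejected
  expect_error(plantSweep(sim$haplotypes, "1", 100, 0.8, 1e6,
                          samples = sampleIDs(sim$haplotypes)[1:2])
               , NA)  # span clipped by SNP availability is fine
  expect_error(simConfig(nPops = 1, samplesPerPop = 5, nChrom = 1,
                         chromLengthBp = 1e6, snpDensity = 100, seed = 1,
                         sweeps = list(list(chrom = "1", positionBp = 9e5,
                                            targetFreq = 0.8, spanBp = 5e5))),
               "exceeds")
})

test_that("plantAutozygosity spans the requested genome fraction", {
  sim <- simulatePopulations(simConfig(nPops = 1, samplesPerPop = 4,
                                       nChrom = 2, chromLengthBp = 20e6,
                                       snpDensity = 100, seed = 8,
                                       missingRate = 0))
  set.seed(5)
  res <- plantAutozygosity(sim$haplotypes, sampleIDs(sim$haplotypes)[1:2],
                           phi = 0.5, chromLengthBp = c("1" = 20e6,
                                                        "2" = 20e6))
  tr <- res$tracts
  tot <- tapply(tr$end_bp - tr$start_bp + 1, tr$sample_id, sum)
  expect_equal(as.numeric(tot) / 40e6, c(0.5, 0.5), tolerance = 1e-6)
  # phi = 1: the individual becomes fully homozygous (F_HOM = 1)
  set.seed(6)
  res1 <- plantAutozygosity(sim$haplotypes, sampleIDs(sim$haplotypes)[1],
                            phi = 1, chromLengthBp = c("1" = 20e6,
                                                       "2" = 20e6),
                            maxTractBp = 25e6)
  g1 <- collapseToGenotypes(res1$haplotypes)
  expect_true(all(genotypeCalls(g1)[1, ] %in% c(0L, 2L)))
  # phi = 0: identity
  res0 <- plantAutozygosity(sim$haplotypes, sampleIDs(sim$haplotypes)[1],
                            phi = 0, chromLengthBp = c("1" = 20e6,
                                                       "2" = 20e6))
  expect_identical(haplotypes(res0$haplotypes), haplotypes(sim$haplotypes))
})
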