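test_that("simulated reference honours length, seed and alphabet", {
  ref <- simulateReference(2000, seed = 1)
  expect_equal(refLength(ref), 2000L)
  expect_identical(refSequence(ref),
                   refSequence(simulateReference(2000, seed = 1)))
  s1 <- strsplit(refSequence(ref), "")[[1]]
  s2 <- strsplit(refSequence(simulateReference(2000, seed = 2)), "")[[1]]
  expect_gt(sum(s1 != s2), 0)
  expect_true(all(s1 %in% c("A", "C", "G", "T")))
  expect_error(simulateReference(10), "length")
})

test_that("parental haplotypes are biallelic subsets of the chosen sites", {
  ref <- simulateReference(5000, seed = 3)
  p0 <- simulateParents(ref, 1, 0, seed = 1)
  expect_true(all(genotypeCalls(p0) == "-") || ncol(genotypeCalls(p0)) == 0)
  par <- simulateParents(ref, 23, 32, seed = 5)
  expect_identical(genotypeCalls(par),
                   genotypeCalls(simulateParents(ref, 23, 32, seed = 5)))
  expect_lte(ncol(genotypeCalls(par)), 32)
  l <- loci(par)
  expect_true(all(diff(l$position) > 0))
  expect_true(all(l$alt != l$ref))
  # each column contains only '-' and the single alt base
  for (j in seq_len(ncol(genotypeCalls(par))))
    expect_true(all(genotypeCalls(par)[, j] %in% c("-", l$alt[j])))
  expect_error(simulateParents(ref, 2, 5000, seed = 1), "nSites")
})

test_that("noiseless crosses transmit the recorded father's haplotype", {
  co <- makeTinyCohort(contamination = 0, leakage = 0, mu = 0)
  prog <- progenyTable(co$ped)
  for (i in seq_len(nrow(prog)))
    expect_identical(genotypeCalls(co$sim$progeny)[prog$progenyId[i], ],
                     genotypeCalls(co$parents)[prog$father[i], ])
  expect_true(all(co$sim$truth$event == "PATERNAL"))
  expect_identical(co$sim$truth$trueDonor, prog$father)
})

test_that("forced maternal leakage transmits the mother's haplotype", {
  co <- makeTinyCohort(contamination = 0, leakage = 1, mu = 0)
  prog <- progenyTable(co$ped)
  for (i in seq_len(nrow(prog)))
    expect_identical(genotypeCalls(co$sim$progeny)[prog$progenyId[i], ],
                     genotypeCalls(co$parents)[prog$mother[i], ])
  expect_true(all(co$sim$truth$event == "LEAKAGE"))
})

test_that("transmission event frequencies converge to the configured rates", {
  ref <- simulateReference(2000, seed = 7)
  cfg <- simulationConfig(nMothers = 2, nFathers = 2,
                          nProgenyPerCross = 500, genomeLength = 2000,
                          nPolymorphicSites = 10, contaminationRate = 0.2,
                          leakageRate = 0.1, deNovoMu = 0)
  ped <- simulatePedigree(2, 2, nProgenyPerCross = 500)
  par <- simulateParents(ref, 4, 10, seed = 8, ids = sampledClones(ped))
  sim <- simulateCross(par, ped, cfg, seed = 9)
  n <- nrow(progenyTable(ped))
  for (spec in list(c("CONTAMINATION", 0.2), c("LEAKAGE", 0.1))) {
    obs <- sum(sim$truth$event == spec[1])
    rate <- as.numeric(spec[2])
    ci <- qbinom(c(0.005, 0.995), n, rate)
    expect_gte(obs, ci[1])
    expect_lte(obs, ci[2])
  }
})

test_that("de novo mutation counts follow the Poisson transmission model", {
  # lambda = mu * L * g = 0.2e-9 * 121000 * 25 = 6.05e-4 per progeny
  n <- 1e5
  ref <- simulateReference(1000, seed = 2)
  cfg <- simulationConfig(nMothers = 1, nFathers = 1, nProgenyPerCross = n,
                          genomeLength = 121000, nPolymorphicSites = 4,
                          contaminationRate = 0, leakageRate = 0,
                          deNovoMu = 0.2e-9, generationYears = 25)
  ped <- simulatePedigree(1, 1, nProgenyPerCross = n)
  # parents simulated on a small reference; positions are within 121 kb
  par <- simulateParents(ref, 2, 4, seed = 3, ids = sampledClones(ped))
  sim <- simulateCross(par, ped, cfg, seed = 4)
  counts <- lengths(strsplit(sim$truth$deNovoPositions, ","))
  counts[sim$truth$deNovoPositions == ""] <- 0L
  lambda <- 0.2e-9 * 121000 * 25
  expect_equal(lambda, 6.05e-4)
  se <- sqrt(lambda / n)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
  expect_true(all(as.integer(unlist(strsplit(
    sim$truth$deNovoPositions[sim$truth$deNovoPositions != ""], ","))) <=
    121000))
})

test_that("error-free reads reproduce the haplotype at every position", {
  co <- makeTinyCohort()
  hap <- haplotypeSequence(co$ref, co$all, sampleIds(co$all)[1])
  rd <- simulateReads(hap, co$ref, co$cfg, sample = "s", seed = 21)
  for (i in sample(nrow(rd), 25)) {
    expect_identical(rd$seq[i],
                     substr(hap, rd$pos[i], rd$pos[i] + nchar(rd$seq[i]) - 1))
  }
})

test_that("realized depth tracks the configured mean and SAM is reproducible", {
  ref <- simulateReference(20000, seed = 5)
  cfg <- simulationConfig(genomeLength = 20000, depthMean = 12.3,
                          readLength = 150, baseErrorRate = 0,
                          fracLowMapq = 0, fracLowBaseq = 0)
  rd <- simulateReads(refSequence(ref), ref, cfg, sample = "s", seed = 31)
  meanDepth <- sum(nchar(rd$seq)) / refLength(ref)
  expect_lt(abs(meanDepth - 12.3) / 12.3, 0.10)
  f1 <- tempfile(fileext = ".sam"); f2 <- tempfile(fileext = ".sam")
  writeSam(rd, ref, f1)
  writeSam(simulateReads(refSequence(ref), ref, cfg, sample = "s",
                         seed = 31), ref, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(
    simulateReads(refSequence(ref), ref,
                  simulationConfig(genomeLength = 20000,
                                   readLength = 30000,
                                   insertSize = 60000), sample = "s"),
    "readLength|insertSize")
})

test_that("simulation config validates probabilities and design sizes", {
  expect_error(simulationConfig(contaminationRate = 0.7, leakageRate = 0.5),
               "<= 1")
  expect_error(simulationConfig(baseErrorRate = 2), "probabilities")
  expect_error(simulationConfig(nMothers = 0), ">= 1")
  expect_error(simulateCross(
    simulateParents(simulateReference(2000, 1), 2, 4, 1,
                    ids = c("M01", "F01")),
    pedigree(data.frame(progenyId = character(), mother = character(),
                        father = character())),
    simulationConfig(genomeLength = 2000)), "empty pedigree")
})
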