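test_that("haplotype distance treats N as the reference state", {
  expect_equal(unname(haplotypeDistance(c("-", "T", "N"), c("-", "T", "N"))),
               c(3, 0))
  expect_equal(unname(haplotypeDistance(c("-", "T", "-"), c("-", "-", "-"))),
               c(3, 1))
  # N vs '-' contributes no mismatch under AS_REFERENCE ...
  expect_equal(unname(haplotypeDistance(c("N"), c("-"))), c(1, 0))
  # ... but N vs the alt base is a mismatch (N collapsed to reference)
  expect_equal(unname(haplotypeDistance(c("N"), c("T"))), c(1, 1))
  # under PAIRWISE_DELETE the N locus is not compared at all
  expect_equal(unname(haplotypeDistance(c("N"), c("T"),
                                        nPolicy = "PAIRWISE_DELETE")),
               c(0, 0))
  expect_error(haplotypeDistance(c("-", "-"), c("-")), "incompatible")
})

test_that("haplotype distance is a pseudometric on matrix rows", {
  set.seed(42)
  rows <- replicate(12, sample(c("-", "T", "N"), 15, replace = TRUE),
                    simplify = FALSE)
  d <- function(a, b) unname(haplotypeDistance(a, b))[2]
  for (k in 1:30) {
    i <- sample(12, 3)
    a <- rows[[i[1]]]; b <- rows[[i[2]]]; c_ <- rows[[i[3]]]
    expect_equal(d(a, a), 0)
    expect_equal(d(a, b), d(b, a))
    expect_lte(d(a, c_), d(a, b) + d(b, c_))
  }
})

test_that("the tester-design fixture classifies as the design dictates", {
  fx <- testerDesignFixture()
  rep <- classifyPedigree(fx$pedigree, fx$matrix)
  expect_equal(nrow(rep), 45L)
  byId <- setNames(rep$mode, rep$progenyId)
  donor <- setNames(rep$assignedDonor, rep$progenyId)
  # N4's seven progeny match their recorded father exactly
  expect_true(all(byId[fx$families$N4] == "PATERNAL_MATCH"))
  # the eight S1 progeny all match W03 instead of S1
  expect_true(all(byId[fx$families$S1] == "ALTERNATE_FATHER"))
  expect_true(all(donor[fx$families$S1] == "W03"))
  # W03's own progeny match it; 222's nine match the ramet consensus
  expect_true(all(byId[fx$families$W03] == "PATERNAL_MATCH"))
  expect_true(all(byId[fx$families$`222`] == "PATERNAL_MATCH"))
  # progeny of the unsampled father S2 match no sampled clone ...
  expect_true(all(byId[fx$families$S2] == "NOVEL"))
  # ... yet share one uniform haplotype among themselves
  expect_true(familyUniformity(fx$families$S2, fx$matrix)$uniform)
})

test_that("no progeny matches its mother in the tester fixture", {
  fx <- testerDesignFixture()
  rep <- classifyPedigree(fx$pedigree, fx$matrix)
  expect_true(all(rep$mode != "MATERNAL_MATCH"))
  motherDist <- rep$distToMother[!is.na(rep$distToMother)]
  expect_true(all(motherDist > 0))
})

test_that("ramet conflicts are confined to the known discordant site", {
  fx <- testerDesignFixture()
  conf <- rametConsistency("222", fx$matrix, fx$pedigree)
  expect_equal(conf$position, 101157L)
  expect_equal(nrow(rametConsistency("N4", fx$matrix, fx$pedigree)), 0L)
  expect_error(rametConsistency("W03", fx$matrix, fx$pedigree),
               "fewer than two")
})

test_that("an injected ramet genotyping error is flagged at that locus only", {
  co <- makeTinyCohort(nMothers = 2, nFathers = 2)
  m <- co$all
  cells <- genotypeCalls(m)
  # give clone F01 three ramets, one carrying a flipped cell at locus 4
  extra <- rbind(F01_r2 = cells["F01", ], F01_r3 = cells["F01", ])
  extra["F01_r3", 4] <- if (extra["F01_r3", 4] == "-")
    loci(m)$alt[4] else "-"
  m2 <- genotypeMatrix(rbind(cells, extra), positions(m),
                       loci(m)$ref, loci(m)$alt)
  ram <- cloneRamets(co$ped)
  ram[["F01"]] <- c("F01", "F01_r2", "F01_r3")
  ped2 <- pedigree(progenyTable(co$ped), ram)
  conf <- rametConsistency("F01", m2, ped2)
  expect_equal(conf$position, positions(m)[4])
  # majority consensus still matches the clean haplotype
  cons <- cloneConsensus("F01", m2, ped2)
  expect_identical(as.character(cons), unname(cells["F01", ]))
  expect_equal(attr(cons, "conflicts"), positions(m)[4])
})

test_that("noiseless paternal simulations classify 100% PATERNAL_MATCH", {
  co <- makeTinyCohort(nMothers = 3, nFathers = 3, nSites = 16, seed = 91)
  rep <- classifyPedigree(co$ped, co$all)
  expect_true(all(rep$mode == "PATERNAL_MATCH"))
  expect_identical(rep$assignedDonor, progenyTable(co$ped)$father)
})

test_that("contamination progeny from external donors classify NOVEL", {
  ref <- simulateReference(2000, seed = 12)
  cfg <- simulationConfig(nMothers = 2, nFathers = 2, nProgenyPerCross = 10,
                          genomeLength = 2000, nPolymorphicSites = 14,
                          contaminationRate = 1, leakageRate = 0,
                          deNovoMu = 0)
  ped <- simulatePedigree(2, 2, nProgenyPerCross = 10)
  par <- simulateParents(ref, 4, 14, seed = 13, ids = sampledClones(ped))
  sim <- simulateCross(par, ped, cfg, seed = 14)
  m <- genotypeMatrix(rbind(genotypeCalls(par), genotypeCalls(sim$progeny)),
                      positions(par), loci(par)$ref, loci(par)$alt)
  rep <- classifyPedigree(ped, m)
  expect_true(all(sim$truth$event == "CONTAMINATION"))
  # external haplotypes are generated distinct from every sampled clone
  expect_true(all(rep$mode == "NOVEL"))
})

test_that("progeny absent from matrix or candidate-free pedigrees error", {
  fx <- testerDesignFixture()
  expect_error(classifyProgeny("nope", fx$pedigree, fx$matrix), "not found")
  emptyPed <- pedigree(progenyTable(fx$pedigree),
                       list(N4 = character(), S1 = character()))
  expect_error(classifyProgeny(progenyTable(fx$pedigree)$progenyId[1],
                               emptyPed, fx$matrix),
               "no sampled candidate")
})

test_that("de novo expectation is the rate-length-time product", {
  e <- expectedDeNovo(0.2e-9, 121000, 25)
  expect_equal(e$expectedCount, 6.05e-4, tolerance = 1e-12)
  expect_lt(e$expectedCount, 0.02)
  expect_equal(expectedDeNovo(0, 121000, 25)$expectedCount, 0)
  expect_equal(expectedDeNovo(0, 121000, 25)$pGeK, 0)
  expect_error(expectedDeNovo(0.2e-9, -1, 25), "positive")
})

test_that("Poisson tails match explicit series summation", {
  for (lambda in c(6.05e-4, 0.02, 1.3)) {
    for (k in 1:4) {
      e <- expectedDeNovo(lambda / (121000 * 25), 121000, 25, k = k)
      expect_equal(e$pGeK, oraclePoissonTail(k, lambda), tolerance = 1e-12)
    }
  }
})

test_that("de novo expectation is linear in each parameter", {
  base <- expectedDeNovo(0.2e-9, 121000, 25)$expectedCount
  expect_equal(expectedDeNovo(0.4e-9, 121000, 25)$expectedCount, 2 * base)
  expect_equal(expectedDeNovo(0.2e-9, 242000, 25)$expectedCount, 2 * base)
  expect_equal(expectedDeNovo(0.2e-9, 121000, 50)$expectedCount, 2 * base)
})

test_that("leakage test reports the exact upper-tail binomial", {
  lt <- leakageTest(9, 45)
  expect_equal(lt$observedFraction, 0.2)
  expect_equal(lt$pValue, oracleBinomTail(9, 45, 0.01), tolerance = 1e-12)
  expect_equal(leakageTest(0, 45)$pValue, 1.0)
  expect_error(leakageTest(1, 0), "positive")
  expect_error(leakageTest(50, 45), "lie in")
})

test_that("concordance counts agreements over mutually called cells", {
  fx <- testerDesignFixture()
  m <- fx$matrix
  expect_equal(concordance(m, m)$overall, 1.0)
  # flip one cell in a 10-sample x 10-locus window
  sub <- m[1:10, 1:10]
  cells <- genotypeCalls(sub)
  cells[3, 7] <- if (cells[3, 7] == "-") loci(sub)$alt[7] else "-"
  sub2 <- genotypeMatrix(cells, positions(sub), loci(sub)$ref,
                         loci(sub)$alt)
  cc <- concordance(sub, sub2)
  expect_equal(cc$overall, 0.99)
  expect_equal(nrow(cc$disagreements), 1L)
  expect_equal(cc$disagreements$position, positions(sub)[7])
  # masked cells are excluded from the denominator
  cells[1, 1] <- "N"
  sub3 <- genotypeMatrix(cells, positions(sub), loci(sub)$ref,
                         loci(sub)$alt)
  expect_equal(concordance(sub, sub3)$nCompared, 99L)
  expect_error(concordance(sub, fx$matrix[11:20, ]), "incompatible")
})

test_that("tester-design sample labels parse into their components", {
  p <- parseSampleLabel(c("F222_M014_5", "014 K1-9-10", "S1_L1-3-7"))
  expect_equal(p$type, c("progeny", "parent", "parent"))
  expect_equal(p$father[1], "222")
  expect_equal(p$mother[1], "014")
  expect_equal(p$index[1], 5L)
  expect_equal(p$clone[2:3], c("014", "S1"))
  expect_equal(p$location[2:3], c("K1-9-10", "L1-3-7"))
})
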