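test_that("read filter keeps exactly the uniquely, properly paired reads", {
  rd <- rbind(
    samRecord(1, "ACGT", mapq = 19L, flag = 99L),   # low MAPQ
    samRecord(1, "ACGT", mapq = 20L, flag = 99L),   # boundary: kept
    samRecord(1, "ACGT", mapq = 60L, flag = 97L),   # not proper pair
    samRecord(1, "ACGT", mapq = 60L, flag = 355L),  # secondary
    samRecord(1, "ACGT", mapq = 60L, flag = 2147L), # supplementary
    samRecord(1, "ACGT", mapq = 60L, flag = 101L))  # unmapped
  kept <- filterReads(rd)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$mapq, 20L)
})

test_that("a simulated improper-pair fraction is removed by count", {
  flags <- c(rep(99L, 70), rep(97L, 30))
  rd <- do.call(rbind, lapply(seq_along(flags), function(i)
    samRecord(i, "ACGT", flag = flags[i], qname = paste0("r", i))))
  expect_equal(nrow(filterReads(rd)), 70L)
})

test_that("pileup excludes sub-Q20 bases and conserves depth", {
  ref <- referenceGenome(strrep("A", 1000))
  # one read with a Q19 base ('4' = Q19) at its third position
  rd <- samRecord(11, "GGGG", qual = "II4I")
  pu <- buildPileup(rd, ref)
  expect_equal(unname(pu$counts[13, "G"]), 0L)   # Q19 base dropped
  expect_equal(unname(pu$counts[12, "G"]), 1L)
  expect_equal(pu$depth, as.integer(rowSums(pu$counts)))
})

test_that("pileup walks soft-clips, insertions and deletions correctly", {
  ref <- referenceGenome(strrep("A", 100))
  # 2S3M1D2M: query CCGGGTT -> GGG at 10..12, deletion at 13, TT at 14..15
  rd <- samRecord(10, "CCGGGTT", qual = "IIIIIII")
  rd$cigar <- "2S3M1D2M"
  pu <- buildPileup(rd, ref)
  expect_equal(unname(pu$counts[10:12, "G"]), c(1L, 1L, 1L))
  expect_equal(sum(pu$counts[13, ]), 0L)
  expect_equal(unname(pu$counts[14:15, "T"]), c(1L, 1L))
  expect_equal(sum(pu$counts[c(8:9, 16L), ]), 0L)
})

test_that("error-free reads give unanimous pileup columns", {
  co <- makeTinyCohort()
  s <- sampleIds(co$all)[1]
  hap <- haplotypeSequence(co$ref, co$all, s)
  rd <- simulateReads(hap, co$ref, co$cfg, sample = s, seed = 41)
  pu <- buildPileup(filterReads(rd), co$ref)
  hapChars <- strsplit(hap, "")[[1]]
  covered <- which(pu$depth > 0)
  for (p in covered)
    expect_equal(unname(pu$counts[p, hapChars[p]]), pu$depth[p])
})

test_that("single-column calls match their definitions", {
  expect_equal(callSite(c(G = 2), "G")$status, "MISSING")
  expect_equal(callSite(c(G = 2), "G")$calledBase, "N")
  u <- callSite(c(T = 6), "G")
  expect_equal(u$status, "ALT")
  expect_equal(u$calledBase, "T")
  expect_equal(u$majorFraction, 1.0)
  h <- callSite(c(T = 5, G = 4), "G")
  expect_equal(h$status, "HETEROPLASMIC_EXCLUDED")
  expect_equal(h$calledBase, "N")
  expect_equal(h$majorFraction, 5 / 9, tolerance = 1e-12)
  # tie for the majority base is excluded, not arbitrarily resolved
  expect_equal(callSite(c(A = 3, C = 3), "A", homoplasmy = 0.4)$status,
               "HETEROPLASMIC_EXCLUDED")
})

test_that("caller matches the brute-force oracle on all depth-<=6 columns", {
  grid <- allCountConfigs(6)
  for (thr in c(0.9, 0.75, 1.0)) {
    for (refBase in c("A", "G")) {
      got <- vapply(seq_len(nrow(grid)), function(i)
        callSite(c(A = grid$a[i], C = grid$c[i], G = grid$g[i],
                   T = grid$t[i]), refBase, homoplasmy = thr)$status, "")
      want <- vapply(seq_len(nrow(grid)), function(i)
        oracleCallSite(grid$a[i], grid$c[i], grid$g[i], grid$t[i],
                       refBase, homoplasmy = thr), "")
      expect_identical(got, want)
    }
  }
})

test_that("raising the homoplasmy threshold only ever demotes calls", {
  grid <- allCountConfigs(5)
  thrs <- c(0.6, 0.8, 0.9, 0.95, 1.0)
  for (i in sample(nrow(grid), 60)) {
    prev <- NULL
    for (thr in thrs) {
      cur <- callSite(c(A = grid$a[i], C = grid$c[i], G = grid$g[i],
                        T = grid$t[i]), "A", homoplasmy = thr)$status
      if (!is.null(prev)) {
        if (prev == "MISSING") expect_equal(cur, "MISSING")
        if (prev == "HETEROPLASMIC_EXCLUDED")
          expect_true(cur %in% c("HETEROPLASMIC_EXCLUDED", "MISSING"))
        if (prev %in% c("REF", "ALT"))
          expect_true(cur %in% c(prev, "HETEROPLASMIC_EXCLUDED"))
      }
      prev <- cur
    }
  }
})

test_that("whole-sample calling recovers the exact ALT sites of a haplotype", {
  co <- makeTinyCohort(depth = 12)
  s <- progenyTable(co$ped)$progenyId[1]
  truthSites <- positions(co$all)[genotypeCalls(co$all)[s, ] != "-"]
  hap <- haplotypeSequence(co$ref, co$all, s)
  f <- tempfile(fileext = ".sam")
  writeSam(simulateReads(hap, co$ref, co$cfg, sample = s, seed = 51),
           co$ref, f)
  res <- callSample(f, co$ref, sample = s)
  altPos <- res$calls$position[res$calls$status == "ALT"]
  expect_setequal(altPos, truthSites)
  expect_gt(res$coverage$breadth1x, 0.95)
  expect_lt(abs(res$coverage$meanDepth - 12) / 12, 0.15)
})

test_that("ALT precision and recall reach 0.99 on noiseless depth-5 cohorts", {
  co <- makeTinyCohort(nMothers = 3, nFathers = 3, depth = 5, nSites = 20,
                       seed = 61)
  tp <- 0; fp <- 0; fn <- 0
  for (s in sampleIds(co$all)[1:8]) {
    truthSites <- positions(co$all)[genotypeCalls(co$all)[s, ] != "-"]
    rd <- simulateReads(haplotypeSequence(co$ref, co$all, s), co$ref,
                        co$cfg, sample = s, seed = 70 + match(s, sampleIds(co$all)))
    res <- callSample(rd, co$ref, sample = s)
    altPos <- res$calls$position[res$calls$status == "ALT"]
    # recall is measured over callable sites: a site the caller reports as
    # MISSING (depth < 3) is a no-call, not a miscall
    missingPos <- res$calls$position[res$calls$status == "MISSING"]
    tp <- tp + length(intersect(altPos, truthSites))
    fp <- fp + length(setdiff(altPos, truthSites))
    fn <- fn + length(setdiff(setdiff(truthSites, altPos), missingPos))
  }
  expect_gte(tp / (tp + fp), 0.99)
  expect_gte(tp / (tp + fn), 0.99)
})

test_that("zero reads give an empty pileup and zero breadth", {
  ref <- referenceGenome(strrep("ACGT", 300))
  rd <- samRecord(1, "ACGT")[0, ]
  res <- callSample(rd, ref, sample = "empty")
  expect_equal(sum(res$calls$status == "ALT"), 0L)
  expect_equal(res$coverage$breadth1x, 0)
  expect_equal(res$coverage$meanDepth, 0)
})

test_that("package pileup agrees with the Rsamtools pileup engine", {
  co <- makeTinyCohort(L = 4000, depth = 8, baseError = 0.01,
                       fracLowBaseq = 0.05, seed = 81)
  s <- sampleIds(co$all)[1]
  f <- tempfile(fileext = ".sam")
  writeSam(simulateReads(haplotypeSequence(co$ref, co$all, s), co$ref,
                         co$cfg, sample = s, seed = 82), co$ref, f)
  rd <- readSam(f)
  pu <- buildPileup(filterReads(rd), co$ref)
  bam <- Rsamtools::asBam(f, tempfile(), overwrite = TRUE)
  flags <- Rsamtools::scanBamFlag(isProperPair = TRUE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  rp <- Rsamtools::pileup(bam,
    scanBamParam = Rsamtools::ScanBamParam(flag = flags, mapqFilter = 20),
    pileupParam = Rsamtools::PileupParam(min_base_quality = 20,
                                         min_mapq = 20,
                                         min_nucleotide_depth = 1,
                                         distinguish_strands = FALSE,
                                         max_depth = 10000))
  for (i in seq_len(nrow(rp))) {
    b <- as.character(rp$nucleotide[i])
    if (!b %in% c("A", "C", "G", "T")) next
    expect_equal(unname(pu$counts[rp$pos[i], b]), rp$count[i])
  }
  # and nothing extra: total counted bases agree
  rpAcgt <- rp[rp$nucleotide %in% c("A", "C", "G", "T"), ]
  expect_equal(sum(pu$counts), sum(rpAcgt$count))
})

test_that("mismatched SAM contig is rejected", {
  ref <- referenceGenome(strrep("A", 1000), id = "other")
  rd <- samRecord(1, "AAAA")
  expect_error(callSample(rd, ref), "malformed")
})
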