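# Independent oracles and small builders shared across tests.

# Brute-force genotype of a single pileup column, written as a direct
# transcription of the filter definitions, independent of callSite().
oracleCallSite <- function(a, c, g, t, refBase, minDepth = 3L,
                           homoplasmy = 0.9) {
  counts <- c(A = a, C = c, G = g, T = t)
  depth <- a + c + g + t
  if (depth < minDepth) return("MISSING")
  winners <- names(counts)[counts == max(counts)]
  if (length(winners) > 1L) return("HETEROPLASMIC_EXCLUDED")
  if (max(counts) / depth < homoplasmy) return("HETEROPLASMIC_EXCLUDED")
  if (winners == refBase) "REF" else "ALT"
}

# All base-count configurations with total depth <= maxDepth.
allCountConfigs <- function(maxDepth) {
  grid <- expand.grid(a = 0:maxDepth, c = 0:maxDepth, g = 0:maxDepth,
                      t = 0:maxDepth)
  grid[rowSums(grid) <= maxDepth, ]
}

# Upper-tail Poisson probability by explicit series summation.
oraclePoissonTail <- function(k, lambda, terms = 80L) {
  kk <- k:(k + terms)
  sum(exp(-lambda) * lambda^kk / factorial(kk))
}

# Upper-tail binomial probability by explicit summation.
oracleBinomTail <- function(x, n, p) {
  kk <- x:n
  sum(choose(n, kk) * p^kk * (1 - p)^(n - kk))
}

# A tiny noiseless cohort: reference, parents, pedigree, cross.
makeTinyCohort <- function(nMothers = 2L, nFathers = 2L, L = 4000L,
                           nSites = 12L, contamination = 0,
                           leakage = 0, mu = 0, depth = 12,
                           baseError = 0, fracLowMapq = 0,
                           fracLowBaseq = 0, seed = 11L) {
  ref <- simulateReference(L, seed = seed)
  cfg <- simulationConfig(nMothers = nMothers, nFathers = nFathers,
                          genomeLength = L, nPolymorphicSites = nSites,
                          contaminationRate = contamination,
                          leakageRate = leakage, deNovoMu = mu,
                          depthMean = depth, readLength = 100L,
                          insertSize = 250L, baseErrorRate = baseError,
                          fracLowMapq = fracLowMapq,
                          fracLowBaseq = fracLowBaseq, seed = seed)
  ped <- simulatePedigree(nMothers, nFathers)
  parents <- simulateParents(ref, nMothers + nFathers, nSites,
                             seed = seed + 1L, ids = sampledClones(ped))
  sim <- simulateCross(parents, ped, cfg, seed = seed + 2L)
  allCells <- rbind(genotypeCalls(parents), genotypeCalls(sim$progeny))
  list(ref = ref, cfg = cfg, ped = ped, parents = parents, sim = sim,
       all = genotypeMatrix(allCells, positions(parents),
                            loci(parents)$ref, loci(parents)$alt))
}

# Hand-built SAM record data.frame (single-end-style rows with chosen flags).
samRecord <- function(pos, seq, qual = strrep("I", nchar(seq)),
                      flag = 99L, mapq = 60L, qname = "r1",
                      rname = "cpgenome") {
  data.frame(qname = qname, flag = flag, rname = rname, pos = pos,
             mapq = mapq, cigar = paste0(nchar(seq), "M"), rnext = "=",
             pnext = pos, tlen = 0L, seq = seq, qual = qual,
             stringsAsFactors = FALSE)
}
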