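#' Reference chloroplast genome
#'
#' A circular (or linear) reference sequence with 1-based forward-strand
#' coordinates.  All site positions used elsewhere in the package (genotype
#' matrices, annotations, SAM records) refer to this coordinate system.
#'
#' @slot id single-sequence identifier (used as the SAM/VCF contig name).
#' @slot sequence a [Biostrings::DNAString] over the alphabet A/C/G/T.
#' @slot circular logical; circular molecules are recorded as such, but
#'   simulated reads never span the origin.
#'
#' @seealso [simulateReference()], [referenceGenome()]
#' @exportClass ReferenceGenome
setClass("ReferenceGenome",
  representation(id = "character", sequence = "DNAString", circular = "logical"))

setValidity("ReferenceGenome", function(object) {
  msg <- character()
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "'id' must be a single non-empty string")
  if (length(object@sequence) < 1L)
    msg <- c(msg, "'sequence' must be non-empty")
  freq <- Biostrings::alphabetFrequency(object@sequence)
  if (sum(freq[c("A", "C", "G", "T")]) != length(object@sequence))
    msg <- c(msg, "'sequence' may only contain A, C, G, T")
  if (length(object@circular) != 1L || is.na(object@circular))
    msg <- c(msg, "'circular' must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' Construct a ReferenceGenome
#'
#' @param sequence a character string or [Biostrings::DNAString].
#' @param id contig name.
#' @param circular logical; chloroplast genomes are circular molecules.
#' @return a [ReferenceGenome-class] object.
#' @examples
#' ref <- referenceGenome("ACGTACGTACGT", id = "demo")
#' refLength(ref)
#' @export
referenceGenome <- function(sequence, id = "cpgenome", circular = TRUE) {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  new("ReferenceGenome", id = id, sequence = sequence, circular = circular)
}

#' @describeIn referenceGenome genome length in bp.
#' @param x a `ReferenceGenome`.
#' @export
refLength <- function(x) length(x@sequence)

#' @describeIn referenceGenome the sequence as a plain character string.
#' @export
refSequence <- function(x) as.character(x@sequence)

#' @describeIn referenceGenome the contig identifier.
#' @export
refId <- function(x) x@id

setMethod("show", "ReferenceGenome", function(object) {
  cat("ReferenceGenome '", object@id, "': ", length(object@sequence), " bp, ",
      if (object@circular) "circular" else "linear", "\n", sep = "")
})

#' Simulation settings for the synthetic-pedigree generator
#'
#' Holds every tunable of the synthetic cohort: mating-design dimensions,
#' polymorphism panel size, transmission-noise rates, the chloroplast
#' substitution rate and generation time used for de novo mutation, and the
#' short-read error model.  Defaults describe a conifer tester-design study:
#' a 9 x 5 factorial (45 progeny), 32 polymorphic sites on a 121 kb genome,
#' strictly paternal transmission with a 20% pollen-contamination rate, a
#' substitution rate of 2e-10 per site per year over a 25-year generation,
#' and 150 bp paired-end reads at 12.3x mean depth.
#'
#' @slot nMothers,nFathers numbers of maternal and paternal clones.
#' @slot nProgenyPerCross progeny per mother x father combination.
#' @slot genomeLength reference length in bp.
#' @slot nPolymorphicSites biallelic sites segregating among parents.
#' @slot contaminationRate probability a progeny's true pollen donor is an
#'   unsampled external male.
#' @slot leakageRate probability of maternal (leaked) transmission.
#' @slot deNovoMu substitution rate, per site per year.
#' @slot generationYears generation time in years.
#' @slot depthMean mean sequencing depth (reads covering a site).
#' @slot readLength read length in bp.
#' @slot insertSize outer distance between paired-end mates in bp.
#' @slot baseErrorRate per-base sequencing error probability.
#' @slot fracLowMapq fraction of read pairs emitted with low mapping quality
#'   and without the proper-pair flag.
#' @slot fracLowBaseq fraction of bases given a quality below Q20.
#' @slot nExternal size of the external (unsampled) pollen-donor pool.
#' @slot seed integer seed controlling all randomness.
#' @seealso [simulateCross()], [simulateReads()]
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    nMothers = "integer", nFathers = "integer", nProgenyPerCross = "integer",
    genomeLength = "integer", nPolymorphicSites = "integer",
    contaminationRate = "numeric", leakageRate = "numeric",
    deNovoMu = "numeric", generationYears = "numeric",
    depthMean = "numeric", readLength = "integer", insertSize = "integer",
    baseErrorRate = "numeric", fracLowMapq = "numeric",
    fracLowBaseq = "numeric", nExternal = "integer", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  pos <- c(nMothers = object@nMothers, nFathers = object@nFathers,
           nProgenyPerCross = object@nProgenyPerCross,
           genomeLength = object@genomeLength, readLength = object@readLength,
           insertSize = object@insertSize, nExternal = object@nExternal)
  bad <- names(pos)[pos < 1L]
  if (length(bad))
    msg <- c(msg, paste0("must be >= 1: ", paste(bad, collapse = ", ")))
  pr <- c(contaminationRate = object@contaminationRate,
          leakageRate = object@leakageRate,
          baseErrorRate = object@baseErrorRate,
          fracLowMapq = object@fracLowMapq, fracLowBaseq = object@fracLowBaseq)
  bad <- names(pr)[pr < 0 | pr > 1]
  if (length(bad))
    msg <- c(msg, paste0("probabilities must lie in [0,1]: ",
                         paste(bad, collapse = ", ")))
  if (object@contaminationRate + object@leakageRate > 1)
    msg <- c(msg, "contaminationRate + leakageRate must be <= 1")
  if (object@nPolymorphicSites < 0L)
    msg <- c(msg, "nPolymorphicSites must be >= 0")
  if (object@nPolymorphicSites >= object@genomeLength)
    msg <- c(msg, "nPolymorphicSites must be < genomeLength")
  if (object@deNovoMu < 0 || object@generationYears <= 0)
    msg <- c(msg, "deNovoMu must be >= 0 and generationYears > 0")
  if (object@depthMean <= 0)
    msg <- c(msg, "depthMean must be > 0")
  if (object@insertSize < 2L * object@readLength)
    msg <- c(msg, "insertSize must be >= 2 * readLength")
  if (length(msg)) msg else TRUE
})

#' @rdname SimulationConfig-class
#' @param nMothers,nFathers,nProgenyPerCross mating design.
#' @param genomeLength,nPolymorphicSites genome and panel size.
#' @param contaminationRate,leakageRate transmission-noise probabilities.
#' @param deNovoMu,generationYears mutation model (per-site per-year rate and
#'   generation time).
#' @param depthMean,readLength,insertSize,baseErrorRate,fracLowMapq,fracLowBaseq
#'   short-read model.
#' @param nExternal external pollen-donor pool size.
#' @param seed integer seed.
#' @return a validated `SimulationConfig`.
#' @examples
#' cfg <- simulationConfig(nMothers = 3, nFathers = 2, genomeLength = 5000)
#' cfg
#' @export
simulationConfig <- function(nMothers = 9L, nFathers = 5L,
                             nProgenyPerCross = 1L,
                             genomeLength = 121000L, nPolymorphicSites = 32L,
                             contaminationRate = 0.2, leakageRate = 0,
                             deNovoMu = 0.2e-9, generationYears = 25,
                             depthMean = 12.3, readLength = 150L,
                             insertSize = 350L, baseErrorRate = 0.001,
                             fracLowMapq = 0.05, fracLowBaseq = 0.02,
                             nExternal = 5L, seed = 1L) {
  new("SimulationConfig",
      nMothers = as.integer(nMothers), nFathers = as.integer(nFathers),
      nProgenyPerCross = as.integer(nProgenyPerCross),
      genomeLength = as.integer(genomeLength),
      nPolymorphicSites = as.integer(nPolymorphicSites),
      contaminationRate = contaminationRate, leakageRate = leakageRate,
      deNovoMu = deNovoMu, generationYears = generationYears,
      depthMean = depthMean, readLength = as.integer(readLength),
      insertSize = as.integer(insertSize), baseErrorRate = baseErrorRate,
      fracLowMapq = fracLowMapq, fracLowBaseq = fracLowBaseq,
      nExternal = as.integer(nExternal), seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig: ", object@nMothers, " x ", object@nFathers,
      " design, ", object@nProgenyPerCross, " progeny/cross\n",
      "  genome ", object@genomeLength, " bp, ", object@nPolymorphicSites,
      " polymorphic sites\n",
      "  contamination ", object@contaminationRate, ", leakage ",
      object@leakageRate, ", mu ", object@deNovoMu, "/site/yr over ",
      object@generationYears, " yr\n",
      "  reads ", object@readLength, " bp PE at ", object@depthMean,
      "x, base error ", object@baseErrorRate, "\n", sep = "")
})

#' Samples-by-loci chloroplast genotype matrix
#'
#' Cells use the compact published encoding: `"-"` for an exact match to the
#' reference base, the alternative base letter for a substitution, and `"N"`
#' for missing or heteroplasmy-excluded calls.  Loci are biallelic and stored
#' in strictly increasing 1-based genome order.
#'
#' @slot calls character matrix (samples x loci) of `"-"`, base letters, `"N"`.
#' @slot loci a [S4Vectors::DataFrame] with columns `position` (1-based
#'   integer), `ref` and `alt` (single bases; `alt` may be `NA` for a locus
#'   with no carrier).
#' @seealso [genotypeMatrix()], [buildMatrix()], [filterLoci()],
#'   [readGenotypeMatrix()]
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(calls = "matrix", loci = "DataFrame"))

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  calls <- object@calls
  loci <- object@loci
  if (!is.character(calls))
    msg <- c(msg, "'calls' must be a character matrix")
  if (!all(c("position", "ref", "alt") %in% colnames(loci)))
    msg <- c(msg, "'loci' needs columns position, ref, alt")
  else {
    if (ncol(calls) != nrow(loci))
      msg <- c(msg, "ncol(calls) must equal nrow(loci)")
    if (nrow(loci) > 1L && any(diff(loci$position) <= 0L))
      msg <- c(msg, "locus positions must be strictly increasing")
    if (any(!loci$ref %in% .CP_BASES))
      msg <- c(msg, "locus ref bases must be A/C/G/T")
    if (any(!is.na(loci$alt) & (!loci$alt %in% .CP_BASES | loci$alt == loci$ref)))
      msg <- c(msg, "locus alt bases must be A/C/G/T and differ from ref")
  }
  if (is.character(calls) && !all(calls %in% c("-", "N", .CP_BASES)))
    msg <- c(msg, "cells must be '-', 'N' or a base letter")
  if (is.null(rownames(calls)) && nrow(calls) > 0L)
    msg <- c(msg, "'calls' must carry sample ids as rownames")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param calls character matrix of cells (`"-"`/base/`"N"`) with sample ids
#'   as rownames; columns in locus order.
#' @param positions integer vector of 1-based locus positions.
#' @param ref,alt single reference / alternative bases per locus.
#' @return a [GenotypeMatrix-class].
#' @examples
#' m <- genotypeMatrix(rbind(s1 = c("-", "T"), s2 = c("A", "N")),
#'                     positions = c(100L, 250L), ref = c("G", "C"),
#'                     alt = c("A", "T"))
#' carrierCount(m)
#' @export
genotypeMatrix <- function(calls, positions, ref, alt) {
  colnames(calls) <- as.character(positions)
  new("GenotypeMatrix", calls = calls,
      loci = S4Vectors::DataFrame(position = as.integer(positions),
                                  ref = as.character(ref),
                                  alt = as.character(alt)))
}

#' @describeIn genotypeMatrix locus table (position, ref, alt).
#' @param x a `GenotypeMatrix`.
#' @export
loci <- function(x) x@loci

#' @describeIn genotypeMatrix raw cell matrix.
#' @export
genotypeCalls <- function(x) x@calls

#' @describeIn genotypeMatrix locus positions.
#' @export
positions <- function(x) x@loci$position

#' @describeIn genotypeMatrix sample identifiers.
#' @export
sampleIds <- function(x) rownames(x@calls)

setMethod("dim", "GenotypeMatrix", function(x) dim(x@calls))

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix: ", nrow(object@calls), " samples x ",
      ncol(object@calls), " loci\n", sep = "")
  if (ncol(object@calls)) {
    p <- object@loci$position
    cat("  positions ", p[1L], "..", p[length(p)], "\n", sep = "")
  }
  if (nrow(object@calls)) {
    n <- min(4L, nrow(object@calls))
    for (i in seq_len(n))
      cat("  ", format(rownames(object@calls)[i], width = 12), " ",
          paste(object@calls[i, seq_len(min(24L, ncol(object@calls)))],
                collapse = ""),
          if (ncol(object@calls) > 24L) "..." else "", "\n", sep = "")
    if (nrow(object@calls) > n) cat("  ...\n")
  }
})

#' @export
#' @describeIn genotypeMatrix subset samples (i) and/or loci (j).
#' @param i,j,...,drop subsetting indices (drop is ignored).
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@calls))
  if (missing(j)) j <- seq_len(ncol(x@calls))
  genotypeMatrix(x@calls[i, j, drop = FALSE],
                 x@loci$position[j], x@loci$ref[j], x@loci$alt[j])
})

#' Pedigree of a controlled-cross progeny trial
#'
#' Records each progeny's recorded mother and father clone, and the sampled
#' ramets (clonal copies) available for each parental clone.  Clones with no
#' sampled ramet (e.g. a missing tester male) are legal; progeny of such
#' clones can only be classified against the remaining candidates.
#'
#' @slot progeny data.frame with columns `progenyId`, `mother`, `father`.
#' @slot ramets named list mapping clone id to the character vector of sample
#'   ids (ramets) genotyped for that clone; may be empty for unsampled clones.
#' @seealso [pedigree()], [classifyPedigree()]
#' @exportClass Pedigree
setClass("Pedigree",
  representation(progeny = "data.frame", ramets = "list"))

setValidity("Pedigree", function(object) {
  msg <- character()
  p <- object@progeny
  if (!all(c("progenyId", "mother", "father") %in% colnames(p)))
    msg <- c(msg, "'progeny' needs columns progenyId, mother, father")
  else if (anyDuplicated(p$progenyId))
    msg <- c(msg, "duplicated progeny ids")
  if (length(object@ramets) && is.null(names(object@ramets)))
    msg <- c(msg, "'ramets' must be a named list (clone -> sample ids)")
  if (length(msg)) msg else TRUE
})

#' Construct a Pedigree
#'
#' @param progeny data.frame with columns `progenyId`, `mother`, `father`.
#' @param ramets named list clone id -> sample ids; by default every clone
#'   named in `progeny` is assumed sampled as a single ramet whose sample id
#'   equals the clone id.
#' @return a [Pedigree-class].
#' @examples
#' ped <- pedigree(data.frame(progenyId = "p1", mother = "M1", father = "F1"))
#' sampledClones(ped)
#' @export
pedigree <- function(progeny, ramets = NULL) {
  progeny <- as.data.frame(progeny, stringsAsFactors = FALSE)
  if (is.null(ramets)) {
    clones <- unique(c(progeny$mother, progeny$father))
    ramets <- setNames(as.list(clones), clones)
  }
  new("Pedigree", progeny = progeny, ramets = ramets)
}

#' @describeIn pedigree progeny records.
#' @param x a `Pedigree`.
#' @export
progenyTable <- function(x) x@progeny

#' @describeIn pedigree clone -> ramet sample-id mapping.
#' @export
cloneRamets <- function(x) x@ramets

#' @describeIn pedigree ids of clones with at least one sampled ramet.
#' @export
sampledClones <- function(x) names(x@ramets)[lengths(x@ramets) > 0L]

setMethod("show", "Pedigree", function(object) {
  cat("Pedigree: ", nrow(object@progeny), " progeny, ",
      length(unique(object@progeny$mother)), " mothers x ",
      length(unique(object@progeny$father)), " fathers; ",
      length(sampledClones(object)), "/", length(object@ramets),
      " clones sampled\n", sep = "")
})
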