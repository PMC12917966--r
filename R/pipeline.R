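# End-to-end pipeline: simulate (or load) alignments, call SNPs per sample,
# assemble and filter the genotype matrix, classify progeny, build the tree.

#' Pipeline configuration
#'
#' Collects every path and threshold of a pipeline run in one validated
#' list.  Thresholds default to the package-wide filter set (depth >= 3,
#' MAPQ >= 20, base quality >= 20, homoplasmy >= 0.9, MAF >= 0.05, >= 3
#' carriers, 0 mismatches for a parentage match).  Configurations serialise
#' losslessly to JSON via [jsonlite].
#'
#' @param outDir output directory for the run.
#' @param simulate optional list of [simulationConfig()] arguments; when
#'   present the pipeline generates its own reference, pedigree and reads.
#' @param refPath,samDir,pedigreePath,annotationPath input paths used when
#'   not simulating (`samDir` holds one `<sample>.sam` per sample).
#' @param minDepth,minMapq,minBaseq,homoplasmy,mafMin,minCarriers,maxMismatch
#'   thresholds.
#' @param nPolicy missing-data policy.
#' @param bootstrapReps NJ bootstrap replicates (0 to skip supports).
#' @param seed integer seed for simulation and bootstrap.
#' @return a list of class `cpkinConfig`.
#' @export
pipelineConfig <- function(outDir, simulate = NULL, refPath = NULL,
                           samDir = NULL, pedigreePath = NULL,
                           annotationPath = NULL,
                           minDepth = 3L, minMapq = 20L, minBaseq = 20L,
                           homoplasmy = 0.9, mafMin = 0.05,
                           minCarriers = 3L, maxMismatch = 0L,
                           nPolicy = "AS_REFERENCE",
                           bootstrapReps = 100L, seed = 1L) {
  stopifnot(minDepth >= 1L, minMapq >= 0L, minBaseq >= 0L,
            homoplasmy > 0.5, homoplasmy <= 1,
            mafMin >= 0, mafMin <= 0.5, minCarriers >= 0L,
            maxMismatch >= 0L, bootstrapReps >= 0L)
  nPolicy <- match.arg(nPolicy, c("AS_REFERENCE", "PAIRWISE_DELETE"))
  structure(list(outDir = outDir, simulate = simulate, refPath = refPath,
                 samDir = samDir, pedigreePath = pedigreePath,
                 annotationPath = annotationPath, minDepth = minDepth,
                 minMapq = minMapq, minBaseq = minBaseq,
                 homoplasmy = homoplasmy, mafMin = mafMin,
                 minCarriers = minCarriers, maxMismatch = maxMismatch,
                 nPolicy = nPolicy, bootstrapReps = bootstrapReps,
                 seed = as.integer(seed)),
            class = "cpkinConfig")
}

#' @rdname pipelineConfig
#' @param path JSON file written by [writePipelineConfig()].
#' @export
readPipelineConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$outDir <- cfg$outDir %||% dirname(path)
  do.call(pipelineConfig, cfg)
}

#' @rdname pipelineConfig
#' @param config a `cpkinConfig`.
#' @export
writePipelineConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.log <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  writeLines(msg, con)
  message(msg)
}

#' Run the full chloroplast-kinship pipeline
#'
#' Stages: (1) simulate a cohort (reference, parental haplotypes, crosses
#' with the configured contamination/leakage/mutation rates, paired-end
#' reads per sample) or load existing SAM inputs; (2) call homoplasmic SNPs
#' per sample with the configured filters; (3) assemble the genotype
#' matrix, apply MAF/carrier filtering, write TSV and VCF; (4) classify
#' every progeny's inheritance mode and test observed discordance against
#' the 1% leakage null; (5) build the NJ tree with bootstrap supports.
#' Every output lands in `outDir`; re-running the same configuration
#' reproduces identical files (the log carries a JSON dump of the applied
#' configuration).
#'
#' @param config a [pipelineConfig()] (or path to its JSON form).
#' @return invisibly, a list with the run's `matrix`, `filtered` matrix,
#'   `report` (match report), `leakage`, `tree`, `coverage`, `truth` (when
#'   simulated) and `outDir`.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "cpkinConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  logCon <- file(file.path(config$outDir, "run.log"), "w")
  on.exit(close(logCon))
  .log(logCon, "config: ",
       jsonlite::toJSON(unclass(config), auto_unbox = TRUE, null = "null"))
  truth <- NULL
  if (!is.null(config$simulate)) {
    simArgs <- config$simulate
    simArgs$seed <- simArgs$seed %||% config$seed
    nProgeny <- simArgs$nProgeny          # optional: sample the factorial
    simArgs$nProgeny <- NULL
    scfg <- do.call(simulationConfig, simArgs)
    .log(logCon, "simulating cohort (seed ", scfg@seed, ")")
    ref <- simulateReference(scfg@genomeLength, seed = scfg@seed)
    ped <- simulatePedigree(scfg@nMothers, scfg@nFathers,
                            scfg@nProgenyPerCross, nProgeny = nProgeny,
                            seed = scfg@seed)
    parents <- simulateParents(ref, length(sampledClones(ped)),
                               scfg@nPolymorphicSites, seed = scfg@seed + 1L,
                               ids = sampledClones(ped))
    sim <- simulateCross(parents, ped, scfg, seed = scfg@seed + 2L)
    truth <- sim$truth
    samDir <- file.path(config$outDir, "sam")
    dir.create(samDir, showWarnings = FALSE)
    hapOwners <- rbind(genotypeCalls(parents), genotypeCalls(sim$progeny))
    hapMat <- genotypeMatrix(hapOwners, positions(parents),
                             loci(parents)$ref, loci(parents)$alt)
    for (i in seq_len(nrow(hapOwners))) {
      s <- rownames(hapOwners)[i]
      rd <- simulateReads(haplotypeSequence(ref, hapMat, s), ref, scfg,
                          sample = s, seed = scfg@seed + 100L + i)
      writeSam(rd, ref, file.path(samDir, paste0(s, ".sam")))
    }
    writeXStringSet(DNAStringSet(setNames(refSequence(ref), refId(ref))),
                    file.path(config$outDir, "reference.fasta"))
    write.table(progenyTable(ped),
                file.path(config$outDir, "pedigree.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(truth),
                file.path(config$outDir, "truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    config$samDir <- samDir
  } else {
    if (is.null(config$refPath) || !file.exists(config$refPath))
      stop("missing input: refPath (", config$refPath %||% "NULL", ")")
    if (is.null(config$samDir) || !dir.exists(config$samDir))
      stop("missing input: samDir (", config$samDir %||% "NULL", ")")
    if (is.null(config$pedigreePath) || !file.exists(config$pedigreePath))
      stop("missing input: pedigreePath (",
           config$pedigreePath %||% "NULL", ")")
    seqs <- readDNAStringSet(config$refPath)
    ref <- referenceGenome(as.character(seqs[[1L]]),
                           id = sub("\\s.*", "", names(seqs)[1L]))
    ped <- readPedigree(config$pedigreePath)
  }
  samFiles <- list.files(config$samDir, pattern = "\\.sam$",
                         full.names = TRUE)
  if (!length(samFiles)) stop("no SAM files found in ", config$samDir)
  .log(logCon, "calling SNPs in ", length(samFiles), " samples ",
       "(min depth ", config$minDepth, ", MAPQ >= ", config$minMapq,
       ", baseQ >= ", config$minBaseq, ", homoplasmy >= ",
       config$homoplasmy, ")")
  callsList <- list(); covList <- list()
  for (f in samFiles) {
    s <- sub("\\.sam$", "", basename(f))
    res <- callSample(f, ref, minMapq = config$minMapq,
                      minBaseq = config$minBaseq,
                      minDepth = config$minDepth,
                      homoplasmy = config$homoplasmy, sample = s)
    callsList[[s]] <- res$calls
    covList[[s]] <- res$coverage
  }
  coverage <- do.call(rbind, covList)
  write.table(coverage, file.path(config$outDir, "coverage.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  mat <- buildMatrix(callsList, ref = ref, onMultiallelic = "drop")
  .log(logCon, "matrix: ", nrow(genotypeCalls(mat)), " samples x ",
       length(positions(mat)), " loci before filtering")
  filt <- filterLoci(mat, mafMin = config$mafMin,
                     minCarriers = config$minCarriers,
                     nPolicy = config$nPolicy)
  .log(logCon, "filtered matrix: ", length(positions(filt)),
       " loci (MAF >= ", config$mafMin, ", >= ", config$minCarriers,
       " carriers)")
  writeGenotypeMatrix(mat, file.path(config$outDir, "matrix_all.tsv"))
  writeGenotypeMatrix(filt, file.path(config$outDir, "matrix.tsv"))
  writeGenotypeVcf(filt, file.path(config$outDir, "genotypes.vcf"),
                   contig = refId(ref), contigLength = refLength(ref))
  annSummary <- NULL
  if (!is.null(config$annotationPath)) {
    ann <- readGeneAnnotation(config$annotationPath, contig = refId(ref))
    annSummary <- summarizeAnnotation(filt, ann,
                                      genomeLength = refLength(ref))
    .log(logCon, "annotation: ", annSummary$nGenic, " genic / ",
         annSummary$nIntergenic, " intergenic loci")
  }
  report <- classifyPedigree(ped, filt, nPolicy = config$nPolicy,
                             maxMismatch = config$maxMismatch)
  write.table(as.data.frame(report),
              file.path(config$outDir, "match_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  nDisc <- sum(report$mode != "PATERNAL_MATCH")
  leak <- leakageTest(nDisc, nrow(report))
  .log(logCon, "parentage: ", nDisc, "/", nrow(report),
       " progeny discordant with the recorded father (exact binomial vs ",
       "1% leakage: p = ", format(leak$pValue, digits = 3), ")")
  tree <- NULL
  if (nrow(genotypeCalls(filt)) >= 3L && length(positions(filt)) >= 1L) {
    tree <- if (config$bootstrapReps > 0L)
      bootstrapSupport(filt, nReps = config$bootstrapReps,
                       seed = config$seed, nPolicy = config$nPolicy)
    else njTree(distanceMatrix(filt, nPolicy = config$nPolicy))
    writeNewick(tree, file.path(config$outDir, "tree.nwk"))
  }
  summary <- list(
    nSamples = nrow(genotypeCalls(mat)),
    nLociAll = length(positions(mat)),
    nLociFiltered = length(positions(filt)),
    meanDepth = mean(coverage$meanDepth),
    meanBreadth1x = mean(coverage$breadth1x),
    modes = as.list(table(report$mode)),
    discordantFraction = leak$observedFraction,
    leakagePValue = leak$pValue,
    seed = config$seed)
  jsonlite::write_json(summary, file.path(config$outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  .log(logCon, "done")
  invisible(list(matrix = mat, filtered = filt, report = report,
                 leakage = leak, tree = tree, coverage = coverage,
                 truth = truth, annotation = annSummary,
                 outDir = config$outDir))
}
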