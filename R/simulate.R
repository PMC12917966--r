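# Synthetic-pedigree generator: reference, parental haplotypes, crosses with
# known-truth transmission events, and paired-end reads in SAM format.

# Run code under a private RNG stream so library functions taking an explicit
# seed neither depend on nor disturb the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Simulate a reference chloroplast genome
#'
#' Draws a uniform-composition A/C/G/T sequence of the requested length,
#' standing in for a real chloroplast reference so that all downstream
#' coordinates (1-based, forward strand) behave exactly as they would against
#' a published genome.
#'
#' @param length genome length in bp (>= 1000; chloroplasts are ~120-160 kb).
#' @param seed integer seed; the same seed always yields the same sequence.
#' @param id contig name.
#' @param circular logical, stored on the object.
#' @return a [ReferenceGenome-class].
#' @examples
#' ref <- simulateReference(2000, seed = 1)
#' ref
#' @export
simulateReference <- function(length = 121000L, seed = 1L,
                              id = "cpgenome", circular = TRUE) {
  length <- as.integer(length)
  if (is.na(length) || length < 1000L)
    stop("'length' must be an integer >= 1000")
  seq <- .withSeed(seed,
    paste(sample(.CP_BASES, length, replace = TRUE), collapse = ""))
  referenceGenome(seq, id = id, circular = circular)
}

# random base different from 'base' (vectorised)
.mutateBases <- function(base) {
  alt <- vapply(base, function(b) sample(setdiff(.CP_BASES, b), 1L), "")
  unname(alt)
}

#' Simulate parental chloroplast haplotypes
#'
#' Chooses `nSites` distinct positions on the reference, assigns one
#' alternative base to each (biallelic substitutions only), and gives every
#' parent the alternative allele at each site with probability
#' `carrierProb`.  The result is a [GenotypeMatrix-class] whose rows are the
#' parental clones.
#'
#' @param ref a [ReferenceGenome-class].
#' @param nParents number of parental clones (named `P01`, `P02`, ... unless
#'   `ids` is given).
#' @param nSites number of polymorphic sites (< genome length).
#' @param seed integer seed.
#' @param ids optional parent clone ids.
#' @param carrierProb per-site probability that a parent carries the
#'   alternative allele.
#' @return a `GenotypeMatrix` of parental haplotypes.
#' @examples
#' ref <- simulateReference(2000, seed = 1)
#' par <- simulateParents(ref, nParents = 4, nSites = 10, seed = 2)
#' genotypeCalls(par)
#' @export
simulateParents <- function(ref, nParents, nSites, seed = 1L, ids = NULL,
                            carrierProb = 0.5) {
  stopifnot(is(ref, "ReferenceGenome"))
  nParents <- as.integer(nParents); nSites <- as.integer(nSites)
  if (nParents < 1L) stop("'nParents' must be >= 1")
  if (nSites < 0L || nSites >= refLength(ref))
    stop("'nSites' must satisfy 0 <= nSites < genome length")
  if (is.null(ids)) ids <- sprintf("P%02d", seq_len(nParents))
  stopifnot(length(ids) == nParents, !anyDuplicated(ids))
  .withSeed(seed, {
    pos <- sort(sample.int(refLength(ref), nSites))
    refBase <- if (nSites) substring(refSequence(ref), pos, pos) else character()
    altBase <- if (nSites) .mutateBases(refBase) else character()
    cells <- matrix("-", nParents, nSites, dimnames = list(ids, NULL))
    if (nSites)
      for (j in seq_len(nSites)) {
        hit <- runif(nParents) < carrierProb
        cells[hit, j] <- altBase[j]
      }
    genotypeMatrix(cells, pos, refBase, altBase)
  })
}

#' Materialise the full genome sequence of one haplotype row
#'
#' Applies a sample's substitutions (its non-`"-"`, non-`"N"` cells) to the
#' reference sequence; `"N"` cells fall back to the reference base.
#'
#' @param ref a [ReferenceGenome-class].
#' @param gmat a [GenotypeMatrix-class] with positions on `ref`.
#' @param sample sample id (row of `gmat`).
#' @return a character string of length `refLength(ref)`.
#' @export
haplotypeSequence <- function(ref, gmat, sample) {
  stopifnot(sample %in% sampleIds(gmat))
  seq <- refSequence(ref)
  row <- genotypeCalls(gmat)[sample, ]
  sub <- which(!(row %in% c("-", "N")))
  for (j in sub)
    substr(seq, positions(gmat)[j], positions(gmat)[j]) <- row[j]
  seq
}

#' Build a full-factorial tester-design pedigree
#'
#' Crosses every mother with every father (`nProgenyPerCross` progeny each),
#' or samples `nProgeny` crosses at random from the factorial.  Progeny ids
#' follow the `F<father>_M<mother>_<k>` labelling convention used for
#' tester-design trials (see [parseSampleLabel()]).
#'
#' @param nMothers,nFathers numbers of parental clones (named `M01`.., `F01`..).
#' @param nProgenyPerCross progeny per combination (full factorial).
#' @param nProgeny optional total progeny count; crosses are then drawn with
#'   replacement from the factorial instead.
#' @param seed used only when `nProgeny` is given.
#' @return a [Pedigree-class] (one ramet per clone, sample id = clone id).
#' @examples
#' simulatePedigree(3, 2)
#' @export
simulatePedigree <- function(nMothers = 9L, nFathers = 5L,
                             nProgenyPerCross = 1L, nProgeny = NULL,
                             seed = 1L) {
  mothers <- sprintf("M%02d", seq_len(nMothers))
  fathers <- sprintf("F%02d", seq_len(nFathers))
  grid <- expand.grid(mother = mothers, father = fathers,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (is.null(nProgeny)) {
    grid <- grid[rep(seq_len(nrow(grid)), each = nProgenyPerCross), ]
    k <- sequence(rep(nProgenyPerCross, nrow(grid) / nProgenyPerCross))
  } else {
    idx <- .withSeed(seed, sample.int(nrow(grid), nProgeny, replace = TRUE))
    grid <- grid[idx, ]
    k <- stats::ave(seq_len(nrow(grid)),
                    paste(grid$mother, grid$father), FUN = seq_along)
  }
  progeny <- data.frame(
    progenyId = sprintf("%s_%s_%d", sub("^F", "F", grid$father),
                        sub("^M", "M", grid$mother), k),
    mother = grid$mother, father = grid$father,
    stringsAsFactors = FALSE)
  pedigree(progeny)
}

#' Simulate chloroplast transmission through a pedigree
#'
#' Each progeny inherits the complete chloroplast haplotype of a single
#' donor: its recorded father (probability `1 - contaminationRate -
#' leakageRate`), its mother (`leakageRate`, maternal leakage), or a random
#' member of an internally generated pool of unsampled external pollen donors
#' (`contaminationRate`, pollen contamination).  The inherited haplotype is
#' then perturbed by `Poisson(deNovoMu * genomeLength * generationYears)`
#' de novo substitutions at uniform positions; only those falling on panel
#' sites are visible in the returned matrix, but all are recorded in the
#' truth table.
#'
#' @param parents a [GenotypeMatrix-class] of parental haplotypes containing
#'   every clone named in the pedigree.
#' @param ped a [Pedigree-class]; must be non-empty.
#' @param config a [SimulationConfig-class] (rates, mutation model, pool size).
#' @param seed integer seed; defaults to the config's seed.
#' @return a list with elements
#'   \describe{
#'     \item{progeny}{`GenotypeMatrix` of progeny haplotypes (panel sites).}
#'     \item{truth}{[S4Vectors::DataFrame] with `progenyId`, `recordedMother`,
#'       `recordedFather`, `trueDonor`, `event` (one of `PATERNAL`, `LEAKAGE`,
#'       `CONTAMINATION`) and `deNovoPositions` (comma-separated 1-based
#'       sites, `""` if none).}
#'     \item{external}{`GenotypeMatrix` of the external donor pool.}
#'   }
#' @examples
#' ref <- simulateReference(2000, seed = 1)
#' cfg <- simulationConfig(nMothers = 2, nFathers = 2, genomeLength = 2000,
#'                         nPolymorphicSites = 8, contaminationRate = 0)
#' ped <- simulatePedigree(2, 2)
#' par <- simulateParents(ref, 4, 8, seed = 3,
#'                        ids = c(sampledClones(ped)))
#' sim <- simulateCross(par, ped, cfg, seed = 4)
#' sim$truth$event
#' @export
simulateCross <- function(parents, ped, config, seed = config@seed) {
  stopifnot(is(parents, "GenotypeMatrix"), is(ped, "Pedigree"),
            is(config, "SimulationConfig"))
  prog <- progenyTable(ped)
  if (nrow(prog) == 0L) stop("empty pedigree")
  need <- unique(c(prog$mother, prog$father))
  missing <- setdiff(need, sampleIds(parents))
  if (length(missing))
    stop("pedigree parents absent from 'parents': ",
         paste(missing, collapse = ", "))
  L <- config@genomeLength
  lambda <- config@deNovoMu * L * config@generationYears
  pos <- positions(parents)
  refB <- loci(parents)$ref
  altB <- loci(parents)$alt
  .withSeed(seed, {
    # external pool: haplotypes over the same sites, distinct from all parents
    ext <- matrix("-", config@nExternal, length(pos),
                  dimnames = list(sprintf("EXT%02d", seq_len(config@nExternal)),
                                  NULL))
    parentCells <- genotypeCalls(parents)
    for (i in seq_len(config@nExternal)) {
      for (try in seq_len(100L)) {
        h <- ifelse(runif(length(pos)) < 0.5, altB, "-")
        h[is.na(h)] <- "-"
        clash <- any(apply(parentCells, 1L, function(r) all(r == h))) ||
          (i > 1L && any(apply(ext[seq_len(i - 1L), , drop = FALSE], 1L,
                               function(r) all(r == h))))
        if (!clash || length(pos) == 0L) break
      }
      ext[i, ] <- h
    }
    u <- runif(nrow(prog))
    event <- ifelse(u < config@contaminationRate, "CONTAMINATION",
             ifelse(u < config@contaminationRate + config@leakageRate,
                    "LEAKAGE", "PATERNAL"))
    donor <- character(nrow(prog))
    cells <- matrix("-", nrow(prog), length(pos),
                    dimnames = list(prog$progenyId, NULL))
    deNovo <- character(nrow(prog))
    for (i in seq_len(nrow(prog))) {
      donor[i] <- switch(event[i],
        PATERNAL = prog$father[i],
        LEAKAGE = prog$mother[i],
        CONTAMINATION = sample(rownames(ext), 1L))
      cells[i, ] <- if (event[i] == "CONTAMINATION") ext[donor[i], ]
                    else parentCells[donor[i], ]
      k <- rpois(1L, lambda)
      if (k > 0L) {
        mutPos <- sample.int(L, k)
        deNovo[i] <- paste(sort(mutPos), collapse = ",")
        onPanel <- match(mutPos, pos)
        for (j in onPanel[!is.na(onPanel)]) {
          cur <- if (cells[i, j] %in% c("-", "N")) refB[j] else cells[i, j]
          cells[i, j] <- .mutateBases(cur)
          if (cells[i, j] == refB[j]) cells[i, j] <- "-"
        }
      }
    }
    truth <- S4Vectors::DataFrame(
      progenyId = prog$progenyId, recordedMother = prog$mother,
      recordedFather = prog$father,
      trueDonor = ifelse(event == "CONTAMINATION", "EXTERNAL", donor),
      externalDonor = ifelse(event == "CONTAMINATION", donor, NA_character_),
      event = event, deNovoPositions = deNovo)
    list(progeny = genotypeMatrix(cells, pos, refB, altB),
         truth = truth,
         external = genotypeMatrix(ext, pos, refB, altB))
  })
}

#' Simulate aligned paired-end reads from one haplotype
#'
#' Draws read pairs at uniform fragment positions (reads never span the
#' circular origin), introduces independent per-base sequencing errors and a
#' configurable fraction of sub-Q20 base qualities, and marks a configurable
#' fraction of pairs as low-MAPQ / not-properly-paired so that downstream
#' read filters have something to remove.  Mates are emitted as forward-
#' strand SEQ fields with correct 1-based POS, CIGAR `<len>M`, and FLAG bits
#' for pairing, strand and proper-pair status.
#'
#' @param haplotype full-length haplotype sequence (character), e.g. from
#'   [haplotypeSequence()].
#' @param ref a [ReferenceGenome-class] (supplies contig name and length).
#' @param config a [SimulationConfig-class]; `depthMean`, `readLength`,
#'   `insertSize`, `baseErrorRate`, `fracLowMapq` and `fracLowBaseq` are used.
#' @param sample sample id used as the read-name prefix.
#' @param seed integer seed.
#' @return a data.frame of SAM records (qname, flag, rname, pos, mapq, cigar,
#'   rnext, pnext, tlen, seq, qual), sorted by position.
#' @seealso [writeSam()]
#' @examples
#' ref <- simulateReference(2000, seed = 1)
#' cfg <- simulationConfig(genomeLength = 2000, depthMean = 5,
#'                         readLength = 100, insertSize = 300)
#' rd <- simulateReads(refSequence(ref), ref, cfg, sample = "s1", seed = 7)
#' head(rd$pos)
#' @export
simulateReads <- function(haplotype, ref, config, sample = "sample",
                          seed = config@seed) {
  stopifnot(is(ref, "ReferenceGenome"), is(config, "SimulationConfig"))
  L <- refLength(ref)
  rl <- config@readLength
  ins <- config@insertSize
  if (rl > L) stop("'readLength' exceeds the reference length")
  if (ins > L) stop("'insertSize' exceeds the reference length")
  stopifnot(nchar(haplotype) == L)
  .withSeed(seed, {
    nPairs <- max(1L, rpois(1L, config@depthMean * L / (2 * rl)))
    start1 <- sample.int(L - ins + 1L, nPairs, replace = TRUE)
    start2 <- start1 + ins - rl
    lowq <- runif(nPairs) < config@fracLowMapq
    qname <- sprintf("%s_r%06d", sample, seq_len(nPairs))
    rec <- function(pos, mate, flagOK, flagBad) {
      seqs <- substring(haplotype, pos, pos + rl - 1L)
      n <- nPairs * rl
      chars <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
      err <- which(runif(n) < config@baseErrorRate)
      if (length(err)) chars[err] <- .mutateBases(chars[err])
      q <- rep("I", n)                     # Q40
      low <- which(runif(n) < config@fracLowBaseq)
      q[low] <- "0"                        # Q15, below the Q20 filter
      dim(chars) <- dim(q) <- c(rl, nPairs)
      data.frame(
        qname = qname,
        flag = ifelse(lowq, flagBad, flagOK),
        rname = refId(ref), pos = pos,
        mapq = ifelse(lowq, 10L, 60L),
        cigar = paste0(rl, "M"), rnext = "=", pnext = mate,
        tlen = ifelse(mate >= pos, ins, -ins),
        seq = apply(chars, 2L, paste, collapse = ""),
        qual = apply(q, 2L, paste, collapse = ""),
        stringsAsFactors = FALSE)
    }
    # 99/147: paired, proper, mate-reverse/reverse, first/second in pair
    # 97/145: same but without the proper-pair bit
    out <- rbind(rec(start1, start2, 99L, 97L),
                 rec(start2, start1, 147L, 145L))
    out[order(out$pos, out$qname), , drop = FALSE]
  })
}

#' Write SAM records to a file
#'
#' Emits a minimal valid SAM: `@HD`/`@SQ` header lines followed by the
#' 11 mandatory fields of each record.
#'
#' @param reads data.frame as produced by [simulateReads()].
#' @param ref a [ReferenceGenome-class] for the `@SQ` line.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSam <- function(reads, ref, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", refId(ref), "\tLN:", refLength(ref)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                  reads$qname, reads$flag, reads$rname, reads$pos,
                  reads$mapq, reads$cigar, reads$rnext, reads$pnext,
                  reads$tlen, reads$seq, reads$qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}
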