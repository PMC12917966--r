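# Haplotype matching and inheritance-mode classification.
#
# The transmission model: under strictly paternal chloroplast inheritance a
# progeny's haplotype is identical to its pollen parent's, so any candidate
# at mismatch distance 0 (over compared loci) "matches".  Missing genotypes
# are treated as the reference state before comparison (the AS_REFERENCE
# policy), which makes every locus comparable at the cost of masking
# mismatches that hide behind an N.

.applyPolicy <- function(row, nPolicy) {
  if (nPolicy == "AS_REFERENCE") row[row == "N"] <- "-"
  row
}

#' Mismatch distance between two haplotype rows
#'
#' Counts loci at which two rows differ.  Under `AS_REFERENCE` every `"N"`
#' is first replaced by the reference state `"-"`, so all loci are compared;
#' under `PAIRWISE_DELETE` loci where either row is `"N"` are skipped.  Loci
#' where either row is `NA` (e.g. masked ramet conflicts) are always
#' skipped.  The distance is symmetric and zero on identical rows.
#'
#' @param rowA,rowB character vectors of cells over the same loci.
#' @param nPolicy `"AS_REFERENCE"` (default) or `"PAIRWISE_DELETE"`.
#' @return named numeric vector `c(nCompared, nMismatch)`.
#' @examples
#' haplotypeDistance(c("-", "T", "N"), c("-", "-", "-"))  # 1 mismatch of 3
#' @export
haplotypeDistance <- function(rowA, rowB,
                              nPolicy = c("AS_REFERENCE",
                                          "PAIRWISE_DELETE")) {
  nPolicy <- match.arg(nPolicy)
  if (length(rowA) != length(rowB))
    stop("incompatible matrices: rows cover different locus sets")
  keep <- !is.na(rowA) & !is.na(rowB)
  a <- .applyPolicy(rowA[keep], nPolicy)
  b <- .applyPolicy(rowB[keep], nPolicy)
  if (nPolicy == "PAIRWISE_DELETE") {
    ok <- a != "N" & b != "N"
    a <- a[ok]; b <- b[ok]
  }
  c(nCompared = length(a), nMismatch = sum(a != b))
}

#' Consensus haplotype of a clone's ramets
#'
#' Ramets of one clone are clonal copies and should be genetically
#' identical; genotyping error or mislabelling shows up as inter-ramet
#' conflicts.  The consensus takes the per-locus majority state across
#' ramets (after applying the missing-data policy); loci with a tied or
#' conflicting majority are set to `NA` so they are excluded from that
#' clone's comparisons.
#'
#' @param clone clone id.
#' @param x a [GenotypeMatrix-class] containing the clone's ramets.
#' @param ped a [Pedigree-class] mapping clones to ramet sample ids.
#' @param nPolicy missing-data policy.
#' @return character vector (one cell per locus, `NA` at conflicts) with the
#'   conflicting positions as attribute `"conflicts"`.
#' @export
cloneConsensus <- function(clone, x, ped,
                           nPolicy = c("AS_REFERENCE", "PAIRWISE_DELETE")) {
  nPolicy <- match.arg(nPolicy)
  ram <- intersect(cloneRamets(ped)[[clone]], sampleIds(x))
  if (!length(ram)) stop("clone ", clone, " has no genotyped ramet")
  cells <- genotypeCalls(x)[ram, , drop = FALSE]
  cells <- t(apply(cells, 1L, .applyPolicy, nPolicy = nPolicy))
  cons <- apply(cells, 2L, function(col) {
    tb <- sort(table(col), decreasing = TRUE)
    if (length(tb) == 1L) return(names(tb)[1L])
    if (tb[1L] > tb[2L]) names(tb)[1L] else NA_character_
  })
  conflicts <- which(apply(cells, 2L, function(col) length(unique(col)) > 1L))
  attr(cons, "conflicts") <- positions(x)[conflicts]
  cons
}

#' Report inter-ramet conflicts for a clone
#'
#' @inheritParams cloneConsensus
#' @return data.frame with one row per conflicting locus: `position` and one
#'   column per ramet with its cell; zero rows when all ramets agree.
#' @export
rametConsistency <- function(clone, x, ped,
                             nPolicy = c("AS_REFERENCE",
                                         "PAIRWISE_DELETE")) {
  nPolicy <- match.arg(nPolicy)
  ram <- intersect(cloneRamets(ped)[[clone]], sampleIds(x))
  if (length(ram) < 2L)
    stop("clone ", clone, " has fewer than two genotyped ramets")
  cells <- genotypeCalls(x)[ram, , drop = FALSE]
  pol <- t(apply(cells, 1L, .applyPolicy, nPolicy = nPolicy))
  bad <- which(apply(pol, 2L, function(col) length(unique(col)) > 1L))
  out <- data.frame(position = positions(x)[bad])
  for (r in ram) out[[r]] <- cells[r, bad]
  out
}

#' Classify one progeny's inheritance mode
#'
#' Compares the progeny's haplotype with the consensus haplotype of every
#' sampled parental clone and classifies, in order of precedence:
#' \describe{
#'   \item{PATERNAL_MATCH}{distance <= `maxMismatch` to the recorded father
#'     -- the expected outcome under paternal inheritance.}
#'   \item{MATERNAL_MATCH}{matches the recorded mother instead: candidate
#'     maternal leakage.}
#'   \item{ALTERNATE_FATHER}{matches exactly one other sampled clone: the
#'     recorded cross is doubtful and that clone is the probable pollen
#'     donor.}
#'   \item{AMBIGUOUS}{matches two or more other clones (tie set reported).}
#'   \item{NOVEL}{matches nobody sampled: pollen contamination from an
#'     unsampled male (or an unsampled recorded father).}
#' }
#'
#' @param progenyId id of the progeny (row of `x`).
#' @param ped a [Pedigree-class].
#' @param x a [GenotypeMatrix-class] holding progeny and parent ramets.
#' @param nPolicy missing-data policy (see [haplotypeDistance()]).
#' @param maxMismatch mismatches tolerated in a "match" (default 0; raise it
#'   only with [expectedDeNovo()] in hand).
#' @return list with `progenyId`, `mode`, `assignedDonor` (clone id or
#'   `NA`), `tieSet`, and `distances` (data.frame clone/nCompared/nMismatch).
#' @export
classifyProgeny <- function(progenyId, ped, x,
                            nPolicy = c("AS_REFERENCE", "PAIRWISE_DELETE"),
                            maxMismatch = 0L) {
  nPolicy <- match.arg(nPolicy)
  if (!progenyId %in% sampleIds(x))
    stop("progeny ", progenyId, " not found in the genotype matrix")
  prog <- progenyTable(ped)
  rec <- prog[prog$progenyId == progenyId, ]
  if (nrow(rec) != 1L)
    stop("progeny ", progenyId, " not found in the pedigree")
  clones <- sampledClones(ped)
  clones <- clones[vapply(clones, function(cl)
    length(intersect(cloneRamets(ped)[[cl]], sampleIds(x))) > 0L,
    logical(1L))]
  if (!length(clones))
    stop("no sampled candidate clones available")
  row <- genotypeCalls(x)[progenyId, ]
  d <- t(vapply(clones, function(cl)
    haplotypeDistance(row, cloneConsensus(cl, x, ped, nPolicy), nPolicy),
    c(nCompared = 0, nMismatch = 0)))
  distances <- data.frame(clone = clones, nCompared = d[, 1L],
                          nMismatch = d[, 2L], row.names = NULL)
  hit <- distances$clone[distances$nMismatch <= maxMismatch]
  mode <- "NOVEL"; donor <- NA_character_; tie <- character()
  if (rec$father %in% hit) {
    mode <- "PATERNAL_MATCH"; donor <- rec$father
  } else if (rec$mother %in% hit) {
    mode <- "MATERNAL_MATCH"; donor <- rec$mother
  } else {
    others <- setdiff(hit, c(rec$father, rec$mother))
    if (length(others) == 1L) {
      mode <- "ALTERNATE_FATHER"; donor <- others
    } else if (length(others) > 1L) {
      mode <- "AMBIGUOUS"; tie <- others
    }
  }
  list(progenyId = progenyId, mode = mode, assignedDonor = donor,
       tieSet = tie, recordedMother = rec$mother, recordedFather = rec$father,
       distances = distances)
}

#' Classify every progeny of a pedigree
#'
#' Applies [classifyProgeny()] to all progeny present in the matrix and
#' returns a per-progeny match report.
#'
#' @inheritParams classifyProgeny
#' @return a [S4Vectors::DataFrame] with one row per progeny: `progenyId`,
#'   `recordedMother`, `recordedFather`, `mode`, `assignedDonor`, `tieSet`
#'   (comma-separated), `minDistance` and `distToFather` /`distToMother`
#'   (`NA` when that parent is unsampled).
#' @export
classifyPedigree <- function(ped, x,
                             nPolicy = c("AS_REFERENCE", "PAIRWISE_DELETE"),
                             maxMismatch = 0L) {
  nPolicy <- match.arg(nPolicy)
  prog <- progenyTable(ped)
  prog <- prog[prog$progenyId %in% sampleIds(x), , drop = FALSE]
  rows <- lapply(prog$progenyId, classifyProgeny, ped = ped, x = x,
                 nPolicy = nPolicy, maxMismatch = maxMismatch)
  getDist <- function(r, clone) {
    i <- match(clone, r$distances$clone)
    if (is.na(i)) NA_real_ else r$distances$nMismatch[i]
  }
  S4Vectors::DataFrame(
    progenyId = vapply(rows, `[[`, "", "progenyId"),
    recordedMother = vapply(rows, `[[`, "", "recordedMother"),
    recordedFather = vapply(rows, `[[`, "", "recordedFather"),
    mode = vapply(rows, `[[`, "", "mode"),
    assignedDonor = vapply(rows, `[[`, "", "assignedDonor"),
    tieSet = vapply(rows, function(r) paste(r$tieSet, collapse = ","), ""),
    minDistance = vapply(rows, function(r) min(r$distances$nMismatch), 0),
    distToFather = vapply(rows, function(r)
      getDist(r, r$recordedFather), 0),
    distToMother = vapply(rows, function(r)
      getDist(r, r$recordedMother), 0))
}

#' Within-family haplotype uniformity
#'
#' For progeny of an unsampled father, paternal inheritance predicts that
#' full sibs still share one haplotype even though it matches no sampled
#' clone.  Reports the pairwise distances among the given samples.
#'
#' @param sampleIdsVec progeny sample ids.
#' @param x a [GenotypeMatrix-class].
#' @param nPolicy missing-data policy.
#' @return list with `uniform` (logical), `maxDistance`, and the pairwise
#'   distance matrix.
#' @export
familyUniformity <- function(sampleIdsVec, x,
                             nPolicy = c("AS_REFERENCE",
                                         "PAIRWISE_DELETE")) {
  nPolicy <- match.arg(nPolicy)
  d <- distanceMatrix(x[match(sampleIdsVec, sampleIds(x)), ],
                      nPolicy = nPolicy)
  list(uniform = all(d == 0), maxDistance = max(d), distances = d)
}

#' Expected de novo chloroplast mutations per generation
#'
#' Mutation counts per transmitted haplotype are modelled as Poisson with
#' mean `mu * L * generationYears`.  For a pine chloroplast (`mu = 2e-10`
#' per site per year, `L = 121000` bp, 25-year generation) the expectation
#' is about `6e-4`, so even one de novo difference between parent and
#' offspring is rare and three or more are essentially impossible --
#' mismatch-based parentage exclusion is therefore safe.
#'
#' @param mu substitution rate, per site per year (> 0 unless exactly 0).
#' @param L haplotype length in bp.
#' @param generationYears generation time in years.
#' @param k report the probability of at least `k` mutations (default 1).
#' @return list with `expectedCount` (`mu * L * generationYears`) and `pGeK`
#'   (upper-tail Poisson probability of >= `k`).
#' @examples
#' expectedDeNovo(0.2e-9, 121000, 25)$expectedCount  # 6.05e-4
#' @export
expectedDeNovo <- function(mu, L, generationYears, k = 1L) {
  if (mu < 0 || L <= 0 || generationYears <= 0 || k < 0)
    stop("'mu' must be >= 0 and 'L', 'generationYears' positive")
  lambda <- mu * L * generationYears
  list(mu = mu, L = L, generationYears = generationYears,
       expectedCount = lambda,
       k = as.integer(k),
       pGeK = ppois(k - 1L, lambda, lower.tail = FALSE))
}

#' Exact binomial test for paternal leakage
#'
#' Tests whether the observed fraction of progeny discordant with their
#' recorded father exceeds a null leakage rate (organellar leakage in
#' conifers is typically reported at 1% or less).  The p-value is the exact
#' upper-tail binomial probability of at least `nDiscordant` events in
#' `nTotal` trials at the null rate; a small p-value says leakage alone
#' cannot plausibly explain the discordance, pointing to pollen
#' contamination instead.
#'
#' @param nDiscordant number of discordant progeny.
#' @param nTotal progeny tested (> 0).
#' @param leakageRateNull null leakage probability (default 0.01).
#' @return list with `nDiscordant`, `nTotal`, `observedFraction`,
#'   `leakageRateNull`, `pValue`.
#' @examples
#' leakageTest(9, 45)$observedFraction  # 0.2
#' @export
leakageTest <- function(nDiscordant, nTotal, leakageRateNull = 0.01) {
  if (nTotal <= 0) stop("'nTotal' must be positive")
  if (nDiscordant < 0 || nDiscordant > nTotal)
    stop("'nDiscordant' must lie in [0, nTotal]")
  p <- binom.test(nDiscordant, nTotal, p = leakageRateNull,
                  alternative = "greater")$p.value
  list(nDiscordant = as.integer(nDiscordant), nTotal = as.integer(nTotal),
       observedFraction = nDiscordant / nTotal,
       leakageRateNull = leakageRateNull, pValue = p)
}

#' Cell-level concordance between two genotype matrices
#'
#' Intersects the samples and loci of two matrices (e.g. short-read calls
#' versus Sanger re-genotyping) and computes agreement over cells that are
#' non-missing in both.  Every disagreement is listed.
#'
#' @param a,b [GenotypeMatrix-class] objects sharing samples and loci.
#' @return list with `overall` agreement fraction, `perSample`, `perLocus`,
#'   `nCompared`, and `disagreements` (data.frame sample/position/cellA/
#'   cellB).
#' @export
concordance <- function(a, b) {
  sharedS <- intersect(sampleIds(a), sampleIds(b))
  sharedP <- intersect(positions(a), positions(b))
  if (!length(sharedS) || !length(sharedP))
    stop("incompatible matrices: no shared samples or loci")
  A <- genotypeCalls(a)[sharedS, match(sharedP, positions(a)), drop = FALSE]
  B <- genotypeCalls(b)[sharedS, match(sharedP, positions(b)), drop = FALSE]
  use <- A != "N" & B != "N"
  agree <- A == B & use
  idx <- which(use & A != B, arr.ind = TRUE)
  list(
    overall = sum(agree) / sum(use),
    perSample = setNames(rowSums(agree) / pmax(rowSums(use), 1L), sharedS),
    perLocus = setNames(colSums(agree) / pmax(colSums(use), 1L),
                        as.character(sharedP)),
    nCompared = sum(use),
    disagreements = data.frame(
      sample = sharedS[idx[, 1L]],
      position = sharedP[idx[, 2L]],
      cellA = A[idx], cellB = B[idx],
      stringsAsFactors = FALSE))
}

#' Parse tester-design sample labels
#'
#' Two labelling schemes are understood: `F<father>_M<mother>_<k>` for
#' progeny (`k` distinguishes full sibs), and `<clone> <location>` (or
#' `<clone>_<location>`) for parental ramets, where the location code (e.g.
#' `I4-15`, `K1-9-10`) identifies the physical tree.
#'
#' @param label character vector of sample labels.
#' @return data.frame with columns `label`, `type` (`progeny` / `parent`),
#'   `father`, `mother`, `index` (progeny only), `clone`, `location`
#'   (parents only).
#' @examples
#' parseSampleLabel(c("F222_M014_5", "014 K1-9-10"))
#' @export
parseSampleLabel <- function(label) {
  one <- function(s) {
    m <- regmatches(s, regexec("^F([^_]+)_M([^_]+)_([0-9]+)$", s))[[1L]]
    if (length(m)) {
      return(data.frame(label = s, type = "progeny", father = m[2L],
                        mother = m[3L], index = as.integer(m[4L]),
                        clone = NA_character_, location = NA_character_,
                        stringsAsFactors = FALSE))
    }
    m <- regmatches(s, regexec("^(\\S+)[ _](\\S+)$", s))[[1L]]
    if (length(m)) {
      return(data.frame(label = s, type = "parent", father = NA_character_,
                        mother = NA_character_, index = NA_integer_,
                        clone = m[2L], location = m[3L],
                        stringsAsFactors = FALSE))
    }
    data.frame(label = s, type = "parent", father = NA_character_,
               mother = NA_character_, index = NA_integer_, clone = s,
               location = NA_character_, stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(label, one))
}

#' Read / write pedigree tables
#'
#' The pedigree TSV has columns `progenyId`, `mother`, `father`; an optional
#' ramet TSV maps `sample` to `clone`.
#'
#' @param path pedigree TSV.
#' @param rametPath optional ramet TSV (`sample`, `clone`); clones absent
#'   from it but named in the pedigree are treated as unsampled when
#'   `rametPath` is given.
#' @return a [Pedigree-class].
#' @export
readPedigree <- function(path, rametPath = NULL) {
  prog <- read.delim(path, stringsAsFactors = FALSE)
  ramets <- NULL
  if (!is.null(rametPath)) {
    rt <- read.delim(rametPath, stringsAsFactors = FALSE)
    clones <- unique(c(prog$mother, prog$father, rt$clone))
    ramets <- lapply(setNames(clones, clones),
                     function(cl) rt$sample[rt$clone == cl])
  }
  pedigree(prog, ramets)
}
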