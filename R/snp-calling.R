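# Homoplasmic chloroplast SNP calling from SAM alignments.
#
# Filtering follows the standard organellar-resequencing recipe: keep only
# uniquely and properly paired reads (MAPQ >= 20, proper-pair flag, no
# secondary/supplementary alignments), count only bases with quality >= 20,
# require depth >= 3 at a site, and accept a genotype only when it is
# homoplasmic (major-allele fraction >= 0.9 by default); anything else is N.

#' Read SAM records into a data.frame
#'
#' Parses a SAM file through [Rsamtools] (conversion to a temporary BAM, then
#' `scanBam`) and returns the mandatory fields needed by the caller.
#'
#' @param path SAM file.
#' @return data.frame with columns qname, flag, rname, pos, mapq, cigar,
#'   seq, qual.
#' @export
readSam <- function(path) {
  stopifnot(file.exists(path))
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam))
  res <- Rsamtools::scanBam(bam,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "mapq", "cigar",
               "seq", "qual")))[[1L]]
  data.frame(qname = res$qname, flag = res$flag,
             rname = as.character(res$rname), pos = res$pos,
             mapq = res$mapq, cigar = res$cigar,
             seq = as.character(res$seq), qual = as.character(res$qual),
             stringsAsFactors = FALSE)
}

#' Read-level filter: uniquely and properly paired reads
#'
#' Retains reads with mapping quality at or above `minMapq`, the proper-pair
#' FLAG bit (0x2) set, and neither the secondary (0x100) nor supplementary
#' (0x800) bit set.  Unmapped reads (0x4) are dropped.
#'
#' @param reads data.frame of SAM records (needs `flag` and `mapq`).
#' @param minMapq minimum mapping quality (default 20).
#' @return the retained subset of `reads` (possibly empty).
#' @examples
#' rd <- data.frame(flag = c(99L, 99L, 355L), mapq = c(60L, 19L, 60L))
#' nrow(filterReads(rd))  # only the first survives
#' @export
filterReads <- function(reads, minMapq = 20L) {
  flag <- reads$flag
  keep <- reads$mapq >= minMapq &
    bitwAnd(flag, 0x2L) != 0L &
    bitwAnd(flag, 0x4L) == 0L &
    bitwAnd(flag, 0x100L) == 0L &
    bitwAnd(flag, 0x800L) == 0L
  reads[keep, , drop = FALSE]
}

# Walk one CIGAR string; returns per-aligned-base reference positions and the
# matching query offsets.  M/=/X consume both; I and S consume query only;
# D and N consume reference only; H and P consume neither.
.cigarAlignedPairs <- function(cigar, pos) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1L]]
  if (length(lens) != length(ops)) stop("malformed CIGAR: ", cigar)
  refPos <- integer(0); qryPos <- integer(0)
  r <- pos; q <- 1L
  for (k in seq_along(ops)) {
    n <- lens[k]
    switch(ops[k],
      "M" = , "=" = , "X" = {
        refPos <- c(refPos, r + 0:(n - 1L))
        qryPos <- c(qryPos, q + 0:(n - 1L))
        r <- r + n; q <- q + n
      },
      "I" = , "S" = { q <- q + n },
      "D" = , "N" = { r <- r + n },
      "H" = , "P" = NULL)
  }
  list(ref = refPos, qry = qryPos)
}

#' Build a base-quality-filtered pileup
#'
#' Counts, at every reference position, the read bases of quality >=
#' `minBaseq` from the supplied (already read-filtered) records.  Simple
#' all-match CIGARs take a fast vectorised path; general CIGARs are walked
#' operation by operation.
#'
#' @param reads data.frame of SAM records (pass through [filterReads()]
#'   first).
#' @param ref a [ReferenceGenome-class].
#' @param minBaseq minimum base quality (Phred, default 20).
#' @return a list with `counts` (integer matrix, genome length x 4, columns
#'   A/C/G/T), `depth` (rowSums) and `ref` (reference base per position).
#' @export
buildPileup <- function(reads, ref, minBaseq = 20L) {
  L <- refLength(ref)
  counts <- matrix(0L, L, 4L, dimnames = list(NULL, .CP_BASES))
  if (nrow(reads)) {
    if (any(reads$pos < 1L))
      stop("malformed input: read positions outside the reference")
    simple <- grepl("^[0-9]+M$", reads$cigar)
    pileOne <- function(posVec, baseVec, qualVec) {
      keep <- qualVec >= minBaseq & baseVec %in% .CP_BASES & posVec <= L
      posVec <- posVec[keep]; baseVec <- baseVec[keep]
      idx <- (match(baseVec, .CP_BASES) - 1L) * L + posVec
      tab <- tabulate(idx, nbins = 4L * L)
      matrix(tab, L, 4L)
    }
    if (any(simple)) {
      rs <- reads[simple, , drop = FALSE]
      w <- nchar(rs$seq)
      if (any(rs$pos + w - 1L > L))
        stop("malformed input: read extends beyond the reference")
      posVec <- rep(rs$pos, w) + sequence(w) - 1L
      baseVec <- unlist(strsplit(rs$seq, "", fixed = TRUE), use.names = FALSE)
      qualVec <- as.integer(charToRaw(paste(rs$qual, collapse = ""))) - 33L
      counts <- counts + pileOne(posVec, baseVec, qualVec)
    }
    if (any(!simple)) {
      rs <- reads[!simple, , drop = FALSE]
      for (i in seq_len(nrow(rs))) {
        ap <- .cigarAlignedPairs(rs$cigar[i], rs$pos[i])
        if (length(ap$ref) == 0L) next
        if (max(ap$ref) > L)
          stop("malformed input: read extends beyond the reference")
        baseVec <- substring(rs$seq[i], ap$qry, ap$qry)
        qualVec <- as.integer(charToRaw(rs$qual[i]))[ap$qry] - 33L
        counts <- counts + pileOne(ap$ref, baseVec, qualVec)
      }
    }
  }
  list(counts = counts, depth = as.integer(rowSums(counts)),
       ref = strsplit(refSequence(ref), "", fixed = TRUE)[[1L]])
}

#' Call the genotype of a single pileup column
#'
#' Depth below `minDepth` gives a `MISSING` call (base `N`); otherwise the
#' majority base is accepted only if its fraction of the column depth reaches
#' `homoplasmy`, in which case the call is `REF` or `ALT` by comparison to
#' the reference base.  Columns below the homoplasmy threshold -- candidate
#' heteroplasmy or contamination -- are `HETEROPLASMIC_EXCLUDED` with base
#' `N`, as are exact ties for the majority base.
#'
#' @param counts named integer vector of base counts (names among A/C/G/T;
#'   absent bases count 0).
#' @param refBase reference base at the position.
#' @param minDepth minimum post-filter depth (default 3).
#' @param homoplasmy minimum major-allele fraction (default 0.9).
#' @return list with `calledBase`, `status` (`REF`, `ALT`, `MISSING`,
#'   `HETEROPLASMIC_EXCLUDED`), `depth`, `majorFraction`.
#' @examples
#' callSite(c(T = 6), "G")                  # unanimous ALT
#' callSite(c(T = 5, G = 4), "G")           # 0.556 < 0.9 -> excluded
#' callSite(c(G = 2), "G")                  # depth 2 -> MISSING
#' @export
callSite <- function(counts, refBase, minDepth = 3L, homoplasmy = 0.9) {
  full <- setNames(integer(4L), .CP_BASES)
  full[names(counts)] <- as.integer(counts)
  depth <- sum(full)
  if (depth < minDepth)
    return(list(calledBase = "N", status = "MISSING", depth = depth,
                majorFraction = NA_real_))
  top <- max(full)
  frac <- top / depth
  if (sum(full == top) > 1L || frac < homoplasmy)
    return(list(calledBase = "N", status = "HETEROPLASMIC_EXCLUDED",
                depth = depth, majorFraction = frac))
  base <- .CP_BASES[which.max(full)]
  list(calledBase = base, status = if (base == refBase) "REF" else "ALT",
       depth = depth, majorFraction = frac)
}

# Vectorised call over a whole pileup; returns per-position status and base.
.callColumns <- function(pileup, minDepth = 3L, homoplasmy = 0.9) {
  counts <- pileup$counts
  depth <- pileup$depth
  top <- do.call(pmax, as.data.frame(counts))
  nTop <- rowSums(counts == top)
  frac <- ifelse(depth > 0L, top / depth, NA_real_)
  major <- .CP_BASES[max.col(counts, ties.method = "first")]
  status <- rep("MISSING", length(depth))
  ok <- depth >= minDepth
  status[ok] <- ifelse(nTop[ok] > 1L | frac[ok] < homoplasmy,
                       "HETEROPLASMIC_EXCLUDED",
                       ifelse(major[ok] == pileup$ref[ok], "REF", "ALT"))
  called <- ifelse(status %in% c("REF", "ALT"), major, "N")
  list(status = status, calledBase = called, depth = depth,
       majorFraction = ifelse(depth >= minDepth, frac, NA_real_))
}

#' Call homoplasmic SNPs and coverage statistics for one sample
#'
#' Runs the full per-sample pipeline: read-level filtering
#' ([filterReads()]), base-quality-filtered pileup ([buildPileup()]), and
#' per-column genotype calls ([callSite()] semantics).  Variant and
#' non-reference-callable sites are returned; positions called `REF` are
#' omitted.
#'
#' @param reads a SAM file path or a data.frame of SAM records.
#' @param ref a [ReferenceGenome-class] matching the alignment target.
#' @param minMapq,minBaseq,minDepth,homoplasmy filter thresholds.
#' @param sample sample id recorded in the output.
#' @return list with
#'   \describe{
#'     \item{calls}{[S4Vectors::DataFrame] of sites with status `ALT`,
#'       `MISSING` or `HETEROPLASMIC_EXCLUDED`: position, refBase,
#'       calledBase, status, depth, majorFraction.}
#'     \item{coverage}{data.frame with `sample`, `meanDepth` (post-filter
#'       reads per site) and `breadth1x` (fraction of the genome at >= 1x).}
#'   }
#' @export
callSample <- function(reads, ref, minMapq = 20L, minBaseq = 20L,
                       minDepth = 3L, homoplasmy = 0.9, sample = "sample") {
  if (is.character(reads)) reads <- readSam(reads)
  if (nrow(reads) && !all(reads$rname %in% c(refId(ref), "*")))
    stop("malformed input: SAM contig does not match the reference id")
  kept <- filterReads(reads, minMapq = minMapq)
  pu <- buildPileup(kept, ref, minBaseq = minBaseq)
  cc <- .callColumns(pu, minDepth = minDepth, homoplasmy = homoplasmy)
  keep <- cc$status != "REF"
  calls <- S4Vectors::DataFrame(
    sample = sample,
    position = which(keep),
    refBase = pu$ref[keep],
    calledBase = cc$calledBase[keep],
    status = cc$status[keep],
    depth = cc$depth[keep],
    majorFraction = cc$majorFraction[keep])
  coverage <- data.frame(
    sample = sample,
    meanDepth = sum(pu$depth) / refLength(ref),
    breadth1x = mean(pu$depth >= 1L))
  list(calls = calls, coverage = coverage)
}
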