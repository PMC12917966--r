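# Assembly of per-sample calls into the samples-by-loci genotype matrix,
# carrier counting, minor-allele-frequency filtering, and TSV/VCF round trips.

#' Assemble per-sample calls into a GenotypeMatrix
#'
#' Combines the `calls` tables of [callSample()] into the compact matrix
#' encoding: `"-"` where a sample is reference-callable at a locus, the
#' alternative base where it carries a substitution, and `"N"` where the call
#' is missing or heteroplasmy-excluded.  A panel locus never observed in a
#' sample's call table is reference by construction.
#'
#' @param callsList named list (sample id -> `calls` DataFrame from
#'   [callSample()]).
#' @param lociSet optional integer positions defining the locus panel; by
#'   default the union of all `ALT` positions across samples.
#' @param ref a [ReferenceGenome-class], used to fill reference bases for
#'   panel loci never called ALT (may be omitted when `lociSet` is default).
#' @param onMultiallelic `"error"` (default) to fail when two samples carry
#'   different alternative bases at one locus, `"drop"` to discard such loci
#'   with a message.
#' @return a [GenotypeMatrix-class].
#' @export
buildMatrix <- function(callsList, lociSet = NULL, ref = NULL,
                        onMultiallelic = c("error", "drop")) {
  onMultiallelic <- match.arg(onMultiallelic)
  stopifnot(length(callsList) > 0L, !is.null(names(callsList)))
  alt <- do.call(rbind, lapply(names(callsList), function(s) {
    cl <- as.data.frame(callsList[[s]])
    cl[cl$status == "ALT", c("position", "refBase", "calledBase")]
  }))
  if (is.null(lociSet)) {
    lociSet <- sort(unique(alt$position))
  } else {
    lociSet <- sort(as.integer(lociSet))
    alt <- alt[alt$position %in% lociSet, , drop = FALSE]
  }
  refBase <- setNames(rep(NA_character_, length(lociSet)),
                      as.character(lociSet))
  altBase <- refBase
  if (nrow(alt)) {
    for (p in unique(alt$position)) {
      sub <- alt[alt$position == p, ]
      if (length(unique(sub$calledBase)) > 1L) {
        if (onMultiallelic == "error")
          stop("multi-allelic locus at position ", p, ": bases ",
               paste(sort(unique(sub$calledBase)), collapse = "/"))
        message("dropping multi-allelic locus ", p)
        lociSet <- setdiff(lociSet, p)
        next
      }
      refBase[as.character(p)] <- sub$refBase[1L]
      altBase[as.character(p)] <- sub$calledBase[1L]
    }
    refBase <- refBase[as.character(lociSet)]
    altBase <- altBase[as.character(lociSet)]
  }
  if (any(is.na(refBase))) {
    if (is.null(ref))
      stop("need 'ref' to fill reference bases for loci with no ALT call")
    idx <- which(is.na(refBase))
    refBase[idx] <- substring(refSequence(ref), lociSet[idx], lociSet[idx])
  }
  cells <- matrix("-", length(callsList), length(lociSet),
                  dimnames = list(names(callsList), NULL))
  for (s in names(callsList)) {
    cl <- as.data.frame(callsList[[s]])
    cl <- cl[cl$position %in% lociSet, , drop = FALSE]
    j <- match(cl$position, lociSet)
    cells[s, j] <- ifelse(cl$status == "ALT", cl$calledBase, "N")
  }
  genotypeMatrix(cells, lociSet, unname(refBase), unname(altBase))
}

#' Count carriers of the alternative allele
#'
#' A carrier is a sample whose cell equals the locus's alternative base.
#' Under the `AS_REFERENCE` missing-data policy, `"N"` cells count as the
#' reference state (the convention used throughout the package for
#' comparisons); under `EXCLUDE`, `"N"` cells are removed from both the
#' count and the denominator reported by [minorAlleleFrequency()].
#'
#' @param x a [GenotypeMatrix-class].
#' @param locus optional position(s); default all loci.
#' @param nPolicy `"AS_REFERENCE"` (default) or `"EXCLUDE"`.
#' @return named integer vector of carrier counts.
#' @examples
#' m <- genotypeMatrix(rbind(a = c("T"), b = c("N"), c = c("-")),
#'                     positions = 5L, ref = "G", alt = "T")
#' carrierCount(m)  # 1
#' @export
carrierCount <- function(x, locus = NULL,
                         nPolicy = c("AS_REFERENCE", "EXCLUDE")) {
  nPolicy <- match.arg(nPolicy)
  stopifnot(is(x, "GenotypeMatrix"))
  j <- .lociIndex(x, locus)
  alt <- loci(x)$alt[j]
  cells <- genotypeCalls(x)[, j, drop = FALSE]
  cnt <- colSums(cells == matrix(alt, nrow(cells), length(j), byrow = TRUE),
                 na.rm = TRUE)
  setNames(as.integer(cnt), as.character(positions(x)[j]))
}

.lociIndex <- function(x, locus) {
  if (is.null(locus)) return(seq_len(ncol(genotypeCalls(x))))
  j <- match(as.integer(locus), positions(x))
  if (anyNA(j))
    stop("locus not found: ", paste(locus[is.na(j)], collapse = ", "))
  j
}

#' Minor allele frequency per locus
#'
#' The frequency of the rarer allele, whichever it is: near-fixed loci where
#' almost every sample carries the alternative base have a small MAF because
#' the *reference* allele is the minor one there.  Denominator is the full
#' sample count under `AS_REFERENCE` (`"N"` counts as reference) or the
#' number of non-missing cells under `EXCLUDE`.
#'
#' @inheritParams carrierCount
#' @return named numeric vector of MAFs in `[0, 0.5]`.
#' @export
minorAlleleFrequency <- function(x, locus = NULL,
                                 nPolicy = c("AS_REFERENCE", "EXCLUDE")) {
  nPolicy <- match.arg(nPolicy)
  j <- .lociIndex(x, locus)
  cnt <- carrierCount(x, positions(x)[j], nPolicy)
  denom <- if (nPolicy == "AS_REFERENCE") rep(nrow(genotypeCalls(x)), length(j))
           else colSums(genotypeCalls(x)[, j, drop = FALSE] != "N")
  f <- ifelse(denom > 0L, cnt / denom, NA_real_)
  setNames(pmin(f, 1 - f), names(cnt))
}

#' Filter loci on frequency and carrier count
#'
#' Retains biallelic loci whose alternative (non-reference) allele reaches a
#' cohort frequency of at least `mafMin` with at least `minCarriers`
#' carriers.  The filter targets rarity of the substitution relative to the
#' reference, so near-fixed loci -- where almost every sample carries the
#' alternative base and the *reference* allele is the rare one -- are
#' retained.  The operation is idempotent.
#'
#' @param x a [GenotypeMatrix-class].
#' @param mafMin minimum alternative-allele frequency (default 0.05).
#' @param minCarriers minimum number of alt carriers (default 3).
#' @param biallelicOnly drop loci whose cells contain a base other than the
#'   recorded alternative (default TRUE).
#' @param nPolicy missing-data policy for MAF and carrier counting.
#' @return the filtered [GenotypeMatrix-class].
#' @export
filterLoci <- function(x, mafMin = 0.05, minCarriers = 3L,
                       biallelicOnly = TRUE,
                       nPolicy = c("AS_REFERENCE", "EXCLUDE")) {
  nPolicy <- match.arg(nPolicy)
  cnt <- carrierCount(x, nPolicy = nPolicy)
  denom <- if (nPolicy == "AS_REFERENCE")
    rep(nrow(genotypeCalls(x)), length(cnt))
  else colSums(genotypeCalls(x) != "N")
  altFreq <- ifelse(denom > 0L, cnt / denom, NA_real_)
  keep <- !is.na(altFreq) & altFreq >= mafMin & cnt >= minCarriers
  if (biallelicOnly) {
    cells <- genotypeCalls(x)
    alt <- loci(x)$alt
    third <- vapply(seq_len(ncol(cells)), function(j) {
      b <- setdiff(unique(cells[, j]), c("-", "N", alt[j]))
      length(b) > 0L
    }, logical(1L))
    keep <- keep & !third
  }
  x[, which(keep)]
}

#' Write / read the genotype matrix as TSV
#'
#' The published table layout: a header of `sample` plus the locus
#' positions, a `REF` row and an `ALT` row of per-locus bases, then one row
#' per sample with cells `"-"`, the alternative base, or `"N"`.
#'
#' @param x a [GenotypeMatrix-class].
#' @param path TSV file.
#' @return `writeGenotypeMatrix`: `path` invisibly; `readGenotypeMatrix`:
#'   a `GenotypeMatrix`.
#' @export
writeGenotypeMatrix <- function(x, path) {
  l <- loci(x)
  hdr <- paste(c("sample", l$position), collapse = "\t")
  refRow <- paste(c("REF", l$ref), collapse = "\t")
  altRow <- paste(c("ALT", ifelse(is.na(l$alt), ".", l$alt)), collapse = "\t")
  cells <- genotypeCalls(x)
  body <- vapply(seq_len(nrow(cells)), function(i)
    paste(c(rownames(cells)[i], cells[i, ]), collapse = "\t"), "")
  writeLines(c(hdr, refRow, altRow, body), path)
  invisible(path)
}

#' @rdname writeGenotypeMatrix
#' @export
readGenotypeMatrix <- function(path) {
  tab <- read.delim(path, header = TRUE, check.names = FALSE,
                    colClasses = "character")
  pos <- as.integer(colnames(tab)[-1L])
  ids <- tab[[1L]]
  cells <- as.matrix(tab[, -1L, drop = FALSE])
  special <- toupper(ids) %in% c("REF", "ALT")
  refRow <- if ("REF" %in% toupper(ids)) cells[toupper(ids) == "REF", ] else NULL
  altRow <- if ("ALT" %in% toupper(ids)) cells[toupper(ids) == "ALT", ] else NULL
  cells <- cells[!special, , drop = FALSE]
  rownames(cells) <- ids[!special]
  if (is.null(altRow)) {
    # infer the alternative base as the commonest non-reference cell
    altRow <- apply(cells, 2L, function(col) {
      b <- col[!col %in% c("-", "N")]
      if (!length(b)) NA_character_ else names(sort(table(b),
                                                    decreasing = TRUE))[1L]
    })
  }
  altRow[altRow == "."] <- NA_character_
  if (is.null(refRow))
    stop("matrix TSV lacks a REF row; reference bases are required")
  colnames(cells) <- NULL
  genotypeMatrix(cells, pos, unname(refRow), unname(altRow))
}

#' Export the genotype matrix as a multi-sample VCF (v4.2)
#'
#' Haploid genotypes: `0` reference, `1` alternative, `.` missing.  Loci
#' with no alternative base (monomorphic) are skipped.  The companion
#' `readGenotypeVcf()` reads such a file back into a [GenotypeMatrix-class]
#' (requires the VariantAnnotation package).
#'
#' @param x a [GenotypeMatrix-class].
#' @param path VCF file.
#' @param contig contig name written to `#CHROM` (default `cpgenome`).
#' @param contigLength optional contig length for the `##contig` header.
#' @return `path`, invisibly.
#' @export
writeGenotypeVcf <- function(x, path, contig = "cpgenome",
                             contigLength = NULL) {
  l <- loci(x)
  keep <- !is.na(l$alt)
  l <- l[keep, ]
  cells <- genotypeCalls(x)[, keep, drop = FALSE]
  gt <- ifelse(cells == "N", ".", ifelse(cells == "-", "0", "1"))
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s%s>", contig,
                   if (is.null(contigLength)) ""
                   else paste0(",length=", contigLength)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(cells)), collapse = "\t"))
  body <- vapply(seq_len(nrow(l)), function(j)
    paste(c(contig, l$position[j], ".", l$ref[j], l$alt[j], ".", "PASS",
            ".", "GT", gt[, j]), collapse = "\t"), "")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname writeGenotypeVcf
#' @export
readGenotypeVcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("readGenotypeVcf requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  pos <- GenomicRanges::start(SummarizedExperiment::rowRanges(vcf))
  ref <- as.character(VariantAnnotation::ref(vcf))
  altL <- VariantAnnotation::alt(vcf)
  alt <- vapply(seq_along(altL), function(i) {
    a <- as.character(altL[[i]])
    if (length(a)) a[1L] else NA_character_
  }, "")
  gt <- VariantAnnotation::geno(vcf)$GT
  cells <- t(gt)
  out <- ifelse(cells == ".", "N", ifelse(cells == "0", "-", NA))
  for (j in seq_along(alt)) out[is.na(out[, j]), j] <- alt[j]
  o <- order(pos)
  genotypeMatrix(out[, o, drop = FALSE], pos[o], ref[o], alt[o])
}
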