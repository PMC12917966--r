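# Packaged data: the published 54-sample genotype matrix and 32-locus
# annotation table, plus a fully synthetic reconstruction of a 9 x 5
# tester-design cohort used to exercise the kinship classifier.

#' Paths to the packaged example data
#'
#' `cpSnpMatrixFile()` returns the TSV transcription of a published
#' chloroplast genotype matrix: 54 loblolly-pine individuals from a core
#' breeding population by 32 SNP loci, in the `"-"`/base/`"N"` encoding.
#' `cpSnpAnnotationFile()` returns the matching 32-locus annotation table
#' (position, ref, alt, gene or intergenic-spacer label, product).
#'
#' @return a file path.
#' @examples
#' m <- readGenotypeMatrix(cpSnpMatrixFile())
#' dim(m)
#' @export
cpSnpMatrixFile <- function() {
  system.file("extdata", "breeding54_genotype_matrix.tsv",
              package = "cpKin", mustWork = TRUE)
}

#' @rdname cpSnpMatrixFile
#' @export
cpSnpAnnotationFile <- function() {
  system.file("extdata", "cp_snp_annotation.tsv",
              package = "cpKin", mustWork = TRUE)
}

#' Synthetic tester-design cohort
#'
#' Constructs, entirely in code, a 75-sample cohort (45 progeny plus 30
#' parental ramets) emulating the haplotype structure reported for a 9 x 5
#' loblolly-pine tester design genotyped at 19 chloroplast SNP loci:
#' \itemize{
#'   \item eight maternal clones with one ramet each (the ninth, `W16`,
#'     unsampled), each carrying a haplotype none of its progeny shares;
#'   \item paternal clone `N4` (7 ramets) whose 7 progeny match it exactly;
#'   \item paternal clone `S1` (7 ramets) whose 8 progeny all carry the
#'     haplotype of unrelated sampled male `W03` instead -- the alternate-
#'     father signature;
#'   \item `W03` (1 ramet) and its own 3 progeny, so that 11 progeny in all
#'     share the `W03` haplotype;
#'   \item paternal clone `222` (7 ramets) whose ramet `222_I4-15` differs
#'     from the others at a single locus (position 101157), with all 9
#'     progeny matching the majority ramet haplotype;
#'   \item unsampled paternal clone `S2` whose 9 progeny share one uniform
#'     haplotype matching no sampled clone (pollen contamination from an
#'     unsampled male, or simply the unsampled father);
#'   \item three minor triplets of progeny, each carrying a private novel
#'     haplotype (small extra contamination lineages).
#' }
#' This object is a synthetic stand-in built from the narrative structure of
#' the study design, not the study's genotype data; it exists so the
#' classifier, ramet-consistency check and tree code can be tested without
#' any download.
#'
#' @return list with `matrix` (a 75 x 19 [GenotypeMatrix-class]), `pedigree`
#'   (a [Pedigree-class] with clone-to-ramet mapping) and `families` (list
#'   of progeny ids per paternal clone).
#' @export
testerDesignFixture <- function() {
  pos <- c(10348L, 14321L, 23167L, 23593L, 37238L, 45193L, 45592L, 50158L,
           50842L, 50999L, 59616L, 65304L, 68985L, 90253L, 97585L, 101103L,
           101157L, 113045L, 119714L)
  ref <- c("T", "G", "G", "C", "T", "G", "G", "T", "C", "G", "C", "C", "G",
           "A", "T", "T", "T", "T", "C")
  alt <- c("A", "T", "A", "A", "A", "T", "T", "C", "T", "A", "T", "A", "T",
           "G", "G", "G", "G", "G", "T")
  L <- length(pos)
  hap <- function(idx) { h <- rep("-", L); h[idx] <- alt[idx]; h }
  # distinct haplotypes: maternal clones never match any progeny
  hapMother <- lapply(1:8, function(i) hap(c(i, i + 8L)))
  hapN4 <- hap(c(1L, 6L, 13L))
  hapS1 <- hap(c(2L, 7L, 14L))
  hapW03 <- hap(c(3L, 8L, 15L))
  hap222 <- hap(c(4L, 9L, 16L))
  hapS2kids <- hap(c(5L, 10L, 17L, 19L))   # external haplotype, no owner
  mothers <- c("014", "017", "201", "202", "243", "259", "288", "P100", "W16")
  # progeny groups: ids, recorded father, and the haplotype they carry (the
  # three trailing triplets are contamination lineages with private novel
  # haplotypes, mirroring the small extra haplogroups such designs show)
  groups <- list(
    list(f = "N4", ids = c(4L, 14L, 19L, 24L, 34L, 39L, 44L), hap = hapN4),
    list(f = "S1", ids = c(1L, 6L, 11L, 16L, 21L, 26L, 36L, 41L),
         hap = hapW03),
    list(f = "W03", ids = c(3L, 8L, 33L), hap = hapW03),
    list(f = "222", ids = c(7L, 9L, 10L, 20L, 29L, 30L, 40L, 42L, 45L),
         hap = hap222),
    list(f = "S2", ids = c(15L, 22L, 27L, 28L, 31L, 32L, 35L, 37L, 38L),
         hap = hapS2kids),
    list(f = "N4", ids = c(2L, 12L, 17L), hap = hap(c(1L, 7L, 17L))),
    list(f = "222", ids = c(5L, 25L, 43L), hap = hap(c(2L, 8L, 16L))),
    list(f = "W03", ids = c(13L, 18L, 23L), hap = hap(c(3L, 9L, 15L))))
  allIds <- unlist(lapply(groups, `[[`, "ids"))
  stopifnot(length(allIds) == 45L, !anyDuplicated(allIds))
  rows <- list(); prog <- list()
  for (g in groups) {
    for (k in g$ids) {
      mother <- mothers[(k - 1L) %% 9L + 1L]
      id <- sprintf("F%s_M%s_%d", g$f, mother, k)
      rows[[id]] <- g$hap
      prog[[id]] <- data.frame(progenyId = id, mother = mother, father = g$f,
                               stringsAsFactors = FALSE)
    }
  }
  ramets <- list()
  for (i in 1:8) {
    id <- paste0(mothers[i], "_K1-", i)
    rows[[id]] <- hapMother[[i]]
    ramets[[mothers[i]]] <- id
  }
  ramets[["W16"]] <- character()
  parentHap <- list(N4 = hapN4, S1 = hapS1, `222` = hap222)
  for (f in c("N4", "S1", "222")) {
    ids <- sprintf("%s_I%d-%d", f, 1:7, 7:13)
    if (f == "222") ids[4L] <- "222_I4-15"
    for (j in seq_along(ids)) rows[[ids[j]]] <- parentHap[[f]]
    ramets[[f]] <- ids
  }
  # one ramet of 222 disagrees with its six sibs at position 101157
  j157 <- match(101157L, pos)
  rows[["222_I4-15"]][j157] <-
    if (rows[["222_I4-15"]][j157] == "-") alt[j157] else "-"
  rows[["W03_L1-3-7"]] <- hapW03
  ramets[["W03"]] <- "W03_L1-3-7"
  ramets[["S2"]] <- character()
  cells <- do.call(rbind, rows)
  rownames(cells) <- names(rows)
  mat <- genotypeMatrix(cells, pos, ref, alt)
  ped <- pedigree(do.call(rbind, prog), ramets)
  # ids of each group's progeny, in group order (the narrative families
  # first, then the three contamination triplets)
  famIds <- lapply(groups, function(g)
    sprintf("F%s_M%s_%d", g$f, mothers[(g$ids - 1L) %% 9L + 1L], g$ids))
  names(famIds) <- c("N4", "S1", "W03", "222", "S2",
                     "minor1", "minor2", "minor3")
  list(matrix = mat, pedigree = ped, families = famIds)
}
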