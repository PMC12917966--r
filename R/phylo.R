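# Distance-based haplogroup trees: pairwise mismatch distances,
# neighbor-joining, column-bootstrap support, Newick export.

.distFromCells <- function(cells, nPolicy = "AS_REFERENCE",
                           normalize = FALSE) {
  rn <- rownames(cells)
  cells <- matrix(.applyPolicy(c(t(cells)), nPolicy),
                  nrow(cells), ncol(cells), byrow = TRUE,
                  dimnames = list(rn, NULL))
  n <- nrow(cells)
  # fast path: no masked cells and, under AS_REFERENCE, no N left -- the
  # number of agreeing loci per pair is a sum of indicator cross-products
  if (!anyNA(cells) && !(nPolicy == "PAIRWISE_DELETE" && any(cells == "N"))) {
    agree <- matrix(0, n, n)
    for (v in unique(c(cells)))
      agree <- agree + tcrossprod(cells == v)
    d <- ncol(cells) - agree
    if (normalize) d <- d / max(ncol(cells), 1L)
    dimnames(d) <- list(rn, rn)
    return(d)
  }
  d <- matrix(0, n, n, dimnames = list(rn, rn))
  if (n > 1L)
    for (i in seq_len(n - 1L))
      for (j in (i + 1L):n) {
        keep <- !is.na(cells[i, ]) & !is.na(cells[j, ])
        a <- cells[i, keep]; b <- cells[j, keep]
        if (nPolicy == "PAIRWISE_DELETE") {
          ok <- a != "N" & b != "N"
          a <- a[ok]; b <- b[ok]
        }
        mis <- sum(a != b)
        d[i, j] <- d[j, i] <- if (normalize) mis / max(length(a), 1L) else mis
      }
  d
}

#' Pairwise haplotype mismatch distances
#'
#' Builds the symmetric matrix of pairwise [haplotypeDistance()] mismatch
#' counts among all samples (optionally normalised by the number of compared
#' loci).
#'
#' @param x a [GenotypeMatrix-class] with at least two samples.
#' @param nPolicy missing-data policy.
#' @param normalize divide each distance by the number of compared loci.
#' @return a symmetric numeric matrix with sample ids as dimnames.
#' @export
distanceMatrix <- function(x, nPolicy = c("AS_REFERENCE",
                                          "PAIRWISE_DELETE"),
                           normalize = FALSE) {
  nPolicy <- match.arg(nPolicy)
  stopifnot(is(x, "GenotypeMatrix"))
  if (nrow(genotypeCalls(x)) < 2L)
    stop("insufficient samples: need at least 2")
  .distFromCells(genotypeCalls(x), nPolicy, normalize)
}

#' Neighbor-joining tree
#'
#' Standard neighbor-joining (via [ape::nj()]) on a symmetric distance
#' matrix.  Negative branch lengths, an artefact NJ can produce on
#' non-additive input, are clamped to zero, and zero-length internal
#' branches are optionally collapsed so that sets of identical haplotypes
#' appear as polytomies (an all-zero matrix yields a star tree).  NJ is
#' exact on additive matrices: it recovers the generating topology and
#' branch lengths.
#'
#' @param d symmetric distance matrix with ids as dimnames (>= 3 taxa).
#' @param collapseZero collapse zero-length internal branches into
#'   polytomies (default TRUE).
#' @return an [ape::phylo] tree.
#' @export
njTree <- function(d, collapseZero = TRUE) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("insufficient samples: NJ needs >= 3 taxa")
  if (!isTRUE(all.equal(d, t(d), check.attributes = FALSE)))
    stop("distance matrix must be symmetric")
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  if (collapseZero) tr <- ape::di2multi(tr, tol = 1e-10)
  tr
}

#' Column-bootstrap support for the NJ tree
#'
#' Resamples loci (matrix columns) with replacement `nReps` times, rebuilds
#' the NJ tree from each resampled matrix, and labels each internal node of
#' the full-data tree with the percentage of replicates containing its
#' bipartition.
#'
#' @param x a [GenotypeMatrix-class].
#' @param nReps bootstrap replicates (default 1000).
#' @param seed integer seed making the supports reproducible.
#' @param nPolicy missing-data policy for the distances.
#' @return the NJ tree with integer percentage supports in `node.label`.
#' @export
bootstrapSupport <- function(x, nReps = 1000L, seed = 1L,
                             nPolicy = c("AS_REFERENCE",
                                         "PAIRWISE_DELETE")) {
  nPolicy <- match.arg(nPolicy)
  stopifnot(nReps >= 1L)
  cells <- genotypeCalls(x)
  buildFun <- function(m) njTree(.distFromCells(m, nPolicy),
                                 collapseZero = FALSE)
  base <- buildFun(cells)
  counts <- .withSeed(seed,
    ape::boot.phylo(base, cells, buildFun, B = nReps, quiet = TRUE,
                    rooted = FALSE))
  support <- round(100 * counts / nReps)
  tr <- base
  tr$node.label <- as.character(support)
  # hide the (meaningless) root-node value on an unrooted NJ tree
  tr$node.label[1L] <- ""
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Write a tree as Newick text
#'
#' Branch lengths are kept and internal-node labels (bootstrap supports)
#' are written as standard Newick internal labels; the output is a single
#' line ending in `;` that round-trips through [ape::read.tree()].
#'
#' @param tree an [ape::phylo] object.
#' @param path optional file; when omitted the Newick string is returned.
#' @return the Newick string (invisibly when written to a file).
#' @export
writeNewick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
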