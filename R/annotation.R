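# Locus annotation: assign each SNP position to a gene or to the intergenic
# spacer between its two flanking genes, and summarise the genic/intergenic
# composition of a locus panel.

#' Build a gene annotation from a feature table
#'
#' Converts a simple feature table (name, start, end, strand, product; 1-based
#' closed intervals) into a [GenomicRanges::GRanges] used by
#' [annotateLocus()].  BED-style half-open input can be converted by passing
#' `zeroBased = TRUE`.
#'
#' @param features data.frame with columns `name`, `start`, `end`, and
#'   optionally `strand` (`+`/`-`) and `product`.
#' @param contig contig name (must match the coordinate system of the loci).
#' @param zeroBased if TRUE, `start` is interpreted as 0-based half-open
#'   (BED) and shifted to 1-based closed.
#' @return a `GRanges` with metadata columns `name` and `product`.
#' @export
geneAnnotation <- function(features, contig = "cpgenome", zeroBased = FALSE) {
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "start", "end") %in% colnames(features)))
  start <- as.integer(features$start) + if (zeroBased) 1L else 0L
  end <- as.integer(features$end)
  if (any(start > end)) stop("feature start must be <= end")
  strand <- if ("strand" %in% colnames(features)) features$strand else "*"
  gr <- GenomicRanges::GRanges(contig, IRanges::IRanges(start, end),
                               strand = strand)
  gr$name <- features$name
  gr$product <- if ("product" %in% colnames(features)) features$product
                else NA_character_
  sort(gr, ignore.strand = TRUE)
}

#' @rdname geneAnnotation
#' @param path TSV file with the feature-table columns.
#' @export
readGeneAnnotation <- function(path, contig = "cpgenome",
                               zeroBased = FALSE) {
  geneAnnotation(read.delim(path, stringsAsFactors = FALSE),
                 contig = contig, zeroBased = zeroBased)
}

#' Annotate one or more SNP positions
#'
#' A position inside a feature interval (closed, both boundaries included) is
#' `GENIC` and labelled with the gene name -- with overlapping features
#' joined by `"/"` and counted once.  A position between features is
#' `INTERGENIC`, labelled `"upstream ~ downstream"` by the nearest flanking
#' features on the coordinate line.  Positions before the first or after the
#' last feature are an error: the annotation does not span them.
#'
#' @param position integer vector of 1-based positions.
#' @param annotation a `GRanges` from [geneAnnotation()].
#' @return a data.frame with columns `position`, `category` (`GENIC` /
#'   `INTERGENIC`), `label`, `product`.
#' @examples
#' ann <- geneAnnotation(data.frame(
#'   name = c("rbcL", "atpB"), start = c(100, 600), end = c(400, 900),
#'   product = c("RuBisCO large subunit", "ATP synthase beta")))
#' annotateLocus(c(250, 500), ann)
#' @export
annotateLocus <- function(position, annotation) {
  position <- as.integer(position)
  st <- GenomicRanges::start(annotation)
  en <- GenomicRanges::end(annotation)
  if (any(position < min(st)) || any(position > max(en)))
    stop("position outside the span of the annotation")
  one <- function(p) {
    hit <- which(st <= p & en >= p)
    if (length(hit)) {
      data.frame(position = p, category = "GENIC",
                 label = paste(unique(annotation$name[hit]), collapse = "/"),
                 product = paste(unique(stats::na.omit(
                   annotation$product[hit])), collapse = "; "),
                 stringsAsFactors = FALSE)
    } else {
      up <- which(en < p); dn <- which(st > p)
      upF <- up[which.max(en[up])]
      dnF <- dn[which.min(st[dn])]
      data.frame(position = p, category = "INTERGENIC",
                 label = paste(annotation$name[upF], "~",
                               annotation$name[dnF]),
                 product = paste(unique(stats::na.omit(
                   annotation$product[c(upF, dnF)])), collapse = ", "),
                 stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, lapply(position, one))
}

#' Summarise the genic/intergenic composition of a locus panel
#'
#' Counts genic and intergenic loci, tallies loci per gene, and reports the
#' share of each gene among genic loci (and among a larger SNP total, e.g.
#' the pre-filter discovery set, when `totalSnps` is given).  `x` may be a
#' [GenotypeMatrix-class], a vector of positions annotated against a
#' `GRanges`, or a precomputed locus-annotation table (data.frame with
#' `position` and `label`, where labels containing `"~"` denote intergenic
#' spacers) in which case `annotation` may be omitted.
#'
#' @param x positions, `GenotypeMatrix`, or locus-annotation data.frame.
#' @param annotation a `GRanges` from [geneAnnotation()] (unless `x` already
#'   carries labels).
#' @param totalSnps optional denominator for `shareOfTotal` (e.g. all SNPs
#'   discovered before frequency filtering).
#' @param genomeLength optional genome length; adds `densityPerBp` =
#'   `totalSnps / genomeLength` (or panel size / length if no total given).
#' @return a list with `nLoci`, `nGenic`, `nIntergenic`, `perGene` (named
#'   integer vector over genic labels), `perGeneShareOfGenic` (percent),
#'   `perGeneShareOfTotal` (percent, if `totalSnps`), `densityPerBp` (if
#'   `genomeLength`), and the per-locus `table`.
#' @export
summarizeAnnotation <- function(x, annotation = NULL, totalSnps = NULL,
                                genomeLength = NULL) {
  if (is(x, "GenotypeMatrix")) x <- positions(x)
  if (is.numeric(x)) {
    if (is.null(annotation))
      stop("positions need an 'annotation' to be classified")
    tab <- annotateLocus(x, annotation)
  } else {
    tab <- as.data.frame(x, stringsAsFactors = FALSE)
    stopifnot(all(c("position", "label") %in% colnames(tab)))
    if (!"category" %in% colnames(tab))
      tab$category <- ifelse(grepl("~", tab$label, fixed = TRUE),
                             "INTERGENIC", "GENIC")
  }
  genic <- tab$category == "GENIC"
  perGene <- if (any(genic)) table(tab$label[genic]) else table(character())
  perGene <- setNames(as.integer(perGene), names(perGene))
  out <- list(nLoci = nrow(tab),
              nGenic = sum(genic),
              nIntergenic = sum(!genic),
              nGenes = length(perGene),
              perGene = perGene,
              perGeneShareOfGenic =
                if (sum(genic)) 100 * perGene / sum(genic) else perGene,
              table = tab)
  if (!is.null(totalSnps))
    out$perGeneShareOfTotal <- 100 * perGene / totalSnps
  if (!is.null(genomeLength))
    out$densityPerBp <-
      (if (is.null(totalSnps)) nrow(tab) else totalSnps) / genomeLength
  out
}

#' SNP density per base pair
#'
#' @param nSnps number of SNP loci.
#' @param genomeLength genome length in bp.
#' @return SNPs per bp.
#' @examples
#' signif(snpDensity(81, 121000), 2)  # 6.7e-04
#' @export
snpDensity <- function(nSnps, genomeLength) {
  stopifnot(nSnps >= 0, genomeLength > 0)
  nSnps / genomeLength
}
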