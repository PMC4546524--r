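#' Map CNV segments onto gene intervals
#'
#' A gene is marked involved for a sample iff at least one of that sample's
#' (filtered) segments overlaps the gene interval by >= 1 bp. Both inputs use
#' half-open bp semantics on disk; abutting intervals do not overlap.
#'
#' @param segments Filtered segment \code{GRanges} ([filterSegments()]).
#' @param genes Gene \code{GRanges} with a \code{name} column ([readBed()]).
#' @param byState Split involvement by gain/loss instead of pooling (returns
#'   a list of two matrices).
#' @return Binary matrix genes x samples (rownames = gene names, colnames =
#'   sample ids), or a list \code{loss}/\code{gain} of such matrices.
#' @export
mapSegmentsToGenes <- function(segments, genes, byState = FALSE) {
  samp <- unique(mcols(segments)$sample)
  build <- function(seg) {
    m <- matrix(0L, nrow = length(genes), ncol = length(samp),
                dimnames = list(mcols(genes)$name, samp))
    hits <- findOverlaps(genes, seg)
    if (length(hits)) {
      gi <- S4Vectors::queryHits(hits)
      si <- match(mcols(seg)$sample[S4Vectors::subjectHits(hits)], samp)
      m[cbind(gi, si)] <- 1L
    }
    m
  }
  if (byState)
    list(loss = build(segments[mcols(segments)$state == "loss"]),
         gain = build(segments[mcols(segments)$state == "gain"]))
  else build(segments)
}

#' Per-gene CNV involvement frequencies
#'
#' Fraction of samples in which each gene is hit by an amplification and by a
#' deletion, the quantities plotted in genome-wide CNV frequency histograms.
#'
#' @param segments Filtered segment \code{GRanges}.
#' @param genes Gene \code{GRanges}.
#' @return data.frame: gene, chrom, pos (interval start), loss_freq,
#'   gain_freq, each in [0, 1] over the declared sample count.
#' @export
cnvFrequency <- function(segments, genes) {
  m <- mapSegmentsToGenes(segments, genes, byState = TRUE)
  data.frame(gene = mcols(genes)$name,
             chrom = as.character(seqnames(genes)),
             pos = start(genes) - 1L,
             loss_freq = rowMeans(m$loss),
             gain_freq = rowMeans(m$gain),
             stringsAsFactors = FALSE)
}

#' Per-gene Fisher tests of CNV involvement versus outcome
#'
#' For each gene, the 2x2 table of involvement against the binary outcome is
#' tested with the two-sided Fisher exact test (summing all tables with
#' probability at most the observed one); p-values are Benjamini-Hochberg
#' adjusted across genes. Genes hit in no sample (or all samples) carry no
#' information and get p = 1.
#'
#' @param matrix Binary genes x samples matrix ([mapSegmentsToGenes()]).
#' @param labels Logical outcome per sample (column order).
#' @param genes Optional gene \code{GRanges} supplying coordinates; output is
#'   then sorted by genomic position for Manhattan plotting.
#' @return data.frame: gene, (chrom, pos if available,) p, adjusted_p,
#'   minus_log10_p.
#' @export
geneFisher <- function(matrix, labels, genes = NULL) {
  labels <- as.logical(labels)
  stopifnot(ncol(matrix) == length(labels))
  if (length(unique(labels)) < 2L)
    stop("both outcome classes must be present")
  p <- apply(matrix, 1, function(row) {
    if (all(row == row[1])) return(1)
    fisher.test(table(factor(row, levels = 0:1),
                      factor(labels, levels = c(FALSE, TRUE))))$p.value
  })
  out <- data.frame(gene = rownames(matrix), p = p,
                    adjusted_p = p.adjust(p, "BH"),
                    stringsAsFactors = FALSE)
  if (!is.null(genes)) {
    idx <- match(out$gene, mcols(genes)$name)
    out$chrom <- as.character(seqnames(genes))[idx]
    out$pos <- start(genes)[idx] - 1L
    out <- out[order(out$chrom, out$pos), ]
    out <- out[, c("gene", "chrom", "pos", "p", "adjusted_p")]
  }
  out$minus_log10_p <- -log10(out$p)
  rownames(out) <- NULL
  out
}

#' Pathway enrichment by Kolmogorov-Smirnov test on gene p-values
#'
#' For each gene set, compares the adjusted p-values of in-set genes against
#' those of all out-of-set genes with the two-sample KS test; set-level
#' p-values are Benjamini-Hochberg adjusted across sets. Sets are intersected
#' with the tested genes first; sets that become empty, singleton, or cover
#' all genes are errors (nothing to contrast).
#'
#' @param geneAdjustedP Named numeric vector of adjusted gene p-values.
#' @param geneSets Named list of character vectors ([readGmt()]).
#' @return data.frame: set, n_genes, p, adjusted_p.
#' @export
pathwayKS <- function(geneAdjustedP, geneSets) {
  stopifnot(!is.null(names(geneAdjustedP)), length(geneSets) > 0)
  p <- vapply(names(geneSets), function(nm) {
    inset <- names(geneAdjustedP) %in% geneSets[[nm]]
    if (sum(inset) < 2L)
      stop("gene set '", nm, "' has fewer than 2 tested genes")
    if (all(inset))
      stop("gene set '", nm, "' covers all tested genes; no contrast")
    suppressWarnings(
      ks.test(geneAdjustedP[inset], geneAdjustedP[!inset]))$p.value
  }, numeric(1))
  nGenes <- vapply(geneSets, function(s)
    sum(names(geneAdjustedP) %in% s), integer(1))
  data.frame(set = names(geneSets), n_genes = nGenes, p = p,
             adjusted_p = p.adjust(p, "BH"), row.names = NULL,
             stringsAsFactors = FALSE)
}
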