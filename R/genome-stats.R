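# Per-genome quality and architecture statistics: single-copy-gene
# completeness, duplicate-marker rate, GC%, N50, coding density and
# overlapping-gene counts. Coordinates are 1-based inclusive throughout
# (GFF3 dialect); percentages are reported to one decimal, rounded half
# away from zero.

#' The 54 archaeal single-copy marker identifiers
#'
#' A fixed set of 54 conserved single-copy gene labels used as the
#' completeness denominator. The labels are positional identifiers
#' (SCG01..SCG54); completeness only depends on which of the 54 are
#' detected, not on their biological names.
#'
#' @return character vector of length 54
#' @export
singleCopyMarkerSet <- function() sprintf("SCG%02d", 1:54)

.markerCounts <- function(genome, marker_set) {
  if (length(unique(marker_set)) != 54L)
    .fail("marker_set must contain exactly 54 distinct marker ids")
  labs <- genome@genes$marker_label
  labs <- labs[!is.na(labs) & labs %in% marker_set]
  table(factor(labs, levels = marker_set))
}

#' Single-copy-gene completeness
#'
#' Percentage of the 54 conserved single-copy markers detected at least
#' once in the genome. Duplicated markers do not raise completeness.
#'
#' @param genome a \linkS4class{GenomeRecord}
#' @param marker_set character vector of exactly 54 distinct marker ids
#' @return percent, one decimal
#' @export
completeness <- function(genome, marker_set = singleCopyMarkerSet()) {
  cnt <- .markerCounts(genome, marker_set)
  roundHalfUp(100 * sum(cnt >= 1L) / 54, 1)
}

#' Duplicate single-copy-marker percentage
#'
#' Percentage of the 54 markers present two or more times — a simple
#' within-set redundancy indicator (each duplicated marker counts once
#' however many extra copies it has).
#'
#' @inheritParams completeness
#' @return percent, one decimal
#' @export
duplicateMarkerPct <- function(genome, marker_set = singleCopyMarkerSet()) {
  cnt <- .markerCounts(genome, marker_set)
  roundHalfUp(100 * sum(cnt >= 2L) / 54, 1)
}

#' N50 of scaffold lengths
#'
#' The largest length L such that scaffolds of length >= L together
#' cover at least half the assembly.
#'
#' @param lengths positive integer vector of scaffold lengths
#' @return N50 in bp (always one of the input lengths)
#' @export
n50 <- function(lengths) {
  if (!length(lengths) || any(lengths <= 0))
    .fail("n50: need a non-empty vector of positive lengths")
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  half <- sum(s) / 2
  s[which(cumsum(s) >= half)[1]]
}

#' Coding density
#'
#' Percentage of total scaffold length covered by the union of gene
#' intervals; bases inside overlapping genes are counted once.
#'
#' @param genome a \linkS4class{GenomeRecord}
#' @return percent, one decimal
#' @export
codingDensity <- function(genome) {
  total <- sum(width(genome@scaffolds))
  if (!length(genome@genes)) return(0)
  covered <- sum(width(GenomicRanges::reduce(genome@genes,
                                             ignore.strand = TRUE)))
  roundHalfUp(100 * covered / total, 1)
}

#' Overlapping genes
#'
#' A gene is "overlapped" when it shares at least one bp with any other
#' gene on the same scaffold, regardless of strand.
#'
#' @param genome a \linkS4class{GenomeRecord}
#' @return list with \code{count} and \code{percent} (of all genes,
#'   one decimal)
#' @export
overlappedGenes <- function(genome) {
  g <- genome@genes
  if (!length(g)) return(list(count = 0L, percent = 0))
  ov <- GenomicRanges::findOverlaps(g, minoverlap = 1L,
                                    ignore.strand = TRUE,
                                    drop.self = TRUE)
  cnt <- length(unique(S4Vectors::queryHits(ov)))
  list(count = cnt, percent = roundHalfUp(100 * cnt / length(g), 1))
}

#' GC content
#'
#' Percentage of G+C among unambiguous bases (A, C, G, T); ambiguous
#' bases are excluded from the denominator.
#'
#' @param sequences a \code{DNAStringSet}, \code{DNAString} or character
#' @return percent (not rounded)
#' @export
gcPercent <- function(sequences) {
  x <- DNAStringSet(sequences)
  if (!length(x) || sum(width(x)) == 0L) .fail("gcPercent: empty input")
  f <- colSums(letterFrequency(x, c("A", "C", "G", "T")))
  denom <- sum(f)
  if (denom == 0) .fail("gcPercent: no unambiguous bases")
  100 * (f[["G"]] + f[["C"]]) / denom
}

#' Full per-genome statistics report
#'
#' Computes the assembly-quality row set for one genome: completeness and
#' duplicate-marker rate over the 54 single-copy markers, GC%, N50,
#' coding density, gene counts and lengths, and overlapping genes.
#'
#' @inheritParams completeness
#' @return one-row data.frame with columns genome_id, completeness_pct,
#'   duplicate_marker_pct, gc_pct, n50_bp, coding_density_pct, n_genes,
#'   mean_gene_length_bp, n_overlapped_genes, overlapped_pct
#' @export
genomeStats <- function(genome, marker_set = singleCopyMarkerSet()) {
  ov <- overlappedGenes(genome)
  g <- genome@genes
  data.frame(
    genome_id = genome@genomeId,
    completeness_pct = completeness(genome, marker_set),
    duplicate_marker_pct = duplicateMarkerPct(genome, marker_set),
    gc_pct = roundHalfUp(gcPercent(genome@scaffolds), 1),
    n50_bp = n50(width(genome@scaffolds)),
    coding_density_pct = codingDensity(genome),
    n_genes = length(g),
    mean_gene_length_bp = if (length(g)) roundHalfUp(mean(width(g)), 1) else 0,
    n_overlapped_genes = ov$count,
    overlapped_pct = ov$percent,
    stringsAsFactors = FALSE
  )
}

#' Write a genome statistics table
#'
#' @param genomes list of \linkS4class{GenomeRecord}
#' @param path output TSV path
#' @param marker_set completeness marker set
#' @return the combined data.frame, invisibly
#' @export
writeGenomeStats <- function(genomes, path,
                             marker_set = singleCopyMarkerSet()) {
  tab <- do.call(rbind, lapply(genomes, genomeStats, marker_set = marker_set))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
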