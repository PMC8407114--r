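# Fixtures built in code: toy genomes with fully controlled gene layouts.

suppressPackageStartupMessages({
  library(Biostrings)
  library(GenomicRanges)
  library(IRanges)
  library(SummarizedExperiment)
})

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

randProt <- function(len) paste(sample(AA20, len, replace = TRUE),
                                collapse = "")

randDna <- function(len, gc = 0.5) {
  p <- c(A = (1 - gc)/2, C = gc/2, G = gc/2, T = (1 - gc)/2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

# Build a GenomeRecord from a compact description.
# scaffolds: named integer vector of lengths.
# genes: data.frame(scaffold, start, end) plus optional marker_label,
# protein, is_marker_rps3 columns.
makeGenome <- function(id = "toy", scaffolds = c(s1 = 1000L),
                       genes = NULL, lineage = c("Archaea", "PhylX"),
                       closeClade = FALSE, gc = 0.5) {
  seqs <- DNAStringSet(vapply(scaffolds, randDna, "", gc = gc))
  names(seqs) <- names(scaffolds)
  if (is.null(genes) || nrow(genes) == 0) {
    gr <- GRanges()
  } else {
    n <- nrow(genes)
    gr <- GRanges(genes$scaffold, IRanges(genes$start, genes$end),
                  strand = if (!is.null(genes$strand)) genes$strand else "+")
    gr$gene_id <- if (!is.null(genes$gene_id)) genes$gene_id
                  else sprintf("%s_g%03d", id, seq_len(n))
    gr$rank_on_scaffold <- NA_integer_
    gr$protein <- AAStringSet(
      if (!is.null(genes$protein)) genes$protein
      else vapply(seq_len(n), function(i) randProt(80), ""))
    gr$marker_label <- if (!is.null(genes$marker_label)) genes$marker_label
                       else NA_character_
    gr$is_marker_rps3 <- if (!is.null(genes$is_marker_rps3))
      genes$is_marker_rps3 else FALSE
  }
  GenomeRecord(id, seqs, gr, lineage, closeClade)
}

# A genome carrying a given set of single-copy markers (possibly with
# duplicates), one gene per entry, laid out disjointly.
makeMarkerGenome <- function(markers, id = "mg") {
  n <- max(length(markers), 1L)
  genes <- data.frame(
    scaffold = "s1",
    start = seq(1, by = 200, length.out = n),
    end = seq(150, by = 200, length.out = n)
  )
  if (length(markers)) genes$marker_label <- markers
  makeGenome(id, scaffolds = c(s1 = as.integer(200 * n + 100)),
             genes = genes)
}
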