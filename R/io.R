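# Plain-text interchange: FASTA via Biostrings, GFF3 via rtracklayer,
# TSV depth/taxonomy tables, JSON ground truth and manifests.

#' Write genome scaffolds to FASTA
#' @param genome a \linkS4class{GenomeRecord}
#' @param path output path
#' @return the path, invisibly
#' @export
writeScaffoldFasta <- function(genome, path) {
  writeXStringSet(genome@scaffolds, path)
  invisible(path)
}

#' Write genome proteins to FASTA (ids = gene ids)
#' @inheritParams writeScaffoldFasta
#' @export
writeProteinFasta <- function(genome, path) {
  prot <- genome@genes$protein
  names(prot) <- genome@genes$gene_id
  writeXStringSet(prot, path)
  invisible(path)
}

#' Write a genome's gene table as GFF3
#'
#' 1-based inclusive coordinates with \code{ID=} attributes, via
#' rtracklayer.
#'
#' @inheritParams writeScaffoldFasta
#' @export
writeGeneGff3 <- function(genome, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    .fail("rtracklayer is required for GFF3 export")
  g <- genome@genes
  out <- GRanges(seqnames(g), IRanges(start(g), end(g)), strand = strand(g))
  out$type <- "CDS"
  out$phase <- 0L
  out$ID <- g$gene_id
  out$marker_label <- g$marker_label
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}

#' Read a gene table from GFF3 into a GRanges
#' @param path GFF3 path
#' @return GRanges with an \code{ID} metadata column
#' @export
readGeneGff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    .fail("rtracklayer is required for GFF3 import")
  rtracklayer::import(path, format = "gff3")
}

#' Write an OTU/marker depth table as TSV
#'
#' Rows are OTUs (or markers/genomes), columns are samples, with a header
#' row and the row id in the first column.
#'
#' @param depth matrix or \linkS4class{OtuTable}
#' @param path output path
#' @param id_col name of the id column
#' @return the path, invisibly
#' @export
writeDepthTable <- function(depth, path, id_col = "otu_id") {
  if (is(depth, "OtuTable")) depth <- otuDepth(depth)
  df <- data.frame(rownames(depth), depth, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a depth table TSV into a matrix
#' @param path TSV path (first column = row ids, header row of samples)
#' @return numeric matrix
#' @export
readDepthTable <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a taxonomy table for a genome collection
#'
#' Columns: genome_id, lineage (semicolon-joined), close_clade (0/1).
#'
#' @param genomes list of \linkS4class{GenomeRecord}
#' @param path output path
#' @return the path, invisibly
#' @export
writeTaxonomyTable <- function(genomes, path) {
  df <- data.frame(
    genome_id = vapply(genomes, function(g) g@genomeId, ""),
    lineage = vapply(genomes, function(g) paste(g@lineage, collapse = ";"),
                     ""),
    close_clade = vapply(genomes, function(g) as.integer(g@closeClade), 0L),
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy table
#' @param path TSV path from \code{\link{writeTaxonomyTable}}
#' @return data.frame with genome_id, lineage, close_clade
#' @export
readTaxonomyTable <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write ground truth (or a run manifest) as JSON
#' @param x a list
#' @param path output path
#' @return the path, invisibly
#' @export
writeJsonReport <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
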