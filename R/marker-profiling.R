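# Marker-gene (rpS3) community profiling: greedy centroid clustering of
# marker nucleotide sequences into OTUs at 95% global-alignment identity,
# aggregation of per-marker sequencing depths into the OTU table, and the
# minimum-occurrence filter applied before network inference.

#' Greedy centroid clustering of marker sequences into OTUs
#'
#' Sequences are processed in order of decreasing length (ties broken by
#' id, lexicographic). Each sequence joins the first existing centroid
#' whose global-alignment identity to it is at least the threshold;
#' otherwise it founds a new OTU and becomes its centroid. Centroids are
#' never re-assigned. Identity is computed over all alignment columns
#' (gaps included) of a global alignment at match +1 / mismatch -1,
#' gap open 5 / extend 2 — a fixed, documented convention so clustering
#' is exactly reproducible.
#'
#' @param markers named \code{DNAStringSet} (or character vector) of
#'   marker nucleotide sequences; names are marker ids
#' @param genome_ids optional named character vector mapping marker id to
#'   genome id (used for consensus taxonomy later)
#' @param identity_threshold minimum identity fraction to join a centroid
#' @return data.frame (one row per OTU) with columns \code{otu_id},
#'   \code{representative}, and list-column \code{members}
#' @export
clusterMarkers <- function(markers, genome_ids = NULL,
                           identity_threshold = 0.95) {
  markers <- DNAStringSet(markers)
  if (!length(markers)) .fail("clusterMarkers: no marker sequences")
  if (is.null(names(markers)))
    names(markers) <- paste0("marker_", seq_along(markers))
  ord <- order(-width(markers), names(markers))
  markers <- markers[ord]
  scoring <- .nucleotideScoring(gapOpening = 5, gapExtension = 2)
  centroids <- integer(0)             # indices into markers
  membership <- integer(length(markers))
  for (i in seq_along(markers)) {
    hit <- NA_integer_
    if (length(centroids)) {
      # identity against every centroid in one vectorized call, then the
      # first centroid (in founding order) meeting the threshold wins --
      # equivalent to testing centroids one by one
      alns <- pairwiseAlignment(markers[centroids], markers[[i]],
                                type = "global",
                                substitutionMatrix = scoring$matrix,
                                gapOpening = scoring$gapOpening,
                                gapExtension = scoring$gapExtension)
      idents <- Biostrings::nmatch(alns) / Biostrings::nchar(alns)
      ok <- which(idents >= identity_threshold)
      if (length(ok)) hit <- ok[1]
    }
    if (is.na(hit)) {
      centroids <- c(centroids, i)
      membership[i] <- length(centroids)
    } else {
      membership[i] <- hit
    }
  }
  otus <- lapply(seq_along(centroids), function(ci) {
    mem <- names(markers)[membership == ci]
    data.frame(otu_id = sprintf("OTU_%03d", ci),
               representative = names(markers)[centroids[ci]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, otus)
  out$members <- lapply(seq_along(centroids),
                        function(ci) names(markers)[membership == ci])
  attr(out, "genome_ids") <- genome_ids
  out
}

.consensusTaxonomy <- function(members, representative, genome_ids,
                               taxonomy) {
  if (is.null(genome_ids) || is.null(taxonomy)) return(NA_character_)
  lins <- unname(taxonomy[genome_ids[members]])
  lins <- lins[!is.na(lins)]
  if (!length(lins)) return(NA_character_)
  tb <- sort(table(lins), decreasing = TRUE)
  top <- names(tb)[tb == max(tb)]
  if (length(top) == 1L) return(top)
  repLin <- taxonomy[[genome_ids[[representative]]]]
  if (!is.null(repLin) && repLin %in% top) repLin else top[1]
}

#' Aggregate per-marker depths into an OTU table
#'
#' \code{depth(OTU, sample)} is the sum of the member markers' depths in
#' that sample, so total depth per sample is conserved by clustering.
#'
#' @param skeleton output of \code{\link{clusterMarkers}}
#' @param marker_depths numeric matrix, rows = marker ids, cols = samples
#' @param taxonomy optional named character vector: genome id -> lineage
#'   string, used for the majority-vote OTU taxonomy (ties broken by the
#'   representative's lineage)
#' @return an \linkS4class{OtuTable}
#' @export
otuDepths <- function(skeleton, marker_depths, taxonomy = NULL) {
  marker_depths <- as.matrix(marker_depths)
  allMembers <- unlist(skeleton$members, use.names = FALSE)
  missing <- setdiff(allMembers, rownames(marker_depths))
  if (length(missing))
    .fail("otuDepths: no depth rows for markers: %s",
          paste(missing, collapse = ", "))
  genome_ids <- attr(skeleton, "genome_ids")
  depth <- t(vapply(skeleton$members, function(mem)
    colSums(marker_depths[mem, , drop = FALSE]),
    numeric(ncol(marker_depths))))
  rownames(depth) <- skeleton$otu_id
  colnames(depth) <- colnames(marker_depths)
  tax <- vapply(seq_len(nrow(skeleton)), function(i)
    .consensusTaxonomy(skeleton$members[[i]], skeleton$representative[i],
                       genome_ids, taxonomy), "")
  OtuTable(depth,
           representative = skeleton$representative,
           members = skeleton$members,
           taxonomy = tax)
}

#' Minimum-occurrence filter
#'
#' Retains OTUs observed (depth strictly > 0) in at least
#' \code{min_samples} samples; row order is preserved. Zeros in the depth
#' table are treated as structural absences.
#'
#' @param otu_table an \linkS4class{OtuTable}
#' @param min_samples minimum number of samples with non-zero depth
#' @return filtered \linkS4class{OtuTable}
#' @export
occurrenceFilter <- function(otu_table, min_samples = 6) {
  d <- otuDepth(otu_table)
  keep <- rowSums(d > 0) >= min_samples
  if (!any(keep))
    .fail("occurrence filter removed every OTU (min_samples = %d)",
          min_samples)
  otu_table[keep, ]
}
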