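#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom IRanges IRanges CharacterList
#' @importFrom GenomicRanges GRanges seqnames start end strand width
#' @importFrom Biostrings DNAStringSet AAStringSet writeXStringSet
#'   readDNAStringSet readAAStringSet letterFrequency pairwiseAlignment
#'   alignedPattern alignedSubject nucleotideSubstitutionMatrix
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData
#'   colData assays
#' @importFrom stats cor var quantile density rmultinom rnorm runif rbinom
#'   setNames lm coef
#' @importFrom utils head write.table read.table
NULL

#' GenomeRecord: a draft genome with scaffolds, genes and taxonomy
#'
#' The unit over which assembly statistics, HGT detection and partner
#' evidence are computed. Scaffolds are held as a \code{DNAStringSet};
#' genes as a \code{GRanges} (1-based inclusive, GFF3 dialect) whose
#' metadata columns carry \code{gene_id}, \code{rank_on_scaffold},
#' \code{protein} (an \code{AAStringSet}), \code{marker_label} (single-copy
#' marker id or \code{NA}) and \code{is_marker_rps3}.
#'
#' @slot genomeId single genome identifier
#' @slot scaffolds \code{DNAStringSet} of scaffold sequences, uniquely named
#' @slot genes \code{GRanges} of protein-coding genes on those scaffolds
#' @slot lineage ordered taxon labels, domain to species
#' @slot closeClade logical; TRUE when the genome belongs to the "close"
#'   taxonomy clade (here, DPANN-like lineages)
#' @export
setClass("GenomeRecord",
  slots = c(
    genomeId   = "character",
    scaffolds  = "DNAStringSet",
    genes      = "GRanges",
    lineage    = "character",
    closeClade = "logical"
  )
)

setValidity("GenomeRecord", function(object) {
  msgs <- character()
  sn <- names(object@scaffolds)
  if (is.null(sn) || anyDuplicated(sn))
    msgs <- c(msgs, "scaffold names must be present and unique")
  g <- object@genes
  if (length(g)) {
    sc <- as.character(seqnames(g))
    if (!all(sc %in% sn)) {
      msgs <- c(msgs, "genes reference unknown scaffolds")
    } else {
      lens <- setNames(width(object@scaffolds), sn)
      if (any(start(g) < 1L) || any(end(g) > lens[sc]))
        msgs <- c(msgs, "gene coordinates outside scaffold bounds")
    }
    mc <- S4Vectors::mcols(g)
    need <- c("gene_id", "rank_on_scaffold", "protein",
              "marker_label", "is_marker_rps3")
    if (!all(need %in% colnames(mc)))
      msgs <- c(msgs, paste("gene metadata must carry:",
                            paste(need, collapse = ", ")))
    else if (anyDuplicated(mc$gene_id))
      msgs <- c(msgs, "gene ids must be unique")
  }
  if (length(object@genomeId) != 1L)
    msgs <- c(msgs, "genomeId must be a single string")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GenomeRecord
#'
#' @param genomeId genome identifier
#' @param scaffolds named \code{DNAStringSet}
#' @param genes \code{GRanges} with the metadata columns described in
#'   \linkS4class{GenomeRecord}; ranks are recomputed from start order
#' @param lineage character vector of taxon labels (domain first)
#' @param closeClade logical close-clade membership flag
#' @return a validated \linkS4class{GenomeRecord}
#' @export
GenomeRecord <- function(genomeId, scaffolds, genes, lineage,
                         closeClade = FALSE) {
  if (length(genes)) {
    ord <- order(as.character(seqnames(genes)), start(genes), end(genes))
    genes <- genes[ord]
    rk <- unlist(lapply(split(seq_along(genes),
                              as.character(seqnames(genes)))[
                          unique(as.character(seqnames(genes)))],
                        seq_along), use.names = FALSE)
    genes$rank_on_scaffold <- rk
  }
  new("GenomeRecord", genomeId = genomeId, scaffolds = scaffolds,
      genes = genes, lineage = lineage, closeClade = closeClade)
}

#' OtuTable: OTU-by-sample depth matrix with cluster membership
#'
#' Extends \code{SummarizedExperiment}: the single assay \code{"depth"}
#' holds mean per-base sequencing depths (rows = OTUs, columns = samples);
#' \code{rowData} carries the representative marker, the member markers
#' (a \code{CharacterList}) and the consensus taxonomy of each OTU.
#'
#' @export
setClass("OtuTable", contains = "SummarizedExperiment")

setValidity("OtuTable", function(object) {
  msgs <- character()
  if (!"depth" %in% names(assays(object)))
    msgs <- c(msgs, "assay 'depth' is required")
  else if (any(assay(object, "depth") < 0))
    msgs <- c(msgs, "depths must be non-negative")
  rd <- rowData(object)
  need <- c("representative", "members", "taxonomy")
  if (!all(need %in% colnames(rd)))
    msgs <- c(msgs, paste("rowData must carry:", paste(need, collapse = ", ")))
  else {
    inMember <- mapply(function(rep, mem) rep %in% mem,
                       rd$representative, as.list(rd$members))
    if (length(inMember) && !all(inMember))
      msgs <- c(msgs, "each representative must be one of its members")
    allMembers <- unlist(as.list(rd$members), use.names = FALSE)
    if (anyDuplicated(allMembers))
      msgs <- c(msgs, "a marker may belong to only one OTU")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an OtuTable
#'
#' @param depth numeric matrix, rows = OTUs (named), columns = samples (named)
#' @param representative character vector, representative marker per OTU
#' @param members list or \code{CharacterList} of member marker ids per OTU
#' @param taxonomy character vector of consensus lineages per OTU
#' @return an \linkS4class{OtuTable}
#' @export
OtuTable <- function(depth, representative, members, taxonomy) {
  depth <- as.matrix(depth)
  if (is.null(rownames(depth)))
    rownames(depth) <- paste0("OTU_", seq_len(nrow(depth)))
  rd <- DataFrame(
    representative = representative,
    members = as(members, "CharacterList"),
    taxonomy = taxonomy,
    row.names = rownames(depth)
  )
  new("OtuTable",
      SummarizedExperiment(assays = list(depth = depth), rowData = rd))
}

#' Depth matrix accessor
#' @param x an \linkS4class{OtuTable}
#' @return the OTU-by-sample depth matrix
#' @export
otuDepth <- function(x) assay(x, "depth")

setMethod("show", "GenomeRecord", function(object) {
  cat("GenomeRecord:", object@genomeId, "\n")
  cat(" ", length(object@scaffolds), "scaffolds,",
      sum(width(object@scaffolds)), "bp;",
      length(object@genes), "genes\n")
  cat("  lineage:", paste(object@lineage, collapse = "; "),
      if (object@closeClade) "[close clade]" else "", "\n")
})

#' CorrelationNetwork: filtered basis-correlation network over OTUs
#'
#' Holds the symmetric basis-correlation (rho) and permutation pseudo-p
#' matrices, the edge set passing the |rho| and alpha filters, and a
#' modularity partition of the nodes.
#'
#' @slot rho symmetric OTU-by-OTU basis correlation matrix, unit diagonal
#' @slot pseudoP symmetric matrix of two-sided permutation pseudo-p values
#' @slot edges data.frame with columns source, target, rho, p (and module
#'   after \code{detectModules})
#' @slot nodes character vector of node (OTU) ids
#' @slot taxonomy character vector of node taxonomies (parallel to nodes)
#' @slot modules named integer vector, node -> module id (may be empty)
#' @slot modularity modularity Q of the partition (NA before detection)
#' @slot params list of the filter parameters used
#' @export
setClass("CorrelationNetwork",
  slots = c(
    rho        = "matrix",
    pseudoP    = "matrix",
    edges      = "data.frame",
    nodes      = "character",
    taxonomy   = "character",
    modules    = "integer",
    modularity = "numeric",
    params     = "list"
  )
)

setValidity("CorrelationNetwork", function(object) {
  msgs <- character()
  r <- object@rho
  if (!isTRUE(all.equal(r, t(r), tolerance = 1e-8)))
    msgs <- c(msgs, "rho must be symmetric")
  if (any(abs(diag(r) - 1) > 1e-8))
    msgs <- c(msgs, "rho must have unit diagonal")
  p <- object@pseudoP
  pv <- p[upper.tri(p)]
  if (any(pv < 0 | pv > 1, na.rm = TRUE))
    msgs <- c(msgs, "pseudo-p values must lie in [0, 1]")
  if (nrow(object@edges) &&
      !all(c(object@edges$source, object@edges$target) %in% object@nodes))
    msgs <- c(msgs, "edges must connect known nodes")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "CorrelationNetwork", function(object) {
  cat("CorrelationNetwork:", length(object@nodes), "nodes,",
      nrow(object@edges), "edges\n")
  if (length(object@modules))
    cat("  modules:", length(unique(object@modules)),
        " Q =", signif(object@modularity, 3), "\n")
  cat("  filters: |rho|", if (isTRUE(object@params$inclusive)) ">=" else ">",
      object@params$rho_threshold, ", p <", object@params$alpha, "\n")
})

#' Edge table accessor
#' @param x a \linkS4class{CorrelationNetwork}
#' @return data.frame of retained edges
#' @export
networkEdges <- function(x) x@edges

#' Module partition accessor
#' @param x a \linkS4class{CorrelationNetwork}
#' @return named integer vector mapping node to module id
#' @export
networkModules <- function(x) x@modules
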