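# Shared alignment kernel used by marker clustering and both HGT detectors.
# Conventions follow BLAST: identity is computed over all alignment columns
# (gap columns included, "pident"); a gap of length L costs open + L * ext.

.proteinScoring <- function() {
  m <- getBLOSUM62()
  list(matrix = m, gapOpening = 11, gapExtension = 1, type = "protein")
}

.nucleotideScoring <- function(match = 1, mismatch = -1,
                               gapOpening = 5, gapExtension = 2) {
  m <- nucleotideSubstitutionMatrix(match = match, mismatch = mismatch,
                                    baseOnly = TRUE)
  list(matrix = m, gapOpening = gapOpening, gapExtension = gapExtension,
       type = "nucleotide")
}

# BLOSUM62 without loading Biostrings' data() at run time
getBLOSUM62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

.asXString <- function(x, type) {
  if (type == "protein") {
    if (is.character(x)) Biostrings::AAString(x) else x
  } else {
    if (is.character(x)) Biostrings::DNAString(x) else x
  }
}

# alignment-column statistics; identity over all columns (gaps included),
# coverage counts the query residues inside the aligned region. `side`
# names which side of the PairwiseAlignments object carries the query.
.alnStats <- function(aln, queryLen, side = c("pattern", "subject")) {
  side <- match.arg(side)
  ncol <- Biostrings::nchar(aln)
  nid <- Biostrings::nmatch(aln)
  rng <- if (side == "pattern") Biostrings::pattern(aln)
         else Biostrings::subject(aln)
  qres <- end(rng) - start(rng) + 1L
  list(
    identity_pct = 100 * nid / ncol,
    aligned_length = as.integer(ncol),
    query_coverage_pct = 100 * qres / queryLen
  )
}

#' Global pairwise alignment with BLAST-style identity
#'
#' Optimal Needleman-Wunsch alignment. Identity is the fraction of
#' identical columns over all alignment columns, gap columns included
#' (the BLAST "pident" convention); query coverage is the fraction of
#' query residues inside the alignment (always 100 for a global
#' alignment).
#'
#' @param a,b sequences (character, \code{AAString}/\code{DNAString})
#' @param type "protein" (BLOSUM62, gap open 11 / extend 1) or
#'   "nucleotide" (match +1 / mismatch -1, gap open 5 / extend 2)
#' @param scoring optional list overriding \code{matrix},
#'   \code{gapOpening}, \code{gapExtension}
#' @param query_id,subject_id identifiers echoed in the result
#' @return list with \code{query_id}, \code{subject_id}, \code{score},
#'   \code{identity_pct}, \code{aligned_length}, \code{query_coverage_pct}
#' @export
alignGlobal <- function(a, b, type = c("protein", "nucleotide"),
                        scoring = NULL, query_id = "query",
                        subject_id = "subject") {
  type <- match.arg(type)
  if (is.null(scoring))
    scoring <- if (type == "protein") .proteinScoring()
               else .nucleotideScoring()
  qa <- .asXString(a, type); sb <- .asXString(b, type)
  if (length(qa) == 0L || length(sb) == 0L)
    .fail("alignGlobal: sequences must be non-empty")
  aln <- pairwiseAlignment(qa, sb, type = "global",
                           substitutionMatrix = scoring$matrix,
                           gapOpening = scoring$gapOpening,
                           gapExtension = scoring$gapExtension)
  st <- .alnStats(aln, length(qa))
  c(list(query_id = query_id, subject_id = subject_id,
         score = Biostrings::score(aln)), st)
}

#' Local pairwise alignment (Smith-Waterman)
#'
#' Optimal local alignment; \code{aligned_length} counts the columns of
#' the optimal local block and coverage the query residues inside it.
#' When no positive-scoring block exists the result is a no-hit record
#' (score 0, aligned_length 0).
#'
#' @inheritParams alignGlobal
#' @return as \code{alignGlobal}, plus \code{hit} (logical)
#' @export
alignLocal <- function(a, b, type = c("protein", "nucleotide"),
                       scoring = NULL, query_id = "query",
                       subject_id = "subject") {
  type <- match.arg(type)
  if (is.null(scoring))
    scoring <- if (type == "protein") .proteinScoring()
               else .nucleotideScoring()
  qa <- .asXString(a, type); sb <- .asXString(b, type)
  if (length(qa) == 0L || length(sb) == 0L)
    .fail("alignLocal: sequences must be non-empty")
  aln <- pairwiseAlignment(qa, sb, type = "local",
                           substitutionMatrix = scoring$matrix,
                           gapOpening = scoring$gapOpening,
                           gapExtension = scoring$gapExtension)
  sc <- Biostrings::score(aln)
  if (sc <= 0) {
    return(list(query_id = query_id, subject_id = subject_id, score = 0,
                identity_pct = NA_real_, aligned_length = 0L,
                query_coverage_pct = 0, hit = FALSE))
  }
  st <- .alnStats(aln, length(qa))
  c(list(query_id = query_id, subject_id = subject_id, score = sc),
    st, list(hit = TRUE))
}

#' Exhaustive homology search with self-normalized scores
#'
#' Aligns every query locally against every database entry (desk-scale
#' exhaustive; no heuristic prefilter) and normalizes each alignment
#' score by the query's self-alignment score, so a perfect hit scores 1
#' regardless of length. Hits below \code{min_score} (raw score) are
#' dropped; remaining hits are ordered by score descending, ties by
#' subject id ascending.
#'
#' @param queries named \code{AAStringSet} (or character vector)
#' @param database named \code{AAStringSet} (or character vector)
#' @param taxonomy optional named character vector or list mapping
#'   database entry name to its taxonomy (lineage string or vector)
#' @param min_score drop hits with raw score below this
#' @param type passed to the aligners
#' @return named list (one element per query) of data.frames with columns
#'   query_id, subject_id, score, normalized_score, identity_pct,
#'   aligned_length, query_coverage_pct, subject_taxonomy
#' @export
searchAll <- function(queries, database, taxonomy = NULL, min_score = 0,
                      type = "protein") {
  queries <- if (type == "protein") AAStringSet(queries)
             else DNAStringSet(queries)
  database <- if (type == "protein") AAStringSet(database)
              else DNAStringSet(database)
  if (length(database) == 0L) .fail("searchAll: database is empty")
  if (is.null(names(queries)))
    names(queries) <- paste0("q", seq_along(queries))
  if (is.null(names(database)))
    names(database) <- paste0("s", seq_along(database))
  scoring <- if (type == "protein") .proteinScoring()
             else .nucleotideScoring()
  taxOf <- function(id) {
    if (is.null(taxonomy)) return(NA_character_)
    tx <- taxonomy[[id]]
    if (is.null(tx)) NA_character_ else paste(tx, collapse = ";")
  }
  out <- vector("list", length(queries))
  names(out) <- names(queries)
  for (qi in seq_along(queries)) {
    q <- queries[[qi]]
    selfScore <- Biostrings::score(
      pairwiseAlignment(q, q, type = "local",
                        substitutionMatrix = scoring$matrix,
                        gapOpening = scoring$gapOpening,
                        gapExtension = scoring$gapExtension))
    if (selfScore <= 0)
      .fail("searchAll: query '%s' has non-positive self-score",
            names(queries)[qi])
    alns <- pairwiseAlignment(database, q, type = "local",
                              substitutionMatrix = scoring$matrix,
                              gapOpening = scoring$gapOpening,
                              gapExtension = scoring$gapExtension)
    scores <- Biostrings::score(alns)
    keep <- which(scores > 0 & scores >= min_score)
    if (!length(keep)) {
      out[[qi]] <- data.frame(query_id = character(), subject_id = character(),
                              score = numeric(), normalized_score = numeric(),
                              identity_pct = numeric(),
                              aligned_length = integer(),
                              query_coverage_pct = numeric(),
                              subject_taxonomy = character(),
                              stringsAsFactors = FALSE)
      next
    }
    # pattern side of alns is the database entry; the query is the subject
    kept <- alns[keep]
    ncolA <- Biostrings::nchar(kept)
    nid <- Biostrings::nmatch(kept)
    qrng <- Biostrings::subject(kept)
    hits <- data.frame(
      query_id = names(queries)[qi],
      subject_id = names(database)[keep],
      score = scores[keep],
      normalized_score = scores[keep] / selfScore,
      identity_pct = 100 * nid / ncolA,
      aligned_length = as.integer(ncolA),
      query_coverage_pct = 100 * (end(qrng) - start(qrng) + 1L) / length(q),
      subject_taxonomy = vapply(names(database)[keep], taxOf, ""),
      stringsAsFactors = FALSE
    )
    hits <- hits[order(-hits$score, hits$subject_id), , drop = FALSE]
    rownames(hits) <- NULL
    out[[qi]] <- hits
  }
  out
}
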