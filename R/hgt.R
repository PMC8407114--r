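# Two horizontal-gene-transfer detectors.
#
# (1) Directional interphylum HGT calls: each gene's homology hits are
# split by subject taxonomy into self (the recipient's own lineage,
# dropped), close (the DPANN-like clade) and distal (everything else);
# the summed normalized scores of the close and distal groups place the
# gene in a 2-D score space, and a gene is called transferred when its
# close support is low and its distal support high relative to
# per-genome thresholds fitted from the score distributions.
#
# (2) Recent-HGT xenolog scan: high-identity protein matches between a
# focal genome and companion community genomes outside the close clade,
# with identity/length thresholds and a terminal-gene/scaffold-length
# filter to avoid binning artefacts at contig edges.

#' Taxonomy grouping for HGT scoring
#'
#' @param self_taxa taxon labels treated as the recipient's own lineage
#'   (hits dropped)
#' @param close_taxa taxon labels of the close clade (here, DPANN-like)
#' @return list of class \code{TaxonomyGrouping}
#' @export
taxonomyGrouping <- function(self_taxa, close_taxa) {
  structure(list(self_taxa = as.character(self_taxa),
                 close_taxa = as.character(close_taxa)),
            class = "TaxonomyGrouping")
}

.hitGroup <- function(subject_taxonomy, grouping) {
  labs <- strsplit(subject_taxonomy %||% "", ";", fixed = TRUE)[[1]]
  if (any(labs %in% grouping$self_taxa)) return("self")
  if (any(labs %in% grouping$close_taxa)) return("close")
  "distal"
}

#' Close/distal score sums for one gene
#'
#' Drops self-taxa hits, then sums the normalized scores of the close
#' and distal groups, each over at most \code{max_hits} best hits.
#'
#' @param hits data.frame of hits for one gene (as returned per query by
#'   \code{\link{searchAll}}), sorted by score descending
#' @param grouping a \code{\link{taxonomyGrouping}}
#' @param max_hits cap on hits counted per group
#' @return list with \code{close_score}, \code{distal_score}, and
#'   \code{best_distal} (row of the best distal hit, or NULL)
#' @export
groupScores <- function(hits, grouping, max_hits = 50) {
  if (is.null(hits) || nrow(hits) == 0)
    return(list(close_score = 0, distal_score = 0, best_distal = NULL))
  grp <- vapply(hits$subject_taxonomy, .hitGroup, "", grouping = grouping,
                USE.NAMES = FALSE)
  close <- hits[grp == "close", , drop = FALSE]
  distal <- hits[grp == "distal", , drop = FALSE]
  list(
    close_score = sum(head(close$normalized_score, max_hits)),
    distal_score = sum(head(distal$normalized_score, max_hits)),
    best_distal = if (nrow(distal)) distal[1, , drop = FALSE] else NULL
  )
}

.kdeValley <- function(x) {
  d <- stats::density(x, bw = "nrd0", n = 512)
  y <- d$y
  # interior local maxima; ignore noise wiggles below 10% of the peak
  ismax <- which(diff(sign(diff(y))) == -2) + 1L
  ismax <- ismax[y[ismax] >= 0.1 * max(y)]
  if (length(ismax) >= 2) {
    lo <- ismax[1]; hi <- ismax[2]
    valley <- lo + which.min(y[lo:hi]) - 1L
    # a real valley dips well below both flanking modes
    if (y[valley] <= 0.5 * min(y[lo], y[hi]))
      return(list(tau = d$x[valley], fallback = FALSE))
  }
  list(tau = NA_real_, fallback = TRUE)
}

#' Fit close/distal score thresholds for one genome
#'
#' A Gaussian kernel density (Silverman's rule bandwidth, 512-point grid)
#' is fitted to each score distribution; the threshold is the score at
#' the first local minimum between the first two modes. When a
#' distribution is unimodal the fallback is the 25th percentile for the
#' close scores and the 75th for the distal scores, and the report flags
#' the fallback.
#'
#' @param scores data.frame with columns \code{close_score} and
#'   \code{distal_score}, one row per gene (>= 20 genes)
#' @return list with \code{tau_close}, \code{tau_distal},
#'   \code{close_fallback}, \code{distal_fallback}, \code{method}
#' @export
fitThresholds <- function(scores) {
  if (nrow(scores) < 20)
    .fail(paste("fitThresholds: need >= 20 genes (have %d);",
                "supply explicit thresholds instead"), nrow(scores))
  fitOne <- function(x, fallback_q) {
    if (length(unique(x)) == 1L)
      return(list(tau = x[1], fallback = TRUE))
    v <- .kdeValley(x)
    if (v$fallback) v$tau <- unname(quantile(x, fallback_q))
    v
  }
  cl <- fitOne(scores$close_score, 0.25)
  di <- fitOne(scores$distal_score, 0.75)
  list(tau_close = cl$tau, tau_distal = di$tau,
       close_fallback = cl$fallback, distal_fallback = di$fallback,
       method = "kde_valley")
}

#' Call directional interphylum HGTs for one genome
#'
#' A gene is called horizontally transferred when its close-group score
#' is at or below \code{tau_close} and its distal-group score at or
#' above \code{tau_distal}. The donor is the phylum (second lineage
#' field) of the gene's best distal hit; only calls whose donor phylum
#' differs from the recipient's phylum are reported ("interphylum"), and
#' hits without a phylum are attributed to "unclassified" and excluded.
#'
#' @param gene_hits named list of per-gene hit data.frames (from
#'   \code{\link{searchAll}})
#' @param grouping a \code{\link{taxonomyGrouping}}
#' @param taus list with \code{tau_close}, \code{tau_distal} (from
#'   \code{\link{fitThresholds}} or supplied explicitly)
#' @param recipient_phylum the recipient genome's phylum label
#' @param max_hits per-group hit cap
#' @return data.frame, one row per gene: gene_id, close_score,
#'   distal_score, is_hgt, donor_phylum, donor_taxon
#' @export
callHgt <- function(gene_hits, grouping, taus, recipient_phylum,
                    max_hits = 50) {
  rows <- lapply(names(gene_hits), function(gid) {
    gs <- groupScores(gene_hits[[gid]], grouping, max_hits)
    donorPhylum <- NA_character_
    donorTaxon <- NA_character_
    if (!is.null(gs$best_distal)) {
      lin <- strsplit(gs$best_distal$subject_taxonomy, ";", fixed = TRUE)[[1]]
      donorPhylum <- if (length(lin) >= 2) lin[2] else "unclassified"
      donorTaxon <- gs$best_distal$subject_taxonomy
    }
    isHgt <- gs$close_score <= taus$tau_close &&
             gs$distal_score >= taus$tau_distal &&
             !is.null(gs$best_distal) &&
             !is.na(donorPhylum) && donorPhylum != "unclassified" &&
             donorPhylum != recipient_phylum
    data.frame(gene_id = gid,
               close_score = gs$close_score,
               distal_score = gs$distal_score,
               is_hgt = isHgt,
               donor_phylum = if (isHgt) donorPhylum else NA_character_,
               donor_taxon = if (isHgt) donorTaxon else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Donor-phylum summary of interphylum HGT calls
#'
#' @param calls data.frame of calls (possibly concatenated over genomes)
#'   with columns \code{is_hgt} and \code{donor_phylum}
#' @return data.frame sorted by count descending: donor_phylum, count,
#'   percent (of all interphylum calls, one decimal)
#' @export
donorSummary <- function(calls) {
  if (is.null(calls) || !nrow(calls)) .fail("donorSummary: no calls")
  hg <- calls[calls$is_hgt & !is.na(calls$donor_phylum), , drop = FALSE]
  if (!nrow(hg))
    return(data.frame(donor_phylum = character(), count = integer(),
                      percent = numeric(), stringsAsFactors = FALSE))
  tb <- sort(table(hg$donor_phylum), decreasing = TRUE)
  data.frame(donor_phylum = names(tb),
             count = as.integer(tb),
             percent = roundHalfUp(100 * as.integer(tb) / nrow(hg), 1),
             stringsAsFactors = FALSE)
}

#' Least-squares fit of HGT count on gene count across genomes
#'
#' Descriptive companion to the donor summary: ordinary least squares of
#' the per-genome interphylum HGT count on the per-genome gene total,
#' with R-squared.
#'
#' @param n_genes per-genome gene counts
#' @param n_hgts per-genome interphylum HGT counts
#' @return list with \code{intercept}, \code{slope}, \code{r_squared}
#' @export
hgtRegression <- function(n_genes, n_hgts) {
  fit <- lm(n_hgts ~ n_genes)
  list(intercept = unname(coef(fit)[1]),
       slope = unname(coef(fit)[2]),
       r_squared = summary(fit)$r.squared)
}

.terminalFlags <- function(genome) {
  g <- genome@genes
  sc <- as.character(seqnames(g))
  rk <- g$rank_on_scaffold
  nOn <- stats::ave(rep(1L, length(g)), sc, FUN = sum)
  setNames(rk == 1L | rk == nOn, g$gene_id)
}

.scaffoldLenOf <- function(genome) {
  lens <- setNames(width(genome@scaffolds), names(genome@scaffolds))
  setNames(lens[as.character(seqnames(genome@genes))],
           genome@genes$gene_id)
}

#' Scan for recent xenologs between a focal genome and its community
#'
#' Every focal protein is searched against all proteins of community
#' genomes outside the close clade. A pair passes when identity >=
#' \code{min_identity}, aligned region >= \code{min_aln_aa} amino acids,
#' both genes sit on scaffolds >= \code{min_scaffold_bp}, and neither
#' gene is the first or last gene of its scaffold (terminal genes are
#' frequent chimera/binning artefacts). Every rejected pair that reached
#' the alignment stage is kept with reason codes; partners inside the
#' close clade are excluded before alignment.
#'
#' @param focal a \linkS4class{GenomeRecord}
#' @param community list of \linkS4class{GenomeRecord} (the companion
#'   genomes binned from the same communities)
#' @param min_identity minimum percent identity (default 70)
#' @param min_aln_aa minimum aligned length in amino acids (default 100)
#' @param min_scaffold_bp minimum scaffold length for eligibility
#'   (default 5000)
#' @param min_report_identity pairs below this identity are not recorded
#'   at all (keeps the report to plausible homologs; default 30)
#' @return data.frame, one row per recorded pair: focal_gene_id,
#'   partner_gene_id, partner_genome_id, identity_pct, aligned_length_aa,
#'   query_coverage_pct, focal_terminal, partner_terminal, passes,
#'   reasons (comma-separated codes: LOW_IDENTITY, SHORT_ALIGNMENT,
#'   TERMINAL_GENE, SHORT_SCAFFOLD)
#' @export
recentHgtScan <- function(focal, community, min_identity = 70,
                          min_aln_aa = 100, min_scaffold_bp = 5000,
                          min_report_identity = 30) {
  if (!length(community)) .fail("recentHgtScan: community set is empty")
  community <- unname(Filter(function(g) !g@closeClade, community))
  if (!length(community))
    .fail("recentHgtScan: no community genomes outside the close clade")
  fTerm <- .terminalFlags(focal)
  fScaf <- .scaffoldLenOf(focal)
  # pooled partner protein set with genome bookkeeping
  pProt <- do.call(c, lapply(community, function(g) {
    p <- g@genes$protein
    names(p) <- g@genes$gene_id
    p
  }))
  pGenome <- unlist(lapply(community, function(g)
    setNames(rep(g@genomeId, length(g@genes)), g@genes$gene_id)))
  pTerm <- unlist(lapply(community, .terminalFlags))
  pScaf <- unlist(lapply(community, .scaffoldLenOf))
  scoring <- .proteinScoring()
  rows <- list()
  for (fi in seq_along(focal@genes)) {
    fid <- focal@genes$gene_id[fi]
    fprot <- focal@genes$protein[[fi]]
    alns <- pairwiseAlignment(pProt, fprot, type = "local",
                              substitutionMatrix = scoring$matrix,
                              gapOpening = scoring$gapOpening,
                              gapExtension = scoring$gapExtension)
    scores <- Biostrings::score(alns)
    keep <- which(scores > 0)
    if (!length(keep)) next
    kept <- alns[keep]
    ncolA <- Biostrings::nchar(kept)
    idPct <- 100 * Biostrings::nmatch(kept) / ncolA
    qrng <- Biostrings::subject(kept)   # focal side
    qres <- end(qrng) - start(qrng) + 1L
    for (k in seq_along(keep)) {
      pid <- names(pProt)[keep[k]]
      if (is.na(idPct[k]) || idPct[k] < min_report_identity) next
      reasons <- character()
      if (idPct[k] < min_identity) reasons <- c(reasons, "LOW_IDENTITY")
      if (ncolA[k] < min_aln_aa) reasons <- c(reasons, "SHORT_ALIGNMENT")
      if (fScaf[[fid]] < min_scaffold_bp || pScaf[[pid]] < min_scaffold_bp)
        reasons <- c(reasons, "SHORT_SCAFFOLD")
      if (fTerm[[fid]] || pTerm[[pid]])
        reasons <- c(reasons, "TERMINAL_GENE")
      rows[[length(rows) + 1L]] <- data.frame(
        focal_gene_id = fid,
        partner_gene_id = pid,
        partner_genome_id = unname(pGenome[[pid]]),
        identity_pct = idPct[k],
        aligned_length_aa = as.integer(ncolA[k]),
        query_coverage_pct = 100 * qres[k] / length(fprot),
        focal_terminal = unname(fTerm[[fid]]),
        partner_terminal = unname(pTerm[[pid]]),
        passes = length(reasons) == 0L,
        reasons = paste(reasons, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(focal_gene_id = character(),
                      partner_gene_id = character(),
                      partner_genome_id = character(),
                      identity_pct = numeric(), aligned_length_aa = integer(),
                      query_coverage_pct = numeric(),
                      focal_terminal = logical(), partner_terminal = logical(),
                      passes = logical(), reasons = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(-out$identity_pct, out$focal_gene_id, out$partner_gene_id), ,
      drop = FALSE] -> out
  rownames(out) <- NULL
  out
}
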