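# Synthetic genome-collection generator: random scaffolds at a target GC,
# genes laid left-to-right with a controllable overlapped-gene fraction,
# planted single-copy markers, one rpS3 marker per genome, and planted
# horizontal-transfer events at controlled amino-acid divergence (with
# optional placement as the first/last gene of a scaffold). Every planted
# record is resolvable to a generated id through the returned ground truth.

.AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
           "L","K","M","F","P","S","T","W","Y","V")

.randProtein <- function(len) paste(sample(.AA20, len, replace = TRUE),
                                    collapse = "")

# sample one integer from [lo, hi]; safe when lo == hi (plain
# sample(lo:hi, 1) would misread a scalar as a population size)
.sampleRange <- function(lo, hi) {
  if (lo >= hi) return(as.integer(lo))
  as.integer(lo + sample.int(hi - lo + 1L, 1L) - 1L)
}

.samplePick <- function(pool, n = 1L) pool[sample.int(length(pool), n)]

.randDna <- function(len, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

#' Substitute a controlled number of residues in a protein
#'
#' Replaces exactly \code{round(nchar(x) * divergence)} positions, chosen
#' without replacement, by a uniform draw over the other 19 standard
#' residues (the original residue is never re-drawn), so the expected
#' global identity to the original is analytically exact:
#' \code{100 * (L - round(L * divergence)) / L}.
#'
#' @param x protein sequence (character)
#' @param divergence amino-acid divergence in [0, 1)
#' @return mutated protein sequence
#' @export
mutateProtein <- function(x, divergence) {
  if (divergence < 0 || divergence >= 1)
    .fail("divergence must lie in [0, 1)")
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  L <- length(chars)
  k <- round(L * divergence)
  if (k == 0) return(x)
  pos <- sample.int(L, k)
  for (i in pos) {
    chars[i] <- sample(setdiff(.AA20, chars[i]), 1)
  }
  paste(chars, collapse = "")
}

#' Genome collection simulation configuration
#'
#' @param n_genomes number of genomes
#' @param scaffolds_per_genome integer range \code{c(min, max)}
#' @param scaffold_length bp range \code{c(min, max)}
#' @param genes_per_scaffold integer range \code{c(min, max)}
#' @param overlap_fraction target fraction of genes sharing >= 1 bp with a
#'   neighbour
#' @param gc target GC fraction of scaffold sequence
#' @param marker_presence list (length n_genomes; NULL plants none) of
#'   single-copy marker id vectors to plant per genome; duplicated ids
#'   plant extra copies
#' @param planted_hgt_events list of events, each a list with fields
#'   \code{donor}, \code{recipient} (genome indices, distinct),
#'   \code{n_genes}, \code{aa_divergence} in [0, 1), \code{terminal}
#'   (logical), and optional \code{label} ("recent" requires divergence
#'   < 0.3, "ancient" requires >= 0.5)
#' @param close_clade_members integer indices of genomes in the "close"
#'   (DPANN-like) clade
#' @param lineages optional list of lineage character vectors per genome;
#'   defaults assign one phylum per genome (close-clade members share a
#'   DPANN-like phylum)
#' @param seed master integer seed
#' @return validated config list of class \code{GenomeConfig}
#' @export
genomeConfig <- function(n_genomes,
                         scaffolds_per_genome = c(2L, 3L),
                         scaffold_length = c(8000L, 15000L),
                         genes_per_scaffold = c(6L, 10L),
                         overlap_fraction = 0.2,
                         gc = 0.32,
                         marker_presence = NULL,
                         planted_hgt_events = list(),
                         close_clade_members = integer(),
                         lineages = NULL,
                         seed = 1) {
  stopifnot(n_genomes >= 1)
  .checkProb(overlap_fraction, "overlap_fraction")
  .checkProb(gc, "gc", lo = 0, hi = 1, lo.open = TRUE)
  if (overlap_fraction > 0 && max(genes_per_scaffold) < 2)
    .fail("overlap_fraction > 0 is unreachable with < 2 genes per scaffold")
  for (ev in planted_hgt_events) {
    if (ev$donor == ev$recipient) .fail("HGT donor must differ from recipient")
    if (ev$donor > n_genomes || ev$recipient > n_genomes ||
        ev$donor < 1 || ev$recipient < 1)
      .fail("HGT event genome index out of range")
    if (ev$aa_divergence < 0 || ev$aa_divergence >= 1)
      .fail("aa_divergence must lie in [0, 1)")
    lab <- ev$label
    if (!is.null(lab)) {
      if (lab == "recent" && ev$aa_divergence >= 0.3)
        .fail("'recent' events require aa_divergence < 0.3")
      if (lab == "ancient" && ev$aa_divergence < 0.5)
        .fail("'ancient' events require aa_divergence >= 0.5")
    }
  }
  if (!is.null(marker_presence) && length(marker_presence) != n_genomes)
    .fail("marker_presence must have one entry per genome")
  structure(list(n_genomes = as.integer(n_genomes),
                 scaffolds_per_genome = as.integer(scaffolds_per_genome),
                 scaffold_length = as.integer(scaffold_length),
                 genes_per_scaffold = as.integer(genes_per_scaffold),
                 overlap_fraction = overlap_fraction,
                 gc = gc,
                 marker_presence = marker_presence,
                 planted_hgt_events = planted_hgt_events,
                 close_clade_members = as.integer(close_clade_members),
                 lineages = lineages,
                 seed = as.integer(seed)),
            class = "GenomeConfig")
}

.defaultLineage <- function(i, close) {
  if (close) c("Archaea", "DPANN-like", sprintf("CloseGenus_%02d", i),
               sprintf("close_sp_%02d", i))
  else c("Archaea", sprintf("Phylum_%02d", i), sprintf("Genus_%02d", i),
         sprintf("sp_%02d", i))
}

# lay genes on one scaffold; returns data.frame(start, end) with
# n_overlap junctions producing overlapped neighbours
.layGenes <- function(scafLen, nGenes, nOverlapJunctions) {
  space <- scafLen / nGenes
  lenNt <- pmax(189, 3 * floor(runif(nGenes, 0.45, 0.72) * space / 3))
  ovJunc <- rep(FALSE, nGenes)
  if (nOverlapJunctions > 0 && nGenes >= 2) {
    # non-adjacent junctions so each marks exactly two genes
    cand <- seq(2, nGenes, by = 2)
    ovJunc[cand[seq_len(min(nOverlapJunctions, length(cand)))]] <- TRUE
  }
  start <- integer(nGenes); end <- integer(nGenes)
  pos <- 1L
  for (k in seq_len(nGenes)) {
    if (k > 1L) {
      pos <- if (ovJunc[k]) end[k - 1L] - sample(3:30, 1)
             else end[k - 1L] + sample(10:60, 1)
      pos <- min(max(pos, 1L), scafLen - 60L)
    }
    start[k] <- pos
    end[k] <- min(pos + lenNt[k] - 1L, scafLen)
  }
  data.frame(start = start, end = end)
}

#' Generate a synthetic genome collection with planted ground truth
#'
#' Builds \code{n_genomes} \linkS4class{GenomeRecord} objects: random
#' scaffolds at the configured GC, genes laid left-to-right with the
#' target overlapped fraction, planted single-copy markers (copies of a
#' fixed reference marker protein set), one rpS3 marker nucleotide
#' sequence per genome, and planted transfer events realised by copying
#' the donor protein into the recipient with exactly
#' \code{round(L * aa_divergence)} substitutions. "Terminal" events place
#' the transferred copy as the first or last gene of its scaffold;
#' otherwise a mid-scaffold slot on a scaffold >= 5 kb is used.
#'
#' @param config a \code{\link{genomeConfig}}
#' @return list with \code{genomes} (named list of GenomeRecord),
#'   \code{rps3} (named \code{DNAStringSet}, one per genome) and
#'   \code{truth} (list: \code{planted_hgt_genes} data.frame with
#'   recipient/donor gene ids and expected identity,
#'   \code{planted_marker_counts}, \code{close_clade_members})
#' @export
generateGenomes <- function(config) {
  stopifnot(inherits(config, "GenomeConfig"))
  set.seed(streamSeed(config$seed, "genomes"))
  markerSet <- singleCopyMarkerSet()
  refMarkers <- setNames(vapply(markerSet, function(m)
    .randProtein(.sampleRange(120L, 200L)), ""), markerSet)

  nG <- config$n_genomes
  genomes <- vector("list", nG)
  rps3 <- character(nG)
  geneTabs <- vector("list", nG)

  for (i in seq_len(nG)) {
    gid <- sprintf("genome_%02d", i)
    nSc <- .sampleRange(config$scaffolds_per_genome[1],
                        config$scaffolds_per_genome[2])
    scLens <- vapply(seq_len(nSc), function(s)
      .sampleRange(config$scaffold_length[1], config$scaffold_length[2]), 0L)
    scNames <- sprintf("%s_scaf_%02d", gid, seq_len(nSc))
    rows <- list()
    for (s in seq_len(nSc)) {
      nGenes <- .sampleRange(config$genes_per_scaffold[1],
                             config$genes_per_scaffold[2])
      nOvJ <- ceiling(config$overlap_fraction * nGenes / 2)
      lay <- .layGenes(scLens[s], nGenes, nOvJ)
      rows[[s]] <- data.frame(scaffold = scNames[s], start = lay$start,
                              end = lay$end, stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    tab$gene_id <- sprintf("%s_g%03d", gid, seq_len(nrow(tab)))
    tab$protein <- vapply(seq_len(nrow(tab)), function(k)
      .randProtein(max(60L, (tab$end[k] - tab$start[k] + 1L) %/% 3L - 1L)), "")
    tab$marker_label <- NA_character_
    tab$is_marker_rps3 <- FALSE
    tab$hgt_used <- FALSE
    geneTabs[[i]] <- list(gid = gid, scLens = setNames(scLens, scNames),
                          tab = tab)
    rps3[i] <- .randDna(651L, config$gc)
  }

  # plant single-copy markers (and the rpS3 flag) into free gene slots
  plantedMarkerCounts <- integer(nG)
  for (i in seq_len(nG)) {
    want <- if (is.null(config$marker_presence)) character()
            else config$marker_presence[[i]]
    tab <- geneTabs[[i]]$tab
    free <- which(is.na(tab$marker_label))
    if (length(want) + 1L > length(free))
      .fail("genome %d has too few genes (%d) to plant %d markers + rpS3",
            i, nrow(tab), length(want))
    slots <- free[seq_along(want)]
    tab$marker_label[slots] <- want
    tab$protein[slots] <- unname(refMarkers[want])
    rpSlot <- free[length(want) + 1L]
    tab$is_marker_rps3[rpSlot] <- TRUE
    geneTabs[[i]]$tab <- tab
    plantedMarkerCounts[i] <- length(unique(want))
  }

  # realise planted HGT events
  hgtTruth <- list()
  for (ev in config$planted_hgt_events) {
    dTab <- geneTabs[[ev$donor]]$tab
    rTab <- geneTabs[[ev$recipient]]$tab
    rLens <- geneTabs[[ev$recipient]]$scLens
    # donor genes must themselves be detectable xenolog partners:
    # mid-scaffold, on a scaffold >= 5 kb, and >= 100 aa
    dLens <- geneTabs[[ev$donor]]$scLens
    dRk <- stats::ave(dTab$start, dTab$scaffold, FUN = rank)
    dN <- stats::ave(rep(1, nrow(dTab)), dTab$scaffold, FUN = sum)
    dPool <- which(is.na(dTab$marker_label) & !dTab$is_marker_rps3 &
                   nchar(dTab$protein) >= 100 &
                   dTab$scaffold %in% names(dLens)[dLens >= 5000] &
                   dRk != 1 & dRk != dN)
    if (length(dPool) < ev$n_genes)
      .fail("donor genome %d lacks %d eligible genes", ev$donor, ev$n_genes)
    dPick <- .samplePick(dPool, ev$n_genes)
    for (dg in dPick) {
      bigScafs <- names(rLens)[rLens >= 5000]
      scOk <- rTab$scaffold %in% bigScafs
      rk <- stats::ave(rTab$start, rTab$scaffold, FUN = rank)
      nOn <- stats::ave(rep(1, nrow(rTab)), rTab$scaffold, FUN = sum)
      isTerm <- rk == 1 | rk == nOn
      pool <- if (isTRUE(ev$terminal))
        which(scOk & isTerm & is.na(rTab$marker_label) &
              !rTab$is_marker_rps3 & !rTab$hgt_used)
      else
        which(scOk & !isTerm & is.na(rTab$marker_label) &
              !rTab$is_marker_rps3 & !rTab$hgt_used)
      if (!length(pool))
        .fail("no eligible %s slot in recipient genome %d",
              if (isTRUE(ev$terminal)) "terminal" else "mid-scaffold",
              ev$recipient)
      slot <- .samplePick(pool)
      donorProt <- dTab$protein[dg]
      rTab$protein[slot] <- mutateProtein(donorProt, ev$aa_divergence)
      L <- nchar(donorProt)
      hgtTruth[[length(hgtTruth) + 1L]] <- data.frame(
        recipient_genome = geneTabs[[ev$recipient]]$gid,
        recipient_gene = rTab$gene_id[slot],
        donor_genome = geneTabs[[ev$donor]]$gid,
        donor_gene = dTab$gene_id[dg],
        expected_identity_pct = 100 * (L - round(L * ev$aa_divergence)) / L,
        terminal = isTRUE(ev$terminal),
        stringsAsFactors = FALSE)
      rTab$hgt_used[slot] <- TRUE
      geneTabs[[ev$recipient]]$tab <- rTab
    }
  }

  # materialise GenomeRecord objects
  out <- list()
  for (i in seq_len(nG)) {
    gt <- geneTabs[[i]]
    scafs <- DNAStringSet(vapply(gt$scLens, .randDna, "", gc = config$gc))
    names(scafs) <- names(gt$scLens)
    tab <- gt$tab
    gr <- GRanges(seqnames = tab$scaffold,
                  ranges = IRanges(start = tab$start, end = tab$end),
                  strand = sample(c("+", "-"), nrow(tab), replace = TRUE))
    gr$gene_id <- tab$gene_id
    gr$rank_on_scaffold <- NA_integer_
    gr$protein <- AAStringSet(tab$protein)
    gr$marker_label <- tab$marker_label
    gr$is_marker_rps3 <- tab$is_marker_rps3
    close <- i %in% config$close_clade_members
    lin <- if (!is.null(config$lineages)) config$lineages[[i]]
           else .defaultLineage(i, close)
    out[[gt$gid]] <- GenomeRecord(gt$gid, scafs, gr, lin, close)
  }
  rps3set <- DNAStringSet(rps3)
  names(rps3set) <- sprintf("rps3_%s", names(out))
  truth <- list(
    planted_hgt_genes = if (length(hgtTruth)) do.call(rbind, hgtTruth)
                        else NULL,
    planted_marker_counts = setNames(plantedMarkerCounts, names(out)),
    close_clade_members = names(out)[config$close_clade_members]
  )
  list(genomes = out, rps3 = rps3set, truth = truth)
}
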