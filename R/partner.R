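# Integration of network and recent-HGT evidence into ranked partner
# hypotheses for a focal OTU, plus the end-to-end pipeline runner.

#' Depth correlation between two OTUs
#'
#' Pearson correlation of sequencing depths across samples, either over
#' the samples where both OTUs are observed (depth > 0; the default,
#' matching how co-occurrence is usually reported) or over all samples.
#'
#' @param otu_table an \linkS4class{OtuTable} or depth matrix
#' @param otu_a,otu_b row ids
#' @param mode "co_observed" or "all"
#' @return list with \code{pearson_r}, \code{r_squared},
#'   \code{n_samples_used}
#' @export
depthCorrelation <- function(otu_table, otu_a, otu_b,
                             mode = c("co_observed", "all")) {
  mode <- match.arg(mode)
  d <- if (is(otu_table, "OtuTable")) otuDepth(otu_table)
       else as.matrix(otu_table)
  if (!all(c(otu_a, otu_b) %in% rownames(d)))
    .fail("depthCorrelation: OTU not in table")
  a <- d[otu_a, ]; b <- d[otu_b, ]
  use <- if (mode == "co_observed") a > 0 & b > 0 else rep(TRUE, length(a))
  if (sum(use) < 3)
    .fail("depthCorrelation: only %d usable samples (need >= 3)", sum(use))
  r <- cor(a[use], b[use])
  list(pearson_r = r, r_squared = r^2, n_samples_used = sum(use))
}

#' Rank candidate partners for a focal OTU
#'
#' Candidates are the union of the focal OTU's network neighbours and
#' the OTUs of genomes contributing passing recent-HGT pairs. Ranking is
#' lexicographic, in descending priority: both evidence types present;
#' number of passing recent-HGT pairs; |rho|; best pair identity; ties
#' broken by OTU id (ascending). No fused score is computed — the two
#' evidence lines are kept separate and reported in full, with absent
#' evidence explicitly NA.
#'
#' @param network a \linkS4class{CorrelationNetwork} (modules detected or
#'   not; module co-membership is reported when available)
#' @param recent_pairs data.frame from \code{\link{recentHgtScan}} (only
#'   rows with \code{passes} are used), or NULL
#' @param otu_table the \linkS4class{OtuTable} used for the network
#' @param focal_otu focal OTU id
#' @param genome_to_otu named character vector mapping genome id -> OTU
#'   id (from the marker clustering membership); genomes without a
#'   marker-bearing OTU cannot appear as network candidates and surface
#'   with HGT-only evidence under their genome id
#' @return data.frame of hypotheses, rank 1 = strongest; empty (with a
#'   warning) when the focal OTU has no evidence of either kind
#' @export
rankPartners <- function(network, recent_pairs, otu_table, focal_otu,
                         genome_to_otu = NULL) {
  e <- network@edges
  touch <- e$source == focal_otu | e$target == focal_otu
  nbrs <- ifelse(e$source[touch] == focal_otu, e$target[touch],
                 e$source[touch])
  edgeOf <- function(otu) {
    i <- which(touch)[nbrs == otu]
    if (length(i)) e[i[1], ] else NULL
  }
  hgt <- if (!is.null(recent_pairs) && nrow(recent_pairs))
    recent_pairs[recent_pairs$passes, , drop = FALSE]
  else recent_pairs
  hgtByOtu <- list()
  if (!is.null(hgt) && nrow(hgt)) {
    partnerOtu <- if (!is.null(genome_to_otu))
      ifelse(hgt$partner_genome_id %in% names(genome_to_otu),
             genome_to_otu[hgt$partner_genome_id], hgt$partner_genome_id)
    else hgt$partner_genome_id
    hgtByOtu <- split(hgt, partnerOtu)
  }
  candidates <- sort(unique(c(nbrs, names(hgtByOtu))))
  candidates <- setdiff(candidates, focal_otu)
  if (!length(candidates)) {
    warning("focal OTU has no network or recent-HGT evidence",
            call. = FALSE)
    return(data.frame())
  }
  mods <- network@modules
  depthNames <- rownames(otuDepth(otu_table))
  rows <- lapply(candidates, function(otu) {
    ed <- edgeOf(otu)
    pr <- hgtByOtu[[otu]]
    best <- if (!is.null(pr) && nrow(pr)) pr[which.max(pr$identity_pct), ]
            else NULL
    dc <- if (otu %in% depthNames && focal_otu %in% depthNames)
      tryCatch(depthCorrelation(otu_table, focal_otu, otu),
               error = function(e) NULL)
    else NULL
    data.frame(
      focal_otu = focal_otu,
      candidate_otu = otu,
      rho = if (!is.null(ed)) ed$rho else NA_real_,
      pseudo_p = if (!is.null(ed)) ed$p else NA_real_,
      shared_module = if (length(mods) && otu %in% names(mods))
        unname(mods[otu] == mods[focal_otu]) else NA,
      n_recent_hgt_pairs = if (!is.null(pr)) nrow(pr) else 0L,
      best_pair_identity_pct = if (!is.null(best)) best$identity_pct
                               else NA_real_,
      best_pair_aligned_length = if (!is.null(best))
        best$aligned_length_aa else NA_integer_,
      pearson_r = if (!is.null(dc)) dc$pearson_r else NA_real_,
      r_squared = if (!is.null(dc)) dc$r_squared else NA_real_,
      n_co_observed_samples = if (!is.null(dc)) dc$n_samples_used
                              else NA_integer_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  hasEdge <- !is.na(out$rho)
  hasHgt <- out$n_recent_hgt_pairs > 0
  key <- order(-(hasEdge & hasHgt),
               -out$n_recent_hgt_pairs,
               -ifelse(is.na(out$rho), 0, abs(out$rho)),
               -ifelse(is.na(out$best_pair_identity_pct), 0,
                       out$best_pair_identity_pct),
               out$candidate_otu)
  out <- out[key, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Default synthetic host-symbiont scenario
#'
#' The reference study conditions used throughout the package's
#' evaluation: a 20-OTU community profiled over 88 samples at 80%
#' occupancy with one planted symbiont-host basis correlation of 0.9
#' (OTUs 1 and 2), and a matching 20-genome collection in which genome 1
#' (the symbiont, close clade) received one recent mid-scaffold xenolog
#' from genome 2 (the host) at 11% amino-acid divergence (~89%
#' identity). Genomes are kept compact (two scaffolds, five to seven
#' genes each) so a full evidence chain runs in seconds.
#'
#' @param seed master integer seed; community and genome streams are
#'   derived from it
#' @return list with \code{community_config} and \code{genome_config}
#' @export
defaultScenario <- function(seed = 1) {
  list(
    community_config = communityConfig(
      n_otus = 20, n_samples = 88, occupancy = 0.8,
      planted_pairs = list(c(1, 2, 0.9)),
      seed = streamSeed(seed, "scenario-community")),
    genome_config = genomeConfig(
      n_genomes = 20,
      scaffolds_per_genome = c(2, 2),
      scaffold_length = c(8000, 12000),
      genes_per_scaffold = c(5, 7),
      close_clade_members = 1L,
      planted_hgt_events = list(
        list(donor = 2, recipient = 1, n_genes = 1,
             aa_divergence = 0.11, terminal = FALSE, label = "recent")),
      seed = streamSeed(seed, "scenario-genomes"))
  )
}

#' Run the full synthetic partner-inference pipeline
#'
#' Generates a community and genome collection with a planted
#' host-symbiont pair, then runs the full evidence chain: rpS3
#' clustering into OTUs, depth aggregation, occurrence filtering, basis
#' correlation network with permutation pseudo-p values, module
#' detection, recent-HGT xenolog scan of the focal genome against the
#' community genomes, and partner ranking. All thresholds and per-stage
#' counts are recorded in the run manifest. Re-running with the same
#' seed reproduces the ranking exactly.
#'
#' @param community_config a \code{\link{communityConfig}} whose first
#'   planted pair is the (symbiont, host) ground truth; OTU i of the
#'   community corresponds to genome i of the genome collection
#' @param genome_config a \code{\link{genomeConfig}} with
#'   \code{n_genomes == n_otus}; its first planted HGT event should run
#'   host -> symbiont to plant the xenolog evidence
#' @param focal_genome index of the focal (symbiont) genome
#' @param rho_threshold,alpha,n_permutations network filter settings
#' @param min_samples occurrence filter
#' @param otu_identity marker clustering identity threshold
#' @param min_identity,min_aln_aa,min_scaffold_bp xenolog filter settings
#' @param seed master seed for the network permutations and module
#'   detection (generator seeds live in the two configs)
#' @return list with \code{otu_table}, \code{network}, \code{recent_pairs},
#'   \code{hypotheses}, \code{truth} (community + genome ground truth),
#'   \code{manifest}
#' @export
runPipeline <- function(community_config, genome_config,
                        focal_genome = 1L,
                        rho_threshold = 0.6, alpha = 0.05,
                        n_permutations = 100, min_samples = 6,
                        otu_identity = 0.95, min_identity = 70,
                        min_aln_aa = 100, min_scaffold_bp = 5000,
                        seed = 1) {
  if (community_config$n_otus != genome_config$n_genomes)
    .fail("runPipeline: n_otus must equal n_genomes (OTU i <-> genome i)")
  comm <- generateCommunity(community_config)
  gen <- generateGenomes(genome_config)
  genomeIds <- names(gen$genomes)
  markerIds <- names(gen$rps3)
  markerToGenome <- setNames(genomeIds, markerIds)
  lineages <- setNames(vapply(gen$genomes, function(g)
    paste(g@lineage, collapse = ";"), ""), genomeIds)

  skeleton <- clusterMarkers(gen$rps3, genome_ids = markerToGenome,
                             identity_threshold = otu_identity)
  markerDepths <- otuDepth(comm$otu_table)
  rownames(markerDepths) <- markerIds   # marker i carries OTU i's depths
  tab <- otuDepths(skeleton, markerDepths, taxonomy = lineages)
  nBefore <- nrow(tab)
  tab <- occurrenceFilter(tab, min_samples = min_samples)
  nAfter <- nrow(tab)

  est <- sparccRho(otuDepth(tab), mode = "dirichlet", n_resamples = 20,
                   seed = streamSeed(seed, "sparcc"))
  p <- pseudoP(otuDepth(tab), est$rho, n_permutations = n_permutations,
               seed = streamSeed(seed, "pseudo-p"))
  net <- buildNetwork(est$rho, p, rho_threshold = rho_threshold,
                      alpha = alpha,
                      taxonomy = rowData(tab)$taxonomy)
  net <- detectModules(net, seed = streamSeed(seed, "modules"))

  focalId <- genomeIds[focal_genome]
  community <- gen$genomes[setdiff(genomeIds, focalId)]
  pairs <- recentHgtScan(gen$genomes[[focalId]], community,
                         min_identity = min_identity,
                         min_aln_aa = min_aln_aa,
                         min_scaffold_bp = min_scaffold_bp)

  genomeToOtu <- vapply(genomeIds, function(g) {
    marker <- names(markerToGenome)[markerToGenome == g]
    hit <- vapply(seq_len(nrow(skeleton)), function(i)
      marker %in% skeleton$members[[i]], logical(1))
    if (any(hit)) skeleton$otu_id[which(hit)[1]] else NA_character_
  }, "")
  genomeToOtu <- genomeToOtu[!is.na(genomeToOtu)]

  focalOtu <- unname(genomeToOtu[focalId])
  hyps <- if (!is.na(focalOtu) && focalOtu %in% net@nodes)
    rankPartners(net, pairs, tab, focalOtu, genome_to_otu = genomeToOtu)
  else data.frame()

  manifest <- list(
    thresholds = list(rho_threshold = rho_threshold, alpha = alpha,
                      n_permutations = n_permutations,
                      min_samples = min_samples,
                      otu_identity = otu_identity,
                      min_identity = min_identity,
                      min_aln_aa = min_aln_aa,
                      min_scaffold_bp = min_scaffold_bp),
    seeds = list(pipeline = seed,
                 community = community_config$seed,
                 genomes = genome_config$seed),
    counts = list(n_otus_before_filter = nBefore,
                  n_otus_after_filter = nAfter,
                  n_otus_removed = nBefore - nAfter,
                  n_edges = nrow(net@edges),
                  n_modules = length(unique(net@modules)),
                  n_recent_pairs_scanned = nrow(pairs),
                  n_recent_pairs_passing = sum(pairs$passes),
                  n_hypotheses = nrow(hyps))
  )
  list(otu_table = tab, network = net, recent_pairs = pairs,
       hypotheses = hyps, focal_otu = focalOtu,
       genome_to_otu = genomeToOtu,
       truth = list(community = comm$truth, genomes = gen$truth),
       manifest = manifest)
}
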