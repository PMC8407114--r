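# Directional HGT scoring/calling and the recent-xenolog filter.

mkHits <- function(scores, taxa) {
  data.frame(query_id = "g", subject_id = paste0("s", seq_along(scores)),
             score = scores * 100, normalized_score = scores,
             identity_pct = 50, aligned_length = 100L,
             query_coverage_pct = 90, subject_taxonomy = taxa,
             stringsAsFactors = FALSE)[order(-scores), ]
}

grouping <- taxonomyGrouping(self_taxa = "self_sp",
                             close_taxa = c("DPANN-like"))

test_that("group scores drop self hits and cap each group at max_hits", {
  allSelf <- mkHits(c(0.9, 0.8), rep("Archaea;PhyA;self_sp", 2))
  gs <- groupScores(allSelf, grouping)
  expect_equal(gs$close_score, 0)
  expect_equal(gs$distal_score, 0)

  mix <- mkHits(c(0.9, 0.8, 0.5),
                c("Archaea;DPANN-like;spX", "Archaea;DPANN-like;spY",
                  "Archaea;Euryarchaeota;spZ"))
  gs2 <- groupScores(mix, grouping)
  expect_equal(gs2$close_score, 1.7)
  expect_equal(gs2$distal_score, 0.5)
  expect_equal(gs2$best_distal$subject_taxonomy, "Archaea;Euryarchaeota;spZ")

  gs3 <- groupScores(mix, grouping, max_hits = 1)
  expect_equal(gs3$close_score, 0.9)
  expect_equal(gs3$distal_score, 0.5)
})

test_that("threshold fitting finds the KDE valley between two modes", {
  set.seed(66)
  scores <- data.frame(
    close_score = c(rnorm(50, 0.1, 0.05), rnorm(50, 2.0, 0.2)),
    distal_score = c(rnorm(50, 0.1, 0.05), rnorm(50, 2.0, 0.2))
  )
  taus <- fitThresholds(scores)
  expect_gt(taus$tau_close, 0.3)
  expect_lt(taus$tau_close, 1.5)
  expect_false(taus$close_fallback)

  uni <- data.frame(close_score = rnorm(60, 1, 0.1),
                    distal_score = rnorm(60, 1, 0.1))
  tu <- fitThresholds(uni)
  expect_true(tu$close_fallback)
  expect_equal(unname(tu$tau_close), unname(quantile(uni$close_score, 0.25)))

  const <- data.frame(close_score = rep(0.5, 30), distal_score = rep(1, 30))
  tc <- fitThresholds(const)
  expect_true(tc$close_fallback)
  expect_equal(tc$tau_close, 0.5)

  expect_error(fitThresholds(uni[1:10, ]), "20")
})

test_that("HGT calls follow the close/distal threshold rule", {
  taus <- list(tau_close = 0.2, tau_distal = 0.3)
  hits <- list(
    hgt = mkHits(c(0.05, 0.8), c("Archaea;DPANN-like;spX",
                                 "Archaea;Euryarchaeota;spZ")),
    native = mkHits(c(1.5, 0.8), c("Archaea;DPANN-like;spX",
                                   "Archaea;Euryarchaeota;spZ"))
  )
  calls <- callHgt(hits, grouping, taus, recipient_phylum = "PhyA")
  expect_true(calls$is_hgt[calls$gene_id == "hgt"])
  expect_equal(calls$donor_phylum[calls$gene_id == "hgt"], "Euryarchaeota")
  expect_false(calls$is_hgt[calls$gene_id == "native"])
  # intraphylum best-distal hits are not reported as interphylum HGT
  intra <- list(g = mkHits(c(0.05, 0.8), c("Archaea;DPANN-like;spX",
                                           "Archaea;PhyA;spQ")))
  expect_false(callHgt(intra, grouping, taus, "PhyA")$is_hgt)
})

test_that("boundary thresholds flag all-with-distal-hit or nothing", {
  taus_all <- list(tau_close = Inf, tau_distal = 0)
  taus_none <- list(tau_close = 0, tau_distal = Inf)
  hits <- list(
    a = mkHits(c(0.9, 0.4), c("Archaea;DPANN-like;s1",
                              "Archaea;Euryarchaeota;s2")),
    b = mkHits(0.9, "Archaea;DPANN-like;s1")   # no distal hit
  )
  callsAll <- callHgt(hits, grouping, taus_all, "PhyA")
  expect_true(callsAll$is_hgt[callsAll$gene_id == "a"])
  expect_false(callsAll$is_hgt[callsAll$gene_id == "b"])
  expect_false(any(callHgt(hits, grouping, taus_none, "PhyA")$is_hgt))
})

test_that("donor summary percentages are exact and order-invariant", {
  rest <- 2579 - 998 - 193 - 186 - 147
  phyla <- c(rep("Euryarchaeota", 998), rep("Bathyarchaeota", 193),
             rep("Methanomicrobia", 186), rep("Firmicutes", 147),
             rep("OtherA", 600), rep("OtherB", rest - 600))
  calls <- data.frame(gene_id = seq_along(phyla), is_hgt = TRUE,
                      donor_phylum = phyla, stringsAsFactors = FALSE)
  ds <- donorSummary(calls)
  expect_equal(ds$percent[ds$donor_phylum == "Euryarchaeota"], 38.7)
  expect_equal(ds$count[1], 998L)  # sorted descending
  expect_lt(abs(sum(ds$percent) - 100), 0.1)
  # permutation invariance over input order
  ds2 <- donorSummary(calls[sample(nrow(calls)), ])
  expect_equal(ds, ds2)
  single <- donorSummary(data.frame(gene_id = 1, is_hgt = TRUE,
                                    donor_phylum = "X"))
  expect_equal(single$percent, 100)
})

test_that("planted distal transfers are recovered with high precision/recall", {
  set.seed(404)
  nNative <- 90; nHgt <- 10
  native <- vapply(seq_len(nNative), function(i) randProt(150), "")
  donors <- vapply(seq_len(nHgt), function(i) randProt(150), "")
  hgtGenes <- vapply(donors, mutateProtein, "", divergence = 0.15)
  genes <- setNames(c(native, hgtGenes),
                    sprintf("g%03d", seq_len(nNative + nHgt)))
  truthHgt <- names(genes)[(nNative + 1):(nNative + nHgt)]
  # database: close-clade relatives of the native genes (10% diverged),
  # the distal donor genes, and unrelated distal decoys
  db <- c(
    setNames(vapply(native, mutateProtein, "", divergence = 0.10),
             sprintf("close%03d", seq_len(nNative))),
    setNames(donors, sprintf("donor%03d", seq_len(nHgt))),
    setNames(vapply(1:20, function(i) randProt(150), ""),
             sprintf("decoy%03d", 1:20))
  )
  tax <- c(setNames(rep("Archaea;DPANN-like;relative", nNative),
                    sprintf("close%03d", seq_len(nNative))),
           setNames(rep("Archaea;Euryarchaeota;donor_sp", nHgt),
                    sprintf("donor%03d", seq_len(nHgt))),
           setNames(rep("Bacteria;Firmicutes;decoy_sp", 20),
                    sprintf("decoy%03d", 1:20)))
  # min_score suppresses the spurious low-scoring local hits every
  # random protein pair produces (the BLAST analogue is the e-value cut)
  hits <- searchAll(genes, db, taxonomy = as.list(tax), min_score = 100)
  scores <- do.call(rbind, lapply(names(hits), function(g) {
    gs <- groupScores(hits[[g]], grouping)
    data.frame(gene_id = g, close_score = gs$close_score,
               distal_score = gs$distal_score)
  }))
  taus <- fitThresholds(scores)
  calls <- callHgt(hits, grouping, taus, recipient_phylum = "PhyA")
  called <- calls$gene_id[calls$is_hgt]
  tp <- length(intersect(called, truthHgt))
  precision <- tp / max(length(called), 1)
  recall <- tp / nHgt
  expect_gte(precision, 0.9)
  expect_gte(recall, 0.9)
})

# -- recent xenolog scan -----------------------------------------------

# focal genome: 3 genes mid-scaffold on a 6-kb scaffold; partner carries
# controlled homologs
mkScanPair <- function(partnerProt, focalProt, partnerTerminal = FALSE,
                       partnerScaffold = 6000L) {
  focal <- makeGenome("focal", scaffolds = c(fs1 = 6000L),
    genes = data.frame(scaffold = "fs1",
                       start = c(100, 1000, 5000),
                       end = c(700, 1650, 5600),
                       protein = c(randProt(80), focalProt, randProt(80))),
    closeClade = TRUE)
  pGenes <- if (partnerTerminal)
    data.frame(scaffold = "ps1", start = c(100, 1000, 2000),
               end = c(700, 1650, 2600),
               protein = c(partnerProt, randProt(80), randProt(80)))
  else
    data.frame(scaffold = "ps1", start = c(100, 1000, 2000),
               end = c(700, 1650, 2600),
               protein = c(randProt(80), partnerProt, randProt(80)))
  partner <- makeGenome("partner", scaffolds = c(ps1 = partnerScaffold),
                        genes = pGenes,
                        lineage = c("Archaea", "Crenarchaeota", "Pyro"))
  list(focal = focal, partner = partner)
}

test_that("a mid-scaffold high-identity xenolog passes; a terminal one fails", {
  set.seed(500)
  donor <- randProt(202)
  xeno <- mutateProtein(donor, 22 / 202)   # ~89.1% identity
  mid <- mkScanPair(donor, xeno)
  pairs <- recentHgtScan(mid$focal, list(mid$partner))
  hit <- pairs[pairs$focal_gene_id == "focal_g002" &
               pairs$partner_gene_id == "partner_g002", ]
  expect_equal(nrow(hit), 1L)
  expect_true(hit$passes)
  expect_gte(hit$identity_pct, 70)
  expect_gte(hit$aligned_length_aa, 100)

  term <- mkScanPair(donor, xeno, partnerTerminal = TRUE)
  pairsT <- recentHgtScan(term$focal, list(term$partner))
  hitT <- pairsT[pairsT$partner_gene_id == "partner_g001", ]
  expect_false(any(hitT$passes))
  expect_true(any(grepl("TERMINAL_GENE", hitT$reasons)))
})

test_that("identity just under 70% is rejected as LOW_IDENTITY", {
  set.seed(501)
  donor <- randProt(1000)
  # substitutions spread evenly so the local alignment cannot trim its
  # way above the threshold
  ch <- strsplit(donor, "")[[1]]
  pos <- round(seq(2, 999, length.out = 301))
  for (i in pos) ch[i] <- setdiff(AA20, ch[i])[1]
  diverged <- paste(ch, collapse = "")
  sc <- mkScanPair(donor, diverged)
  pairs <- recentHgtScan(sc$focal, list(sc$partner))
  hit <- pairs[pairs$focal_gene_id == "focal_g002" &
               pairs$partner_gene_id == "partner_g002", ]
  expect_equal(nrow(hit), 1L)
  expect_false(hit$passes)
  expect_lt(hit$identity_pct, 70)
  expect_true(grepl("LOW_IDENTITY", hit$reasons))
})

test_that("short alignments and short scaffolds are rejected with reasons", {
  set.seed(502)
  shared <- randProt(90)   # high identity but < 100 aa alignable
  sc <- mkScanPair(paste0(shared, randProt(5)), paste0(shared, randProt(5)))
  pairs <- recentHgtScan(sc$focal, list(sc$partner))
  hit <- pairs[pairs$focal_gene_id == "focal_g002" &
               pairs$partner_gene_id == "partner_g002", ]
  expect_false(any(hit$passes))
  expect_true(any(grepl("SHORT_ALIGNMENT", hit$reasons)))

  donor <- randProt(202)
  xeno <- mutateProtein(donor, 0.1)
  small <- mkScanPair(donor, xeno, partnerScaffold = 3000L)
  pairsS <- recentHgtScan(small$focal, list(small$partner))
  hitS <- pairsS[pairsS$focal_gene_id == "focal_g002" &
                 pairsS$partner_gene_id == "partner_g002", ]
  expect_false(any(hitS$passes))
  expect_true(any(grepl("SHORT_SCAFFOLD", hitS$reasons)))
})

test_that("close-clade partners are excluded and ancient transfers dropped", {
  set.seed(503)
  donor <- randProt(300)
  xeno <- mutateProtein(donor, 0.1)
  sc <- mkScanPair(donor, xeno)
  closePartner <- GenomeRecord("cp", sc$partner@scaffolds,
                               sc$partner@genes,
                               c("Archaea", "DPANN-like"), TRUE)
  expect_error(recentHgtScan(sc$focal, list(closePartner)), "close clade")

  # a transfer at ~42% identity (ancient divergence) never passes
  ancient <- mutateProtein(donor, 0.58)
  sa <- mkScanPair(donor, ancient)
  pairsA <- recentHgtScan(sa$focal, list(sa$partner))
  hitA <- pairsA[pairsA$focal_gene_id == "focal_g002", ]
  expect_false(any(hitA$passes))
})

test_that("raising the filters never increases the retained pair count", {
  set.seed(504)
  donor <- randProt(250)
  sc <- mkScanPair(donor, mutateProtein(donor, 0.12))
  n <- function(...) sum(recentHgtScan(sc$focal, list(sc$partner), ...)$passes)
  expect_gte(n(min_identity = 60), n(min_identity = 75))
  expect_gte(n(min_aln_aa = 80), n(min_aln_aa = 150))
})

test_that("HGT count scales with gene count in the descriptive regression", {
  fit <- hgtRegression(n_genes = c(500, 700, 900, 1100, 1300),
                       n_hgts = c(48, 70, 95, 110, 133))
  expect_gt(fit$slope, 0)
  expect_gt(fit$r_squared, 0.9)
})
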