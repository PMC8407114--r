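---
title: "Inferring host-symbiont partners from metagenomic co-occurrence and recent gene transfer"
author: "SymbioNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring host-symbiont partners from metagenomic co-occurrence and recent gene transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SymbioNet)
```

## The problem

Ultra-small archaea of the DPANN superphylum (Nanoarchaeota,
Micrarchaeota, Aenigmarchaeota and relatives) have severely reduced
genomes and are generally thought to live attached to a host cell that
supplies membrane lipids, nucleotides and energy. Most of these
lineages resist cultivation, so the host is usually unknown: all we
have is a collection of metagenome-assembled genomes (MAGs) binned
from community sequencing, plus per-sample sequencing depths. SymbioNet
implements a desk-scale version of the inference chain used to propose
host-symbiont partnerships from such data, combining two independent
evidence lines:

1. **Co-occurrence.** If a symbiont depends on a host, the two
   populations should rise and fall together across samples. We profile
   communities with the single-copy ribosomal protein S3 (rpS3) marker,
   cluster markers into OTUs at 95% nucleotide identity, and estimate
   between-OTU *basis correlations* with a compositionality-aware
   estimator (the SparCC family), with permutation pseudo-p values and
   modularity-based module extraction.
2. **Recent horizontal gene transfer.** Sustained cell-to-cell contact
   leaves a genomic trace: genes transferred between the partners that
   are still nearly identical in both genomes ("recent" xenologs). We
   detect directional interphylum HGT from homology-score distributions
   and screen for high-identity xenologs between a focal genome and the
   companion genomes binned from the same communities.

A candidate partner supported by *both* a strong co-occurrence edge and
a recent xenolog is a far stronger hypothesis than either signal alone;
the package integrates the two into a ranked partner list.

Everything is exercised on synthetic data with planted ground truth, so
each stage of the chain is testable without any sequence download.

## The basis-correlation estimator

Sequencing depths are compositional: per sample only the relative
abundances $f_{ij}$ (OTU $i$, sample $j$, columns summing to 1) are
observed, and naive Pearson correlations between fractions are biased
by the closure. The estimator works on log-ratio variances

$$ t_{ij} = \mathrm{Var}\left[\log\frac{f_i}{f_j}\right] =
   \omega_i^2 + \omega_j^2 - 2\rho_{ij}\omega_i\omega_j, $$

where $\omega_i^2$ is the latent (basis) variance of component $i$ and
$\rho_{ij}$ the basis correlation we want. The system is
under-determined; under the *sparsity assumption* (most pairs
uncorrelated) the row sums $t_i = \sum_{j\ne i} t_{ij}$ satisfy a
linear system $M\omega^2 = t$ with $M = \mathbf{1} + (D-2)I$, which for
$D$ components has the closed form

$$ \hat\omega_i^2 = \frac{t_i - W}{D-2}, \qquad
   W = \frac{\sum_i t_i}{2(D-1)}, $$

and then $\hat\rho_{ij} = (\hat\omega_i^2 + \hat\omega_j^2 - t_{ij}) /
(2\hat\omega_i\hat\omega_j)$, clipped to $[-1, 1]$. A strongly
correlated pair violates the sparsity assumption, so the currently
strongest pair with $|\hat\rho|$ above an exclusion threshold (default
0.1) is removed from the sums and the (now masked) linear system is
re-solved, one pair per round, up to 10 rounds. `basisCorrelations()`
implements exactly this; the closed form above is recovered when
nothing is excluded, which the test suite checks against a constructed
$t$ matrix with $\omega^2 = (1,2,3,4)$.

Fractions come from `estimateFractions()`: either deterministic
pseudocounted proportions, or (the default in the pipeline) 20
Dirichlet posterior draws with parameters (count + 1), with the basis
estimates averaged over draws. At least 4 OTUs are required — below
that the sparsity system is not identifiable.

**Edge significance.** `pseudoP()` permutes each OTU's depths across
samples independently, destroying all between-OTU association while
preserving marginals, and recomputes the full basis-correlation matrix
per round. The two-sided pseudo-p of a pair is the fraction of rounds
whose $|\rho_\text{null}|$ reaches $|\rho_\text{obs}|$; with 100
permutations (the default) the resolution is 0.01 and p may be exactly
0. The procedure is often loosely called "bootstrapping" in the
literature around the original tool; the actual null is per-component
permutation, which is what we implement. An `include_identity` sanity
mode counts the unpermuted table as one round, bounding p away from 0.

**Edge filter.** An edge requires $|\rho| > 0.6$ (strict by default;
an `inclusive` switch exists because published descriptions differ
between "greater than" and "at least") and pseudo-p < 0.05, two-sided.
Negative correlations passing the magnitude rule are retained with
their sign. Modules come from weighted Louvain modularity maximization
(resolution 1, |rho| weights, seeded), and `extractFocalModule()`
returns the focal OTU's direct neighbours within its module — the
candidate set a partner search inspects.

## Marker profiling choices

Clustering is greedy centroid clustering: sequences in order of
decreasing length (ties by id), each joining the first centroid at
$\ge$ 95% global-alignment identity, else founding a new OTU. The
original community-profiling tool is closed-source, so the identity
convention is fixed and documented here instead: identity = identical
columns / all alignment columns (gaps included) of a global alignment
at match +1 / mismatch −1, gap open 5 / extend 2. Depth aggregation
sums member-marker depths per sample, conserving column totals. The
occurrence filter keeps OTUs observed (depth strictly > 0) in at least
6 samples; in the synthetic tables zeros are structural absences, so
"observed" is unambiguous.

## HGT detection choices

For each gene, homology hits are split by subject taxonomy into *self*
(the recipient's own lineage; dropped), *close* (a configured clade —
for DPANN symbionts, the DPANN superphylum) and *distal* (everything
else). Scores are raw local-alignment scores normalized by the query's
self-score, summed per group over at most 50 hits. A gene is called
transferred when its close-group support is at or below a threshold
and its distal-group support at or above another. The reference tool
fits these thresholds from the score distributions without documenting
the exact rule, so the rule here is our own and is flagged in outputs:
a Gaussian KDE (Silverman bandwidth, 512-point grid) per distribution,
thresholded at the first valley between the first two modes; modes
below 10% of the peak are ignored and the valley must dip below half
the lower flanking mode, otherwise the distribution is treated as
unimodal and quantile fallbacks (25th percentile for close, 75th for
distal) are used and flagged. Donor attribution takes the phylum field
of the best distal hit; only calls whose donor phylum differs from the
recipient's are reported (interphylum), and hits without a phylum are
"unclassified" and excluded.

The recent-xenolog scan is a separate, stricter filter aimed at
*current* contact: local protein alignments between the focal genome
and community genomes outside the close clade, retained when identity
$\ge$ 70% over $\ge$ 100 aligned amino acids. Two positional guards
remove common binning artefacts: only genes on scaffolds of at least
5 kb are eligible, and the first or last gene of a scaffold is
discarded (chimeric contig ends). We read the published filter as
applying both guards; each is a separate switch. Every pair that
reaches the alignment stage with at least ~30% identity is recorded
with reason codes (`LOW_IDENTITY`, `SHORT_ALIGNMENT`,
`SHORT_SCAFFOLD`, `TERMINAL_GENE`), so filter behaviour is auditable.
Whether published coverage figures refer to query or subject coverage
is ambiguous; we compute query coverage and record aligned length,
from which the subject figure follows.

Alignment throughout is Biostrings' Needleman-Wunsch / Smith-Waterman
(BLOSUM62, gap open 11 / extend 1 for proteins; +1/−1, open 5 /
extend 2 for nucleotides; a gap of length $L$ costs open + $L \cdot$
ext). Identity uses the BLAST "pident" convention (gap columns count).
The search is exhaustive — every query against every database entry —
which is the correct contract at desk scale; no heuristic prefilter is
applied, and the test suite pins local scores to an independent
brute-force dynamic-programming oracle.

## Evidence integration

`rankPartners()` builds the candidate set as the union of the focal
OTU's network neighbours and the OTUs of genomes contributing passing
xenolog pairs (genomes map to OTUs through the marker clustering; a
genome without a marker can still surface with HGT-only evidence). The
ranking is deliberately lexicographic rather than a fused score —
published arguments of this kind are qualitative ("the transfer
strengthened the relationship"), and inventing weights would
overclaim. Descending priority: both evidence types present; number of
passing xenolog pairs; $|\rho|$; best pair identity; ties by OTU id.
All evidence fields are carried on every hypothesis with absent
evidence explicitly `NA`, including the Pearson depth correlation over
co-observed samples (both-nonzero; an `all`-samples mode exists —
published reports do not always say which was used, and the two agree
at full occupancy). Sample abundance ranks are reportable but never
used in ranking.

## What the synthetic generator emulates

`generateCommunity()` draws latent log abundances from a multivariate
normal whose correlation matrix carries the planted basis correlations
(a Gaussian copula on the log scale), exponentiates, zeroes absent
OTUs, closes each sample to fractions and scales to integer depths by
multinomial sampling. Defaults mirror a multi-site hot-spring survey:
88 samples, log-normal abundances, one planted symbiont-host pair at
basis correlation 0.9, 80% occupancy, 100,000 reads per sample.

Two generator decisions matter for interpretation:

* **Zeros are structural.** An OTU absent by the occupancy draw has
  depth exactly 0; the occurrence filter is defined on these, making
  its boundary exactly testable.
* **A planted positive pair shares its presence pattern.** A
  host-dependent symbiont occurs where its host occurs; drawing the
  pair's presences independently would destroy the very association
  the pair is planted to carry (each unilateral absence injects a
  large uncorrelated log-ratio variance). Real co-occurrence data show
  the same coupling — the published partner pair was co-observed in 33
  of 88 samples. Negative or null pairs keep independent presence.

`generateGenomes()` plants transfers by copying a donor protein and
substituting exactly `round(L * divergence)` positions (chosen without
replacement, never re-drawing the original residue, uniform over the
other 19 standard residues), so expected identity is analytically
exact: a 202-residue protein at divergence 22/202 gives 180/202 =
89.1% — the worked example the tests pin. Donor genes are restricted
to mid-scaffold slots on scaffolds $\ge$ 5 kb so a planted "recent"
event is detectable by construction; `terminal = TRUE` instead places
the copy as the first or last gene of a recipient scaffold to exercise
the terminal-gene guard. Single-copy markers are planted as copies of
a fixed 54-protein reference set, which drives the completeness
statistic. All randomness flows from one master seed through named
streams (`streamSeed()`), so identical configs are byte-identical.

What the generator does *not* emulate: read-level noise (FASTQ),
assembly and binning errors, codon-level evolution, genuinely
unalignable remote homology, and database incompleteness. Passing
tests therefore demonstrate that the estimators and filters implement
their contracts and recover planted structure at realistic sizes — not
that any particular real community will behave as cleanly.

## Problem sizes and numerical choices

The evaluation scenarios (chosen once, as the package's reference
conditions) are: D = 20 OTUs over n = 88 samples for network
properties, 20 seeded replicates for recovery rates, 100 permutations
for pseudo-p (resolution 0.01), and a 20-genome collection with
compact genomes (two scaffolds of 8-12 kb, five to seven genes each)
for the end-to-end chain, keeping a full run to a few seconds while
leaving every filter a non-trivial population to act on. The HGT
detector is evaluated on 100 genes (10 planted transfers at 15%
divergence, close relatives at 10% divergence, 20 distal decoys) with
a raw-score floor of 100 standing in for the e-value cut a database
search would apply.

Numerical guards: negative basis variances (possible under sparsity
violations) are floored at $10^{-12}$ with a warning; correlation
estimates are clipped to $[-1,1]$; an all-zero depth column yields
uniform fractions; planted correlation matrices are checked for
positive semi-definiteness and rejected with a diagnostic otherwise;
Louvain and all permutation loops are seeded, with node order fixed by
the rho-matrix row order.

## Known limitations

* The sparsity estimator is biased when many strong correlations
  coexist; the one-pair-per-round exclusion mitigates but does not
  remove this.
* The KDE-valley threshold rule is a declared stand-in for an
  undocumented step in the reference HGT tool; on genuinely unimodal
  score distributions it falls back to quantiles and says so.
* Exhaustive alignment search scales quadratically; the package is
  intended for curated, desk-scale genome sets, not whole databases.
* Genome-to-OTU mapping relies on each genome carrying its marker;
  marker-less genomes can only ever show HGT evidence.
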