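---
title: "Anchored consensus correction of clustered long cDNA reads"
author: "AnchorCorrect authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchored consensus correction of clustered long cDNA reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AnchorCorrect)
```

## The problem

Oxford Nanopore cDNA reads carry roughly 7% errors (substitutions,
insertions and deletions in comparable amounts). Reference-based polishing
is not an option when no high-quality reference exists or when reference
bias matters, so the errors must be corrected from the reads alone.
Transcriptomic data make this harder than genomic data: reads from one gene
family differ structurally (alternative splicing, variable transcription
start and end sites) and coverage varies along a single read, because an
exon shared by many isoforms is covered far more deeply than an isoform-
specific segment.

`AnchorCorrect` assumes reads have already been grouped into gene-family
clusters (by an upstream clustering tool) and corrects each cluster
independently. The central idea is to correct *intervals* of a read rather
than whole reads, choosing the intervals so that each one is supported by as
many other reads as possible — which lets a read borrow depth from every
isoform that shares the exon, while segments crossing splice boundaries are
naturally avoided because they would be found in fewer reads.

## The procedure

For a cluster $C$ of reads, with k-mer size $k$ and window $w$:

1. **Anchors.** Every read's positional minimizers are computed: at each
   window position the lexicographically smallest $k$-mer. Pairs of
   minimizers $((m_1,p), (m_2,q))$ with $x_{\min} \le q - p \le x_{\max}$
   define candidate intervals $[p+k, q)$; a hash table indexes every
   occurrence of each $(m_1, m_2)$ pair across the cluster. Pairs whose two
   anchors are both poly-A are masked (poly-A tails otherwise flood the
   index).
2. **Support.** The support $a$ of a candidate interval on read $r$ is the
   number of reads carrying the same anchor pair whose spanned segment $s'$
   is *similar* to the read's segment $s$:
   $ed(s, s') < |s| (\epsilon_s + \epsilon_{s'})$, where $\epsilon$ is the
   mean per-base error probability from the quality values. If another read
   carries the pair several times, only its smallest-distance occurrence is
   tested. The read itself always counts, so $a \ge 1$.
3. **Partition.** Weighted interval scheduling with weights
   $a \cdot (q - p - k)$ selects a maximum-weight set of non-overlapping
   intervals — intervals that are deep *and* cover much of the read.
4. **Consensus.** For each selected interval, the supporting segments are
   threaded through a partial-order alignment graph and the heaviest bundle
   is taken as consensus $c$; at most `maxSeqToSpoa` (200) segments enter
   the graph. All segments are then aligned pairwise to $c$ to form an
   alignment matrix $A$ (insertions open gap columns in the consensus row).
5. **Trusted variants.** For each column $j$, the window of
   $\lfloor k/2 \rfloor$ columns on each side defines contexts. The
   consensus context $c'$ is always trusted. Any other context $b$ is
   trusted if it occurs in at least
   $\max(3,\; mT / \min(ed(c', b),\, ed(HC(c'), HC(b))))$
   of the $m$ rows, with $T = 0.1$; $HC$ is homopolymer compression, and a
   context identical to $c'$ under $HC$ is never trusted (a homopolymer
   length wobble, the dominant nanopore artifact, is not believable
   variation). Distances are taken on gap-stripped windows; occurrence
   counting uses exact row equality including gaps.
6. **Correction.** Each symbol of the read's row is replaced by the variant
   of the trusted context nearest (edit distance) to the row's own window;
   decisions are taken per column against the original row and applied at
   once. Ties prefer the higher-count context, then the consensus. The
   corrected interval is spliced back; the anchor $k$-mers themselves and
   everything outside selected intervals stay untouched.

This retains a minor-allele SNP precisely when its context is seen often
enough: for an isolated SNP, at least 3 reads and at least a fraction $T$ of
the matrix rows — the behaviour verified analytically in the test suite.

### Exact and approximate modes

The algorithm above (*exact* mode) recomputes support and consensus for
every read. For clusters of at least `exactInstanceLimit` (50) reads the
*approximate* mode is used: when an interval of read $r$ is corrected, every
supporting row of the matrix is corrected too and stored in a per-read
cache. When a later read is corrected, its cached spans enter the
scheduling instance directly with their stored support; candidate intervals
overlapping a cached span are not recomputed, and a selected cached span
contributes its stored corrected substring, skipping the consensus stage
entirely. Reads are processed in batches of `maxSeq` (1000), with the
anchor index and cache built per batch, and the window grows with cluster
size as $w = k + \lfloor |C|/500 \rfloor$.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 9 | anchor k-mer size (1–10; 3-bit-packed pair keys) |
| `w` | adaptive | minimizer window; `k + floor(|C|/500)` when `NA` |
| `xmin`, `xmax` | `2k`, 80 | anchor pair distance bounds (nt) |
| `tFrac` | 0.1 | trusted-variant fraction threshold $T$ |
| `exactInstanceLimit` | 50 | clusters smaller than this use exact mode |
| `maxSeqToSpoa` | 200 | segments entering the consensus graph |
| `maxSeq` | 1000 | reads per batch within a cluster |
| `defaultErrorRate` | 0.07 | assumed per-base error for FASTA input |

## Numerical and design choices

* **Edit distances** are exact unit-cost Levenshtein distances (bit-parallel
  implementation, verified against `utils::adist` and a textbook dynamic
  program in the tests). Inside cluster correction, all candidate intervals
  sharing a left anchor position on a read pair are scored with one banded
  prefix dynamic program whose band equals the largest similarity threshold
  in the group — prefix values below the band bound are exact, so the
  resulting support is identical to computing each distance separately.
* **Similarity boundary.** The strict test `ed < |s|(eps + eps')` is
  evaluated with a `1e-9` guard so that floating-point addition cannot turn
  an exactly-at-threshold distance into a pass.
* **Scheduling ties** are broken toward the later-ending interval
  (deterministic predecessor DP); all runs are fully deterministic —
  correction uses no randomness at all.
* **Matrix construction.** Insertions relative to the consensus are pooled
  per junction: each junction gets as many columns as the longest insertion
  there, rows left-aligned. Context windows at matrix edges are truncated
  to the available columns.
* **Consensus contract.** Any partial-order consensus satisfying unanimity
  (identical segments reproduce themselves) and majority recovery is
  acceptable; the implementation threads segments through a DAG (match
  fuses, mismatch/insert add nodes) and takes the heaviest source-to-sink
  bundle by edge weight.
* **Exact-mode cutoff** is strict: clusters *smaller than*
  `exactInstanceLimit` reads are corrected exactly.
* **Output qualities.** Corrected reads receive a constant placeholder
  quality (Phred 30); the method does not model post-correction quality.
* **Degenerate inputs.** Reads too short for any anchor pair, or without
  any similar partner, are returned unchanged; an empty cluster yields an
  empty result.

## The simulator and what it does (not) capture

The read simulator applies an i.i.d. per-base error process: an event with
probability `errorRate` (default 0.07), split 0.35/0.30/0.35 among
substitutions, single-base insertions and deletions — the normalised
profile measured on synthetic spike-in controls (2.5%/2.2%/3.0%). Quality
strings encode the nominal rate. The synthetic-gene generator draws exons
uniformly over ACGT (default 6 exons of 120–220 nt, transcripts around
1 kb, matching typical full-length cDNA read lengths) and builds isoforms
as contiguous exon windows — the alternative-start/alternative-end
structure that dominates real cDNA isoform diversity — so isoforms share
interior exons. The depth experiment mixes 1–4 isoforms per gene (some
genes express a single isoform) and draws per-transcript depths
log-uniformly between 1 and 50, the broad dynamic range typical of
expression data. All randomness derives from one explicit seed through a
counter-based splitting scheme, so every experiment is reproducible.

What the i.i.d. model does *not* capture: real nanopore errors cluster in
homopolymers and low-complexity sequence, quality values correlate only
loosely with true error probability, and real isoform differences include
small internal splice shifts. Two consequences observed in the packaged
experiments: (i) uniform errors are easier to out-vote in the alignment
matrix, so post-correction medians at low depth come out somewhat below the
values reported for chromosome-scale simulations with a full nanopore error
model; (ii) a minor-allele read supports its SNP context only when both
flanking anchors and the 9-column context window are error-free, which
under uniform errors makes 20%-frequency SNPs need roughly 30 reads (rather
than 20) and 10%-frequency SNPs roughly 60–90 (rather than 50) to be
retained in 80% of replicates. Passing tests therefore demonstrate the algorithmic
behaviour (thresholds, retention rules, depth trends), not a calibrated
error model of a specific flow cell.

## A small worked run

```{r example, eval = FALSE}
tx <- makeGene(nIsoforms = 3, nExons = 6, exonLenRange = c(120, 220),
               seed = 1, geneId = "demo")
sim <- simulateReads(tx, depth = c(2, 10, 25), errorRate = 0.07, seed = 2)
cluster <- simToCluster(sim, "demo")
corrected <- correctCluster(cluster)
evaluateCorrection(corrected, cluster, sim$truth, tx)$summary
```

## Known limitations

* Reads are assumed oriented and full-length (primer/orientation handling
  is an upstream tool's job) and pre-clustered by gene family.
* Evaluation is transcript-level; genome-level splice-site classification
  would need a spliced aligner and an annotation.
* Regions never covered by a selected interval — in particular read ends
  before the first and after the last anchor — are left uncorrected, so
  very short reads improve less.
* The poly-A mask follows the stated rule exactly (both anchors all-A);
  poly-T anchors on the reverse strand are not masked, since the protocol
  is assumed stranded.
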