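---
title: "Detecting mRNA 3' uridylation from soft-clipped RNA-seq alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting mRNA 3' uridylation from soft-clipped RNA-seq alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(utail)
```

## The measurement model

Ligation-based RNA-seq library preparation attaches adapters directly to
fragmented RNA, so fragments spanning a transcript's 3' terminus carry part
of its tail into the read. An aligner run with soft-clipping enabled cannot
match those non-templated bases to the genome and records them as a terminal
soft clip (CIGAR `S`). utail treats that clip — at the read's *biological*
3' end only — as a sample of the tail.

Three assumptions underpin the measurement:

* **Orientation.** SAM stores sequences in reference orientation. For a
  plus-strand alignment the biological 3' end is the right terminus of the
  stored sequence and CIGAR; for a minus-strand alignment it is the left
  terminus, and the clip must be reverse-complemented before
  classification. A clip at the biological 5' end is ignored: it may be
  adapter remnant or low-quality sequence, never a 3' tail.
* **Purity.** Only clips composed entirely of A and T (reported U) are
  interpretable as tails. Any other character — including N — rejects the
  clip rather than letting ambiguity inflate the `mixed` class.
* **Truncation.** A clip is a *fragment* of the tail, bounded by read
  length and fragmentation. The pipeline therefore never claims a full tail
  length, only the composition and length of the observed extension.

Accepted tails fall into exactly one class of a four-way grammar:
`polyA` (`^A+$`), `oligoU` (`^T+$`), `polyAU` (`^A+T+$` — the uridylation
signature: a poly(A) stretch terminated by uridines), and `mixed` (any
other pure-A/T string). The partition is total and unambiguous, which the
test suite verifies against an independent run-length-based oracle over
every A/T string up to length 8.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| `min_tail_len` | 4 | nt | extensions of 1–3 nt arise too easily from sequencing error or marginal alignment; only extensions longer than 3 nt are counted as tailed |
| `min_anchor` | 20 | nt | a tail hanging off a tiny aligned anchor is unreliable; with typical read lengths (~75–150 nt) the restriction is nearly vacuous |
| `max_distance` | 1000 | nt | a junction farther than 1 kb from every same-strand feature is likely an intergenic artefact; settable to `Inf` for no cutoff |
| `same_strand` | TRUE | — | tails derive from the transcript's own 3' end, so antisense features are excluded from assignment by default |
| `min_total` | 5 | reads | per-gene detection threshold: genes with fewer than 5 poly(A)+poly(A)U reads summed over replicates are too shallow to call |
| `freq_denominator` | `polyA+polyAU` | — | uridylation frequency as the uridylated share of poly(A)-bearing tails; see below |
| `dedup_fragments` | FALSE | — | read-level counting; per-fragment mode keeps one call per template |

### The uridylation-frequency denominator

"Percent uridylated reads" admits two readings: poly(AU) over all tailed
reads, or poly(AU) over poly(A)-bearing reads. We default to
`polyAU / (polyA + polyAU)` restricted to mRNA-assigned tails, because it is
the biologically natural quantity (the probability that a sampled poly(A)
tail end is uridylated) and is insensitive to the oligo(U)/mixed
background, which behaves differently (see the TES analysis below). The
alternative (`all-tailed`) is one argument away, so either convention can
be matched.

### Strain comparisons

Replicate frequencies are averaged *within* strain before the ratio
`loss = 100 × (1 − f_strain / f_baseline)` is taken, matching the
replicate-averaged presentation such comparisons use; pooling reads across
replicates before the ratio is available but weights replicates by depth.

### TES distances

The signed distance is `junction − TES` on the plus strand and
`TES − junction` on the minus strand, so 0 means "exactly at the annotated
end", negative is upstream (inside the gene) and positive downstream. The
cumulative distribution is computed on absolute distances over a 1 kb
window by default — association with the TES is a two-sided phenomenon
(annotation imprecision scatters junctions both ways) — with signed curves
available by argument.

## Feature assignment

Assignment follows "overlap beats proximity": a junction inside a feature
belongs to it even when another feature's boundary is nearer; otherwise the
feature with the smallest base-to-interval distance wins. Two deterministic
choices close gaps the underlying idea (bedtools-style `closest`) leaves
open:

* **Ties** between equidistant features go to the lexicographically
  smallest `feature_id`, so runs are reproducible to the byte.
* **Distance** is the gap between the junction base and the interval
  (0 inside, else `max(start − j, j − end)`), so an interval starting one
  base after the junction is at distance 1, not 0.

The implementation is a chunked vectorised scan over candidate features per
reference (and strand); a brute-force loop over all features serves as the
oracle in the tests, which require exact agreement on 50 random instances
of up to 1000 junctions × 100 features.

Coordinates are handled by `GRanges`/`rtracklayer` throughout, so GFF3
(1-based inclusive) and BED (0-based half-open) converge to one internal
convention at the reader boundary.

## What the simulator emulates — and what it does not

`sim_spec()` defaults describe a uridylating transcriptome as seen through
this assay:

* tailed fraction 1.5% of aligned reads;
* category mixture `polyA = 0.828, polyAU = 0.102, oligoU = 0.04,
  mixed = 0.03` — poly(A)+poly(AU) carry 93% of the tails and poly(AU) is
  ~11% of the poly(A)-bearing ones, the regime of a wild-type strain with
  active cytoplasmic uridylation (`category_mix()` rescales the first two
  entries to any target frequency for mutant strains);
* uridine runs of 1, 2 or 3 nt with probabilities 0.6/0.3/0.1 — uridylation
  adds predominantly one or two uridines;
* poly(A)/poly(AU)/mixed junctions at the TES with Gaussian jitter
  (sd 20 nt, emulating annotation imprecision and tail-boundary wobble),
  oligo(U) junctions uniform over gene bodies — oligo(U) reads associate
  only loosely with the TES;
* per-gene expression log-normal (sdlog 1), a 2% antisense background, and
  a 90% mRNA biotype share.

Gene structures are single-exon, expression sampling is i.i.d., base
qualities are absent, and sequencing error is off by default (a per-base
substitution rate is available). The 10 genomic bases downstream of every
TES are forced to C/G so that the templated/non-templated boundary is
exact by construction. Consequently a passing round-trip demonstrates that
extraction, orientation, classification and assignment are exact *given
correct alignments* — it says nothing about aligner behaviour on
A-rich genomic context (internal priming-like ambiguity), spliced 3' UTRs,
or degraded RNA, which real data contain. The simulator writes SAM directly
precisely so that CIGARs are ground truth; an aligner-in-the-loop test
would confound the pipeline's correctness with the aligner's.

Determinism: every sampled quantity derives from the single `seed`, and no
output file contains a timestamp, so the same spec reproduces genome,
annotation, SAM and truth table byte for byte.

## Numerical and degenerate-input choices

* An empty tail string is a contract error; a zero `total_aligned` is a
  contract error; a zero uridylation denominator yields `NA` (undefined),
  never 0 — while zero uridylated reads over a positive denominator is a
  true 0.
* Mixture and probability vectors must sum to 1 within 1e-9.
* `mixed` tails are generated by rejection sampling from random A/T strings
  until the string escapes the other three grammars, guaranteeing the truth
  label matches the classifier's partition.
* Correlations use `log10(x + 1)`: tail counts track expression over orders
  of magnitude, and the raw scale would let a handful of highly expressed
  genes dominate Pearson r. Zero-variance inputs return `NA` with a
  warning; fewer than 3 shared genes is an error.
* Duplicate-marked reads are kept by default (no deduplication is assumed
  upstream), MAPQ is not filtered by default; both have arguments.
* With `dedup_fragments = TRUE`, ties between mates of equal tail length
  break toward mate 1 — deterministic, and biased toward the mate
  conventionally sequenced first.

## Problem sizes

The test suite exercises the complete pipeline on a 50,000-fragment
simulation (the default spec) plus many smaller targeted fixtures, and runs
in about two minutes. `scripts/acceptance.R` scales to 400,000 fragments ×
2 replicates × 4 strains, chosen so the per-strain poly(A)-bearing mRNA
tail denominators reach ~10,000 and the strain-loss estimator's sampling SD
drops to ~2 percentage points.

## Known limitations

* Genomically templated A stretches adjacent to the cleavage site are not
  distinguished from added poly(A); no internal-priming-style correction is
  applied.
* Observed tail length is a lower bound on the true tail length; no
  full-length tail estimation is attempted.
* Isoform-level TES resolution is out of scope: assignment is to gene-level
  features, and a junction is compared to a single annotated TES.
* Whether both mates of a pair should be counted when both carry clips is
  left to the user (`dedup_fragments`); read-level counting is the
  default.
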