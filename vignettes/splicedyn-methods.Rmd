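---
title: "splicedyn: methods and design notes"
author: "splicedyn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{splicedyn: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicedyn)
```

## What the package models

`splicedyn` analyses an isoform-resolved developmental transcriptome: a
catalog of full-length transcript models (exon chains on a genome), a
staged expression matrix (FPKM over developmental stages with replicates),
poly(A) 3'-end records, and multi-segment fusion-candidate alignments. The
motivating system is a vertebrate embryo sampled daily across early
development (stages E1–E8, three replicates each), where intron retention
(IR) rises sharply during organogenesis and is suspected to down-regulate
specific gene classes through nonsense-mediated decay (NMD).

The pipeline stages are independent and composable:

1. **Catalog** — collapse redundant isoforms, classify against an
   annotation (known / novel isoform of a known gene / novel locus),
   summarise per-gene complexity.
2. **AS events** — classify the five splicing modes (IR, ES, A5SS, A3SS,
   MEE) from pairwise isoform comparison, deduplicated by coordinate
   signature; count presence per stage.
3. **Retained introns** — position within the gene body, length, GC,
   GT–AG canonicality, PWM log-odds splice-site strength; ORF search and
   the 50-nt PTC rule.
4. **IRT dynamics** — the per-gene IR-containing-transcript (IRT) value,
   `sum(FPKM of IR isoforms) / sum(FPKM of all isoforms)` in [0, 1], per
   stage; k-means clustering of the 8-stage trajectories (k = 9).
5. **APA** — 20-nt single-linkage clustering of cleavage sites, per-gene
   site counts, cleavage-context base composition, exhaustive hexamer
   enrichment (the canonical signal appears as DNA hexamer AATAAA).
6. **Fusion filter** — six criteria over merged alignment loci.
7. **Expression dynamics** — sample correlation on log2(FPKM+1),
   stage-pair differential genes (|log2FC| > 1, FDR < 0.01), k-means
   clustering of z-scored stage profiles (k = 10).

## Event definitions and their edge cases

Events come from all isoform pairs of a gene and are deduplicated by
`(type, signature)`, so one biological event supported by many isoform
pairs counts once. The definitions:

* **IR** — an intron `(s, e)` of one isoform lies inside a single exon of
  another (the exon must cover `s − 1` and `e + 1`, i.e. both boundaries
  are used as splice sites by the spliced form; this excludes transcript
  end differences).
* **ES** — an internal exon whose two flanking introns exist in one
  isoform, while another isoform has the single intron spanning from the
  left flank's donor to the right flank's acceptor.
* **A5SS / A3SS** — two introns from different isoforms sharing exactly
  one boundary, *and* whose exons flanking the differing boundary overlap
  between the isoforms. Without the overlap condition every exon-skipping
  pair would also emit one spurious donor-shift and one acceptor-shift
  event (the skip junction shares a boundary with each flanking intron),
  and mutually exclusive exons would emit a spurious pair too; the overlap
  requirement restricts the call to genuinely shifted splice sites, which
  is how standard event classifiers behave. Labels are strand-aware: a
  genomic-left shift at an intron start is a donor shift on `+` and an
  acceptor shift on `-`.
* **MEE** — two non-overlapping internal exons, each absent from the other
  isoform, with both outer flanking boundaries shared, and no isoform of
  the gene containing both exons.

A brute-force enumerator, written independently in the test helpers,
re-derives all events by plain nested loops; `detect_events` must agree
with it exactly on hundreds of random multi-isoform genes.

## The PTC rule

The longest ATG-initiated ORF (first in-frame stop, three sense frames,
ties to the 5'-most start) is located on the spliced transcript. The stop
is premature when

```
(position of last exon–exon junction) − (position of stop codon's last base) > 50
```

in spliced-transcript coordinates, strictly. A stop inside the last exon
gives a negative distance and is never premature. The distance is measured
from the stop codon's *last* base; the convention is fixed here because
the boundary could also be defined from the first base, a 2-nt ambiguity
that moves no call by more than 2 nt. IR transcripts whose retained intron
is not strictly inside the representative transcript's coding span are
excluded from PTC analysis (reasons `outside_cds` / `overlapping_cds`),
because the reading-frame consequence of the retained sequence is
undefined there.

## Splice-site strength

Strength is a position-weight-matrix log-odds score in bits,
`sum(log2 P(base | position) / P_bg(base))`, with the donor window
covering 3 exonic + 6 intronic nt and the acceptor window 20 intronic + 3
exonic nt, trained on the catalog's non-retained introns with a 0.5
pseudocount. This is a deliberately self-contained, monotone surrogate for
table-driven splice-site scorers; outputs are labelled `pwm_logodds` so
they cannot be mistaken for maximum-entropy scores. The qualitative
contrast it must preserve — retained introns score below consistently
spliced ones when their sites are degenerate — is asserted on synthetic
data.

## Differential expression

The gene-level test is limma's moderated t on log2(FPKM + 1) with BH
correction, and a gene is differential when both |log2FC| > 1 (stage-mean
FPKM, pseudocount 1) and FDR < 0.01. An unmoderated two-sample test was
considered and rejected: with three replicates it has 2–4 degrees of
freedom, and in the package's own calibration world (50 planted 8-fold
genes among 2,000 nulls, log-noise 0.1) it recovers only about half of
the planted genes at FDR < 0.01, while variance moderation recovers all
of them with no false positives. The method name is recorded in the
`stage_comparison` metadata.

## Clustering

`kmeans_cluster` is Lloyd's algorithm with k-means++ seeding, best of 10
restarts by within-cluster sum of squares, deterministic under its seed
(the caller's RNG state is saved and restored); an emptied cluster is
re-seeded from the farthest point. k is fixed at 9 for IRT trajectories
and 10 for expression profiles — no model selection is attempted, since
the cluster count is part of the analysis design, not an estimate.
Expression profiles are z-scored per gene after log transform (shape, not
amplitude, defines a temporal class); genes with constant profiles cannot
be z-scored and are dropped. IRT profiles are clustered on their natural
[0, 1] scale. By default only genes possessing at least one IR-containing
transcript are IRT-clustered; genes silent at any stage (denominator zero)
are excluded as ineligible rather than zero-filled, which would fabricate
a "stable low IR" class.

## The synthetic world

The generators state the world the tests and the acceptance run live in;
none of their parameters is tuned to test outcomes.

* **Genome** — i.i.d. bases at GC 0.42 (a typical avian genome-wide
  value), 1–6 chromosomes.
* **Gene models** — per AS mode, each planted gene carries exactly one
  unambiguous two-isoform event with boundary-matched flanking exons; exon
  lengths U(80, 250) nt, intron lengths U(150, 600) nt (modest but
  realistic scales that keep test genomes small); single-isoform control
  genes carry no event. All splice sites are written GT..AG except a
  configurable fraction of retained introns, which become degenerate
  (CA..TC). Retained introns are planted 3'-biased by default (the
  empirically observed localisation), with a uniform option for contrast.
  Genes are spaced 2,200 nt apart so downstream poly(A) planting of
  neighbouring genes cannot interfere.
* **Expression** — stage totals follow one of 10 expression archetypes
  (monotone, peaked, switch-like, oscillating shapes) scaled to a base
  FPKM of 50; within a gene the IR isoforms' share equals one of 9 IRT
  archetypes exactly before noise; replicates are multiplied by log-normal
  noise (sd 0.2 by default — FPKM noise is multiplicative and
  heavy-tailed). Archetypes are assigned round-robin and recorded as
  truth.
* **Poly(A)** — per gene, cleavage sites 60 nt apart downstream of the 3'
  end; each emits jittered copies (integer offsets, sd 2 nt, truncated at
  ±9 nt so a 20-nt clustering window can never bridge two planted sites);
  AATAAA is written 15–25 nt upstream of a `signal_rate` fraction of
  sites.
* **Fusion panel** — pass candidates plus, per criterion, candidates
  violating exactly that criterion.

What the generator does *not* emulate: read-level sampling noise (FPKM is
emitted directly), shared exon structure between neighbouring genes,
overlapping genes, alternative first/last exons, and realistic splice-site
sequence diversity. A green recovery test therefore establishes that the
algorithms invert the stated generative process, not that they would meet
the same accuracy on real long-read catalogs.

## Numerical and procedural choices

* Coordinates are 1-based inclusive (GTF convention) internally; BED
  exports are 0-based half-open. Unstranded transcripts are rejected.
* The rank-sum test enumerates all group assignments exactly when the
  pooled size is at most 10 (ties handled by midranks), otherwise uses the
  normal approximation with tie-corrected variance and continuity
  correction; constant pooled data returns p = 1.
* Poly(A) cluster representatives are the best-supported member position,
  ties resolved to the 3'-most position in transcript orientation
  (favouring distal cleavage); cross-stage site identity reuses the 20-nt
  window as its tolerance.
* Hexamer enrichment replaces a motif-discovery tool with an exhaustive,
  deterministic scan: for each of the 4,096 DNA hexamers, the number of
  50-nt upstream windows containing it is compared with an order-0
  expectation from each window's own base composition (0.25 pseudocount
  per base), with an upper binomial tail at the mean per-window occurrence
  probability. On uniform random windows no hexamer survives Bonferroni
  correction in ≥ 95% of seeds; the planted signal ranks first whenever at
  least half the sites carry it.
* Fusion loci merge same-chromosome segments closer than 1 kb — smaller
  than the 10-kb inter-locus distance criterion, so "two loci too close
  together" remains a distinct, testable failure mode rather than
  collapsing into "one locus".
* A gene's poly(A) cluster is assigned within its span extended 1 kb
  downstream; among several containing genes the nearest 3' end wins.
* The isoform collapse ignores 5' differences (identical intron chains
  merge spanning the union; a 5'-truncated suffix chain with a matching 3'
  terminus is absorbed into the longer chain) because long-read 5' ends
  are unreliable; collapsing is idempotent.

## Known limitations

* Event classification is exact-coordinate: no fuzziness for mapping
  wobble at splice sites.
* PTC calling uses the longest-ORF heuristic, not a trained coding-region
  predictor; non-ATG starts and selenoprotein read-through are out of
  scope.
* The APA module quantifies site presence, not usage ratios.
* Stage presence of an AS event is a threshold rule (each isoform form
  must reach mean FPKM 0.1, the conventional detection floor) — not a
  statistical test of expression.
* The fusion filter consumes pre-computed alignment segments; it performs
  no alignment itself and cannot rescue mis-segmented inputs.
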