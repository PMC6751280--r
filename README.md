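# splicedyn

Isoform-level analysis of a staged developmental transcriptome, built for
catalogs of full-length transcript models (e.g. from long-read isoform
sequencing of embryos sampled across consecutive developmental stages).
It is aimed at genomicists who have a transcript catalog (GTF), a genome
(FASTA), staged expression estimates (FPKM), poly(A) 3'-end records and
fusion-candidate alignments, and want the standard isoform-dynamics
readouts computed reproducibly — plus a fully seeded synthetic-data
generator so the whole pipeline is testable without any sequencing data.

## What it computes

* **Alternative splicing events** from multi-isoform gene models, the five
  classical modes — intron retention (IR), exon skipping (ES), alternative
  5'/3' splice sites (A5SS/A3SS), mutually exclusive exons (MEE) — by
  pairwise isoform comparison, deduplicated by coordinate signature, with
  per-stage presence counts.
* **Retained-intron characterization**: position in the gene body, length,
  GC, GT–AG canonicality, and PWM log-odds splice-site strength
  (donor = 3 exonic + 6 intronic nt, acceptor = 20 intronic + 3 exonic nt)
  trained on the catalog's own non-retained introns.
* **PTC calling** under the NMD 50-nt rule: a stop codon of the longest
  ORF is premature when it lies more than 50 nt (strictly) upstream of the
  last exon–exon junction in spliced-transcript coordinates.
* **IRT dynamics**: the per-gene IR-containing-transcript value
  `IRT = Σ FPKM(IR isoforms) / Σ FPKM(all isoforms) ∈ [0, 1]` per stage,
  and k-means clustering (k = 9) of the 8-stage trajectories.
* **APA**: 20-nt single-linkage clustering of cleavage sites, per-gene
  site counts, ±50-nt cleavage-context base composition, and exhaustive
  hexamer enrichment upstream of the sites (the canonical poly(A) signal
  appears as DNA hexamer AATAAA).
* **Fusion-candidate filtering** by six criteria: ≥ 2 loci, placed
  chromosomes only, ≥ 5% coverage per locus, ≥ 95% total coverage,
  ≥ 10 kb between loci, and short-read junction support.
* **Expression dynamics**: Pearson correlation between samples on
  log2(FPKM+1), stage-pair differential genes (limma moderated t,
  |log2FC| > 1 and BH-FDR < 0.01), and k-means clustering (k = 10) of
  z-scored temporal profiles.

## Worked example

Generate a small synthetic world with five planted events per splicing
mode and recover them:

```r
library(splicedyn)

genome <- generate_genome(n_chrom = 2, chrom_length = 4e5, seed = 7)
world  <- generate_gene_models(genome, n_genes = 40, events_per_type = 5,
                               seed = 8, degenerate_ir_fraction = 0.3)
events <- unlist(lapply(world$models, detect_events), recursive = FALSE)
count_events_by_type(events)
#>   IR   ES A5SS A3SS  MEE
#>    5    5    5    5    5
```

Every planted signature is recovered and the single-isoform control genes
yield zero events. The full pipeline runs from one seeded config:

```r
cfg <- default_run_config()
cfg$seed <- 1
run_pipeline(cfg)
#> splicedyn pipeline report (seed 1, v0.1.0)
#>   catalog_classes: known=85 novel_isoform_known_gene=0 novel_locus=0
#>   n_transcripts: 85
#>   n_genes: 60
#>   pct_single_transcript: 58.3
#>   as_events: IR=5 ES=5 A5SS=5 A3SS=5 MEE=5
#>   ir_events: 5
#>   irt_genes_eligible: 5
#>   polya_clusters: 120
#>   mean_sites_per_gene: 2
#>   top_hexamer: AATAAA
#>   fusion_pass: 10
#>   fusion_failures: a=2 b=2 c=2 d=2 e=2 f=2
#>   de_transitions: 7
#>   expr_clustered_genes: 60
#>   outputs: 20 files in ...
```

Reading the report: the 60-gene synthetic catalog collapses to 85
transcripts (catalog classification is against the generator's own models,
so everything is `known`); all 25 planted AS events are found; the 120
poly(A) clusters are exactly the 2 planted sites × 60 genes, with AATAAA
the top-ranked upstream hexamer; the labelled fusion panel splits into 10
passes and 2 failures per criterion; and expression dynamics are computed
over all 7 adjacent stage transitions. Stage tables (events, IRT profiles
and clusters, poly(A) BED/TSVs, fusion verdicts, correlations, DE counts)
are written under `cfg$out_dir`.

A shell entry point with the same behaviour lives at
`inst/scripts/run_pipeline.R`.

## Acceptance script

`scripts/acceptance.R` re-runs the full pipeline from scratch on the
synthetic world under a given seed and writes its report JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
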