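# regenGRN

Temporal integration of bulk RNA-seq and ATAC-seq for CNS
axon-regeneration gene regulatory networks.

Adult zebrafish fully regenerate optic-nerve axons after injury. Reading
the regulatory program behind that ability takes two time-resolved assays
over the same post-injury course (0, 2, 4, 7, 12 days post-injury, three
replicates each): retinal RNA-seq for what is expressed when, and
ATAC-seq of retinal ganglion cells for which regulatory DNA is accessible.
`regenGRN` is an analysis package for that integration, aimed at
computational biologists working with temporal expression + accessibility
designs:

- **Expression**: TPM normalization; per-transcript negative-binomial
  tests of every post-injury timepoint against baseline (Wald on the log
  fold change, `log(mu_t/mu_0) / SE`) plus a global likelihood-ratio test
  against chi-square(T−1), with adaptively shrunk method-of-moments
  dispersions and Benjamini–Hochberg FDR control; K-means clustering
  (K = 7) of Z-scores of log2(TPM+1) into temporal archetypes.
- **Accessibility**: retention of peak summits at p < 1e-10; fixed 500 bp
  "peaklets" around each summit; read-overlap counting; differential
  accessibility with the same NB machinery; annotation of each peaklet as
  proximal (center ≤ 1 kb of a TSS), distal (1–100 kb) or unassigned,
  with >50 bp exon overlap excluded from that assignment, and a separate
  5'UTR/exon/intron/intergenic classification.
- **Motifs**: JASPAR PFMs to log-odds PWMs
  (`log2(((c + λb)/(Σc + λ))/b)`); both-strand scanning at a fraction
  (0.8) of the maximum score; one-sided Fisher enrichment of motifs in
  cluster-specific proximal/distal peaklet sets; motif co-occurrence
  networks (Jaccard shared-peaklet fractions).
- **Network**: selection of differentially expressed catalog TFs with
  motifs; ranking of TFs by proximity to differentially accessible
  peaklets; motif-based TF → target edges with re-scannable evidence;
  hypergeometric gene-set summarization of target lists.
- **Synthetic data**: a ground-truthed generator emulating the whole
  design (seven planted temporal archetypes, stable peaklets with a small
  set opening at 2 dpi / closing at 12 dpi, motif consensi planted in
  cluster-matched peaklets), so every stage is validated by parameter
  recovery.

All coordinates are 0-based half-open throughout; GFF3 is converted on
read. Supported formats: FASTA, BED3/6, GFF3, JASPAR PFM text, TSV, JSON.

## Worked example

The `analysis/` directory holds the workflow as numbered drivers
(simulate → expression → accessibility → motifs → network), each a thin
script over the package's exported functions that prints what it found
and writes its tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_expression.R
Rscript analysis/03_accessibility.R
Rscript analysis/04_motifs.R
Rscript analysis/05_network.R
```

With the default seed the run prints, among other things:

```
simulated 120 genes on 1 chromosome(s); 84 genes carry one of 7 temporal archetypes, 36 are flat
planted 35 differentially accessible peaklets and 225 motif instances; 84 true TF->target edges

85 of 120 transcripts differential at LRT FDR < 0.05; 0 zero-variance rows flagged
clustered into 7 temporal groups (within-SS 271.8 ); sizes: 12 12 9 15 12 12 13
adjusted Rand index against the planted archetypes: 0.909

349 peaklets retained ( 0 clipped at chromosome edges ); 38 differentially accessible at FDR < 0.05
DA calls by timepoint (dpi): 12=18 2=20

7 differential TFs with motifs; 9 of 13 cluster/compartment motif tests enriched
top of the DA-proximity ranking:
  gene_id min_distance n_flanking
1   g0002          253          2
69 TF->target edges with 116 evidence hits
precision vs planted edges: 1 ; recall: 0.821
```

Reading: of 120 simulated genes, 85 are recalled as differential; the
K-means clusters match the planted archetypes at ARI 0.909; the planted
accessibility changes are recovered at the 5% FDR; the designated
"trigger" TF (`g0002`, whose promoter peaklet was planted to open at
2 dpi) ranks first by distance to differentially accessible chromatin
(253 bp); and the inferred TF → target edges recover 82% of the planted
edges with no false ones.

The same pipeline is available as a single call:

```r
library(regenGRN)
res <- run_all(pipeline_config(sim = sim_config(seed = 1)), out_dir = "results/run")
res$counts
```

Equivalent one-shot runs write `de_results.tsv`, `clusters.tsv`,
`peaklets.bed`, `peaklet_annotation.tsv`, `da_results.tsv`,
`motif_hits.tsv`, `stage_enrichment.tsv`, `cooccurrence.tsv`,
`tf_records.tsv`, `tf_da_proximity.tsv`, `tf_target_edges.tsv`,
`truth.json` and a `manifest.json` with summary counts; reruns with the
same config and seed are byte-identical.

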