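#!/usr/bin/env Rscript
# Stage 5: the regulatory network. Select differentially expressed catalog
# TFs with motifs, test per-cluster stage-specific enrichment in proximal
# and distal peaklets, build the co-occurrence network, rank TFs by
# proximity to differentially accessible peaklets, and infer TF -> target
# edges from motif hits in each target's annotated peaklets.
suppressMessages(library(regenGRN))

genome <- read_fasta("results/data/genome.fa")
gm <- read_gff_genes("results/data/genes.gff3")
motifs <- read_jaspar("results/data/motifs.jaspar")
tf_catalog <- read.delim("results/data/tf_catalog.tsv")
de <- read.delim("results/de_results.tsv")
clusters <- read.delim("results/clusters.tsv")
ann <- read.delim("results/peaklet_annotation.tsv")
da <- read.delim("results/da_results.tsv")
pk_bed <- read_bed("results/peaklets.bed")
peaklets <- data.frame(peaklet_id = pk_bed$name, chrom = pk_bed$chrom,
                       start = pk_bed$start, end = pk_bed$end)

# rebuild in-memory stage objects from the written tables
clustering <- structure(list(
  K = max(clusters$cluster),
  assignment = setNames(clusters$cluster, clusters$transcript_id)),
  class = "temporal_clustering")
bg <- peaklet_background(peaklets, genome)
pwms <- lapply(motifs, pfm_to_pwm, background = bg)
hm <- build_hit_matrix(peaklets, genome, pwms, threshold_fraction = 0.8)
tx2gene <- gm$transcripts

tfs <- select_regeneration_tfs(de, tf_catalog, clustering, tx2gene)
stage_enr <- cluster_stage_enrichment(clustering, ann, hm, tfs, tx2gene)
cooc <- cooccurrence_network(hm, motifs = sort(unique(tfs$motif_id)))
prox <- rank_tfs_by_da_proximity(tfs, da, peaklets, gm)

edges <- NULL; evidence <- NULL
for (i in seq_len(nrow(tfs))) {
  if (is.na(tfs$peak_cluster[i])) next
  t <- infer_tf_targets(tfs[i, ], clustering, ann, hm, tx2gene)
  edges <- rbind(edges, t$edges)
  evidence <- rbind(evidence, t$evidence)
}

write_table(as.data.frame(tfs), "results/tf_records.tsv", "tsv")
write_table(stage_enr, "results/stage_enrichment.tsv", "tsv")
write_table(cooc, "results/cooccurrence.tsv", "tsv")
prox$min_distance <- ifelse(is.finite(prox$min_distance),
                            prox$min_distance, NA)
write_table(prox, "results/tf_da_proximity.tsv", "tsv")
write_table(edges, "results/tf_target_edges.tsv", "tsv")
write_table(evidence, "results/tf_target_evidence.tsv", "tsv")

cat(nrow(tfs), "differential TFs with motifs;",
    sum(stage_enr$enriched), "of", nrow(stage_enr),
    "cluster/compartment motif tests enriched\n")
cat("top of the DA-proximity ranking:\n")
print(head(prox[c("gene_id", "min_distance", "n_flanking")], 3))
cat(nrow(edges), "TF->target edges with", nrow(evidence), "evidence hits\n")

truth <- read_truth("results/data/truth.json")
key <- function(d) paste(d$tf_gene_id, d$target_gene_id)
cat("precision vs planted edges:",
    round(mean(key(edges) %in% key(truth$true_edges)), 3),
    "; recall:", round(mean(key(truth$true_edges) %in% key(edges)), 3), "\n")
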