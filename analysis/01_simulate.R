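#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study -- a toy genome with annotated
# genes, a motif library, the 0/2/4/7/12 dpi expression experiment with
# seven planted temporal archetypes, and ATAC summits/reads with mostly
# stable peaklets plus a small planted set of differentially accessible
# ones -- and write every input in its standard format under results/data/.
suppressMessages(library(regenGRN))

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)
cfg <- sim_config(seed = 1, n_chroms = 1, chrom_length = 1.6e6,
                  n_genes = 120, n_motifs = 10)
ds <- simulate_dataset(cfg)

write_fasta(ds$genome, "results/data/genome.fa")
write_gff_genes(ds$genes, "results/data/genes.gff3")
write_jaspar(ds$motifs, "results/data/motifs.jaspar")

counts <- data.frame(transcript_id = rownames(ds$expression$counts),
                     ds$expression$counts, check.names = FALSE)
write_table(counts, "results/data/counts.tsv", "tsv")
write_table(data.frame(transcript_id = names(ds$expression$effective_length),
                       effective_length = ds$expression$effective_length),
            "results/data/effective_lengths.tsv", "tsv")
write_table(ds$expression$samples, "results/data/samples.tsv", "tsv")

write_table(ds$accessibility$summits[c("chrom", "pos", "p_value")],
            "results/data/summits.tsv", "tsv")
dir.create("results/data/reads", showWarnings = FALSE)
for (s in names(ds$accessibility$reads)) {
  write_table(ds$accessibility$reads[[s]],
              sprintf("results/data/reads/%s.bed", s), "bed")
}
write_table(ds$tf_catalog, "results/data/tf_catalog.tsv", "tsv")
write_truth(ds$truth, "results/data/truth.json")

cl <- unlist(ds$truth$cluster_of_gene)
cat("simulated", cfg$n_genes, "genes on", cfg$n_chroms, "chromosome(s);",
    sum(cl != "null"), "genes carry one of", cfg$n_clusters,
    "temporal archetypes,", sum(cl == "null"), "are flat\n")
cat("planted", nrow(ds$truth$da_peaklets), "differentially accessible",
    "peaklets and", nrow(ds$truth$planted_hits), "motif instances;",
    nrow(ds$truth$true_edges), "true TF->target edges\n")
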