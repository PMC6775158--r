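#!/usr/bin/env Rscript
# Stage 3: accessible chromatin. Retain summits at p < 1e-10, build 500 bp
# peaklets, count read overlaps per sample, test differential accessibility
# against 0 dpi, and annotate each peaklet relative to the gene models
# (proximal <= 1 kb of a TSS, distal 1-100 kb, > 50 bp exon overlap
# excluded from that assignment).
suppressMessages(library(regenGRN))

genome <- read_fasta("results/data/genome.fa")
gm <- read_gff_genes("results/data/genes.gff3")
summits <- read.delim("results/data/summits.tsv")
samples <- read.delim("results/data/samples.tsv")
chrom_lengths <- setNames(Biostrings::width(genome), names(genome))

peaklets <- build_peaklets(summits, chrom_lengths, width = 500,
                           p_cut = 1e-10)
reads <- lapply(setNames(samples$sample_id, samples$sample_id), function(s) {
  read_bed(sprintf("results/data/reads/%s.bed", s))
})
acc <- count_read_overlaps(reads, peaklets)
da <- differential_accessibility(acc, samples, fdr = 0.05)
ann <- annotate_peaklets(peaklets, gm)

write_table(data.frame(chrom = peaklets$chrom, start = peaklets$start,
                       end = peaklets$end, name = peaklets$peaklet_id,
                       score = 0L, strand = "."),
            "results/peaklets.bed", "bed")
write_table(da, "results/da_results.tsv", "tsv")
write_table(ann, "results/peaklet_annotation.tsv", "tsv")
dist <- genomic_distribution(ann)
write_table(dist, "results/genomic_distribution.tsv", "tsv")

cat(nrow(peaklets), "peaklets retained (", sum(peaklets$clipped),
    "clipped at chromosome edges );", sum(da$da),
    "differentially accessible at FDR < 0.05\n")
tp <- table(unlist(strsplit(da$da_timepoints[da$da], ",")))
cat("DA calls by timepoint (dpi):",
    paste(names(tp), tp, sep = "=", collapse = " "), "\n")
print(dist)
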