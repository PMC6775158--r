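#!/usr/bin/env Rscript
# Stage 4: motif scanning. Convert the motif library to log-odds PWMs
# against the peaklet-derived background composition, scan every peaklet
# sequence on both strands at 0.8 of the maximum score, and record the
# peaklet x motif hit matrix.
suppressMessages(library(regenGRN))

genome <- read_fasta("results/data/genome.fa")
motifs <- read_jaspar("results/data/motifs.jaspar")
pk_bed <- read_bed("results/peaklets.bed")
peaklets <- data.frame(peaklet_id = pk_bed$name, chrom = pk_bed$chrom,
                       start = pk_bed$start, end = pk_bed$end)

bg <- peaklet_background(peaklets, genome)
pwms <- lapply(motifs, pfm_to_pwm, background = bg)
hm <- build_hit_matrix(peaklets, genome, pwms, threshold_fraction = 0.8)

write_table(hm$hits, "results/motif_hits.tsv", "tsv")
cat("background composition (A,C,G,T):",
    paste(round(bg, 4), collapse = " "), "\n")
cat(nrow(hm$hits), "hits of", length(pwms), "motifs across",
    sum(rowSums(hm$matrix) > 0), "of", nrow(peaklets), "peaklets\n")
print(colSums(hm$matrix))
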