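# A small config used throughout: 40 genes on one 0.9 Mb chromosome.
small_cfg <- function(seed = 21, ...) {
  sim_config(seed = seed, n_chroms = 1, chrom_length = 9e5, n_genes = 40,
             n_motifs = 9, ...)
}

test_that("the generator is a pure function of (config, seed)", {
  a <- simulate_dataset(small_cfg())
  b <- simulate_dataset(small_cfg())
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$expression$counts, b$expression$counts)
  expect_identical(a$accessibility$summits, b$accessibility$summits)
  expect_identical(a$accessibility$reads, b$accessibility$reads)
  expect_identical(a$truth, b$truth)

  c <- simulate_dataset(small_cfg(seed = 22))
  expect_false(identical(a$expression$counts, c$expression$counts))
})

test_that("simulated genes are disjoint, strand-alternating and well-formed", {
  ga <- simulate_genome_and_annotation(small_cfg())
  g <- ga$genes$genes
  expect_equal(nrow(g), 40L)
  ord <- order(g$start)
  expect_true(all(g$start[ord][-1] >= g$end[ord][-length(ord)]))
  expect_equal(g$strand[order(g$gene_id)], rep(c("+", "-"), 20))
  # exons and UTRs inside their gene; TSS strand-resolved
  expect_true(all(ga$genes$exons$start >= g$start[match(
    ga$genes$exons$gene_id, g$gene_id)]))
  plus <- g[g$strand == "+", ]
  expect_equal(plus$tss, plus$start)
  minus <- g[g$strand == "-", ]
  expect_equal(minus$tss, minus$end - 1L)
})

test_that("gene placement fails loudly when genes cannot fit", {
  expect_error(sim_config(n_genes = 500, n_chroms = 1, chrom_length = 1e6),
               "cannot be placed")
})

test_that("simulated motifs have unit-scaled informative columns", {
  motifs <- simulate_motif_library(small_cfg())
  expect_length(motifs, 9L)
  for (m in motifs) {
    L <- ncol(m$counts)
    expect_true(L >= 8 && L <= 12)
    expect_true(all(abs(colSums(m$counts) - 100) < 1e-9))
    # the dominant base is recoverable from the counts
    expect_true(all(apply(m$counts, 2, max) == 85))
  }
  expect_identical(simulate_motif_library(small_cfg()), motifs)
})

test_that("expression archetypes behave as planted", {
  cfg <- small_cfg(de_log2fc = 2)
  ga <- simulate_genome_and_annotation(cfg)
  expr <- simulate_expression(ga$genes, cfg)
  expect_identical(simulate_expression(ga$genes, cfg)$counts, expr$counts)

  cl <- unlist(expr$truth$cluster_of_gene)
  # the early-up archetype (cluster 1) peaks at 2 dpi in group means
  early <- names(cl)[cl == "1"]
  tx <- paste0(early, ".t1")
  samples <- expr$samples
  gm <- sapply(sort(unique(samples$timepoint_dpi)), function(t) {
    rowMeans(expr$counts[tx, samples$sample_id[samples$timepoint_dpi == t],
                         drop = FALSE])
  })
  peak_tp <- sort(unique(samples$timepoint_dpi))[apply(gm, 1, which.max)]
  expect_true(mean(peak_tp == 2) > 0.8)

  # with a zero effect size every gene is effectively null
  flat <- simulate_expression(ga$genes, small_cfg(de_log2fc = 0))
  de <- nb_differential(flat$counts, flat$samples)
  expect_lt(mean(de$lrt_q < 0.05, na.rm = TRUE), 0.05)
})

test_that("planted archetype separation exceeds within-archetype noise", {
  cfg <- small_cfg()
  ga <- simulate_genome_and_annotation(cfg)
  expr <- simulate_expression(ga$genes, cfg)
  tpm <- compute_tpm(expr$counts, expr$effective_length)
  cl <- unlist(expr$truth$cluster_of_gene)
  de_tx <- paste0(names(cl)[cl != "null"], ".t1")
  z <- log_zscore(tpm, de_tx)
  labels <- as.integer(cl[sub(".t1", "", rownames(z$z), fixed = TRUE)])
  sil <- cluster::silhouette(labels, dist(z$z))
  expect_gt(mean(sil[, "sil_width"]), 0)
})

test_that("accessibility planting follows the first/last-timepoint rule", {
  cfg <- small_cfg()
  ds <- simulate_dataset(cfg)
  da <- ds$truth$da_peaklets
  expect_true(all(da$timepoint %in% c(2, 12)))
  expect_true(all(da$direction[da$timepoint == 2] == "open"))
  expect_true(all(da$direction[da$timepoint == 12] == "closed"))
  # the cluster-1 regulator's proximal peaklet is an opening element
  tf1 <- ds$truth$tf_gene_of_cluster[["1"]]
  pk <- ds$accessibility$peaklets
  tf1_prox <- pk$peaklet_id[!is.na(pk$gene_id) & pk$gene_id == tf1 &
                            pk$kind == "proximal"]
  expect_true(tf1_prox %in% da$peaklet_id[da$direction == "open"])

  none <- simulate_dataset(small_cfg(frac_da_peaklets = 0))
  expect_equal(nrow(none$truth$da_peaklets), 0L)
})

test_that("planted motif instances appear verbatim in the genome", {
  ds <- simulate_dataset(small_cfg(motif_plant_rate = 1))
  pk <- ds$accessibility$peaklets
  ph <- ds$truth$planted_hits
  cl <- unlist(ds$truth$cluster_of_gene)
  consensus <- sapply(ds$motifs, function(m)
    paste(c("A", "C", "G", "T")[apply(m$counts, 2, which.max)],
          collapse = ""))
  names(consensus) <- sapply(ds$motifs, `[[`, "motif_id")
  # at rate 1 every cluster-matched peaklet carries a planted instance
  matched <- pk$peaklet_id[!is.na(pk$gene_id) & cl[pk$gene_id] != "null"]
  expect_true(all(matched %in% ph$peaklet_id))
  # each recorded instance is present verbatim at its coordinates
  for (i in seq_len(nrow(ph))) {
    row <- pk[pk$peaklet_id == ph$peaklet_id[i], ]
    a <- row$start + ph$offset[i] + 1L
    inst <- consensus[[ph$motif_id[i]]]
    found <- as.character(Biostrings::subseq(ds$genome[[row$chrom]], a,
                                             a + nchar(inst) - 1L))
    if (ph$strand[i] == "-") found <- revcomp(found)
    expect_equal(found, inst)
  }
})

test_that("ground-truth manifests round-trip through JSON", {
  ds <- simulate_dataset(small_cfg())
  f <- withr::local_tempfile(fileext = ".json")
  write_truth(ds$truth, f)
  back <- read_truth(f)
  expect_equal(back$cluster_of_gene, ds$truth$cluster_of_gene)
  expect_equal(back$da_peaklets$peaklet_id, ds$truth$da_peaklets$peaklet_id)
  expect_equal(back$true_edges, ds$truth$true_edges)
  # referenced ids all exist in the simulated annotation
  expect_true(all(names(back$cluster_of_gene) %in% ds$genes$genes$gene_id))
  expect_true(all(back$da_peaklets$peaklet_id %in%
                  ds$accessibility$peaklets$peaklet_id))

  f2 <- withr::local_tempfile(fileext = ".json")
  write_truth(list(), f2)
  expect_equal(length(read_truth(f2)), 0L)
})
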