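test_that("peaklets are 500 bp windows around retained summits", {
  summits <- data.frame(chrom = "chr1", pos = c(1000L, 5000L),
                        p_value = c(1e-12, 1e-9))
  pk <- build_peaklets(summits, c(chr1 = 10000L))
  # the 1e-9 summit fails the p < 1e-10 retention rule
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$start, 750L)
  expect_equal(pk$end, 1250L)
  expect_false(pk$clipped)
})

test_that("peaklets clip at chromosome edges and keep overlapping windows", {
  summits <- data.frame(chrom = "chr1", pos = c(100L, 9990L, 2000L, 2100L),
                        p_value = 1e-12)
  pk <- build_peaklets(summits, c(chr1 = 10000L))
  expect_equal(pk$start[pk$summit_pos == 100], 0L)
  expect_equal(pk$end[pk$summit_pos == 100], 350L)
  expect_true(pk$clipped[pk$summit_pos == 100])
  expect_equal(pk$end[pk$summit_pos == 9990], 10000L)
  # two nearby summits both yield distinct (overlapping) peaklets
  expect_equal(sum(pk$summit_pos %in% c(2000, 2100)), 2L)
  # ids follow (chrom, pos) sort order
  expect_equal(pk$peaklet_id, sprintf("pk%06d", 1:4))
  expect_equal(pk$summit_pos, sort(pk$summit_pos))
  expect_error(build_peaklets(summits, c(chr1 = 10000L), width = 501),
               "even")
})

test_that("read overlap counting is half-open and double-counts spanning reads", {
  summits <- data.frame(chrom = "chr1", pos = c(1000L, 1500L),
                        p_value = 1e-12)
  pk <- build_peaklets(summits, c(chr1 = 10000L))  # [750,1250), [1250,1750)
  reads <- list(
    s1 = data.frame(chrom = "chr1", start = c(700L, 749L, 1240L),
                    end = c(750L, 800L, 1260L), stringsAsFactors = FALSE))
  m <- count_read_overlaps(reads, pk)
  # [700,750) does not touch [750,1250); [749,800) does; the spanning read
  # [1240,1260) counts in both peaklets
  expect_equal(unname(m[, "s1"]), c(2L, 1L))
})

test_that("differential accessibility recovers a planted opening element", {
  samples <- toy_samples()
  set.seed(6)
  n_pk <- 100
  mu <- rlnorm(n_pk, log(50), 0.4)
  MU <- matrix(rep(mu, nrow(samples)), n_pk)
  MU[1, samples$timepoint_dpi == 2] <- MU[1, samples$timepoint_dpi == 2] * 4
  counts <- matrix(rnbinom(length(MU), size = 10, mu = MU), nrow = n_pk,
                   dimnames = list(sprintf("pk%06d", 1:n_pk),
                                   samples$sample_id))
  res <- differential_accessibility(counts, samples)
  expect_true(res$da[1])
  expect_equal(res$direction_2[1], "open")

  flat <- matrix(40, 5, nrow(samples),
                 dimnames = list(paste0("p", 1:5), samples$sample_id))
  res0 <- differential_accessibility(flat, samples)
  expect_false(any(res0$da))
})

test_that("annotation follows the proximal/distal/unassigned windows", {
  gm <- toy_gene_models()  # TSSs at 1000 (+) and 11999 (-)
  mk <- function(center) {
    data.frame(peaklet_id = sprintf("pk_%d", center), chrom = "chr1",
               start = center - 250L, end = center + 250L,
               stringsAsFactors = FALSE)
  }
  # center 500 bp from gA's TSS, not overlapping exons by > 50 bp
  near <- mk(500L)
  ann <- annotate_peaklets(near, gm)
  expect_equal(ann$location_class, "proximal")
  expect_equal(ann$nearest_gene, "gA")
  expect_equal(ann$tss_distance, 500)

  far <- mk(62000L)   # ~50 kb from gB's TSS
  ann <- annotate_peaklets(far, gm)
  expect_equal(ann$location_class, "distal")

  # > 100 kb from every TSS
  out <- mk(150000L)
  expect_equal(annotate_peaklets(out, gm)$location_class, "unassigned")
})

test_that("exonic-overlap exclusion applies to location but not genic class", {
  gm <- toy_gene_models()
  pk <- data.frame(peaklet_id = "pk1", chrom = "chr1",
                   start = 1100L, end = 1600L, stringsAsFactors = FALSE)
  ann <- annotate_peaklets(pk, gm)  # overlaps gA exon1 [1000,1500) by 400 bp
  expect_equal(ann$location_class, "unassigned")
  expect_equal(ann$reason, "exonic_overlap")
  expect_equal(ann$genic_class, "exon")
})

test_that("annotation agrees exactly with the brute-force scan on random fixtures", {
  set.seed(8)
  genes <- data.frame(
    gene_id = sprintf("g%02d", 1:20), chrom = sample(c("chr1", "chr2"), 20,
                                                     replace = TRUE),
    start = sample(seq(0, 4e5, by = 2e4), 20), stringsAsFactors = FALSE)
  genes$end <- genes$start + sample(2000:5000, 20)
  genes$strand <- sample(c("+", "-"), 20, replace = TRUE)
  exons <- do.call(rbind, lapply(1:20, function(i) {
    data.frame(gene_id = genes$gene_id[i], chrom = genes$chrom[i],
               start = c(genes$start[i], genes$end[i] - 800L),
               end = c(genes$start[i] + 600L, genes$end[i]),
               stringsAsFactors = FALSE)
  }))
  utr5 <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                     start = ifelse(genes$strand == "+", genes$start,
                                    genes$end - 100L),
                     end = ifelse(genes$strand == "+", genes$start + 100L,
                                  genes$end), stringsAsFactors = FALSE)
  tx <- data.frame(transcript_id = paste0(genes$gene_id, ".t1"),
                   gene_id = genes$gene_id, stringsAsFactors = FALSE)
  gm <- gene_models(genes, tx, exons, utr5)

  centers <- sample(500:450000, 300)
  pk <- data.frame(peaklet_id = sprintf("pk%04d", 1:300),
                   chrom = sample(c("chr1", "chr2", "chr3"), 300,
                                  replace = TRUE),
                   start = centers - 250L, end = centers + 250L,
                   stringsAsFactors = FALSE)
  got <- annotate_peaklets(pk, gm)
  want <- brute_annotate(pk, gm)
  expect_equal(got$location_class, want$location_class)
  expect_equal(got$genic_class, want$genic_class)
  expect_equal(got$nearest_gene, want$nearest_gene)
  expect_equal(got$tss_distance, want$tss_distance)
  # proximal and distal sets are disjoint and exclude exonic-overlap peaklets
  expect_equal(sum(got$location_class == "proximal" &
                   got$location_class == "distal"), 0L)
  expect_true(all(got$exon_overlap[got$location_class %in%
                                   c("proximal", "distal")] <= 50))
})

test_that("genomic distribution fractions sum to one per axis", {
  gm <- toy_gene_models()
  pk <- data.frame(peaklet_id = sprintf("pk%d", 1:4), chrom = "chr1",
                   start = c(200L, 1150L, 2100L, 50000L),
                   end = c(700L, 1650L, 2600L, 50500L),
                   stringsAsFactors = FALSE)
  ann <- annotate_peaklets(pk, gm)
  dist <- genomic_distribution(ann)
  for (ax in c("genic", "location")) {
    expect_equal(sum(dist$fraction[dist$axis == ax]), 1)
  }
  expect_error(genomic_distribution(ann[0, ]), "no annotations")
  # single-class edge case
  solo <- genomic_distribution(annotate_peaklets(pk[4, ], gm))
  expect_equal(solo$fraction[solo$class == "intergenic"], 1)
})
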