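# Independent brute-force oracles and small fixture builders shared across
# the test files. Every oracle is written from the definition, independent
# of the implementation path it checks.

# BH step-up from the definition: q_i = min over j with p_(j) >= p_(i) of
# p_(j) * m / j, capped at 1.
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- which(p[ord] >= p[i] - 1e-15)
    q[i] <- min(pmin(p[ord][js] * m / js, 1))
  }
  q
}

# Upper-tail hypergeometric by explicit tail summation with choose():
# probability of >= k hits in the foreground, given n foreground draws from
# a population of n + N peaklets of which k + K carry the motif.
brute_fisher_greater <- function(k, n, K, N) {
  white <- k + K
  total <- n + N
  i <- max(k, 0):min(n, white)
  sum(choose(white, i) * choose(total - white, n - i)) / choose(total, n)
}

# Character-level PWM scan from the definition; minus-strand score at
# forward offset i is the forward-PWM score of the reverse complement of
# the window.
brute_scan <- function(pwm, seq, threshold_fraction = 0.8) {
  chars <- strsplit(toupper(seq), "")[[1]]
  L <- ncol(pwm$log_odds)
  S <- length(chars)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  score_word <- function(word) {
    s <- 0
    for (j in seq_len(L)) {
      if (word[j] == "N") return(-Inf)
      s <- s + pwm$log_odds[word[j], j]
    }
    s
  }
  thr <- threshold_fraction * pwm$max_score
  out <- list()
  if (S >= L) {
    for (i in 0:(S - L)) {
      w <- chars[(i + 1):(i + L)]
      sp <- score_word(w)
      if (sp >= thr) out[[length(out) + 1]] <-
        data.frame(offset = i, strand = "+", score = sp)
      sm <- score_word(rev(unname(comp[w])))
      if (sm >= thr) out[[length(out) + 1]] <-
        data.frame(offset = i, strand = "-", score = sm)
    }
  }
  if (length(out) == 0) {
    return(data.frame(offset = integer(), strand = character(),
                      score = numeric()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$offset, res$strand), ]
  rownames(res) <- NULL
  res
}

# Exhaustive peaklet annotation by nested loops over genes and features.
brute_annotate <- function(peaklets, gm, proximal_bp = 1000,
                           distal_bp = 100000, exon_overlap_bp = 50) {
  ov <- function(a1, a2, b1, b2) max(0, min(a2, b2) - max(a1, b1))
  genes <- gm$genes[order(gm$genes$gene_id), ]
  out <- NULL
  for (i in seq_len(nrow(peaklets))) {
    ctr <- (peaklets$start[i] + peaklets$end[i]) %/% 2
    best_d <- Inf
    best_g <- NA_character_
    for (j in seq_len(nrow(genes))) {
      if (genes$chrom[j] != peaklets$chrom[i]) next
      d <- abs(ctr - genes$tss[j])
      if (d < best_d) { best_d <- d; best_g <- genes$gene_id[j] }
    }
    exon_ov <- 0
    for (j in seq_len(nrow(gm$exons))) {
      if (gm$exons$chrom[j] != peaklets$chrom[i]) next
      exon_ov <- max(exon_ov, ov(peaklets$start[i], peaklets$end[i],
                                 gm$exons$start[j], gm$exons$end[j]))
    }
    utr_hit <- FALSE
    for (j in seq_len(nrow(gm$utr5))) {
      if (gm$utr5$chrom[j] != peaklets$chrom[i]) next
      if (ov(peaklets$start[i], peaklets$end[i], gm$utr5$start[j],
             gm$utr5$end[j]) > 0) utr_hit <- TRUE
    }
    body_hit <- FALSE
    for (j in seq_len(nrow(genes))) {
      if (genes$chrom[j] != peaklets$chrom[i]) next
      if (ov(peaklets$start[i], peaklets$end[i], genes$start[j],
             genes$end[j]) > 0) body_hit <- TRUE
    }
    genic <- if (utr_hit) "utr5" else if (exon_ov > 0) "exon" else
      if (body_hit) "intron" else "intergenic"
    loc <- if (exon_ov > exon_overlap_bp) "unassigned" else
      if (best_d <= proximal_bp) "proximal" else
      if (best_d < distal_bp) "distal" else "unassigned"
    out <- rbind(out, data.frame(
      peaklet_id = peaklets$peaklet_id[i], location_class = loc,
      genic_class = genic, nearest_gene = best_g,
      tss_distance = if (is.finite(best_d)) best_d else NA,
      stringsAsFactors = FALSE))
  }
  out
}

# Pairwise co-occurrence by explicit set intersection.
brute_cooccurrence <- function(mat) {
  ids <- colnames(mat)
  out <- NULL
  for (a in seq_len(ncol(mat) - 1)) {
    for (b in (a + 1):ncol(mat)) {
      A <- rownames(mat)[mat[, a]]
      B <- rownames(mat)[mat[, b]]
      s <- length(intersect(A, B))
      if (s == 0) next
      out <- rbind(out, data.frame(
        motif_a = ids[a], motif_b = ids[b], shared_peaklets = s,
        shared_fraction = s / length(union(A, B)), stringsAsFactors = FALSE))
    }
  }
  out
}

# A tiny deterministic gene-model fixture: two genes on one chromosome,
# opposite strands.
toy_gene_models <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB"), chrom = "chr1",
    start = c(1000L, 10000L), end = c(3000L, 12000L),
    strand = c("+", "-"), stringsAsFactors = FALSE)
  tx <- data.frame(transcript_id = c("gA.t1", "gB.t1"),
                   gene_id = c("gA", "gB"), stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("gA", "gA", "gB", "gB"), chrom = "chr1",
    start = c(1000L, 2400L, 10000L, 11400L),
    end = c(1500L, 3000L, 10500L, 12000L), stringsAsFactors = FALSE)
  utr5 <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                     start = c(1000L, 11900L), end = c(1100L, 12000L),
                     stringsAsFactors = FALSE)
  gene_models(genes, tx, exons, utr5)
}

# A sample table with `reps` replicates at the standard five timepoints.
toy_samples <- function(reps = 3, tps = c(0, 2, 4, 7, 12)) {
  data.frame(
    sample_id = sprintf("t%02d_r%d", rep(tps, each = reps),
                        rep(seq_len(reps), length(tps))),
    timepoint_dpi = rep(tps, each = reps),
    replicate = rep(seq_len(reps), length(tps)),
    stringsAsFactors = FALSE)
}

# A crisp toy motif: strongly informative columns spelling a consensus.
toy_motif <- function(consensus = "ACGTACGT", motif_id = "M001",
                      tf_name = "TF001") {
  bases <- strsplit(consensus, "")[[1]]
  counts <- vapply(bases, function(b) {
    v <- rep(5, 4)
    v[match(b, c("A", "C", "G", "T"))] <- 85
    v
  }, numeric(4))
  rownames(counts) <- c("A", "C", "G", "T")
  colnames(counts) <- NULL
  list(motif_id = motif_id, tf_name = tf_name, counts = counts)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
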