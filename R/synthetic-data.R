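# Synthetic-data generator: a toy genome with annotated genes, seven planted
# temporal expression archetypes over the 0/2/4/7/12 dpi design, stable
# accessible peaklets near genes with a small set of differentially
# accessible ones concentrated at the first and last post-injury timepoints,
# and motif consensus instances planted into the peaklets of cluster-matched
# genes. Everything is a pure function of (config, seed) and a ground-truth
# manifest makes each pipeline stage testable by parameter recovery.

# The seven temporal archetype shapes (log2-space multipliers, scaled by
# de_log2fc) over timepoints 0/2/4/7/12 dpi: up-regulation peaking early,
# mid, or late; the mirrored down-regulated shapes; and transient
# down-regulation followed by late re-expression.
ARCHETYPE_SHAPES <- rbind(
  early_up     = c(0,  1.0,  0.4,  0.1,  0.0),
  mid_up       = c(0,  0.25, 1.0,  0.7,  0.15),
  late_up      = c(0,  0.0,  0.25, 0.7,  1.0),
  early_down   = c(0, -1.0, -0.4, -0.1,  0.0),
  mid_down     = c(0, -0.25, -1.0, -0.7, -0.15),
  late_down    = c(0,  0.0, -0.25, -0.7, -1.0),
  down_late_up = c(0, -1.0, -0.5,  0.3,  1.0))

#' Simulation configuration
#'
#' Defaults define the study conditions the pipeline is validated under:
#' 7 temporal clusters, 3 replicates at 0/2/4/7/12 dpi, NB dispersion 0.1,
#' a 4-fold planted effect (de_log2fc = 2), 10% differentially accessible
#' peaklets split between opening at 2 dpi and closing at 12 dpi, and a 0.9
#' motif-planting rate in cluster-matched peaklets.
#'
#' @param seed Integer RNG seed; all generator output is a pure function of
#'   the config including this seed.
#' @param n_chroms,chrom_length,n_genes Genome layout; genes must fit
#'   (`chrom_length > 10 * n_genes / n_chroms * 1000`).
#' @param n_motifs Motif library size; must be >= n_clusters (one planted
#'   motif per cluster, the rest decoys).
#' @param n_clusters Number of planted archetypes (2..7, default 7).
#' @param timepoints Days post-injury (default 0, 2, 4, 7, 12).
#' @param replicates Replicates per timepoint (default 3).
#' @param nb_dispersion NB dispersion of counts (default 0.1).
#' @param de_log2fc Planted log2 effect size (default 2).
#' @param frac_da_peaklets Fraction of peaklets planted as differentially
#'   accessible (default 0.1).
#' @param motif_plant_rate Per-peaklet probability of planting the cluster
#'   TF's motif consensus (default 0.9).
#' @param frac_null_genes Fraction of genes with a flat ("null") profile
#'   (default 0.3).
#' @param peaklet_width Peaklet width used when planting (default 500).
#' @return Class "sim_config" list.
#' @export
sim_config <- function(seed = 1, n_chroms = 2, chrom_length = 2e6,
                       n_genes = 200, n_motifs = 10, n_clusters = 7,
                       timepoints = c(0, 2, 4, 7, 12), replicates = 3,
                       nb_dispersion = 0.1, de_log2fc = 2,
                       frac_da_peaklets = 0.1, motif_plant_rate = 0.9,
                       frac_null_genes = 0.3, peaklet_width = 500) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes), n_motifs = as.integer(n_motifs),
              n_clusters = as.integer(n_clusters), timepoints = timepoints,
              replicates = as.integer(replicates),
              nb_dispersion = nb_dispersion, de_log2fc = de_log2fc,
              frac_da_peaklets = frac_da_peaklets,
              motif_plant_rate = motif_plant_rate,
              frac_null_genes = frac_null_genes,
              peaklet_width = as.integer(peaklet_width))
  if (cfg$n_clusters < 2 || cfg$n_clusters > nrow(ARCHETYPE_SHAPES)) {
    stop("n_clusters must be between 2 and ", nrow(ARCHETYPE_SHAPES))
  }
  if (cfg$n_motifs < cfg$n_clusters) stop("n_motifs must be >= n_clusters")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (cfg$frac_da_peaklets < 0 || cfg$frac_da_peaklets > 1 ||
      cfg$motif_plant_rate < 0 || cfg$motif_plant_rate > 1) {
    stop("rates must lie in [0, 1]")
  }
  genes_per_chrom <- ceiling(cfg$n_genes / cfg$n_chroms)
  if (cfg$chrom_length <= 10 * genes_per_chrom * 1000) {
    stop("chrom_length too small: genes cannot be placed without overlap")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a genome and its gene annotation
#'
#' Chromosomes are i.i.d. uniform ACGT. Genes are placed in disjoint
#' per-gene territories, on alternating strands, each with two exons
#' separated by an intron and a 100 bp 5'UTR at the 5' end. Deterministic
#' given the config seed.
#'
#' @param config "sim_config" object.
#' @return list(genome = named DNAStringSet, genes = "gene_models").
#' @export
simulate_genome_and_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chrom_names <- sprintf("chr%d", seq_len(config$n_chroms))
  seqs <- vapply(chrom_names, function(ch) {
    paste(sample(DNA_BASES, config$chrom_length, replace = TRUE),
          collapse = "")
  }, "")

  per_chrom <- rep(config$n_genes %/% config$n_chroms, config$n_chroms)
  extra <- config$n_genes %% config$n_chroms
  if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L

  rows <- list(); exon_rows <- list(); utr_rows <- list(); tx_rows <- list()
  gi <- 0L
  for (ci in seq_len(config$n_chroms)) {
    ng <- per_chrom[ci]
    if (ng == 0L) next
    slot <- config$chrom_length %/% ng
    for (si in seq_len(ng)) {
      gi <- gi + 1L
      slot_start <- (si - 1L) * slot
      glen <- sample(1500:3000, 1L)
      gstart <- slot_start + round(stats::runif(1, 0.35, 0.5) * slot)
      gend <- gstart + glen
      if (gend > slot_start + slot) stop("gene does not fit its territory")
      strand <- if (gi %% 2L == 1L) "+" else "-"
      gid <- sprintf("g%04d", gi)
      e1 <- sample(300:600, 1L)
      intron <- sample(200:500, 1L)
      rows[[gi]] <- data.frame(gene_id = gid, chrom = chrom_names[ci],
                               start = gstart, end = gend, strand = strand,
                               stringsAsFactors = FALSE)
      exon_rows[[gi]] <- data.frame(
        gene_id = gid, chrom = chrom_names[ci],
        start = c(gstart, gstart + e1 + intron), end = c(gstart + e1, gend),
        stringsAsFactors = FALSE)
      utr_rows[[gi]] <- data.frame(
        gene_id = gid, chrom = chrom_names[ci],
        start = if (strand == "+") gstart else gend - 100L,
        end = if (strand == "+") gstart + 100L else gend,
        stringsAsFactors = FALSE)
      tx_rows[[gi]] <- data.frame(transcript_id = paste0(gid, ".t1"),
                                  gene_id = gid, stringsAsFactors = FALSE)
    }
  }
  gm <- gene_models(do.call(rbind, rows), do.call(rbind, tx_rows),
                    do.call(rbind, exon_rows), do.call(rbind, utr_rows))
  list(genome = Biostrings::DNAStringSet(seqs), genes = gm)
}

#' Simulate a motif library
#'
#' Motifs of length 8-12 with one dominant base per column (probability
#' 0.85, others 0.05), counts scaled to 100. The first `n_clusters` motifs
#' are the planted cluster regulator motifs; the rest are decoys.
#'
#' @param config "sim_config" object.
#' @return List of motif matrices (same shape as [read_jaspar()] output).
#' @export
simulate_motif_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  lapply(seq_len(config$n_motifs), function(i) {
    L <- sample(8:12, 1L)
    counts <- vapply(seq_len(L), function(j) {
      probs <- rep(0.05, 4)
      probs[sample.int(4L, 1L)] <- 0.85
      probs * 100
    }, numeric(4L))
    rownames(counts) <- DNA_BASES
    list(motif_id = sprintf("M%03d", i), tf_name = sprintf("TF%03d", i),
         counts = counts)
  })
}

# Internal: consensus sequence of a motif (dominant base per column).
motif_consensus <- function(motif) {
  paste(DNA_BASES[apply(motif$counts, 2L, which.max)], collapse = "")
}

#' Simulate the temporal expression experiment
#'
#' Assigns each gene an archetype (or "null" for a flat profile), designates
#' the lexicographically first gene of each cluster as that cluster's
#' regulator TF, and draws NB counts with per-timepoint means
#' `baseline * 2^(de_log2fc * shape[t])`. One transcript per gene; the
#' effective length is the summed exon length. Deterministic given the seed.
#'
#' @param genes "gene_models" object.
#' @param config "sim_config" object.
#' @return list(counts, effective_length, samples, truth) where truth holds
#'   `cluster_of_gene` (cluster index or "null"), `archetype_of_cluster`,
#'   `tf_gene_of_cluster`, `motif_of_cluster`.
#' @export
simulate_expression <- function(genes, config) {
  stopifnot(inherits(genes, "gene_models"), inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  gids <- sort(genes$genes$gene_id)
  n <- length(gids)
  n_null <- round(config$frac_null_genes * n)
  null_genes <- sort(sample(gids, n_null))
  de_genes <- setdiff(gids, null_genes)
  cluster <- stats::setNames(rep("null", n), gids)
  cluster[de_genes] <- as.character(
    sample(rep_len(seq_len(config$n_clusters), length(de_genes))))

  tf_gene_of_cluster <- vapply(seq_len(config$n_clusters), function(k) {
    members <- names(cluster)[cluster == as.character(k)]
    if (length(members) == 0L) NA_character_ else min(members)
  }, "")
  motif_ids <- sprintf("M%03d", seq_len(config$n_clusters))

  tps <- config$timepoints
  samples <- data.frame(
    sample_id = as.vector(outer(seq_len(config$replicates), tps,
                                function(r, t) sprintf("t%02d_r%d", t, r))),
    timepoint_dpi = rep(tps, each = config$replicates),
    replicate = rep(seq_len(config$replicates), length(tps)),
    stringsAsFactors = FALSE)
  samples <- samples[order(samples$timepoint_dpi, samples$replicate), ,
                     drop = FALSE]
  rownames(samples) <- NULL

  shapes <- ARCHETYPE_SHAPES[seq_len(config$n_clusters), , drop = FALSE]
  baseline <- stats::setNames(stats::rlnorm(n, log(200), 0.7), gids)
  tx <- genes$transcripts
  tx_of_gene <- stats::setNames(tx$transcript_id, tx$gene_id)
  counts <- matrix(0L, nrow = n, ncol = nrow(samples),
                   dimnames = list(tx_of_gene[gids], samples$sample_id))
  size <- 1 / config$nb_dispersion
  for (i in seq_len(n)) {
    g <- gids[i]
    shape <- if (cluster[g] == "null") rep(0, length(tps))
             else shapes[as.integer(cluster[g]), ]
    mu <- baseline[g] * 2^(config$de_log2fc * shape)
    counts[i, ] <- stats::rnbinom(nrow(samples), size = size,
                                  mu = mu[match(samples$timepoint_dpi, tps)])
  }

  exon_len <- tapply(genes$exons$end - genes$exons$start, genes$exons$gene_id,
                     sum)
  effective_length <- stats::setNames(as.numeric(exon_len[gids]),
                                      tx_of_gene[gids])

  truth <- list(
    cluster_of_gene = as.list(cluster),
    archetype_of_cluster = stats::setNames(
      as.list(rownames(shapes)), as.character(seq_len(config$n_clusters))),
    tf_gene_of_cluster = stats::setNames(
      as.list(tf_gene_of_cluster), as.character(seq_len(config$n_clusters))),
    motif_of_cluster = stats::setNames(
      as.list(motif_ids), as.character(seq_len(config$n_clusters))))
  list(counts = counts, effective_length = effective_length,
       samples = samples, truth = truth)
}

#' Simulate chromatin accessibility around the simulated genes
#'
#' Every gene gets one proximal summit (near its TSS) and 1-3 distal summits
#' (1-8 kb away, inside the gene's territory); a small fraction of decoy
#' summits fail the p-value retention cut. Most peaklets are stable
#' (baseline NB counts); `frac_da_peaklets` are planted as differentially
#' accessible, opening at 2 dpi or closing at 12 dpi, and the cluster-1
#' regulator TF's proximal peaklet is always planted open at 2 dpi (the
#' trigger element the ranking stage should recover). The consensus of each
#' cluster's motif is written verbatim into the genome inside the peaklets
#' of that cluster's genes at rate `motif_plant_rate`. Per-sample read
#' intervals are drawn around the summits so that overlap counting recovers
#' the planted count structure.
#'
#' @param genome Named DNAStringSet from [simulate_genome_and_annotation()].
#' @param genes "gene_models" object.
#' @param motifs Motif library from [simulate_motif_library()].
#' @param truth Truth fragment from [simulate_expression()].
#' @param config "sim_config" object.
#' @return list(summits, peaklets, reads (list of BED data.frames by
#'   sample), samples, genome (with planted instances), truth fragment with
#'   `da_peaklets`, `planted_hits`, `true_edges`, and `gene_of_peaklet`).
#' @export
simulate_accessibility <- function(genome, genes, motifs, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  g <- genes$genes
  chrom_lengths <- stats::setNames(Biostrings::width(genome), names(genome))

  summ <- list()
  for (i in seq_len(nrow(g))) {
    clen <- chrom_lengths[[g$chrom[i]]]
    prox <- g$tss[i] + round(stats::rnorm(1, 0, 150))
    prox <- min(max(prox, 300L), clen - 300L)
    nd <- sample(1:3, 1L)
    dist <- round(stats::runif(nd, 1000, 8000)) *
      sample(c(-1L, 1L), nd, replace = TRUE)
    dpos <- pmin(pmax(g$tss[i] + dist, 300L), clen - 300L)
    summ[[i]] <- data.frame(
      chrom = g$chrom[i], pos = as.integer(c(prox, dpos)),
      p_value = 10^-stats::runif(nd + 1L, 11, 30),
      gene_id = g$gene_id[i],
      kind = c("proximal", rep("distal", nd)),
      stringsAsFactors = FALSE)
  }
  summits <- do.call(rbind, summ)
  # decoy summits that fail the retention cut (5% of the retained count)
  n_decoy <- max(1L, round(0.05 * nrow(summits)))
  decoy <- data.frame(
    chrom = sample(names(chrom_lengths), n_decoy, replace = TRUE),
    pos = NA_integer_, p_value = 10^-stats::runif(n_decoy, 2, 9),
    gene_id = NA_character_, kind = "decoy", stringsAsFactors = FALSE)
  decoy$pos <- as.integer(round(stats::runif(
    n_decoy, 300, chrom_lengths[decoy$chrom] - 300)))
  summits <- rbind(summits, decoy)
  rownames(summits) <- NULL

  peaklets <- build_peaklets(summits, chrom_lengths,
                             width = config$peaklet_width, p_cut = 1e-10)

  # plant motif consensus instances into cluster-matched peaklets
  cluster_of_gene <- unlist(truth$cluster_of_gene)
  motif_of_cluster <- unlist(truth$motif_of_cluster)
  motif_by_id <- stats::setNames(motifs, vapply(motifs, `[[`, "", "motif_id"))
  chars <- stats::setNames(as.character(genome), names(genome))
  occupied <- lapply(names(genome), function(x) cbind(integer(0), integer(0)))
  names(occupied) <- names(genome)
  planted <- list()
  for (i in seq_len(nrow(peaklets))) {
    gid <- peaklets$gene_id[i]
    if (is.na(gid) || cluster_of_gene[[gid]] == "null") next
    if (stats::runif(1) > config$motif_plant_rate) next
    motif <- motif_by_id[[motif_of_cluster[[cluster_of_gene[[gid]]]]]]
    L <- ncol(motif$counts)
    pk_w <- peaklets$end[i] - peaklets$start[i]
    if (L > pk_w) stop("planted motif longer than peaklet")
    ch <- peaklets$chrom[i]
    placed <- FALSE
    for (try in 1:20) {
      offset <- sample.int(pk_w - L + 1L, 1L) - 1L
      a <- peaklets$start[i] + offset
      b <- a + L - 1L
      occ <- occupied[[ch]]
      if (nrow(occ) && any(a <= occ[, 2] & b >= occ[, 1])) next
      strand <- sample(c("+", "-"), 1L)
      inst <- motif_consensus(motif)
      if (strand == "-") inst <- revcomp(inst)
      substr(chars[[ch]], a + 1L, b + 1L) <- inst
      occupied[[ch]] <- rbind(occ, c(a, b))
      planted[[length(planted) + 1L]] <- data.frame(
        peaklet_id = peaklets$peaklet_id[i], motif_id = motif$motif_id,
        offset = offset, strand = strand, stringsAsFactors = FALSE)
      placed <- TRUE
      break
    }
  }
  planted_hits <- if (length(planted)) do.call(rbind, planted) else
    data.frame(peaklet_id = character(), motif_id = character(),
               offset = integer(), strand = character(),
               stringsAsFactors = FALSE)
  genome_out <- Biostrings::DNAStringSet(chars)

  # differential accessibility: open at 2 dpi or closed at 12 dpi; the
  # cluster-1 TF's proximal peaklet is always an opening element, and TF
  # proximal peaklets are otherwise kept stable so the proximity ranking
  # has a unique planted answer
  tf_genes <- unlist(truth$tf_gene_of_cluster)
  tf_prox <- peaklets$peaklet_id[peaklets$kind == "proximal" &
                                 peaklets$gene_id %in% tf_genes]
  forced <- if (is.na(tf_genes[[1L]])) character(0) else
    peaklets$peaklet_id[peaklets$kind == "proximal" &
                        !is.na(peaklets$gene_id) &
                        peaklets$gene_id == tf_genes[[1L]]]
  n_da <- round(config$frac_da_peaklets * nrow(peaklets))
  candidates <- setdiff(peaklets$peaklet_id, tf_prox)
  extra_da <- if (n_da > length(forced)) {
    sort(sample(candidates, n_da - length(forced)))
  } else character(0)
  da_ids <- if (n_da == 0L) character(0) else c(forced, extra_da)
  da_dir <- character(0)
  da_tp <- integer(0)
  tp_sorted <- sort(config$timepoints)
  first_post <- tp_sorted[2L]  # first post-injury timepoint (2 dpi default)
  last_post <- tp_sorted[length(tp_sorted)]
  if (length(da_ids)) {
    open <- unique(c(forced, extra_da[seq_len(ceiling(length(extra_da) / 2))]))
    da_dir <- ifelse(da_ids %in% open, "open", "closed")
    da_tp <- ifelse(da_dir == "open", first_post, last_post)
  }
  da <- data.frame(peaklet_id = da_ids, direction = da_dir,
                   timepoint = da_tp, stringsAsFactors = FALSE)

  # per-peaklet, per-sample target counts, then reads drawn around summits
  tps <- config$timepoints
  samples <- data.frame(
    sample_id = sprintf("t%02d_r%d", rep(tps, each = config$replicates),
                        rep(seq_len(config$replicates), length(tps))),
    timepoint_dpi = rep(tps, each = config$replicates),
    replicate = rep(seq_len(config$replicates), length(tps)),
    stringsAsFactors = FALSE)
  base_mu <- stats::setNames(stats::rlnorm(nrow(peaklets), log(50), 0.4),
                             peaklets$peaklet_id)
  fold <- 2^config$de_log2fc
  size <- 1 / config$nb_dispersion
  read_len <- 50L
  reads <- list()
  for (s in seq_len(nrow(samples))) {
    tp <- samples$timepoint_dpi[s]
    mu <- base_mu
    if (nrow(da)) {
      open_ids <- da$peaklet_id[da$direction == "open" & da$timepoint == tp]
      closed_ids <- da$peaklet_id[da$direction == "closed" & da$timepoint == tp]
      mu[open_ids] <- mu[open_ids] * fold
      mu[closed_ids] <- mu[closed_ids] / fold
    }
    n_reads <- stats::rnbinom(nrow(peaklets), size = size, mu = mu)
    centers <- rep(peaklets$summit_pos, n_reads) +
      round(stats::rnorm(sum(n_reads), 0, 80))
    chroms <- rep(peaklets$chrom, n_reads)
    clens <- chrom_lengths[chroms]
    start <- pmax(0L, as.integer(centers - read_len %/% 2L))
    end <- pmin(as.integer(clens), start + read_len)
    reads[[samples$sample_id[s]]] <- data.frame(
      chrom = chroms, start = start, end = end,
      name = sprintf("rd_%s_%06d", samples$sample_id[s], seq_along(start)),
      score = 0L,
      strand = sample(c("+", "-"), length(start), replace = TRUE),
      stringsAsFactors = FALSE)
  }

  # true TF -> target edges: a cluster gene is a true target of its cluster's
  # TF iff at least one of its peaklets carries a planted instance
  gene_of_peaklet <- stats::setNames(peaklets$gene_id, peaklets$peaklet_id)
  edges <- list()
  for (k in seq_len(config$n_clusters)) {
    mk <- motif_of_cluster[[as.character(k)]]
    pk <- planted_hits$peaklet_id[planted_hits$motif_id == mk]
    targets <- sort(unique(gene_of_peaklet[pk]))
    targets <- targets[!is.na(targets)]
    if (length(targets)) {
      edges[[k]] <- data.frame(tf_gene_id = tf_genes[[as.character(k)]],
                               target_gene_id = targets,
                               stringsAsFactors = FALSE)
    }
  }
  true_edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(tf_gene_id = character(), target_gene_id = character(),
               stringsAsFactors = FALSE)
  rownames(true_edges) <- NULL

  list(summits = summits, peaklets = peaklets, reads = reads,
       samples = samples, genome = genome_out,
       truth = list(da_peaklets = da, planted_hits = planted_hits,
                    true_edges = true_edges,
                    gene_of_peaklet = as.list(gene_of_peaklet)))
}

#' Simulate a complete dataset
#'
#' Orchestrates genome/annotation, motif library, expression and
#' accessibility simulation, builds the TF catalog fixture (the designated
#' cluster regulators with their motifs, plus catalog entries without motifs
#' and non-differential decoys to exercise the selection filters), and
#' merges the ground-truth manifest.
#'
#' @param config "sim_config" object.
#' @return list(genome, genes, motifs, expression, accessibility,
#'   tf_catalog, truth).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ga <- simulate_genome_and_annotation(config)
  motifs <- simulate_motif_library(config)
  expr <- simulate_expression(ga$genes, config)
  acc <- simulate_accessibility(ga$genome, ga$genes, motifs, expr$truth,
                                config)

  cluster_of_gene <- unlist(expr$truth$cluster_of_gene)
  tf_genes <- unlist(expr$truth$tf_gene_of_cluster)
  motif_ids <- unlist(expr$truth$motif_of_cluster)
  catalog <- data.frame(
    gene_id = unname(tf_genes),
    family = sprintf("family%s", names(tf_genes)),
    motif_id = unname(motif_ids), stringsAsFactors = FALSE)
  # decoys: a differential gene with no motif, and a null gene carrying an
  # unplanted decoy motif (if the library has spares)
  de_pool <- setdiff(names(cluster_of_gene)[cluster_of_gene != "null"],
                     tf_genes)
  null_pool <- names(cluster_of_gene)[cluster_of_gene == "null"]
  if (length(de_pool)) {
    catalog <- rbind(catalog, data.frame(
      gene_id = min(de_pool), family = "family_nomotif",
      motif_id = NA_character_, stringsAsFactors = FALSE))
  }
  if (length(null_pool) && config$n_motifs > config$n_clusters) {
    catalog <- rbind(catalog, data.frame(
      gene_id = min(null_pool), family = "family_decoy",
      motif_id = sprintf("M%03d", config$n_clusters + 1L),
      stringsAsFactors = FALSE))
  }
  rownames(catalog) <- NULL

  truth <- c(expr$truth, acc$truth)
  list(genome = acc$genome, genes = ga$genes, motifs = motifs,
       expression = expr[c("counts", "effective_length", "samples")],
       accessibility = acc[c("summits", "peaklets", "reads", "samples")],
       tf_catalog = catalog, truth = truth)
}

#' Write the ground-truth manifest as JSON
#'
#' @param truth Truth list (from [simulate_dataset()] or the individual
#'   simulators).
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' Read a ground-truth manifest
#'
#' @param path Path written by [write_truth()].
#' @return Truth list; data.frame members are restored as data.frames.
#' @export
read_truth <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("da_peaklets", "planted_hits", "true_edges")) {
    if (!is.null(truth[[nm]])) truth[[nm]] <- as.data.frame(truth[[nm]])
  }
  truth
}
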