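# Regeneration-associated TF selection, per-cluster stage-specific motif
# enrichment, TF ranking by proximity to differentially accessible regions,
# motif-based TF -> target inference, and generic gene-set enrichment.

#' Select regeneration-associated transcription factors
#'
#' Cross-references the differential-expression results with a TF catalog:
#' a catalog TF is retained iff at least one of its transcripts passes the
#' global LRT at the configured FDR. Its peak cluster is the cluster of its
#' most significant transcript. Catalog TFs without a motif id are reported
#' separately (attribute "no_motif") and excluded from motif analyses.
#'
#' @param de_results [nb_differential()] output (transcript level).
#' @param tf_catalog data.frame(gene_id, family, motif_id) with NA motif_id
#'   allowed.
#' @param clustering "temporal_clustering" over (a subset of) transcripts.
#' @param tx2gene data.frame(transcript_id, gene_id).
#' @param fdr LRT FDR threshold (default 0.05).
#' @return data.frame of TF records (gene_id, family, motif_id,
#'   best_transcript, lrt_q, peak_cluster), class "tf_records", with the
#'   motif-less differential TFs in `attr(, "no_motif")`.
#' @export
select_regeneration_tfs <- function(de_results, tf_catalog, clustering,
                                    tx2gene, fdr = 0.05) {
  if (is.null(tf_catalog) || nrow(tf_catalog) == 0L) stop("empty TF catalog")
  stopifnot(all(c("gene_id", "family", "motif_id") %in% names(tf_catalog)))
  de <- merge(de_results, tx2gene, by.x = "feature_id",
              by.y = "transcript_id", all.x = TRUE)
  rows <- lapply(seq_len(nrow(tf_catalog)), function(i) {
    gid <- tf_catalog$gene_id[i]
    sub <- de[!is.na(de$gene_id) & de$gene_id == gid & !de$filtered, ,
              drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    best <- sub[which.min(sub$lrt_p), , drop = FALSE]
    if (is.na(best$lrt_q) || best$lrt_q >= fdr) return(NULL)
    cl <- clustering$assignment[best$feature_id]
    data.frame(gene_id = gid, family = tf_catalog$family[i],
               motif_id = tf_catalog$motif_id[i],
               best_transcript = best$feature_id,
               lrt_q = best$lrt_q,
               peak_cluster = if (is.na(cl)) NA_integer_ else as.integer(cl),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(gene_id = character(), family = character(),
                      motif_id = character(), best_transcript = character(),
                      lrt_q = numeric(), peak_cluster = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  no_motif <- res[is.na(res$motif_id), , drop = FALSE]
  res <- res[!is.na(res$motif_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "no_motif") <- no_motif
  class(res) <- c("tf_records", "data.frame")
  res
}

# Internal: map each gene to the recovered cluster of its first clustered
# transcript (NA when none of its transcripts were clustered).
gene_cluster_map <- function(clustering, tx2gene) {
  cl <- clustering$assignment
  tx <- tx2gene[tx2gene$transcript_id %in% names(cl), , drop = FALSE]
  tx <- tx[order(tx$transcript_id), , drop = FALSE]
  tapply(cl[tx$transcript_id], tx$gene_id, function(x) x[1L])
}

#' Per-cluster stage-specific motif enrichment
#'
#' For each temporal cluster and compartment (proximal / distal), the
#' foreground is that compartment's peaklets annotated to the cluster's
#' genes; the background is every other proximal-or-distal peaklet. Each of
#' the cluster's temporally matched TF motifs is tested with
#' [motif_enrichment()], and the count of hit-bearing foreground peaklets
#' is reported per motif per compartment.
#'
#' @param clustering "temporal_clustering".
#' @param annotations [annotate_peaklets()] output.
#' @param hit_matrix "hit_matrix".
#' @param tfs "tf_records" from [select_regeneration_tfs()].
#' @param tx2gene data.frame(transcript_id, gene_id).
#' @param fdr Enrichment FDR (default 0.05).
#' @return data.frame(cluster, motif_id, compartment, foreground_size,
#'   foreground_hits, odds_ratio, p, q, enriched).
#' @export
cluster_stage_enrichment <- function(clustering, annotations, hit_matrix,
                                     tfs, tx2gene, fdr = 0.05) {
  gene_cl <- gene_cluster_map(clustering, tx2gene)
  universe <- annotations$peaklet_id[
    annotations$location_class %in% c("proximal", "distal")]
  out <- list()
  for (k in sort(unique(tfs$peak_cluster))) {
    if (is.na(k)) next
    cl_genes <- names(gene_cl)[!is.na(gene_cl) & gene_cl == k]
    motifs_k <- unique(tfs$motif_id[!is.na(tfs$peak_cluster) &
                                    tfs$peak_cluster == k])
    if (length(motifs_k) == 0L) next
    cluster_pk <- annotations$peaklet_id[
      !is.na(annotations$nearest_gene) &
      annotations$nearest_gene %in% cl_genes &
      annotations$location_class %in% c("proximal", "distal")]
    if (length(cluster_pk) == 0L) {
      warning("cluster ", k, " has no annotated peaklets")
      next
    }
    for (comp in c("proximal", "distal")) {
      fg <- annotations$peaklet_id[
        annotations$peaklet_id %in% cluster_pk &
        annotations$location_class == comp]
      if (length(fg) == 0L) next
      bg <- setdiff(universe, fg)
      enr <- motif_enrichment(fg, bg, hit_matrix, fdr = fdr)
      enr <- enr[enr$motif_id %in% motifs_k, , drop = FALSE]
      if (nrow(enr) == 0L) next
      enr$q <- bh_adjust(enr$p)  # BH within the cluster's queried motifs
      enr$enriched <- enr$q < fdr
      out[[length(out) + 1L]] <- data.frame(
        cluster = k, motif_id = enr$motif_id, compartment = comp,
        foreground_size = enr$foreground_size,
        foreground_hits = enr$foreground_hits,
        odds_ratio = enr$odds_ratio, p = enr$p, q = enr$q,
        enriched = enr$enriched, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(cluster = integer(), motif_id = character(),
                      compartment = character(), foreground_size = integer(),
                      foreground_hits = integer(), odds_ratio = numeric(),
                      p = numeric(), q = numeric(), enriched = logical(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rank TFs by proximity to differentially accessible peaklets
#'
#' For each TF gene, the minimum |TSS - DA peaklet center| on its
#' chromosome (infinity when no DA peaklet shares the chromosome), sorted
#' ascending. TFs within `flag_bp` of a DA peaklet are flagged, and the DA
#' peaklets within that window are listed as flanking elements.
#'
#' @param tfs "tf_records".
#' @param da_results [differential_accessibility()] output.
#' @param peaklets "peaklet_set".
#' @param gm "gene_models".
#' @param flag_bp Flagging window (default 1e5).
#' @return data.frame(gene_id, min_distance, n_flanking, flanking_da_peaklets
#'   (comma-joined ids), within_window), sorted by min_distance.
#' @export
rank_tfs_by_da_proximity <- function(tfs, da_results, peaklets, gm,
                                     flag_bp = 1e5) {
  da_ids <- da_results$feature_id[da_results$da]
  da_pk <- peaklets[peaklets$peaklet_id %in% da_ids, , drop = FALSE]
  centers <- (da_pk$start + da_pk$end) %/% 2L
  genes <- gm$genes
  rows <- lapply(tfs$gene_id, function(gid) {
    gi <- match(gid, genes$gene_id)
    if (is.na(gi)) stop("TF gene absent from gene models: ", gid)
    sel <- da_pk$chrom == genes$chrom[gi]
    if (!any(sel)) {
      return(data.frame(gene_id = gid, min_distance = Inf, n_flanking = 0L,
                        flanking_da_peaklets = "", within_window = FALSE,
                        stringsAsFactors = FALSE))
    }
    d <- abs(centers[sel] - genes$tss[gi])
    flank <- da_pk$peaklet_id[sel][d <= flag_bp]
    data.frame(gene_id = gid, min_distance = min(d),
               n_flanking = length(flank),
               flanking_da_peaklets = paste(sort(flank), collapse = ","),
               within_window = min(d) <= flag_bp, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$min_distance, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Infer TF target genes from motif hits in annotated peaklets
#'
#' A gene is a putative target of a TF iff (a) at least one proximal or
#' distal peaklet annotated to the gene carries a hit of the TF's motif,
#' and (b) the gene is differentially expressed with a recovered temporal
#' cluster compatible with the TF's peak cluster. "Compatible" defaults to
#' the same cluster; "same_or_adjacent" and "same_or_later" widen the rule.
#' Every edge records its evidence peaklets and hit coordinates.
#'
#' @param tf A single row of a "tf_records" data.frame (must carry a motif).
#' @param clustering "temporal_clustering".
#' @param annotations [annotate_peaklets()] output.
#' @param hit_matrix "hit_matrix" (hit coordinates are taken from `$hits`).
#' @param tx2gene data.frame(transcript_id, gene_id).
#' @param compat Temporal compatibility rule (default "same").
#' @return list(edges = data.frame(tf_gene_id, target_gene_id, n_evidence),
#'   evidence = data.frame(tf_gene_id, target_gene_id, peaklet_id,
#'   location_class, offset, strand)).
#' @export
infer_tf_targets <- function(tf, clustering, annotations, hit_matrix,
                             tx2gene,
                             compat = c("same", "same_or_adjacent",
                                        "same_or_later")) {
  compat <- match.arg(compat)
  if (nrow(tf) != 1L) stop("pass a single TF record")
  if (is.na(tf$motif_id)) stop("TF has no motif id")
  if (is.na(tf$peak_cluster)) stop("TF has no peak cluster")
  K <- clustering$K
  k <- tf$peak_cluster
  ok_clusters <- switch(compat,
    same = k,
    same_or_adjacent = intersect((k - 1L):(k + 1L), seq_len(K)),
    same_or_later = k:K)
  gene_cl <- gene_cluster_map(clustering, tx2gene)
  ok_genes <- names(gene_cl)[!is.na(gene_cl) & gene_cl %in% ok_clusters]

  hits <- hit_matrix$hits
  hits <- hits[hits$motif_id == tf$motif_id, , drop = FALSE]
  ann <- annotations[annotations$location_class %in% c("proximal", "distal") &
                     !is.na(annotations$nearest_gene) &
                     annotations$nearest_gene %in% ok_genes, , drop = FALSE]
  ev <- merge(hits, ann[c("peaklet_id", "location_class", "nearest_gene")],
              by = "peaklet_id")
  if (nrow(ev) == 0L) {
    return(list(
      edges = data.frame(tf_gene_id = character(),
                         target_gene_id = character(), n_evidence = integer(),
                         stringsAsFactors = FALSE),
      evidence = data.frame(tf_gene_id = character(),
                            target_gene_id = character(),
                            peaklet_id = character(),
                            location_class = character(), offset = integer(),
                            strand = character(), stringsAsFactors = FALSE)))
  }
  evidence <- data.frame(tf_gene_id = tf$gene_id,
                         target_gene_id = ev$nearest_gene,
                         peaklet_id = ev$peaklet_id,
                         location_class = ev$location_class,
                         offset = ev$offset, strand = ev$strand,
                         stringsAsFactors = FALSE)
  evidence <- evidence[order(evidence$target_gene_id, evidence$peaklet_id,
                             evidence$offset), , drop = FALSE]
  rownames(evidence) <- NULL
  tab <- table(evidence$target_gene_id)
  edges <- data.frame(tf_gene_id = tf$gene_id,
                      target_gene_id = names(tab),
                      n_evidence = as.integer(tab), stringsAsFactors = FALSE)
  edges <- edges[order(edges$target_gene_id), , drop = FALSE]
  rownames(edges) <- NULL
  list(edges = edges, evidence = evidence)
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric p per set (the probability of at least the
#' observed overlap between the target list and the set, both restricted to
#' the universe), BH-adjusted across sets.
#'
#' @param target_genes Character vector of genes of interest.
#' @param genesets Named list of gene-id vectors.
#' @param universe Character vector of all eligible genes.
#' @param fdr Enrichment threshold (default 0.05).
#' @return data.frame(set_id, overlap, set_size, n_targets, universe_size,
#'   p, q, enriched).
#' @export
geneset_enrichment <- function(target_genes, genesets, universe, fdr = 0.05) {
  stopifnot(is.list(genesets), !is.null(names(genesets)))
  if (any(lengths(genesets) > length(universe))) {
    stop("universe smaller than a gene set")
  }
  targets <- intersect(unique(target_genes), universe)
  rows <- lapply(names(genesets), function(sid) {
    s <- intersect(unique(genesets[[sid]]), universe)
    k <- length(intersect(targets, s))
    p <- stats::phyper(k - 1, length(s), length(universe) - length(s),
                       length(targets), lower.tail = FALSE)
    data.frame(set_id = sid, overlap = k, set_size = length(s),
               n_targets = length(targets),
               universe_size = length(universe), p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- bh_adjust(res$p)
  res$enriched <- res$q < fdr
  rownames(res) <- NULL
  res
}
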