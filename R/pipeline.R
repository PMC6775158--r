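# End-to-end orchestration: simulate -> expression -> atac -> motifs ->
# network, writing every stage's tables plus a JSON run manifest. The run is
# a pure function of (config, seed): rerunning with the same config yields
# byte-identical outputs.

#' Pipeline configuration
#'
#' Bundles the simulation config with every analysis threshold the
#' workflow exposes: summit retention p-value cut (1e-10), peaklet width
#' (500 bp), proximal/distal TSS windows (1 kb / 100 kb), exon-overlap
#' exclusion (50 bp), expression and accessibility FDR (0.05 each), motif
#' hit threshold (0.8 of the maximum PWM score), and K = 7 temporal
#' clusters.
#'
#' @param sim "sim_config" (default [sim_config()]); its seed drives every
#'   stochastic stage.
#' @param de_fdr,da_fdr,enrich_fdr FDR thresholds (defaults 0.05).
#' @param peak_pcut Summit retention threshold (default 1e-10).
#' @param peaklet_width Peaklet width, bp (default 500).
#' @param proximal_bp,distal_bp TSS windows, bp (defaults 1000 and 1e5).
#' @param exon_overlap_bp Exon-overlap exclusion, bp (default 50).
#' @param motif_threshold Fraction of the maximum PWM score (default 0.8).
#' @param K Number of temporal clusters (default 7).
#' @param kmeans_restarts K-means restarts (default 100).
#' @param compat TF-target temporal compatibility rule (default "same").
#' @return Class "pipeline_config" list.
#' @export
pipeline_config <- function(sim = sim_config(), de_fdr = 0.05, da_fdr = 0.05,
                            enrich_fdr = 0.05, peak_pcut = 1e-10,
                            peaklet_width = 500, proximal_bp = 1000,
                            distal_bp = 1e5, exon_overlap_bp = 50,
                            motif_threshold = 0.8, K = 7,
                            kmeans_restarts = 100, compat = "same") {
  stopifnot(inherits(sim, "sim_config"))
  if (proximal_bp >= distal_bp) stop("proximal_bp must be < distal_bp")
  if (any(c(de_fdr, da_fdr, enrich_fdr, peak_pcut, peaklet_width,
            proximal_bp, distal_bp, motif_threshold) <= 0)) {
    stop("thresholds must be positive")
  }
  sim$peaklet_width <- as.integer(peaklet_width)
  structure(list(sim = sim, de_fdr = de_fdr, da_fdr = da_fdr,
                 enrich_fdr = enrich_fdr, peak_pcut = peak_pcut,
                 peaklet_width = as.integer(peaklet_width),
                 proximal_bp = proximal_bp, distal_bp = distal_bp,
                 exon_overlap_bp = exon_overlap_bp,
                 motif_threshold = motif_threshold, K = as.integer(K),
                 kmeans_restarts = as.integer(kmeans_restarts),
                 compat = compat, seed = sim$seed),
            class = "pipeline_config")
}

# Internal: run a stage, aborting with the stage name on error.
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis end-to-end on simulated data
#'
#' Stages: simulate -> expression (TPM, NB differential testing vs 0 dpi,
#' Z-scores, K-means) -> atac (peaklets, overlap counts, differential
#' accessibility, annotation) -> motifs (PWMs, hit matrix, per-cluster
#' enrichment, co-occurrence) -> network (TF selection, DA proximity
#' ranking, TF -> target edges). Writes every stage's tables under
#' `out_dir` and returns (and writes) a run manifest with summary counts.
#'
#' @param config "pipeline_config" object.
#' @param out_dir Output directory (created if missing).
#' @param write_reads Also write the per-sample simulated read BEDs
#'   (large; default FALSE).
#' @return The run manifest list, invisibly also written as manifest.json.
#' @export
run_all <- function(config, out_dir, write_reads = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(out_dir, f)

  ds <- with_stage("simulate", simulate_dataset(config$sim))

  expr_res <- with_stage("expression", {
    counts <- ds$expression$counts
    samples <- ds$expression$samples
    tpm <- compute_tpm(counts, ds$expression$effective_length)
    de <- nb_differential(counts, samples)
    de_ids <- de$feature_id[!de$filtered & !is.na(de$lrt_q) &
                            de$lrt_q < config$de_fdr]
    if (length(de_ids) < config$K) {
      stop("fewer differential transcripts than clusters")
    }
    z <- log_zscore(tpm, transcripts = de_ids)
    cl <- kmeans_temporal(z, K = config$K, seed = config$seed,
                          n_restarts = config$kmeans_restarts)
    write_table(de, path("de_results.tsv"), "tsv")
    zs <- data.frame(transcript_id = rownames(z$z), z$z,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_table(zs, path("zscores.tsv"), "tsv")
    write_table(data.frame(transcript_id = names(cl$assignment),
                           cluster = as.integer(cl$assignment),
                           stringsAsFactors = FALSE),
                path("clusters.tsv"), "tsv")
    list(de = de, de_ids = de_ids, z = z, clustering = cl, tpm = tpm)
  })

  atac_res <- with_stage("atac", {
    chrom_lengths <- stats::setNames(Biostrings::width(ds$genome),
                                     names(ds$genome))
    peaklets <- build_peaklets(ds$accessibility$summits, chrom_lengths,
                               width = config$peaklet_width,
                               p_cut = config$peak_pcut)
    acc <- count_read_overlaps(ds$accessibility$reads, peaklets)
    da <- differential_accessibility(acc, ds$accessibility$samples,
                                     fdr = config$da_fdr)
    ann <- annotate_peaklets(peaklets, ds$genes,
                             proximal_bp = config$proximal_bp,
                             distal_bp = config$distal_bp,
                             exon_overlap_bp = config$exon_overlap_bp)
    write_table(data.frame(chrom = peaklets$chrom, start = peaklets$start,
                           end = peaklets$end, name = peaklets$peaklet_id,
                           score = 0L, strand = ".",
                           stringsAsFactors = FALSE),
                path("peaklets.bed"), "bed")
    write_table(ann, path("peaklet_annotation.tsv"), "tsv")
    write_table(da, path("da_results.tsv"), "tsv")
    write_table(genomic_distribution(ann), path("genomic_distribution.tsv"),
                "tsv")
    if (write_reads) {
      for (s in names(ds$accessibility$reads)) {
        write_table(ds$accessibility$reads[[s]],
                    path(sprintf("reads_%s.bed", s)), "bed")
      }
    }
    list(peaklets = peaklets, acc = acc, da = da, ann = ann)
  })

  motif_res <- with_stage("motifs", {
    if (is.null(ds$genome)) stop("missing genome")
    bg <- peaklet_background(atac_res$peaklets, ds$genome)
    pwms <- lapply(ds$motifs, pfm_to_pwm, background = bg)
    hm <- build_hit_matrix(atac_res$peaklets, ds$genome, pwms,
                           threshold_fraction = config$motif_threshold)
    write_table(hm$hits, path("motif_hits.tsv"), "tsv")
    list(pwms = pwms, hm = hm, background = bg)
  })

  net_res <- with_stage("network", {
    tx2gene <- ds$genes$transcripts
    tfs <- select_regeneration_tfs(expr_res$de, ds$tf_catalog,
                                   expr_res$clustering, tx2gene,
                                   fdr = config$de_fdr)
    stage_enr <- cluster_stage_enrichment(expr_res$clustering, atac_res$ann,
                                          motif_res$hm, tfs, tx2gene,
                                          fdr = config$enrich_fdr)
    enriched_motifs <- unique(stage_enr$motif_id[stage_enr$enriched])
    cooc <- if (length(enriched_motifs) >= 2L) {
      cooccurrence_network(motif_res$hm, motifs = sort(enriched_motifs))
    } else {
      cooccurrence_network(motif_res$hm, motifs = sort(unique(tfs$motif_id)))
    }
    prox <- rank_tfs_by_da_proximity(tfs, atac_res$da, atac_res$peaklets,
                                     ds$genes, flag_bp = config$distal_bp)
    edges <- list(); evidence <- list()
    for (i in seq_len(nrow(tfs))) {
      if (is.na(tfs$peak_cluster[i])) next
      tgt <- infer_tf_targets(tfs[i, , drop = FALSE], expr_res$clustering,
                              atac_res$ann, motif_res$hm, tx2gene,
                              compat = config$compat)
      edges[[length(edges) + 1L]] <- tgt$edges
      evidence[[length(evidence) + 1L]] <- tgt$evidence
    }
    empty_edges <- data.frame(tf_gene_id = character(),
                              target_gene_id = character(),
                              n_evidence = integer(), stringsAsFactors = FALSE)
    edges <- if (length(edges)) do.call(rbind, edges) else empty_edges
    evidence <- if (length(evidence)) do.call(rbind, evidence) else
      data.frame()
    write_table(as.data.frame(tfs), path("tf_records.tsv"), "tsv")
    write_table(stage_enr, path("stage_enrichment.tsv"), "tsv")
    write_table(cooc, path("cooccurrence.tsv"), "tsv")
    prox_out <- prox
    prox_out$min_distance <- ifelse(is.finite(prox_out$min_distance),
                                    prox_out$min_distance, NA)
    write_table(prox_out, path("tf_da_proximity.tsv"), "tsv")
    write_table(edges, path("tf_target_edges.tsv"), "tsv")
    if (nrow(evidence)) write_table(evidence, path("tf_target_evidence.tsv"),
                                    "tsv")
    list(tfs = tfs, stage_enr = stage_enr, cooc = cooc, prox = prox,
         edges = edges, evidence = evidence)
  })

  write_truth(ds$truth, path("truth.json"))
  manifest <- list(
    package = "regenGRN",
    version = as.character(utils::packageVersion("regenGRN")),
    seed = config$seed,
    thresholds = config[c("de_fdr", "da_fdr", "enrich_fdr", "peak_pcut",
                          "peaklet_width", "proximal_bp", "distal_bp",
                          "exon_overlap_bp", "motif_threshold", "K")],
    counts = list(
      n_transcripts = nrow(expr_res$de),
      n_de_transcripts = length(expr_res$de_ids),
      n_clustered = length(expr_res$clustering$assignment),
      n_peaklets = nrow(atac_res$peaklets),
      n_da_peaklets = sum(atac_res$da$da),
      n_tfs = nrow(net_res$tfs),
      n_edges = nrow(net_res$edges)),
    outputs = sort(list.files(out_dir)))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(manifest, list(data = ds, expression = expr_res,
                             atac = atac_res, motifs = motif_res,
                             network = net_res)))
}
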