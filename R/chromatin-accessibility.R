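# Accessible-chromatin peaklets: fixed-width intervals around retained peak
# summits, read-overlap quantification, differential accessibility against
# the uninjured baseline, and annotation relative to gene models.

#' Build fixed-width peaklets from peak summits
#'
#' Summits with `p_value >= p_cut` are dropped (the retention rule keeps
#' p < 1e-10 by default). Each retained summit at position s yields the
#' interval \[s - width/2, s + width/2) clipped to the chromosome; clipped
#' peaklets are flagged. Overlapping peaklets are kept as distinct entries
#' (no merging). Ids are assigned deterministically in (chrom, pos) sort
#' order. Extra columns of `summits` are carried through.
#'
#' @param summits data.frame(chrom, pos, p_value) of 0-based summit positions.
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param width Peaklet width in bp, even (default 500).
#' @param p_cut Summit retention threshold (default 1e-10).
#' @return data.frame of class "peaklet_set": peaklet_id, chrom, start, end,
#'   summit_pos, summit_p, clipped, plus any extra summit columns.
#' @export
build_peaklets <- function(summits, chrom_lengths, width = 500, p_cut = 1e-10) {
  stopifnot(all(c("chrom", "pos", "p_value") %in% names(summits)))
  if (width %% 2 != 0) stop("peaklet width must be even")
  if (!all(summits$chrom %in% names(chrom_lengths))) {
    stop("summit on unknown chromosome")
  }
  if (any(summits$pos < 0 | summits$pos >= chrom_lengths[summits$chrom])) {
    stop("summit position outside its chromosome")
  }
  keep <- summits$p_value < p_cut
  s <- summits[keep, , drop = FALSE]
  s <- s[order(s$chrom, s$pos), , drop = FALSE]
  half <- width %/% 2
  start <- pmax(0L, as.integer(s$pos - half))
  end <- pmin(as.integer(chrom_lengths[s$chrom]), as.integer(s$pos + half))
  out <- data.frame(
    peaklet_id = sprintf("pk%06d", seq_len(nrow(s))),
    chrom = s$chrom, start = start, end = end,
    summit_pos = s$pos, summit_p = s$p_value,
    clipped = (end - start) != width,
    stringsAsFactors = FALSE)
  extra <- setdiff(names(s), c("chrom", "pos", "p_value"))
  for (col in extra) out[[col]] <- s[[col]]
  rownames(out) <- NULL
  class(out) <- c("peaklet_set", "data.frame")
  out
}

#' Count read overlaps per peaklet and sample
#'
#' A read counts toward a peaklet iff the two half-open intervals overlap by
#' at least 1 bp; a read spanning two peaklets is counted in both (fixed
#' windows are quantified independently).
#'
#' @param reads_by_sample Named list (one element per sample) of BED-style
#'   data.frames with chrom/start/end columns ([read_bed()] output).
#' @param peaklets "peaklet_set" from [build_peaklets()].
#' @return Integer matrix peaklets x samples, rownames = peaklet ids.
#' @export
count_read_overlaps <- function(reads_by_sample, peaklets) {
  stopifnot(is.list(reads_by_sample), !is.null(names(reads_by_sample)))
  pk_gr <- intervals_to_granges(peaklets[c("chrom", "start", "end")])
  counts <- vapply(reads_by_sample, function(reads) {
    rd_gr <- intervals_to_granges(reads[c("chrom", "start", "end")])
    GenomicRanges::countOverlaps(pk_gr, rd_gr, minoverlap = 1L,
                                 ignore.strand = TRUE)
  }, integer(nrow(peaklets)))
  if (nrow(peaklets) == 1L) counts <- matrix(counts, nrow = 1L,
                                             dimnames = list(NULL, names(reads_by_sample)))
  rownames(counts) <- peaklets$peaklet_id
  counts
}

#' Differential accessibility against the baseline timepoint
#'
#' Delegates to [nb_differential()] with the same per-timepoint contrasts as
#' the expression analysis. A peaklet is differentially accessible if any
#' contrast has q < `fdr`; the direction at a significant contrast is the
#' sign of its log2 fold change ("open" when positive, "closed" when
#' negative).
#'
#' @param acc_counts Peaklet x sample count matrix ([count_read_overlaps()]).
#' @param samples Sample table.
#' @param ref_timepoint Baseline timepoint (default 0).
#' @param fdr Per-contrast FDR threshold (default 0.05).
#' @param min_total Total-count filter passed to [nb_differential()].
#' @return data.frame: nb_differential columns plus, per timepoint t,
#'   `sig_t` and `direction_t` ("open"/"closed"/NA), and `da` (any contrast
#'   significant), `da_timepoints` (comma-joined).
#' @export
differential_accessibility <- function(acc_counts, samples, ref_timepoint = 0,
                                       fdr = 0.05, min_total = 10) {
  res <- nb_differential(acc_counts, samples, ref_timepoint = ref_timepoint,
                         min_total = min_total)
  tps <- setdiff(sort(unique(samples$timepoint_dpi)), ref_timepoint)
  sig_any <- rep(FALSE, nrow(res))
  da_tp <- rep("", nrow(res))
  for (t in as.character(tps)) {
    sig <- !is.na(res[[paste0("q_", t)]]) & res[[paste0("q_", t)]] < fdr
    dirn <- ifelse(sig,
                   ifelse(res[[paste0("log2fc_", t)]] > 0, "open", "closed"),
                   NA_character_)
    res[[paste0("sig_", t)]] <- sig
    res[[paste0("direction_", t)]] <- dirn
    da_tp <- ifelse(sig, ifelse(nzchar(da_tp), paste(da_tp, t, sep = ","), t),
                    da_tp)
    sig_any <- sig_any | sig
  }
  res$da <- sig_any
  res$da_timepoints <- da_tp
  res
}

#' Annotate peaklets relative to gene models
#'
#' The TSS distance of a peaklet is the minimum over genes of
#' |peaklet center - TSS| (unstranded absolute distance, center-based rule).
#' Location class: "proximal" if the distance is <= `proximal_bp`, "distal"
#' if in (`proximal_bp`, `distal_bp`), otherwise "unassigned". Peaklets
#' overlapping any single exon by more than `exon_overlap_bp` are excluded
#' from the proximal/distal assignment (location "unassigned", reason
#' "exonic_overlap") but still receive a genic class. Genic class is
#' assigned by precedence 5'UTR > exon > intron > intergenic on any (>= 1 bp)
#' overlap, where "intron" means overlapping a gene body without overlapping
#' its exons or 5'UTRs. Nearest-TSS ties break lexicographically by gene id.
#'
#' @param peaklets "peaklet_set" data.frame.
#' @param gm "gene_models" object.
#' @param proximal_bp Proximal window around a TSS (default 1000).
#' @param distal_bp Outer limit of the distal window (default 100000).
#' @param exon_overlap_bp Exon-overlap exclusion threshold (default 50).
#' @param rule "center" (default) measures the TSS distance from the peaklet
#'   center; "any" uses the distance from the nearest peaklet edge (0 when
#'   the interval covers the TSS).
#' @return data.frame: peaklet_id, location_class, genic_class, nearest_gene,
#'   tss_distance, exon_overlap (max single-exon overlap, bp), reason.
#' @export
annotate_peaklets <- function(peaklets, gm, proximal_bp = 1000,
                              distal_bp = 100000, exon_overlap_bp = 50,
                              rule = c("center", "any")) {
  rule <- match.arg(rule)
  stopifnot(inherits(gm, "gene_models"))
  n <- nrow(peaklets)
  center <- (peaklets$start + peaklets$end) %/% 2L

  genes <- gm$genes[order(gm$genes$gene_id), , drop = FALSE]
  nearest_gene <- rep(NA_character_, n)
  tss_distance <- rep(Inf, n)
  for (ch in unique(peaklets$chrom)) {
    pi <- which(peaklets$chrom == ch)
    gsel <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(gsel) == 0L) next
    if (rule == "center") {
      d <- abs(outer(center[pi], gsel$tss, "-"))
    } else {
      # distance from interval to TSS: 0 if covered, else gap to nearest edge
      lo <- outer(peaklets$start[pi], gsel$tss, function(s, t) t - s)
      hi <- outer(peaklets$end[pi] - 1L, gsel$tss, function(e, t) t - e)
      d <- pmax(hi, -lo, 0)
    }
    j <- max.col(-d, ties.method = "first")  # gsel sorted by gene_id
    nearest_gene[pi] <- gsel$gene_id[j]
    tss_distance[pi] <- d[cbind(seq_along(pi), j)]
  }

  pk_gr <- intervals_to_granges(peaklets[c("chrom", "start", "end")])
  max_overlap <- function(feat) {
    out <- rep(0L, n)
    if (nrow(feat) == 0L) return(out)
    f_gr <- intervals_to_granges(feat[c("chrom", "start", "end")])
    hits <- GenomicRanges::findOverlaps(pk_gr, f_gr, ignore.strand = TRUE)
    if (length(hits) == 0L) return(out)
    ov <- GenomicRanges::width(GenomicRanges::pintersect(
      pk_gr[S4Vectors::queryHits(hits)], f_gr[S4Vectors::subjectHits(hits)]))
    agg <- tapply(ov, S4Vectors::queryHits(hits), max)
    out[as.integer(names(agg))] <- as.integer(agg)
    out
  }
  exon_ov <- max_overlap(gm$exons)
  utr_ov <- max_overlap(gm$utr5)
  body_ov <- max_overlap(gm$genes)

  genic_class <- ifelse(utr_ov > 0L, "utr5",
                 ifelse(exon_ov > 0L, "exon",
                 ifelse(body_ov > 0L, "intron", "intergenic")))

  exonic_excluded <- exon_ov > exon_overlap_bp
  location_class <- ifelse(exonic_excluded, "unassigned",
                    ifelse(tss_distance <= proximal_bp, "proximal",
                    ifelse(tss_distance < distal_bp, "distal", "unassigned")))
  reason <- ifelse(exonic_excluded, "exonic_overlap",
            ifelse(location_class == "unassigned", "distance", ""))

  data.frame(peaklet_id = peaklets$peaklet_id,
             location_class = location_class,
             genic_class = genic_class,
             nearest_gene = nearest_gene,
             tss_distance = ifelse(is.finite(tss_distance), tss_distance, NA),
             exon_overlap = exon_ov,
             reason = reason,
             stringsAsFactors = FALSE)
}

#' Genomic distribution of annotated peaklets
#'
#' Tallies the fraction of peaklets per genic class and per location class;
#' fractions sum to 1 within each axis.
#'
#' @param annotations Output of [annotate_peaklets()].
#' @return data.frame(axis, class, n, fraction).
#' @export
genomic_distribution <- function(annotations) {
  if (nrow(annotations) == 0L) stop("no annotations to summarize")
  one_axis <- function(axis, values, levels) {
    tab <- table(factor(values, levels = levels))
    data.frame(axis = axis, class = names(tab), n = as.integer(tab),
               fraction = as.numeric(tab) / length(values),
               stringsAsFactors = FALSE)
  }
  rbind(
    one_axis("genic", annotations$genic_class,
             c("utr5", "exon", "intron", "intergenic")),
    one_axis("location", annotations$location_class,
             c("proximal", "distal", "unassigned")))
}
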