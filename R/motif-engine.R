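# PWM construction and scanning, per-set motif enrichment by one-sided
# Fisher exact tests, and motif co-occurrence networks over peaklets.

#' Convert a position frequency matrix to a log-odds PWM
#'
#' `log_odds[b, j] = log2((counts[b, j] + pseudocount * background[b]) /
#' (colsum_j + pseudocount) / background[b])`. The pseudocount is split
#' across bases proportionally to the background so columns stay proper
#' probabilities.
#'
#' @param pfm Motif matrix list(motif_id, tf_name, counts) with 4 x L counts
#'   (rows A,C,G,T), as returned by [read_jaspar()].
#' @param background Length-4 base composition (A,C,G,T), summing to 1.
#' @param pseudocount Positive smoothing mass (default 1). A pseudocount of
#'   0 combined with a zero count would give -Inf log odds and is an error.
#' @return Class "pwm": list(motif_id, tf_name, log_odds, background,
#'   pseudocount, max_score, length).
#' @export
pfm_to_pwm <- function(pfm, background = rep(0.25, 4), pseudocount = 1) {
  counts <- pfm$counts
  stopifnot(is.matrix(counts), nrow(counts) == 4L)
  if (is.null(rownames(counts))) rownames(counts) <- DNA_BASES
  counts <- counts[DNA_BASES, , drop = FALSE]
  if (length(background) != 4L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-6) {
    stop("background must be 4 positive probabilities summing to 1")
  }
  if (any(colSums(counts) <= 0)) stop("zero-sum PFM column")
  if (pseudocount <= 0 && any(counts == 0)) {
    stop("pseudocount 0 with zero counts gives -Inf log odds")
  }
  background <- stats::setNames(as.numeric(background), DNA_BASES)
  freq <- sweep(counts + pseudocount * background, 2L,
                colSums(counts) + pseudocount, "/")
  lo <- log2(freq / background)
  structure(list(motif_id = pfm$motif_id, tf_name = pfm$tf_name,
                 log_odds = lo, background = background,
                 pseudocount = pseudocount,
                 max_score = sum(apply(lo, 2L, max)),
                 length = ncol(lo)),
            class = "pwm")
}

# Internal: PWM for the reverse complement (reversed columns, swapped
# complementary rows). Same max_score as the forward PWM.
revcomp_pwm_matrix <- function(lo) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- lo[comp[rownames(lo)], rev(seq_len(ncol(lo))), drop = FALSE]
  rownames(rc) <- rownames(lo)
  rc
}

# Internal: score every window of an integer-encoded sequence (1..4, NA for
# N) against a 4 x L log-odds matrix. Windows containing N score -Inf.
score_windows <- function(enc, lo) {
  L <- ncol(lo)
  nw <- length(enc) - L + 1L
  if (nw < 1L) return(numeric(0))
  scores <- numeric(nw)
  for (j in seq_len(L)) {
    scores <- scores + lo[, j][enc[j:(j + nw - 1L)]]
  }
  scores[is.na(scores)] <- -Inf
  scores
}

#' Scan a sequence with a PWM on both strands
#'
#' Windows are scored as the column-wise sum of log-odds; a window is a hit
#' when its score reaches `threshold_fraction` of the PWM's maximum
#' achievable score. The minus strand is scanned by scoring the reverse
#' -complement PWM on the forward sequence, so all offsets are 0-based
#' positions of the window start on the forward coordinate system. Windows
#' containing N never match. A sequence shorter than the motif yields an
#' empty result.
#'
#' @param pwm "pwm" object from [pfm_to_pwm()].
#' @param seq Character scalar or DNAString over \{A,C,G,T,N\}.
#' @param threshold_fraction Fraction of the maximum score (default 0.8).
#' @return data.frame(offset, strand, score), one row per hit.
#' @export
scan_sequence <- function(pwm, seq, threshold_fraction = 0.8) {
  stopifnot(inherits(pwm, "pwm"))
  seq <- toupper(as.character(seq))
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- !(chars %in% DNA_ALPHABET)
  if (any(bad)) stop("sequence letter outside {A,C,G,T,N}: ", chars[bad][1L])
  enc <- match(chars, DNA_BASES)  # N -> NA
  threshold <- threshold_fraction * pwm$max_score
  hits <- list()
  fwd <- score_windows(enc, pwm$log_odds)
  rev <- score_windows(enc, revcomp_pwm_matrix(pwm$log_odds))
  for (strand in c("+", "-")) {
    sc <- if (strand == "+") fwd else rev
    idx <- which(sc >= threshold)
    if (length(idx)) {
      hits[[strand]] <- data.frame(offset = idx - 1L, strand = strand,
                                   score = sc[idx], stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(offset = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Estimate background base composition from peaklet sequences
#'
#' A,C,G,T frequencies over the full peaklet sequence set (N excluded),
#' matching the universe used by the enrichment tests.
#'
#' @param peaklets "peaklet_set" data.frame.
#' @param genome Named DNAStringSet.
#' @return Length-4 probability vector (A,C,G,T).
#' @export
peaklet_background <- function(peaklets, genome) {
  seqs <- extract_peaklet_seqs(peaklets, genome)
  af <- colSums(Biostrings::alphabetFrequency(Biostrings::DNAStringSet(seqs)))
  bases <- af[DNA_BASES]
  stats::setNames(as.numeric(bases / sum(bases)), DNA_BASES)
}

# Internal: peaklet sequences as a named character vector.
extract_peaklet_seqs <- function(peaklets, genome) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (!all(peaklets$chrom %in% names(genome))) {
    stop("peaklet on chromosome absent from genome")
  }
  lens <- Biostrings::width(genome)[match(peaklets$chrom, names(genome))]
  if (any(peaklets$start < 0 | peaklets$end > lens)) {
    stop("peaklet outside chromosome bounds")
  }
  seqs <- as.character(Biostrings::subseq(
    genome[peaklets$chrom], start = peaklets$start + 1L, end = peaklets$end))
  stats::setNames(seqs, peaklets$peaklet_id)
}

#' Scan every peaklet with every PWM
#'
#' @param peaklets "peaklet_set" data.frame.
#' @param genome Named DNAStringSet (or named character vector).
#' @param pwms List of "pwm" objects.
#' @param threshold_fraction Hit threshold passed to [scan_sequence()].
#' @return Class "hit_matrix": list(matrix = logical peaklets x motifs
#'   (>= 1 hit), hits = data.frame(peaklet_id, motif_id, offset, strand,
#'   score)).
#' @export
build_hit_matrix <- function(peaklets, genome, pwms, threshold_fraction = 0.8) {
  seqs <- extract_peaklet_seqs(peaklets, genome)
  ids <- vapply(pwms, `[[`, "", "motif_id")
  mat <- matrix(FALSE, nrow = length(seqs), ncol = length(pwms),
                dimnames = list(names(seqs), ids))
  all_hits <- list()
  for (m in seq_along(pwms)) {
    for (i in seq_along(seqs)) {
      h <- scan_sequence(pwms[[m]], seqs[[i]], threshold_fraction)
      if (nrow(h)) {
        mat[i, m] <- TRUE
        h$peaklet_id <- names(seqs)[i]
        h$motif_id <- ids[m]
        all_hits[[length(all_hits) + 1L]] <- h
      }
    }
  }
  hits <- if (length(all_hits)) {
    do.call(rbind, all_hits)[, c("peaklet_id", "motif_id", "offset",
                                 "strand", "score")]
  } else {
    data.frame(peaklet_id = character(), motif_id = character(),
               offset = integer(), strand = character(), score = numeric(),
               stringsAsFactors = FALSE)
  }
  rownames(hits) <- NULL
  structure(list(matrix = mat, hits = hits), class = "hit_matrix")
}

#' Motif enrichment in a foreground peaklet set
#'
#' One-sided Fisher exact test per motif on the 2x2 table of hit/no-hit
#' versus foreground/background, BH-adjusted across motifs. Foreground ids
#' present in the background are removed from the background first, so a
#' superset background is handled as background-minus-foreground.
#'
#' @param foreground_ids,background_ids Peaklet id vectors (rows of the hit
#'   matrix). The foreground must be nonempty.
#' @param hit_matrix "hit_matrix" object (or its logical matrix).
#' @param fdr Enrichment threshold on q (default 0.05).
#' @return data.frame: motif_id, foreground_hits, foreground_size,
#'   background_hits, background_size, odds_ratio, p, q, enriched.
#' @export
motif_enrichment <- function(foreground_ids, background_ids, hit_matrix,
                             fdr = 0.05) {
  mat <- if (inherits(hit_matrix, "hit_matrix")) hit_matrix$matrix else hit_matrix
  if (length(foreground_ids) == 0L) stop("empty foreground")
  if (!all(foreground_ids %in% rownames(mat))) {
    stop("foreground id absent from hit matrix")
  }
  bg <- setdiff(background_ids, foreground_ids)
  if (!all(bg %in% rownames(mat))) stop("background id absent from hit matrix")
  n <- length(foreground_ids)
  N <- length(bg)
  res <- lapply(colnames(mat), function(m) {
    k <- sum(mat[foreground_ids, m])
    K <- if (N > 0) sum(mat[bg, m]) else 0L
    # an empty residual background (foreground == background) is a
    # degenerate comparison: no evidence either way
    p <- if (N == 0L) 1 else stats::fisher.test(
      matrix(c(k, n - k, K, N - K), nrow = 2L, byrow = TRUE),
      alternative = "greater")$p.value
    orat <- if (N == 0L) 1 else
      ((k + 0.5) * (N - K + 0.5)) / ((n - k + 0.5) * (K + 0.5))
    data.frame(motif_id = m, foreground_hits = k, foreground_size = n,
               background_hits = K, background_size = N,
               odds_ratio = orat, p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q <- bh_adjust(res$p)
  res$enriched <- res$q < fdr
  res
}

#' Motif co-occurrence network over peaklets
#'
#' For every unordered motif pair, counts the peaklets carrying hits of
#' both, and the shared fraction (Jaccard by default: shared / union of the
#' two motifs' peaklet sets; "min" divides by the smaller set). Pairs with
#' no shared peaklet are omitted.
#'
#' @param hit_matrix "hit_matrix" object (or logical matrix).
#' @param motifs Motif ids to include (default: all columns).
#' @param peaklet_subset Optional peaklet ids to restrict rows.
#' @param denominator "union" (Jaccard, default) or "min".
#' @return data.frame(motif_a, motif_b, shared_peaklets, shared_fraction).
#' @export
cooccurrence_network <- function(hit_matrix, motifs = NULL,
                                 peaklet_subset = NULL,
                                 denominator = c("union", "min")) {
  denominator <- match.arg(denominator)
  mat <- if (inherits(hit_matrix, "hit_matrix")) hit_matrix$matrix else hit_matrix
  if (!is.null(motifs)) {
    if (!all(motifs %in% colnames(mat))) stop("unknown motif id")
    mat <- mat[, motifs, drop = FALSE]
  }
  if (!is.null(peaklet_subset)) {
    if (!all(peaklet_subset %in% rownames(mat))) stop("unknown peaklet id")
    mat <- mat[peaklet_subset, , drop = FALSE]
  }
  m <- ncol(mat)
  if (m < 2L) {
    return(data.frame(motif_a = character(), motif_b = character(),
                      shared_peaklets = integer(), shared_fraction = numeric(),
                      stringsAsFactors = FALSE))
  }
  B <- mat * 1L
  shared <- crossprod(B)
  sizes <- colSums(B)
  out <- list()
  for (a in seq_len(m - 1L)) {
    for (b in (a + 1L):m) {
      s <- shared[a, b]
      if (s == 0L) next
      denom <- if (denominator == "union") sizes[a] + sizes[b] - s
               else min(sizes[a], sizes[b])
      out[[length(out) + 1L]] <- data.frame(
        motif_a = colnames(mat)[a], motif_b = colnames(mat)[b],
        shared_peaklets = as.integer(s),
        shared_fraction = as.numeric(s / denom), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(motif_a = character(), motif_b = character(),
                      shared_peaklets = integer(), shared_fraction = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
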