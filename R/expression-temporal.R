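# Temporal expression analysis: TPM normalization, Z-scores of log2(TPM+1),
# negative-binomial differential testing of every post-injury timepoint
# against the uninjured baseline, BH FDR control, and K-means clustering of
# standardized temporal profiles.

#' Validate a sample table
#'
#' @param samples data.frame(sample_id, timepoint_dpi, replicate).
#' @return The validated data.frame (invisibly the same object).
#' @export
sample_table <- function(samples) {
  stopifnot(all(c("sample_id", "timepoint_dpi", "replicate") %in% names(samples)))
  if (anyDuplicated(samples$sample_id)) stop("duplicated sample_id")
  key <- paste(samples$timepoint_dpi, samples$replicate)
  if (anyDuplicated(key)) stop("duplicated (timepoint, replicate) pair")
  samples
}

#' Transcripts-per-million normalization
#'
#' `tpm[i, s] = 1e6 * (counts[i, s] / length[i]) / sum_j(counts[j, s] / length[j])`.
#' Column sums are 1e6 by construction; this is not preserved under row
#' subsetting, so recompute after subsetting if the invariant matters.
#'
#' @param counts Transcript x sample matrix of nonnegative counts with rownames.
#' @param effective_length Named positive vector of effective lengths (bp),
#'   one entry per row of `counts`.
#' @return Matrix of TPM values, same dimnames as `counts`.
#' @export
compute_tpm <- function(counts, effective_length) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  len <- effective_length[rownames(counts)]
  if (anyNA(len)) stop("effective_length missing for some transcripts")
  if (any(len <= 0)) stop("effective lengths must be positive")
  if (any(counts < 0)) stop("negative counts")
  rate <- counts / len
  denom <- colSums(rate)
  if (any(denom == 0)) {
    stop("sample with all-zero counts: ", colnames(counts)[denom == 0][1L])
  }
  sweep(rate, 2L, denom, "/") * 1e6
}

#' Row-standardized log2(TPM + 1) profiles
#'
#' Each retained row is centered and scaled across ALL samples at all
#' timepoints using the sample (n-1) standard deviation, so that retained
#' rows have mean 0 and SD 1. Rows with zero variance are flagged and
#' excluded from the returned Z matrix (they carry no temporal shape).
#'
#' @param tpm TPM matrix (see [compute_tpm()]).
#' @param transcripts Optional character vector restricting to a row subset.
#' @param pseudocount Added before the log2 transform (default 1).
#' @return List with `z` (retained rows x samples), `flagged` (zero-variance
#'   transcript ids), `pseudocount`, `log_base` (2). Class "zscore_matrix".
#' @export
log_zscore <- function(tpm, transcripts = NULL, pseudocount = 1) {
  stopifnot(is.matrix(tpm))
  if (!is.null(transcripts)) {
    missing <- setdiff(transcripts, rownames(tpm))
    if (length(missing)) stop("transcripts not in matrix: ", missing[1L])
    tpm <- tpm[transcripts, , drop = FALSE]
  }
  lt <- log2(tpm + pseudocount)
  mu <- rowMeans(lt)
  sdev <- apply(lt, 1L, stats::sd)
  flagged <- rownames(lt)[sdev < .Machine$double.eps^0.5]
  keep <- setdiff(rownames(lt), flagged)
  z <- (lt[keep, , drop = FALSE] - mu[keep]) / sdev[keep]
  structure(list(z = z, flagged = flagged, pseudocount = pseudocount,
                 log_base = 2), class = "zscore_matrix")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin validated wrapper around `stats::p.adjust(method = "BH")` (the
#' step-up procedure: q_i = min over j with p_(j) >= p_(i) of p_(j)*m/j,
#' capped at 1).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Negative-binomial differential testing against the baseline timepoint
#'
#' Fits, per feature, an NB model with one mean per timepoint. The
#' dispersion is estimated per feature by method of moments across
#' timepoint groups (mean of (s^2 - m)/m^2 over groups with positive mean)
#' and then shrunk toward the pooled mean dispersion by an adaptive
#' moment-matched (James-Stein style) weight, floored at 1e-8. The
#' shrinkage -- the same idea behind limma/edgeR dispersion moderation --
#' is what keeps the tests calibrated with only a few replicates: raw
#' per-feature moment estimates are so noisy at n = 3 that features with
#' accidentally small estimates produce badly inflated statistics. Each
#' post-baseline timepoint is compared to the baseline with a Wald test on
#' the log fold change (asymptotic normal, delta-method SE), and a
#' likelihood-ratio test compares the per-timepoint model to a single-mean
#' null against chi-square with (T - 1) df. Features with total count below
#' `min_total` are filtered before testing (NA statistics). BH q-values are
#' computed within each test family over tested features.
#'
#' @param counts Feature x sample count matrix with dimnames.
#' @param samples Sample table matching `colnames(counts)`.
#' @param ref_timepoint Baseline timepoint (default 0 dpi).
#' @param min_total Total-count filter threshold (default 10).
#' @return data.frame with one row per feature: `feature_id`, `filtered`,
#'   `dispersion`, and per non-baseline timepoint t columns `log2fc_t`,
#'   `p_t`, `q_t`, plus `lrt_stat`, `lrt_p`, `lrt_q`.
#' @export
nb_differential <- function(counts, samples, ref_timepoint = 0,
                            min_total = 10) {
  samples <- sample_table(samples)
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  if (!all(samples$sample_id %in% colnames(counts))) {
    stop("sample_id missing from count matrix columns")
  }
  counts <- counts[, samples$sample_id, drop = FALSE]
  tps <- sort(unique(samples$timepoint_dpi))
  if (!ref_timepoint %in% tps) stop("baseline timepoint absent from samples")
  groups <- split(samples$sample_id, factor(samples$timepoint_dpi, levels = tps))
  if (any(lengths(groups) < 2L)) {
    stop("each timepoint needs at least 2 replicates")
  }

  tested <- rowSums(counts) >= min_total
  n_feat <- nrow(counts)
  M <- vapply(groups, function(s) rowMeans(counts[, s, drop = FALSE]),
              numeric(n_feat))
  V <- vapply(groups, function(s) apply(counts[, s, drop = FALSE], 1L,
                                        stats::var), numeric(n_feat))
  if (n_feat == 1L) { M <- matrix(M, 1L); V <- matrix(V, 1L) }
  colnames(M) <- colnames(V) <- as.character(tps)

  # Method-of-moments dispersion: per-feature mean of the per-group terms
  # (s^2 - m)/m^2, shrunk toward the pooled mean by moment matching. The
  # shrinkage weight is the estimated fraction of the cross-feature spread
  # of raw estimates that is real signal rather than sampling noise (the
  # sampling variance of each feature's mean term is estimated from the
  # spread of its own per-group terms). With few replicates the raw
  # estimates are so noisy that unshrunk plug-ins leave the Wald/LRT badly
  # anticonservative; under a common true dispersion the weight goes to 0
  # (near-pooled estimate), under genuine heterogeneity it grows.
  terms <- (V - M) / M^2
  terms[!is.finite(terms)] <- NA
  raw <- rowMeans(terms, na.rm = TRUE)
  raw[!is.finite(raw)] <- 0
  noise_var <- apply(terms, 1L, function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 2L) return(NA_real_)
    stats::var(x) / length(x)
  })
  pooled <- if (any(tested)) mean(pmax(raw[tested], 0)) else 0
  mean_noise <- mean(noise_var[tested], na.rm = TRUE)
  spread <- if (sum(tested) > 1L) stats::var(raw[tested]) else 0
  b <- if (is.finite(mean_noise) && spread > 0) {
    min(max(1 - mean_noise / spread, 0), 1)
  } else 0
  alpha <- pmax(pooled + b * (raw - pooled), 1e-8)

  mu_floor <- 0.5  # half a count; guards logs and NB likelihoods at zero means
  n_per <- lengths(groups)
  ref <- as.character(ref_timepoint)
  res <- data.frame(feature_id = rownames(counts),
                    filtered = !tested,
                    dispersion = ifelse(tested, alpha, NA_real_),
                    stringsAsFactors = FALSE)

  mu0 <- pmax(M[, ref], mu_floor)
  v0 <- (1 / mu0 + alpha) / n_per[ref]
  for (t in setdiff(as.character(tps), ref)) {
    mut <- pmax(M[, t], mu_floor)
    lfc <- log2(mut / mu0)
    se <- sqrt((1 / mut + alpha) / n_per[t] + v0)
    z <- log(mut / mu0) / se
    p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
    p <- pmin(p, 1)
    res[[paste0("log2fc_", t)]] <- ifelse(tested, lfc, NA_real_)
    res[[paste0("p_", t)]] <- ifelse(tested, p, NA_real_)
    q <- rep(NA_real_, n_feat)
    q[tested] <- bh_adjust(p[tested])
    res[[paste0("q_", t)]] <- q
  }

  # likelihood ratio: per-timepoint means vs grand mean, shared dispersion
  size <- 1 / alpha
  grand <- pmax(rowMeans(counts), mu_floor)
  ll_full <- numeric(n_feat)
  ll_null <- numeric(n_feat)
  for (t in as.character(tps)) {
    mut <- pmax(M[, t], mu_floor)
    for (s in groups[[t]]) {
      ll_full <- ll_full + stats::dnbinom(counts[, s], size = size, mu = mut,
                                          log = TRUE)
      ll_null <- ll_null + stats::dnbinom(counts[, s], size = size, mu = grand,
                                          log = TRUE)
    }
  }
  stat <- pmax(2 * (ll_full - ll_null), 0)
  lrt_p <- stats::pchisq(stat, df = length(tps) - 1L, lower.tail = FALSE)
  res$lrt_stat <- ifelse(tested, stat, NA_real_)
  res$lrt_p <- ifelse(tested, lrt_p, NA_real_)
  res$lrt_q <- NA_real_
  res$lrt_q[tested] <- bh_adjust(lrt_p[tested])
  rownames(res) <- NULL
  res
}

#' K-means clustering of standardized temporal profiles
#'
#' Lloyd's algorithm with Euclidean distance on Z-score rows. Each restart
#' initializes centroids by sampling K distinct rows; iterations stop when
#' the assignment is unchanged or after `max_iter` iterations; an empty
#' cluster is repaired by reseeding it with the point farthest from its
#' assigned centroid. The restart with the lowest within-cluster sum of
#' squares is kept. Deterministic given `seed`.
#'
#' @param z "zscore_matrix" object or plain numeric matrix (rows clustered).
#' @param K Number of clusters (default 7).
#' @param seed Integer RNG seed.
#' @param n_restarts Number of random restarts (default 100; Lloyd local
#'   optima are common enough at K = 7 that sparse restarts visibly hurt
#'   recovery, and restarts are cheap at this scale).
#' @param max_iter Maximum Lloyd iterations per restart (default 300).
#' @return Class "temporal_clustering": list(K, assignment (named integer),
#'   centroids (K x samples), within_ss, seed, n_restarts, iterations).
#' @export
kmeans_temporal <- function(z, K = 7, seed = 1, n_restarts = 100,
                            max_iter = 300) {
  if (inherits(z, "zscore_matrix")) z <- z$z
  stopifnot(is.matrix(z), !is.null(rownames(z)))
  if (K < 2) stop("K must be at least 2")
  n <- nrow(z)
  if (K > n) stop("K exceeds the number of retained rows")

  sq_norm <- rowSums(z^2)
  assign_step <- function(centers) {
    # squared distances point x center via the expansion |x|^2 - 2 x.c + |c|^2
    d2 <- outer(sq_norm, rowSums(centers^2), "+") - 2 * (z %*% t(centers))
    d2[d2 < 0] <- 0
    list(cluster = max.col(-d2, ties.method = "first"),
         d2 = d2)
  }

  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    centers <- z[sample.int(n, K), , drop = FALSE]
    cl <- rep(0L, n)
    prev_wss <- Inf
    iter <- 0L
    repeat {
      iter <- iter + 1L
      a <- assign_step(centers)
      new_cl <- a$cluster
      point_d2 <- a$d2[cbind(seq_len(n), new_cl)]
      # repair empty clusters with the point farthest from its centroid
      for (k in which(tabulate(new_cl, K) == 0L)) {
        far <- which.max(point_d2)
        new_cl[far] <- k
        point_d2[far] <- 0
      }
      wss <- sum(point_d2)
      stopifnot(wss <= prev_wss + 1e-8)  # Lloyd objective never increases
      converged <- identical(new_cl, cl)
      cl <- new_cl
      prev_wss <- wss
      if (converged || iter >= max_iter) break
      centers <- t(vapply(seq_len(K), function(k) {
        colMeans(z[cl == k, , drop = FALSE])
      }, numeric(ncol(z))))
    }
    wss <- sum(vapply(seq_len(K), function(k) {
      d <- z[cl == k, , drop = FALSE]
      sum(sweep(d, 2L, colMeans(d))^2)
    }, 0))
    if (is.null(best) || wss < best$within_ss) {
      centers <- t(vapply(seq_len(K), function(k) {
        colMeans(z[cl == k, , drop = FALSE])
      }, numeric(ncol(z))))
      best <- list(K = K,
                   assignment = stats::setNames(cl, rownames(z)),
                   centroids = centers,
                   within_ss = wss,
                   seed = seed, n_restarts = n_restarts, iterations = iter)
    }
  }
  structure(best, class = "temporal_clustering")
}

#' @export
print.temporal_clustering <- function(x, ...) {
  cat("temporal_clustering: K =", x$K, ",", length(x$assignment),
      "transcripts, within-SS =", signif(x$within_ss, 6), "\n")
  invisible(x)
}

#' Adjusted Rand index between two labelings
#'
#' Hubert-Arabie adjusted Rand index; 1 for identical partitions, ~0 for
#' independent ones.
#'
#' @param a,b Label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxim <- (sum_a + sum_b) / 2
  if (maxim == expected) return(1)
  (sum_ij - expected) / (maxim - expected)
}
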