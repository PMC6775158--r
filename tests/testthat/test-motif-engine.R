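test_that("log-odds construction matches hand arithmetic", {
  pfm <- list(motif_id = "M1", tf_name = "T1",
              counts = matrix(c(100, 0, 0, 0), 4, 1,
                              dimnames = list(c("A", "C", "G", "T"), NULL)))
  pwm <- pfm_to_pwm(pfm, background = rep(0.25, 4), pseudocount = 1)
  expect_equal(unname(pwm$log_odds["A", 1]), log2((100.25 / 101) / 0.25),
               tolerance = 1e-12)
  expect_equal(unname(pwm$log_odds["A", 1]), 1.989, tolerance = 1e-3)

  # counts proportional to the background give ~0 log odds
  flat <- list(motif_id = "M2", tf_name = "T2",
               counts = matrix(25, 4, 4,
                               dimnames = list(c("A", "C", "G", "T"), NULL)))
  pwm2 <- pfm_to_pwm(flat)
  expect_true(all(abs(pwm2$log_odds) < 0.01))

  expect_error(pfm_to_pwm(pfm, pseudocount = 0), "-Inf")
})

test_that("a planted consensus is found at its offset on both strands", {
  motif <- toy_motif("ACGGTACA")
  pwm <- pfm_to_pwm(motif)
  set.seed(10)
  left <- random_dna(37)
  right <- random_dna(55)
  seq <- paste0(left, "ACGGTACA", right)
  hits <- scan_sequence(pwm, seq)
  expect_true(any(hits$offset == 37 & hits$strand == "+"))

  rcseq <- paste0(left, revcomp("ACGGTACA"), right)
  hits_rc <- scan_sequence(pwm, rcseq)
  expect_true(any(hits_rc$offset == 37 & hits_rc$strand == "-"))

  # too-short sequences give empty results, not errors
  expect_equal(nrow(scan_sequence(pwm, "ACG")), 0L)
  # windows containing N never match
  expect_equal(nrow(scan_sequence(pwm, "ACGGNACA")), 0L)
})

test_that("scanning is strand-symmetric", {
  set.seed(12)
  motif <- toy_motif("GATTACAT")
  pwm <- pfm_to_pwm(motif)
  for (i in 1:10) {
    seq <- paste0(random_dna(40), "GATTACAT", random_dna(40))
    fwd <- scan_sequence(pwm, seq)
    rev <- scan_sequence(pwm, revcomp(seq))
    # a + hit at offset i maps to a - hit at S - L - i on the reverse
    S <- nchar(seq); L <- pwm$length
    mirrored <- data.frame(offset = S - L - rev$offset,
                           strand = ifelse(rev$strand == "+", "-", "+"),
                           score = rev$score)
    mirrored <- mirrored[order(mirrored$offset, mirrored$strand), ]
    rownames(mirrored) <- NULL
    expect_equal(fwd$offset, mirrored$offset)
    expect_equal(fwd$strand, mirrored$strand)
    expect_equal(fwd$score, mirrored$score, tolerance = 1e-9)
  }
})

test_that("scanning matches the brute-force scorer on random sequences", {
  set.seed(13)
  cfg <- sim_config(seed = 13)
  motifs <- simulate_motif_library(cfg)[1:3]
  for (m in motifs) {
    pwm <- pfm_to_pwm(m)
    for (i in 1:10) {
      seq <- random_dna(200)
      got <- scan_sequence(pwm, seq, threshold_fraction = 0.6)
      want <- brute_scan(pwm, seq, threshold_fraction = 0.6)
      expect_equal(got$offset, want$offset)
      expect_equal(got$strand, want$strand)
      expect_equal(got$score, want$score, tolerance = 1e-9)
    }
  }
})

test_that("hit matrices record planted instances and validate inputs", {
  set.seed(14)
  genome <- Biostrings::DNAStringSet(c(chr1 = random_dna(4000)))
  summits <- data.frame(chrom = "chr1", pos = c(1000L, 3000L),
                        p_value = 1e-12)
  pk <- build_peaklets(summits, c(chr1 = 4000L))
  motif <- toy_motif("TTACGGAC")
  # plant the consensus inside the first peaklet only
  chars <- as.character(genome[[1]])
  substr(chars, 801, 808) <- "TTACGGAC"
  genome <- Biostrings::DNAStringSet(c(chr1 = chars))
  pwms <- list(pfm_to_pwm(motif))
  hm <- build_hit_matrix(pk, genome, pwms)
  expect_true(hm$matrix["pk000001", "M001"])
  expect_true(any(hm$hits$peaklet_id == "pk000001" & hm$hits$offset == 50))

  expect_equal(ncol(build_hit_matrix(pk, genome, list())$matrix), 0L)
  bad <- pk; bad$end[2] <- 5000L
  expect_error(build_hit_matrix(bad, genome, pwms), "outside")
})

test_that("Fisher enrichment matches the hypergeometric tail sum", {
  # k=5 of n=10 foreground vs K=10 of N=40 background
  mat <- matrix(FALSE, 50, 1, dimnames = list(sprintf("p%02d", 1:50), "M1"))
  mat[1:5, 1] <- TRUE    # foreground hits
  mat[11:20, 1] <- TRUE  # background hits
  fg <- sprintf("p%02d", 1:10)
  bg <- sprintf("p%02d", 11:50)
  res <- motif_enrichment(fg, bg, mat)
  expect_equal(res$p, brute_fisher_greater(5, 10, 10, 40), tolerance = 1e-10)
  expect_equal(res$foreground_hits, 5L)
  expect_equal(res$background_hits, 10L)

  # foreground identical to background: degenerate, no signal
  same <- motif_enrichment(fg, fg, mat)
  expect_equal(same$p, 1)
  expect_equal(same$odds_ratio, 1)

  expect_error(motif_enrichment(character(), bg, mat), "empty")
})

test_that("Fisher p equals the brute-force tail over random small tables", {
  set.seed(15)
  for (i in 1:200) {
    n <- sample(1:40, 1); N <- sample(1:80, 1)
    k <- sample(0:n, 1); K <- sample(0:N, 1)
    ids <- sprintf("x%03d", seq_len(n + N))
    mat <- matrix(FALSE, n + N, 1, dimnames = list(ids, "M"))
    if (k > 0) mat[1:k, 1] <- TRUE
    if (K > 0) mat[n + (1:K), 1] <- TRUE
    res <- motif_enrichment(ids[1:n], ids[(n + 1):(n + N)], mat)
    expect_equal(res$p, brute_fisher_greater(k, n, K, N), tolerance = 1e-10)
  }
})

test_that("co-occurrence edges match brute-force set intersections", {
  set.seed(16)
  mat <- matrix(runif(100 * 10) < 0.3, 100, 10,
                dimnames = list(sprintf("p%03d", 1:100),
                                sprintf("M%02d", 1:10)))
  got <- cooccurrence_network(mat)
  want <- brute_cooccurrence(mat)
  expect_equal(got, want)

  ident <- cbind(a = mat[, 1], b = mat[, 1])
  e <- cooccurrence_network(ident)
  expect_equal(e$shared_fraction, 1)

  disj <- cbind(a = c(TRUE, FALSE, FALSE), b = c(FALSE, TRUE, FALSE))
  rownames(disj) <- paste0("p", 1:3)
  expect_equal(nrow(cooccurrence_network(disj)), 0L)

  # "min" denominator variant
  sub <- cbind(a = c(TRUE, TRUE, FALSE), b = c(TRUE, FALSE, FALSE))
  rownames(sub) <- paste0("p", 1:3)
  e2 <- cooccurrence_network(sub, denominator = "min")
  expect_equal(e2$shared_fraction, 1)  # shared 1 / min(2, 1)
})

test_that("peaklet background frequencies reflect the sequence composition", {
  genome <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGT", 500)))
  pk <- data.frame(peaklet_id = "pk1", chrom = "chr1", start = 0L,
                   end = 2000L, stringsAsFactors = FALSE)
  bg <- peaklet_background(pk, genome)
  expect_equal(unname(bg), rep(0.25, 4))
  expect_equal(sum(bg), 1)
})
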