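# Readers/writers for the standard formats the pipeline touches, plus the
# shared coordinate conventions. Every coordinate inside the package is
# 0-based, half-open [start, end); GFF3 is the only 1-based entry point and
# is converted on read. Strand is one of "+", "-", ".".

DNA_BASES <- c("A", "C", "G", "T")
DNA_ALPHABET <- c(DNA_BASES, "N")

#' Read a FASTA file into a DNAStringSet
#'
#' Sequences are uppercased and restricted to the closed alphabet
#' \{A,C,G,T,N\}; anything else (including IUPAC ambiguity codes other than N)
#' is rejected, because downstream PWM scanning assumes that alphabet.
#' Record ids are the header tokens up to the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^>", lines))) {
    stop("malformed FASTA (no '>' header line): ", path)
  }
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  if (any(Biostrings::width(seqs) < 1L)) {
    stop("malformed FASTA: zero-length sequence in ", path)
  }
  af <- Biostrings::alphabetFrequency(seqs)
  other <- rowSums(af[, !colnames(af) %in% DNA_ALPHABET, drop = FALSE])
  if (any(other > 0)) {
    stop("sequence letters outside {A,C,G,T,N} in record: ",
         names(seqs)[other > 0][1L])
  }
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}

#' Read a BED3/BED6 file
#'
#' BED is taken at its native convention: 0-based half-open intervals. With
#' fewer than 6 columns, strand defaults to "." and name/score to "."/0.
#'
#' @param path Path to a tab-separated BED file.
#' @return A data.frame with columns chrom, start, end, name, score, strand.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("BED line ", which(nf < 3L)[1L], ": fewer than 3 tab-separated columns")
  }
  col <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[[i]] else default, "")
  }
  chrom <- col(1L, NA_character_)
  start <- suppressWarnings(as.integer(col(2L, NA_character_)))
  end <- suppressWarnings(as.integer(col(3L, NA_character_)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop("BED line ", bad[1L], ": non-numeric coordinates")
  bad <- which(start < 0L | start >= end)
  if (length(bad)) {
    stop("BED line ", bad[1L], ": invalid interval [",
         start[bad[1L]], ", ", end[bad[1L]], ")")
  }
  strand <- col(6L, ".")
  if (!all(strand %in% c("+", "-", "."))) {
    stop("BED line ", which(!strand %in% c("+", "-", "."))[1L],
         ": strand must be one of +, -, .")
  }
  score <- suppressWarnings(as.numeric(col(5L, "0")))
  score[is.na(score)] <- 0
  data.frame(chrom = chrom, start = start, end = end,
             name = col(4L, "."), score = score, strand = strand,
             stringsAsFactors = FALSE)
}

#' Write a table as TSV (with header) or BED (without)
#'
#' @param rows A data.frame. For BED it must carry chrom/start/end columns;
#'   name, score and strand are filled with "."/0/"." when absent.
#' @param path Output path.
#' @param format Either "tsv" or "bed".
#' @export
write_table <- function(rows, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(rows))
  if (format == "tsv") {
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    need <- c("chrom", "start", "end")
    if (!all(need %in% names(rows))) {
      stop("BED output needs columns chrom, start, end")
    }
    n <- nrow(rows)
    bed <- data.frame(
      rows$chrom, rows$start, rows$end,
      if (!is.null(rows$name)) rows$name else rep(".", n),
      if (!is.null(rows$score)) rows$score else rep(0L, n),
      if (!is.null(rows$strand)) rows$strand else rep(".", n),
      stringsAsFactors = FALSE)
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Construct a set of gene models
#'
#' Container used by annotation and simulation: per-gene interval and
#' strand-resolved TSS, transcript membership, exon and 5'UTR intervals.
#' All coordinates 0-based half-open. The TSS of a "+" gene is its start,
#' of a "-" gene its end - 1 (the biological 5' end).
#'
#' @param genes data.frame(gene_id, chrom, start, end, strand).
#' @param transcripts data.frame(transcript_id, gene_id).
#' @param exons data.frame(gene_id, chrom, start, end).
#' @param utr5 data.frame(gene_id, chrom, start, end).
#' @return An object of class "gene_models".
#' @export
gene_models <- function(genes, transcripts, exons, utr5) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in% names(genes)))
  stopifnot(all(genes$start >= 0), all(genes$start < genes$end))
  stopifnot(all(genes$strand %in% c("+", "-", ".")))
  if (anyDuplicated(genes$gene_id)) stop("duplicated gene_id")
  genes$tss <- ifelse(genes$strand == "-", genes$end - 1L, genes$start)
  for (tab in list(exons, utr5)) {
    if (nrow(tab)) {
      m <- match(tab$gene_id, genes$gene_id)
      if (anyNA(m)) stop("feature references unknown gene_id")
      if (any(tab$start < genes$start[m] | tab$end > genes$end[m])) {
        stop("exon/UTR outside its gene interval")
      }
    }
  }
  if (anyNA(match(transcripts$gene_id, genes$gene_id))) {
    stop("transcript references unknown gene_id")
  }
  structure(list(genes = genes, transcripts = transcripts,
                 exons = exons, utr5 = utr5),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,", nrow(x$transcripts),
      "transcripts,", nrow(x$exons), "exons\n")
  invisible(x)
}

#' Read gene models from GFF3
#'
#' Accepts gene / mRNA (or transcript) / exon / five_prime_UTR features wired
#' by ID/Parent attributes. GFF3 1-based closed coordinates are converted to
#' the package's 0-based half-open convention; the TSS is resolved from
#' strand. An exon or UTR whose Parent does not resolve to a known mRNA (or
#' gene), or an mRNA with an unknown gene Parent, is a format error.
#'
#' @param path Path to a GFF3 file.
#' @return A "gene_models" object.
#' @export
read_gff_genes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  id <- as.character(gr$ID)
  parent <- vapply(as.list(gr$Parent), function(p) {
    if (length(p) == 0) NA_character_ else as.character(p[[1L]])
  }, "")

  is_gene <- type == "gene"
  if (!any(is_gene)) stop("GFF3 contains no gene features: ", path)
  genes <- data.frame(
    gene_id = id[is_gene],
    chrom = as.character(GenomicRanges::seqnames(gr))[is_gene],
    start = GenomicRanges::start(gr)[is_gene] - 1L,
    end = GenomicRanges::end(gr)[is_gene],
    strand = as.character(GenomicRanges::strand(gr))[is_gene],
    stringsAsFactors = FALSE)
  genes$strand[genes$strand == "*"] <- "."

  is_tx <- type %in% c("mRNA", "transcript")
  if (any(is_tx & !(parent %in% genes$gene_id))) {
    stop("orphan mRNA Parent in GFF3: ",
         id[is_tx & !(parent %in% genes$gene_id)][1L])
  }
  tx <- data.frame(transcript_id = id[is_tx], gene_id = parent[is_tx],
                   stringsAsFactors = FALSE)

  feature_tab <- function(ftype) {
    sel <- type == ftype
    if (!any(sel)) {
      return(data.frame(gene_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        stringsAsFactors = FALSE))
    }
    par <- parent[sel]
    known <- par %in% tx$transcript_id | par %in% genes$gene_id
    if (any(!known)) {
      stop("orphan ", ftype, " Parent in GFF3: ", par[!known][1L])
    }
    gid <- ifelse(par %in% tx$transcript_id,
                  tx$gene_id[match(par, tx$transcript_id)], par)
    data.frame(gene_id = gid,
               chrom = as.character(GenomicRanges::seqnames(gr))[sel],
               start = GenomicRanges::start(gr)[sel] - 1L,
               end = GenomicRanges::end(gr)[sel],
               stringsAsFactors = FALSE)
  }

  gene_models(genes, tx, feature_tab("exon"), feature_tab("five_prime_UTR"))
}

#' Write gene models as GFF3
#'
#' Inverse of [read_gff_genes()]: emits gene/mRNA/exon/five_prime_UTR rows
#' with ID/Parent attributes, converting back to 1-based closed coordinates.
#'
#' @param gm A "gene_models" object.
#' @param path Output path.
#' @export
write_gff_genes <- function(gm, path) {
  stopifnot(inherits(gm, "gene_models"))
  row <- function(chrom, type, start0, end0, strand, attr) {
    paste(chrom, "regenGRN", type, start0 + 1L, end0, ".", strand, ".", attr,
          sep = "\t")
  }
  out <- c("##gff-version 3")
  g <- gm$genes[order(gm$genes$gene_id), , drop = FALSE]
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    strand <- if (g$strand[i] == ".") "." else g$strand[i]
    out <- c(out, row(g$chrom[i], "gene", g$start[i], g$end[i], strand,
                      paste0("ID=", gid)))
    txs <- gm$transcripts$transcript_id[gm$transcripts$gene_id == gid]
    for (tid in sort(txs)) {
      out <- c(out, row(g$chrom[i], "mRNA", g$start[i], g$end[i], strand,
                        paste0("ID=", tid, ";Parent=", gid)))
      ex <- gm$exons[gm$exons$gene_id == gid, , drop = FALSE]
      ex <- ex[order(ex$start), , drop = FALSE]
      for (j in seq_len(nrow(ex))) {
        out <- c(out, row(ex$chrom[j], "exon", ex$start[j], ex$end[j], strand,
                          paste0("ID=", tid, ".exon", j, ";Parent=", tid)))
      }
      u5 <- gm$utr5[gm$utr5$gene_id == gid, , drop = FALSE]
      for (j in seq_len(nrow(u5))) {
        out <- c(out, row(u5$chrom[j], "five_prime_UTR", u5$start[j], u5$end[j],
                          strand, paste0("ID=", tid, ".utr5.", j,
                                         ";Parent=", tid)))
      }
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a JASPAR-style PFM text file
#'
#' Parses ">motif_id tf_name" headers followed by four count rows, either
#' labelled ("A [ 1 2 ]") or bare. Labelled rows are reordered into fixed
#' A,C,G,T order regardless of file order; bare rows are assumed already
#' A,C,G,T. Rows of unequal length are a format error.
#'
#' @param path Path to a JASPAR PFM text file.
#' @return A list of motif matrices, each a list(motif_id, tf_name, counts)
#'   with a 4 x L counts matrix (rows A,C,G,T).
#' @export
read_jaspar <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("malformed JASPAR file (no '>' header): ", path)
  ends <- c(hdr[-1L] - 1L, length(lines))
  motifs <- vector("list", length(hdr))
  for (k in seq_along(hdr)) {
    block <- lines[hdr[k]:ends[k]]
    header <- sub("^>", "", block[1L])
    toks <- strsplit(header, "\\s+")[[1L]]
    motif_id <- toks[1L]
    tf_name <- if (length(toks) > 1L) toks[2L] else toks[1L]
    rows <- block[-1L]
    if (length(rows) != 4L) {
      stop("motif ", motif_id, ": expected 4 count rows, found ", length(rows))
    }
    labels <- toupper(substr(trimws(rows), 1L, 1L))
    labelled <- all(labels %in% DNA_BASES) && !anyDuplicated(labels)
    parse_row <- function(r) {
      r <- gsub("^[ACGTacgt]", "", trimws(r))
      r <- gsub("[][]", " ", r)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(r), "\\s+")[[1L]]))
      if (anyNA(vals)) stop("motif ", motif_id, ": non-numeric count row")
      vals
    }
    vals <- lapply(rows, parse_row)
    if (length(unique(lengths(vals))) != 1L) {
      stop("motif ", motif_id, ": count rows of unequal length")
    }
    counts <- do.call(rbind, vals)
    rownames(counts) <- if (labelled) labels else DNA_BASES
    counts <- counts[DNA_BASES, , drop = FALSE]
    if (any(counts < 0)) stop("motif ", motif_id, ": negative counts")
    if (ncol(counts) < 1L) stop("motif ", motif_id, ": empty matrix")
    if (any(colSums(counts) <= 0)) {
      stop("motif ", motif_id, ": zero-sum column")
    }
    motifs[[k]] <- list(motif_id = motif_id, tf_name = tf_name, counts = counts)
  }
  motifs
}

#' Write motif matrices in JASPAR text format
#'
#' @param motifs List of motif matrices as returned by [read_jaspar()].
#' @param path Output path.
#' @export
write_jaspar <- function(motifs, path) {
  out <- character()
  for (m in motifs) {
    out <- c(out, paste0(">", m$motif_id, " ", m$tf_name))
    for (b in DNA_BASES) {
      out <- c(out, paste0(b, " [ ", paste(m$counts[b, ], collapse = " "), " ]"))
    }
  }
  writeLines(out, path)
  invisible(path)
}

# Internal: 0-based half-open data.frame intervals -> GRanges (1-based).
intervals_to_granges <- function(df) {
  strand <- if (!is.null(df$strand)) {
    s <- df$strand
    s[s == "."] <- "*"
    s
  } else "*"
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand)
}

#' Reverse complement of a DNA string
#'
#' @param x Character scalar over \{A,C,G,T,N\}.
#' @return The reverse complement as a character scalar.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
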