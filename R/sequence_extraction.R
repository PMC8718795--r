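#' Extract the PROMOTER sequence of a gene
#'
#' The PROMOTER region is the 1,500 bp immediately upstream of the
#' translation start site (TLS), excluding the TLS base itself, reported
#' 5'->3' on the gene's coding strand. Coordinates are 1-based inclusive.
#' At a contig edge the window is clipped (with a warning) rather than
#' padded.
#'
#' @param genome A named [Biostrings::DNAStringSet] (one entry per contig).
#' @param gene A list or one-row data.frame with fields `chrom`, `tls`,
#'   `strand`.
#' @param width Window width in bp (default 1500).
#' @return A single uppercase DNA string of length <= `width`.
#' @export
extract_promoter <- function(genome, gene, width = 1500L) {
  chrom <- as.character(gene$chrom)
  tls <- as.integer(gene$tls)
  strand <- as.character(gene$strand)
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  clen <- length(genome[[chrom]])
  if (strand == "+") {
    lo <- tls - width
    hi <- tls - 1L
  } else {
    lo <- tls + 1L
    hi <- tls + width
  }
  lo_c <- max(lo, 1L)
  hi_c <- min(hi, clen)
  if (hi_c < lo_c) return("")
  if (lo_c != lo || hi_c != hi) {
    warning(sprintf("promoter window clipped at contig edge (%s:%d-%d -> %d-%d)",
                    chrom, lo, hi, lo_c, hi_c))
  }
  s <- Biostrings::subseq(genome[[chrom]], lo_c, hi_c)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  toupper(as.character(s))
}

#' Extract the MIDDLE sequence between TLS and enhancer
#'
#' The MIDDLE region is 300 bp centred at the midpoint between the gene's
#' TLS and the 35S enhancer coordinate, oriented on the gene's coding
#' strand. When the enhancer-TLS distance is shorter than the window, the
#' window is clipped to the bases strictly between the two anchors.
#'
#' @inheritParams extract_promoter
#' @param enhancer_position 1-based genomic coordinate of the 35S enhancer;
#'   must be on the same contig as the gene.
#' @param enhancer_chrom Contig of the enhancer (defaults to the gene's).
#' @param width Window width in bp (default 300).
#' @return A single uppercase DNA string of length <= `width`.
#' @export
extract_middle <- function(genome, gene, enhancer_position,
                           enhancer_chrom = NULL, width = 300L) {
  chrom <- as.character(gene$chrom)
  if (!is.null(enhancer_chrom) && enhancer_chrom != chrom) {
    stop("enhancer is on a different chromosome (", enhancer_chrom,
         ") than the gene (", chrom, ")")
  }
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  tls <- as.integer(gene$tls)
  enh <- as.integer(enhancer_position)
  clen <- length(genome[[chrom]])
  half <- width %/% 2L
  m <- (tls + enh) %/% 2L
  lo <- m - half
  hi <- m + half - 1L
  # bases strictly between the two anchors
  a <- min(tls, enh) + 1L
  b <- max(tls, enh) - 1L
  if (abs(enh - tls) < width) {
    lo <- max(lo, a)
    hi <- min(hi, b)
  }
  lo <- max(lo, 1L)
  hi <- min(hi, clen)
  if (hi < lo) return("")
  s <- Biostrings::subseq(genome[[chrom]], lo, hi)
  if (as.character(gene$strand) == "-") s <- Biostrings::reverseComplement(s)
  toupper(as.character(s))
}

#' Extract PROMOTER and MIDDLE sequences for every record of a dataset
#'
#' @param genome A named [Biostrings::DNAStringSet].
#' @param dataset A `timgo_dataset` or mutant-record data.frame with columns
#'   `line_id`, `gene_id`, `chrom`, `tls`, `strand`, `enhancer_pos`.
#' @param promoter_width,middle_width Window widths in bp.
#' @return A list with `promoter` and `middle`: character vectors named by
#'   record id (`<line_id>|<gene_id>`).
#' @export
extract_sequences <- function(genome, dataset, promoter_width = 1500L,
                              middle_width = 300L) {
  ids <- record_ids(dataset)
  n <- nrow(dataset)
  prom <- character(n)
  midd <- character(n)
  for (i in seq_len(n)) {
    gene <- dataset[i, ]
    prom[i] <- extract_promoter(genome, gene, promoter_width)
    midd[i] <- extract_middle(genome, gene, dataset$enhancer_pos[i],
                              width = middle_width)
  }
  names(prom) <- names(midd) <- ids
  list(promoter = prom, middle = midd)
}

#' Record identifiers used to key sequences and feature matrices
#' @param dataset Mutant-record data.frame.
#' @return Character vector `<line_id>|<gene_id>`.
#' @export
record_ids <- function(dataset) {
  paste(dataset$line_id, dataset$gene_id, sep = "|")
}

#' Write extracted sequences to FASTA
#'
#' Sequence IDs follow `<line_id>|<gene_id>|PROMOTER` and `...|MIDDLE`.
#'
#' @param sequences Result of [extract_sequences()].
#' @param path Output FASTA path.
#' @export
write_sequence_fasta <- function(sequences, path) {
  ids <- c(paste0(names(sequences$promoter), "|PROMOTER"),
           paste0(names(sequences$middle), "|MIDDLE"))
  seqs <- c(unname(sequences$promoter), unname(sequences$middle))
  keep <- nchar(seqs) > 0
  ss <- Biostrings::DNAStringSet(seqs[keep])
  names(ss) <- ids[keep]
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
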