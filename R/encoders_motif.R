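IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' Read a motif library
#'
#' A motif library is a TSV with columns `name` and `consensus`, one plant
#' cis-element consensus (IUPAC alphabet) per row. A compact built-in
#' library of common plant regulatory elements ships at
#' `system.file("extdata", "plant_motifs.tsv", package = "timgo")`; users
#' with access to the full PLACE / RegSite collections can supply their own
#' file in the same format.
#'
#' @param path TSV file path.
#' @return A `motif_library` data.frame with columns `name`, `consensus`.
#' @export
read_motif_library <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "plant_motifs.tsv", package = "timgo")
  }
  df <- read.delim(path, header = TRUE, sep = "\t",
                   colClasses = "character")
  if (!all(c("name", "consensus") %in% names(df))) {
    stop("motif library needs columns name, consensus")
  }
  df$consensus <- toupper(df$consensus)
  bad <- grepl(sprintf("[^%s]", paste(names(IUPAC_CODES), collapse = "")),
               df$consensus)
  if (any(bad)) {
    stop("non-IUPAC consensus: ", df$consensus[which(bad)[1]])
  }
  class(df) <- c("motif_library", "data.frame")
  df
}

# IUPAC consensus -> 4 x L position probability matrix. Bases allowed at a
# position share its probability mass uniformly; all bases then receive a
# 0.01 pseudocount and the column is renormalised, so mismatches score
# finitely.
iupac_ppm <- function(consensus, pseudocount = 0.01) {
  chars <- strsplit(consensus, "", fixed = TRUE)[[1]]
  ppm <- vapply(chars, function(ch) {
    allowed <- IUPAC_CODES[[ch]]
    p <- setNames(rep(0, 4), c("A", "C", "G", "T"))
    p[allowed] <- 1 / length(allowed)
    p <- p + pseudocount
    p / sum(p)
  }, numeric(4))
  rownames(ppm) <- c("A", "C", "G", "T")
  ppm
}

# Exact p-value lookup for PWM scores under a 0-order background, by
# dynamic programming over integer-discretised scores (the FIMO approach).
# Returns function(score) -> P(score' >= score) for a random background
# window.
pwm_score_pvalue <- function(lod, bg, granularity = 1000L) {
  m <- ncol(lod)
  rng <- sum(apply(lod, 2, max)) - sum(apply(lod, 2, min))
  scale <- if (rng > 0) granularity / rng else 1
  ilod <- round(lod * scale)
  offset <- apply(ilod, 2, min)
  ilod <- sweep(ilod, 2, offset)  # per-column scores now >= 0
  maxsum <- sum(apply(ilod, 2, max))
  pmf <- c(1, rep(0, maxsum))
  for (j in seq_len(m)) {
    new <- rep(0, maxsum + 1)
    for (b in 1:4) {
      s <- ilod[b, j]
      new[(s + 1):(maxsum + 1)] <- new[(s + 1):(maxsum + 1)] +
        bg[b] * pmf[1:(maxsum + 1 - s)]
    }
    pmf <- new
  }
  sf <- rev(cumsum(rev(pmf)))  # survival incl. the score itself
  off_total <- sum(offset)
  pval <- function(score) {
    i <- round(score * scale) - off_total
    i <- pmax(0, pmin(length(sf) - 1, i))
    sf[i + 1]
  }
  # smallest raw score whose exact p-value is <= p
  threshold <- function(p) {
    i <- which(sf <= p)
    if (length(i) == 0) return(Inf)
    (min(i) - 1 + off_total) / scale
  }
  list(pval = pval, threshold = threshold)
}

#' Scan promoter sequences for motif occurrences
#'
#' Each IUPAC consensus is converted to a position probability matrix and
#' scored as a log2 odds ratio against a 0-order background estimated from
#' the scanned sequences themselves (pooled base frequencies). Both strands
#' are scanned; a hit is reported where the exact score-distribution
#' p-value is at most `p_threshold`. Palindromic motifs matching the same
#' site on both strands are reported once, on the + strand.
#'
#' @param promoters Character vector of promoter sequences (names used as
#'   record ids).
#' @param lib A [read_motif_library()] object.
#' @param p_threshold Hit p-value cutoff (default 1e-4).
#' @param background Optional length-4 named base-frequency vector; by
#'   default estimated from `promoters`.
#' @return data.frame of hits: `seq_id`, `motif`, `start`, `end`, `strand`,
#'   `score`, `p_value`. Coordinates are 1-based on the scanned sequence.
#' @export
motif_scan <- function(promoters, lib, p_threshold = 1e-4,
                       background = NULL) {
  stopifnot(inherits(lib, "motif_library"))
  if (is.null(names(promoters))) {
    names(promoters) <- paste0("seq", seq_along(promoters))
  }
  promoters <- toupper(promoters)
  if (is.null(background)) {
    counts <- colSums(Biostrings::letterFrequency(
      Biostrings::DNAStringSet(promoters[nchar(promoters) > 0]),
      c("A", "C", "G", "T")))
    if (sum(counts) == 0) counts <- rep(1, 4)
    background <- counts / sum(counts)
  }
  bg <- pmax(background, 1e-6)
  bg <- bg / sum(bg)
  codes <- lapply(promoters, dna_codes)
  hits <- list()
  for (mi in seq_len(nrow(lib))) {
    ppm <- iupac_ppm(lib$consensus[mi])
    lod <- log2(ppm / bg)
    m <- ncol(lod)
    dist <- pwm_score_pvalue(lod, bg)
    s_min <- dist$threshold(p_threshold)
    if (!is.finite(s_min)) next
    for (si in seq_along(promoters)) {
      cd <- codes[[si]]
      L <- length(cd)
      if (L < m) next
      for (str in c("+", "-")) {
        use <- if (str == "+") lod else lod[4:1, m:1, drop = FALSE]
        sc <- numeric(L - m + 1)
        ok <- rep(TRUE, L - m + 1)
        for (j in seq_len(m)) {
          v <- use[, j][cd[j:(L - m + j)]]
          ok <- ok & !is.na(v)
          v[is.na(v)] <- 0
          sc <- sc + v
        }
        sel <- which(ok & sc >= s_min)
        if (length(sel) > 0) {
          hits[[length(hits) + 1]] <- data.frame(
            seq_id = names(promoters)[si], motif = lib$name[mi],
            start = sel, end = sel + m - 1L, strand = str,
            score = sc[sel], p_value = dist$pval(sc[sel]))
        }
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(seq_id = character(0), motif = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0),
                      p_value = numeric(0)))
  }
  out <- do.call(rbind, hits)
  # palindrome de-duplication: identical (seq, motif, coords) on both strands
  key <- paste(out$seq_id, out$motif, out$start, out$end)
  out <- out[order(key, out$strand != "+"), ]
  out <- out[!duplicated(paste(out$seq_id, out$motif, out$start, out$end)), ]
  out <- out[order(match(out$seq_id, names(promoters)), out$motif, out$start), ]
  rownames(out) <- NULL
  out
}

#' Summarise motif hits into the 4-per-motif feature block
#'
#' Per motif i over one promoter: `Number` = hit count; `Conserve` = summed
#' scan score / Number; `Orientation` = fraction of hits on the coding (+)
#' strand; `Dis` = mean distance in bp from each hit to the TLS. The three
#' ratio features are 0 when the motif is absent. The TLS sits immediately
#' 3' of the promoter, so a hit starting at position p is `L - p + 1` bp
#' from it.
#'
#' @param hits Hit table from [motif_scan()].
#' @param lib Motif library (defines the motif order of the output block).
#' @param seq_ids Record ids (row order of the output).
#' @param promoter_lengths Named vector of promoter lengths.
#' @return Numeric matrix with `4 * nrow(lib)` columns named
#'   `<motif>_number`, `<motif>_conserve`, `<motif>_orientation`,
#'   `<motif>_dis` (motif-major order).
#' @export
motif_features <- function(hits, lib, seq_ids, promoter_lengths) {
  nm <- nrow(lib)
  out <- matrix(0, nrow = length(seq_ids), ncol = 4 * nm)
  colnames(out) <- as.vector(t(outer(lib$name, c("number", "conserve",
                                                 "orientation", "dis"),
                                     paste, sep = "_")))
  rownames(out) <- seq_ids
  if (nrow(hits) > 0) {
    hits$dist_tls <- promoter_lengths[hits$seq_id] - hits$start + 1
    grp <- split(hits, list(hits$seq_id, hits$motif), drop = TRUE)
    for (g in grp) {
      i <- match(g$seq_id[1], seq_ids)
      if (is.na(i)) next
      j <- 4 * (match(g$motif[1], lib$name) - 1)
      n <- nrow(g)
      out[i, j + 1] <- n
      out[i, j + 2] <- sum(g$score) / n
      out[i, j + 3] <- sum(g$strand == "+") / n
      out[i, j + 4] <- sum(g$dist_tls) / n
    }
  }
  out
}
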