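#' K-mer specification
#'
#' Describes a (multi-)k-mer vocabulary: all oligonucleotides of lengths
#' `k_min` to `k_max`, optionally with reverse-complement pairs collapsed
#' into a single strand-agnostic class (RevKmer).
#'
#' @param k_min,k_max Inclusive k range, `k_min >= 1`.
#' @param collapse_revcomp Collapse each k-mer with its reverse complement
#'   (RevKmer encoding)?
#' @return A `kmer_spec` object.
#' @export
kmer_spec <- function(k_min, k_max = k_min, collapse_revcomp = FALSE) {
  k_min <- as.integer(k_min); k_max <- as.integer(k_max)
  if (is.na(k_min) || k_min < 1L) stop("k_min must be >= 1")
  if (k_max < k_min) stop("k_max must be >= k_min")
  structure(list(k_min = k_min, k_max = k_max,
                 collapse_revcomp = isTRUE(collapse_revcomp)),
            class = "kmer_spec")
}

#' Enumerate a k-mer vocabulary
#'
#' Vocabulary entries are ordered by k (ascending) then lexicographically
#' (A < C < G < T). When reverse complements are collapsed, each class is
#' represented by the lexicographically smaller of the k-mer and its
#' reverse complement. Sizes follow the closed forms sum(4^k) and
#' sum((4^k + p_k)/2) with p_k = 4^(k/2) palindromes for even k, 0 for odd.
#'
#' @param spec A [kmer_spec()].
#' @return Character vector of oligonucleotides (class representatives).
#' @export
kmer_vocabulary <- function(spec) {
  stopifnot(inherits(spec, "kmer_spec"))
  unlist(lapply(spec$k_min:spec$k_max, function(k) {
    words <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
    if (spec$collapse_revcomp) {
      rc <- revcomp(words)
      sort(unique(pmin(words, rc)))
    } else {
      words
    }
  }), use.names = FALSE)
}

# Per-k occurrence counting on the coding strand; windows containing a
# non-ACGT base are skipped (they match no vocabulary word).
kmer_counts_one_k <- function(seqs, k, collapse) {
  ss <- Biostrings::DNAStringSet(ifelse(nchar(seqs) >= k, seqs,
                                        strrep("N", k)))
  m <- Biostrings::oligonucleotideFrequency(ss, width = k)
  m[nchar(seqs) < k, ] <- 0
  if (collapse) {
    words <- colnames(m)
    rc <- revcomp(words)
    reps <- sort(unique(pmin(words, rc)))
    out <- m[, reps, drop = FALSE]
    nonpal <- reps != revcomp(reps)
    out[, nonpal] <- out[, nonpal] + m[, revcomp(reps)[nonpal], drop = FALSE]
    out
  } else {
    m
  }
}

#' Count k-mer occurrences
#'
#' Sliding-window occurrence counts of every vocabulary word on the given
#' (coding-strand) sequences: a word occurring twice is encoded as 2, an
#' absent word as 0. With `collapse_revcomp`, the count of a class is the
#' sum over the k-mer and its reverse complement (palindromes counted
#' once).
#'
#' @param seqs Character vector of DNA sequences (may be length 1).
#' @param spec A [kmer_spec()].
#' @param vocabulary Optional subset of [kmer_vocabulary()] columns to keep.
#' @return Numeric matrix, one row per sequence, one column per word.
#' @export
kmer_counts <- function(seqs, spec, vocabulary = NULL) {
  stopifnot(inherits(spec, "kmer_spec"))
  seqs <- toupper(seqs)
  m <- do.call(cbind, lapply(spec$k_min:spec$k_max, function(k) {
    kmer_counts_one_k(seqs, k, spec$collapse_revcomp)
  }))
  rownames(m) <- names(seqs)
  if (!is.null(vocabulary)) {
    missing <- setdiff(vocabulary, colnames(m))
    if (length(missing) > 0) {
      stop("vocabulary words outside the spec: ", paste(head(missing, 3),
                                                        collapse = ", "))
    }
    m <- m[, vocabulary, drop = FALSE]
  }
  m
}
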