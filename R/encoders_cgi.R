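#' Detect CpG islands
#'
#' Sliding-window CpG-island detection in the newcpgreport style: a CpG
#' island is a maximal region of at least `min_length` bp in which every
#' window of `window` bp has GC percentage >= `min_gc` and an
#' observed/expected CpG ratio >= `min_oe`, where
#' OE = count(CG) * window / (count(C) * count(G)).
#'
#' @param seq A DNA string.
#' @param window Sliding-window size in bp (default 100).
#' @param min_length Minimum island length in bp (default 200).
#' @param min_gc Minimum GC percentage per window (default 50).
#' @param min_oe Minimum observed/expected CpG ratio per window (default 0.6).
#' @return data.frame with one row per island: `start`, `end`, `length`,
#'   `gc_percent`, `oe`, `cpg_count` (island-level values computed over the
#'   full island with the same formula). Zero rows when no island is found
#'   or the sequence is shorter than `window`.
#' @export
detect_cgis <- function(seq, window = 100L, min_length = 200L,
                        min_gc = 50, min_oe = 0.6) {
  seq <- toupper(seq)
  L <- nchar(seq)
  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), gc_percent = numeric(0),
                      oe = numeric(0), cpg_count = integer(0))
  if (L < window || L < min_length) return(empty)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  is_c <- as.integer(chars == "C")
  is_g <- as.integer(chars == "G")
  is_cg <- as.integer(chars[-L] == "C" & chars[-1] == "G")
  cum_c <- c(0, cumsum(is_c))
  cum_g <- c(0, cumsum(is_g))
  cum_cg <- c(0, cumsum(is_cg))
  win_stats <- function(lo, hi) {
    n_c <- cum_c[hi + 1] - cum_c[lo]
    n_g <- cum_g[hi + 1] - cum_g[lo]
    n_cg <- cum_cg[hi] - cum_cg[lo]  # CG dinucleotides fully inside window
    len <- hi - lo + 1
    gc <- 100 * (n_c + n_g) / len
    oe <- ifelse(n_c * n_g > 0, n_cg * len / (n_c * n_g), 0)
    list(gc = gc, oe = oe, cpg = n_cg)
  }
  starts <- seq_len(L - window + 1L)
  st <- win_stats(starts, starts + window - 1L)
  pass <- st$gc >= min_gc & st$oe >= min_oe
  if (!any(pass)) return(empty)
  r <- rle(pass)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  keep <- which(r$values)
  islands <- lapply(keep, function(i) {
    lo <- run_start[i]
    hi <- run_end[i] + window - 1L
    if (hi - lo + 1L < min_length) return(NULL)
    s <- win_stats(lo, hi)
    data.frame(start = lo, end = hi, length = hi - lo + 1L,
               gc_percent = s$gc, oe = s$oe, cpg_count = s$cpg)
  })
  islands <- islands[!vapply(islands, is.null, logical(1))]
  if (length(islands) == 0) return(empty)
  out <- do.call(rbind, islands)
  rownames(out) <- NULL
  out
}

#' Aggregate CpG islands into the 5-dimensional CGI feature vector
#'
#' Features: number of islands, total island length, mean island distance
#' to the TLS, mean island GC percentage, and mean observed/expected CpG
#' ratio. The TLS is taken to sit immediately 3' of the sequence (position
#' `seq_length + 1 + tls_offset`); the distance of an island is measured
#' from its 3' end, so an island ending at the sequence's 3' end has
#' distance `tls_offset`. All mean fields are 0 when there is no island.
#'
#' @param islands data.frame from [detect_cgis()].
#' @param seq_length Length of the scanned sequence.
#' @param tls_offset Gap in bp between the sequence 3' end and the TLS
#'   (default 0: the promoter window abuts the TLS).
#' @return Named numeric vector of length 5.
#' @export
cgi_features <- function(islands, seq_length, tls_offset = 0) {
  if (nrow(islands) == 0) {
    return(c(n_islands = 0, total_length = 0, mean_distance_to_tls = 0,
             mean_gc_percent = 0, mean_oe = 0))
  }
  dist <- (seq_length - islands$end) + tls_offset
  c(n_islands = nrow(islands),
    total_length = sum(islands$length),
    mean_distance_to_tls = mean(dist),
    mean_gc_percent = mean(islands$gc_percent),
    mean_oe = mean(islands$oe))
}

# CGI feature matrix over a set of sequences.
cgi_feature_matrix <- function(seqs, window = 100L, min_length = 200L,
                               min_gc = 50, min_oe = 0.6) {
  m <- t(vapply(seqs, function(s) {
    cgi_features(detect_cgis(s, window, min_length, min_gc, min_oe),
                 seq_length = nchar(s))
  }, numeric(5)))
  rownames(m) <- names(seqs)
  m
}
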