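#' Read an oligonucleotide physicochemical property table
#'
#' A property table is a TSV whose first column `oligo` lists every
#' dinucleotide (16 rows) or trinucleotide (64 rows) and whose remaining
#' columns each hold one named physicochemical property. The package ships
#' two synthetic tables in this format -- 15 dinucleotide properties and 12
#' trinucleotide properties, matching the dimensionalities of the
#' DiProDB-derived and Pse-in-One property sets -- under
#' `system.file("extdata", ..., package = "timgo")`; users can substitute
#' real property compilations in the same format.
#'
#' @param path TSV path, or one of the shortcuts `"dinucleotide"` /
#'   `"trinucleotide"` for the bundled synthetic tables.
#' @return A `property_table`: list with `unit` (2 or 3), `oligos`,
#'   and `values` (oligos x properties numeric matrix, standardized to
#'   mean 0 / sd 1 per property across oligonucleotides).
#' @export
read_property_table <- function(path = "dinucleotide") {
  if (path %in% c("dinucleotide", "trinucleotide")) {
    fname <- sprintf("%s_properties_synthetic.tsv", path)
    path <- system.file("extdata", fname, package = "timgo")
  }
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (names(df)[1] != "oligo") stop("first column must be 'oligo'")
  oligos <- toupper(df$oligo)
  unit <- unique(nchar(oligos))
  if (length(unit) != 1 || !unit %in% c(2, 3)) {
    stop("oligos must be all dinucleotides or all trinucleotides")
  }
  expected <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), unit)
  if (!setequal(oligos, expected)) {
    stop(sprintf("table must cover all %d oligonucleotides of length %d",
                 length(expected), unit))
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (any(!is.finite(vals))) stop("non-numeric property values")
  rownames(vals) <- oligos
  vals <- vals[expected, , drop = FALSE]
  vals <- scale(vals)  # standardized across oligonucleotides
  attr(vals, "scaled:center") <- attr(vals, "scaled:scale") <- NULL
  structure(list(unit = as.integer(unit), oligos = expected,
                 values = vals, properties = colnames(vals)),
            class = "property_table")
}

# Overlapping-unit relative frequencies of a sequence; units containing a
# non-ACGT base are skipped.
unit_frequencies <- function(seq, unit) {
  ss <- Biostrings::DNAStringSet(if (nchar(seq) >= unit) seq
                                 else strrep("N", unit))
  cnt <- Biostrings::oligonucleotideFrequency(ss, width = unit)[1, ]
  tot <- sum(cnt)
  if (tot == 0) cnt else cnt / tot
}

#' Physicochemical composition encoding (DNP / TNP)
#'
#' Each feature is the relative frequency of one oligonucleotide in the
#' sequence multiplied by the value of one property for that
#' oligonucleotide; dimension = properties x oligonucleotides (240 for the
#' 15-property dinucleotide table, 768 for the 12-property trinucleotide
#' table).
#'
#' @param seqs Character vector of DNA sequences.
#' @param table A [read_property_table()] object.
#' @return Numeric matrix, one row per sequence, columns named
#'   `<property>_<oligo>` (property-major order).
#' @export
property_encode <- function(seqs, table) {
  stopifnot(inherits(table, "property_table"))
  np <- ncol(table$values)
  no <- length(table$oligos)
  out <- matrix(0, nrow = length(seqs), ncol = np * no)
  colnames(out) <- as.vector(vapply(table$properties, function(p) {
    paste(p, table$oligos, sep = "_")
  }, character(no)))
  rownames(out) <- names(seqs)
  for (i in seq_along(seqs)) {
    f <- unit_frequencies(seqs[i], table$unit)
    out[i, ] <- as.vector(vapply(seq_len(np), function(p) {
      f * table$values[, p]
    }, numeric(no)))
  }
  out
}

# Property-value signal along a sequence: W x n_properties matrix, one row
# per overlapping unit; units containing N give NA rows.
property_signal <- function(seq, table) {
  unit <- table$unit
  L <- nchar(seq)
  W <- L - unit + 1L
  if (W < 1) stop("sequence shorter than the oligonucleotide unit")
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  words <- vapply(seq_len(W), function(i) {
    paste(chars[i:(i + unit - 1)], collapse = "")
  }, character(1))
  idx <- match(words, table$oligos)
  table$values[idx, , drop = FALSE]
}

#' Auto-cross covariance encoding (DACC / TACC)
#'
#' Treats each standardized physicochemical property as a signal along the
#' sequence's overlapping di-/trinucleotide units and encodes, for lags
#' g = 1..lag, the autocovariance of every property (AC) and the cross
#' covariance of every ordered property pair (CC):
#' AC(p,g) = mean over i of (v_p(i) - vbar_p)(v_p(i+g) - vbar_p), and
#' analogously for pairs. Dimension = N*lag + N*(N-1)*lag for N properties
#' (15 -> 900, 12 -> 576).
#'
#' @param seqs Character vector of DNA sequences.
#' @param table A [read_property_table()] object.
#' @param lag Maximum lag g (default 4); every sequence must have more
#'   units than `lag`.
#' @return Numeric matrix; AC columns (`AC_<prop>_lag<g>`) then CC columns
#'   (`CC_<p1>_<p2>_lag<g>`), deterministic order.
#' @export
acc_encode <- function(seqs, table, lag = 4L) {
  stopifnot(inherits(table, "property_table"))
  np <- ncol(table$values)
  props <- table$properties
  pairs <- subset(expand.grid(p2 = seq_len(np), p1 = seq_len(np)),
                  p1 != p2)[, c("p1", "p2")]
  pairs <- pairs[order(pairs$p1, pairs$p2), ]
  ac_names <- as.vector(vapply(props, function(p)
    paste0("AC_", p, "_lag", seq_len(lag)), character(lag)))
  cc_names <- as.vector(mapply(function(a, b)
    paste0("CC_", props[a], "_", props[b], "_lag", seq_len(lag)),
    pairs$p1, pairs$p2))
  out <- matrix(0, nrow = length(seqs),
                ncol = np * lag + nrow(pairs) * lag)
  colnames(out) <- c(ac_names, cc_names)
  rownames(out) <- names(seqs)
  for (i in seq_along(seqs)) {
    sig <- property_signal(seqs[i], table)
    keep <- stats::complete.cases(sig)
    sig <- sig[keep, , drop = FALSE]
    W <- nrow(sig)
    if (W <= lag) {
      stop(sprintf("sequence %d has %d units (<= lag %d)", i, W, lag))
    }
    centered <- sweep(sig, 2, colMeans(sig))
    cov_lag <- function(a, b, g) {
      sum(centered[1:(W - g), a] * centered[(1 + g):W, b]) / (W - g)
    }
    col <- 1L
    for (p in seq_len(np)) for (g in seq_len(lag)) {
      out[i, col] <- cov_lag(p, p, g); col <- col + 1L
    }
    for (r in seq_len(nrow(pairs))) for (g in seq_len(lag)) {
      out[i, col] <- cov_lag(pairs$p1[r], pairs$p2[r], g); col <- col + 1L
    }
  }
  out
}

#' Pseudo k-tuple nucleotide composition (PseKNC)
#'
#' Combines local k-tuple composition with global sequence-order
#' information. The first 4^k components are the normalized k-tuple
#' frequencies f_u / (1 + w * sum(theta)); the last `lambda` components are
#' w * theta_j / (1 + w * sum(theta)), where theta_j is the mean squared
#' difference of the `mu` standardized dinucleotide property values between
#' all dinucleotide pairs j positions apart. All components sum to 1.
#'
#' @param seqs Character vector of DNA sequences.
#' @param k Tuple size (the frequency part uses 4^k k-tuples).
#' @param lambda Number of correlation tiers (default 4); must be smaller
#'   than every sequence length.
#' @param w Weight factor for the correlation part (default 0.2).
#' @param table Dinucleotide [read_property_table()] used for theta
#'   (defaults to the bundled table); its column count is mu.
#' @return Numeric matrix with `4^k + lambda` columns.
#' @export
pseknc_encode <- function(seqs, k = 2L, lambda = 4L, w = 0.2,
                          table = read_property_table("dinucleotide")) {
  stopifnot(inherits(table, "property_table"), table$unit == 2L)
  k <- as.integer(k); lambda <- as.integer(lambda)
  if (k < 1) stop("k must be >= 1")
  tuples <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  out <- matrix(0, nrow = length(seqs), ncol = 4^k + lambda)
  colnames(out) <- c(paste0("f_", tuples), paste0("theta_", seq_len(lambda)))
  rownames(out) <- names(seqs)
  for (i in seq_along(seqs)) {
    L <- nchar(seqs[i])
    if (lambda >= L - 1) {
      stop(sprintf("lambda (%d) must be < sequence length (%d)", lambda, L))
    }
    f <- unit_frequencies(seqs[i], k)
    if (sum(f) == 0) stop("sequence has no unambiguous k-tuple")
    sig <- property_signal(seqs[i], table)  # (L-1) x mu dinucleotide values
    mu <- ncol(sig)
    theta <- vapply(seq_len(lambda), function(j) {
      n_pairs <- nrow(sig) - j
      d2 <- (sig[1:n_pairs, , drop = FALSE] -
             sig[(1 + j):nrow(sig), , drop = FALSE])^2
      mean(rowSums(d2, na.rm = TRUE) / mu, na.rm = TRUE)
    }, numeric(1))
    denom <- 1 + w * sum(theta)
    out[i, ] <- c(f / denom, w * theta / denom)
  }
  out
}
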