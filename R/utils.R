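# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a stream-specific child seed from a base seed (kept < 2^31).
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream * 16807) %% 2147483647
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# DNA string -> integer codes A=1 C=2 G=3 T=4, NA for anything else.
dna_codes <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  match(chars, c("A", "C", "G", "T"))
}

# Stratified fold assignment: within each class, records are shuffled and
# dealt round-robin into k folds.
stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# Fit [-1, 1] min-max scaling on the training matrix; constant columns map
# to 0 so they carry no information.
fit_scaler <- function(x) {
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  list(lo = lo, hi = hi, span = ifelse(hi > lo, hi - lo, 1))
}

apply_scaler <- function(scaler, x) {
  x <- sweep(x, 2, scaler$lo, "-")
  x <- sweep(x, 2, scaler$span, "/")
  x <- 2 * x - 1
  const <- scaler$hi == scaler$lo
  if (any(const)) x[, const] <- 0
  pmin(pmax(x, -1), 1)
}
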