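# Shared fixtures, built in code at test time.

# A small deterministic mutant table written to a temp TSV.
make_mutant_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

toy_mutants <- function() {
  data.frame(
    line_id = sprintf("L%02d", 1:6),
    gene_id = sprintf("g%02d", 1:6),
    chrom = "chr1",
    tls = c(1000L, 2000L, 3000L, 4000L, 5000L, 6000L),
    strand = c("+", "-", "+", "+", "-", "+"),
    enhancer_pos = c(3500L, 1200L, 2100L, 9000L, 4800L, 6600L),
    status = c("Ac", "Ac", "NE", "NE", "ND", "Ko"),
    stringsAsFactors = FALSE)
}

# A toy genome: one contig with a recognisable base pattern so coordinate
# arithmetic can be checked against direct slicing.
toy_genome <- function(len = 10000L, seed = 5L) {
  set.seed(seed)
  s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
             collapse = "")
  g <- Biostrings::DNAStringSet(s)
  names(g) <- "chr1"
  g
}

slice <- function(genome, chrom, lo, hi) {
  as.character(Biostrings::subseq(genome[[chrom]], lo, hi))
}

rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# A small simulated panel shared by model-level tests (cached per session).
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_records = 80L, seed = 7L)
      sim <- simulate_dataset(cfg)
      ds <- filter_dataset(sim$records, quiet = TRUE)
      sq <- extract_sequences(sim$genome, ds)
      cache <<- list(cfg = cfg, sim = sim, ds = ds, sq = sq)
    }
    cache
  }
})

# Shared encoded features for the 80-record panel (k = 2 and 4 PseKNC
# candidates cover every configuration the tests use).
shared_conf <- function() timgo_config(pseknc_k_range = c(2L, 4L))

shared_fs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- encode_features(shared_sim()$sq, shared_conf())
    }
    cache
  }
})

# One trained two-layer model on the shared panel.
shared_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- shared_sim()
      cache <<- suppressWarnings(
        train_timgo(shared_fs(), fx$ds$label, fx$ds$distance_bp,
                    shared_conf(), seed = 21))
    }
    cache
  }
})
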