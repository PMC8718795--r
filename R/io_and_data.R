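#' @importFrom stats glm binomial coef predict var sd setNames quantile
#'   rbinom rnorm runif pt plogis fitted vcov complete.cases
#' @importFrom utils read.delim write.table head tail packageVersion
NULL

STATUS_LEVELS <- c("Ac", "NE", "ND", "Ko")

MUTANT_COLUMNS <- c("line_id", "gene_id", "chrom", "tls", "strand",
                    "enhancer_pos", "status")

#' Read a mutant table
#'
#' Reads a tab-separated table of experimentally validated T-DNA insertion
#' events. Each row pairs one target gene with one insertion event: the
#' gene's translation start site (TLS, first base of the start codon,
#' 1-based), the genomic coordinate of the 35S enhancer on the inserted
#' T-DNA, and the RT-PCR expression status of the gene in that mutant line.
#'
#' @param path Path to a TSV file with header columns `line_id`, `gene_id`,
#'   `chrom`, `tls`, `strand`, `enhancer_pos`, `status`.
#' @return A `data.frame` of mutant records with an added `distance_bp`
#'   column, the absolute enhancer-TLS distance in base pairs. Status is a
#'   factor with levels `Ac`, `NE`, `ND`, `Ko` (activated, no significant
#'   effect, non-detectable, knockout).
#' @export
read_mutant_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t",
                   colClasses = "character", check.names = FALSE)
  missing <- setdiff(MUTANT_COLUMNS, names(df))
  if (length(missing) > 0) {
    stop("mutant table is missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- df[, MUTANT_COLUMNS]
  for (col in c("tls", "enhancer_pos")) {
    val <- suppressWarnings(as.integer(df[[col]]))
    bad <- which(is.na(val) & !is.na(df[[col]]))
    if (length(bad) > 0) {
      stop(sprintf("non-integer %s at row %d: '%s'", col, bad[1], df[[col]][bad[1]]))
    }
    df[[col]] <- val
  }
  bad_status <- which(!df$status %in% STATUS_LEVELS)
  if (length(bad_status) > 0) {
    stop(sprintf("unknown status '%s' at row %d (expected one of %s)",
                 df$status[bad_status[1]], bad_status[1],
                 paste(STATUS_LEVELS, collapse = "/")))
  }
  bad_strand <- which(!df$strand %in% c("+", "-"))
  if (length(bad_strand) > 0) {
    stop(sprintf("invalid strand '%s' at row %d", df$strand[bad_strand[1]],
                 bad_strand[1]))
  }
  if (any(df$tls < 1L) || any(df$enhancer_pos < 1L)) {
    stop("coordinates must be 1-based positive integers")
  }
  df$status <- factor(df$status, levels = STATUS_LEVELS)
  df$distance_bp <- abs(df$enhancer_pos - df$tls)
  class(df) <- c("mutant_table", "data.frame")
  df
}

#' Write a mutant table
#'
#' Inverse of [read_mutant_table()]; the derived `distance_bp` column is not
#' written (it is recomputed on read).
#'
#' @param records Mutant record data.frame.
#' @param path Output TSV path.
#' @export
write_mutant_table <- function(records, path) {
  out <- as.data.frame(records)[, MUTANT_COLUMNS]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter mutant records into a binary-labelled dataset
#'
#' Applies the dataset assembly rules: non-detectable (ND) and knockout (Ko)
#' genes are removed, and NE ("no significant effect") genes are relabelled
#' as nonactivated (NAc). The result carries a two-level `label` column,
#' `Ac` (positive) vs `NAc` (negative).
#'
#' @param records Mutant records as returned by [read_mutant_table()].
#' @param quiet Suppress the dropped-record message.
#' @return A `timgo_dataset` data.frame restricted to Ac/NAc records.
#' @export
filter_dataset <- function(records, quiet = FALSE) {
  records <- as.data.frame(records)
  drop <- records$status %in% c("ND", "Ko")
  kept <- records[!drop, , drop = FALSE]
  if (nrow(kept) == 0) {
    stop("no Ac/NE records remain after filtering; nothing to train on")
  }
  if (!quiet && any(drop)) {
    tab <- table(factor(records$status[drop], levels = c("ND", "Ko")))
    message(sprintf("dropped %d record(s): %d ND, %d Ko",
                    sum(drop), tab[["ND"]], tab[["Ko"]]))
  }
  kept$label <- factor(ifelse(as.character(kept$status) == "Ac", "Ac", "NAc"),
                       levels = c("NAc", "Ac"))
  rownames(kept) <- NULL
  class(kept) <- c("timgo_dataset", "data.frame")
  kept
}

#' Balanced training / independent-testing split
#'
#' Draws `n_train_per_class` records uniformly at random from each class
#' (Ac and NAc) to form a 1:1 balanced training set; everything else
#' becomes the independent testing set.
#'
#' @param dataset A `timgo_dataset` (see [filter_dataset()]).
#' @param n_train_per_class Number of records per class in the training set.
#' @param seed Integer seed; the same seed reproduces the same partition.
#' @return A list with elements `train` and `test`.
#' @export
balanced_split <- function(dataset, n_train_per_class, seed) {
  stopifnot(is.data.frame(dataset), "label" %in% names(dataset))
  counts <- table(dataset$label)
  for (cls in c("Ac", "NAc")) {
    if (counts[[cls]] < n_train_per_class) {
      stop(sprintf("class %s has only %d records (< %d requested)",
                   cls, counts[[cls]], n_train_per_class))
    }
  }
  idx_pos <- which(dataset$label == "Ac")
  idx_neg <- which(dataset$label == "NAc")
  take <- with_seed(seed, {
    sort(c(sample(idx_pos, n_train_per_class),
           sample(idx_neg, n_train_per_class)))
  })
  train <- dataset[take, , drop = FALSE]
  test <- dataset[-take, , drop = FALSE]
  rownames(train) <- rownames(test) <- NULL
  class(train) <- class(test) <- c("timgo_dataset", "data.frame")
  list(train = train, test = test)
}

#' Extract gene annotations (TLS anchors) from a GFF3 file
#'
#' The translation start site of each gene is taken from its CDS features,
#' strand-aware: the minimum CDS start on the + strand, the maximum CDS end
#' on the - strand. When several transcripts are annotated the representative
#' (first-listed) transcript's CDS set is used.
#'
#' @param path GFF3 file path.
#' @return data.frame with columns `gene_id`, `chrom`, `tls`, `strand`.
#' @export
read_gene_annotations <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  cds <- gr[gr$type == "CDS"]
  if (length(cds) == 0) stop("no CDS features in ", path)
  parent <- vapply(S4Vectors::mcols(cds)$Parent, function(p) {
    if (length(p) == 0) NA_character_ else p[[1]]
  }, character(1))
  mrna <- gr[gr$type %in% c("mRNA", "transcript")]
  tx2gene <- setNames(
    vapply(S4Vectors::mcols(mrna)$Parent, function(p) {
      if (length(p) == 0) NA_character_ else p[[1]]
    }, character(1)),
    S4Vectors::mcols(mrna)$ID)
  gene_of <- ifelse(parent %in% names(tx2gene), tx2gene[parent], parent)
  # representative transcript = first mRNA listed per gene
  rep_tx <- tapply(S4Vectors::mcols(mrna)$ID, tx2gene, `[`, 1)
  use <- !(parent %in% names(tx2gene)) | parent == rep_tx[gene_of]
  cds <- cds[use]
  gene_of <- gene_of[use]
  df <- data.frame(
    gene_id = gene_of,
    chrom = as.character(GenomicRanges::seqnames(cds)),
    start = GenomicRanges::start(cds),
    end = GenomicRanges::end(cds),
    strand = as.character(GenomicRanges::strand(cds)),
    stringsAsFactors = FALSE)
  parts <- split(df, df$gene_id)
  out <- do.call(rbind, lapply(parts, function(d) {
    tls <- if (d$strand[1] == "+") min(d$start) else max(d$end)
    data.frame(gene_id = d$gene_id[1], chrom = d$chrom[1], tls = tls,
               strand = d$strand[1], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
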