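#' Simulation configuration for synthetic mutant panels
#'
#' Describes a synthetic activation-tagging panel: each record is one
#' T-DNA insertion event next to one gene. The enhancer-TLS distance is
#' drawn log-uniformly; the activation label is Bernoulli with probability
#' `plogis(beta0 + beta1 * distance)` (negative `beta1`: activation falls
#' off with distance); conditional on the label, each configured motif is
#' planted into the promoter with the class-specific probability, at a
#' uniform position and in a random orientation. Defaults give a roughly
#' balanced panel with a strong G-box enrichment in activated promoters
#' and a weaker secondary ABRE-like signal, over a rice-like 44% GC
#' background.
#'
#' @param n_records Number of insertion events.
#' @param distance_range Log-uniform distance range in bp.
#' @param beta0,beta1 True logistic intercept and slope (per bp).
#' @param motifs data.frame with columns `name`, `consensus` (IUPAC),
#'   `p_ac`, `p_nac` (planting probabilities per class).
#' @param gc Background GC content.
#' @param promoter_width Promoter window the motifs are planted into.
#' @param contig_length Maximum synthetic contig length; gene cassettes
#'   are laid out left to right and overflow onto new contigs.
#' @param seed Integer seed; the same configuration and seed give
#'   byte-identical output files.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_records = 300L,
                       distance_range = c(200, 40000),
                       beta0 = 1.25, beta1 = -1.5e-4,
                       motifs = data.frame(
                         name = c("GBOX_PLANT", "ABRE_LIKE"),
                         consensus = c("CACGTG", "ACGTGGC"),
                         p_ac = c(0.9, 0.5),
                         p_nac = c(0.1, 0.2),
                         stringsAsFactors = FALSE),
                       gc = 0.44, promoter_width = 1500L,
                       contig_length = 1e6, seed = 1L) {
  stopifnot(n_records >= 1, distance_range[1] >= 1,
            distance_range[2] >= distance_range[1],
            beta1 <= 0, gc > 0, gc < 1)
  if (!is.null(motifs) && nrow(motifs) > 0) {
    stopifnot(all(c("name", "consensus", "p_ac", "p_nac") %in%
                    names(motifs)),
              all(motifs$p_ac >= 0 & motifs$p_ac <= 1),
              all(motifs$p_nac >= 0 & motifs$p_nac <= 1))
  }
  structure(list(n_records = as.integer(n_records),
                 distance_range = distance_range,
                 beta0 = beta0, beta1 = beta1, motifs = motifs,
                 gc = gc, promoter_width = as.integer(promoter_width),
                 contig_length = contig_length, seed = as.integer(seed)),
            class = "sim_config")
}

random_dna <- function(n, gc) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(probs), n, replace = TRUE, prob = probs),
        collapse = "")
}

# Resolve an IUPAC consensus to one concrete realization.
realize_iupac <- function(consensus) {
  chars <- strsplit(consensus, "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(ch) {
    allowed <- IUPAC_CODES[[ch]]
    allowed[sample.int(length(allowed), 1)]
  }, character(1)), collapse = "")
}

#' Simulate a synthetic mutant panel
#'
#' Generates a genome (one or more contigs), gene annotations, a mutant
#' table, and a truth table of all latent draws. Gene cassettes are laid
#' out left to right so genes never overlap; a cassette that cannot fit
#' on an empty contig raises an error. Each gene gets an ATG at its TLS
#' and a 300-bp CDS; strands alternate at random. When `dir` is given the
#' four standard files (`genome.fa`, `genes.gff3`, `mutants.tsv`,
#' `truth.tsv`) are written there.
#'
#' @param cfg A [sim_config()].
#' @param dir Optional output directory.
#' @return List: `genome` ([Biostrings::DNAStringSet]), `annotations`
#'   (gene_id/chrom/tls/strand), `records` (mutant table with status
#'   `Ac`/`NE`), `truth` (per-record latent draws: distance, activation
#'   probability, label, planted motif indicators), `files` (paths, when
#'   written).
#' @export
simulate_dataset <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  pw <- cfg$promoter_width
  n_motifs <- if (is.null(cfg$motifs)) 0L else nrow(cfg$motifs)

  res <- with_seed(cfg$seed, {
    d <- round(exp(runif(cfg$n_records, log(cfg$distance_range[1]),
                         log(cfg$distance_range[2]))))
    p_act <- plogis(cfg$beta0 + cfg$beta1 * d)
    label <- rbinom(cfg$n_records, 1, p_act)
    strand <- sample(c("+", "-"), cfg$n_records, replace = TRUE)

    contigs <- list()
    cur <- character(0)   # cassette strings of the contig under construction
    cur_len <- 0
    rec <- vector("list", cfg$n_records)
    planted <- matrix(0L, cfg$n_records, max(1, n_motifs))

    for (i in seq_len(cfg$n_records)) {
      lead <- max(pw, d[i]) + 100L  # bases 5' of the TLS in the cassette
      cass_len <- lead + 400L       # room for the 300-bp CDS + pad
      if (cass_len > cfg$contig_length) {
        stop(sprintf(
          "infeasible placement: cassette of %d bp exceeds contig length %g",
          cass_len, cfg$contig_length))
      }
      # promoter on the coding strand, with planted motifs
      prom <- random_dna(pw, cfg$gc)
      if (n_motifs > 0) {
        for (m in seq_len(n_motifs)) {
          p_plant <- if (label[i] == 1) cfg$motifs$p_ac[m] else
            cfg$motifs$p_nac[m]
          if (runif(1) < p_plant) {
            site <- realize_iupac(cfg$motifs$consensus[m])
            if (runif(1) < 0.5) site <- revcomp(site)
            pos <- sample.int(pw - nchar(site) + 1L, 1)
            substr(prom, pos, pos + nchar(site) - 1L) <- site
            planted[i, m] <- 1L
          }
        }
      }
      body <- random_dna(cass_len - pw, cfg$gc)
      # cassette on the coding strand: [pad][promoter][ATG + CDS ...]
      cass <- paste0(substr(body, 1, lead - pw), prom,
                     "ATG", substr(body, lead - pw + 4, cass_len - pw))
      tls_local <- lead + 1L
      if (strand[i] == "-") {
        cass <- revcomp(cass)
        tls_local <- cass_len - tls_local + 1L
      }
      if (cur_len + cass_len > cfg$contig_length && cur_len > 0) {
        contigs[[length(contigs) + 1]] <- paste(cur, collapse = "")
        cur <- character(0); cur_len <- 0
      }
      offset <- cur_len
      cur <- c(cur, cass); cur_len <- cur_len + cass_len
      tls <- offset + tls_local
      enh <- if (strand[i] == "+") tls - d[i] else tls + d[i]
      rec[[i]] <- data.frame(
        line_id = sprintf("M%04d", i), gene_id = sprintf("g%04d", i),
        chrom = sprintf("chrS%02d", length(contigs) + 1L),
        tls = tls, strand = strand[i], enhancer_pos = enh,
        stringsAsFactors = FALSE)
    }
    if (cur_len > 0) contigs[[length(contigs) + 1]] <- paste(cur,
                                                             collapse = "")
    list(d = d, p_act = p_act, label = label, rec = do.call(rbind, rec),
         contigs = contigs, planted = planted)
  })

  genome <- Biostrings::DNAStringSet(unlist(res$contigs))
  names(genome) <- sprintf("chrS%02d", seq_along(res$contigs))
  records <- res$rec
  records$status <- ifelse(res$label == 1, "Ac", "NE")
  records$distance_bp <- abs(records$enhancer_pos - records$tls)
  annotations <- records[, c("gene_id", "chrom", "tls", "strand")]
  truth <- data.frame(records[, c("line_id", "gene_id", "distance_bp")],
                      p_activation = res$p_act,
                      label = ifelse(res$label == 1, "Ac", "NAc"),
                      stringsAsFactors = FALSE)
  if (n_motifs > 0) {
    pm <- res$planted
    colnames(pm) <- paste0("planted_", cfg$motifs$name)
    truth <- cbind(truth, pm)
  }

  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- list(genome = file.path(dir, "genome.fa"),
                  gff = file.path(dir, "genes.gff3"),
                  mutants = file.path(dir, "mutants.tsv"),
                  truth = file.path(dir, "truth.tsv"))
    Biostrings::writeXStringSet(genome, files$genome)
    write_simple_gff3(annotations, files$gff)
    write_mutant_table(records, files$mutants)
    write.table(truth, files$truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  list(genome = genome, annotations = annotations, records = records,
       truth = truth, files = files)
}

# Minimal GFF3 writer: gene -> mRNA -> single 300-bp CDS anchored at the
# TLS, strand-aware.
write_simple_gff3 <- function(annotations, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    if (a$strand == "+") {
      lo <- a$tls; hi <- a$tls + 299L
    } else {
      lo <- a$tls - 299L; hi <- a$tls
    }
    gid <- a$gene_id
    writeLines(c(
      sprintf("%s\ttimgo_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              a$chrom, lo, hi, a$strand, gid),
      sprintf("%s\ttimgo_sim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.1;Parent=%s",
              a$chrom, lo, hi, a$strand, gid, gid),
      sprintf("%s\ttimgo_sim\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.1.cds;Parent=%s.1",
              a$chrom, lo, hi, a$strand, gid, gid)), con)
  }
  invisible(path)
}

#' Empirical activation fraction per distance bin
#'
#' Bins the truth table by enhancer-TLS distance and reports the fraction
#' of activated records in each bin; with a negative distance slope the
#' expected curve is monotonically non-increasing. Empty bins are flagged,
#' not interpolated.
#'
#' @param truth Truth table from [simulate_dataset()] (needs
#'   `distance_bp` and `label`).
#' @param edges_kb Bin edges in kb.
#' @return data.frame: `bin`, `n`, `ac_fraction` (`NA` when empty),
#'   `empty`.
#' @export
distance_activation_curve <- function(truth,
                                      edges_kb = c(0, 2, 5, 10, 15, 20,
                                                   25, Inf)) {
  bin <- cut(truth$distance_bp / 1000, edges_kb, right = TRUE)
  ac <- truth$label == "Ac"
  n <- as.vector(table(bin))
  n_ac <- vapply(levels(bin), function(b) sum(ac[!is.na(bin) & bin == b]),
                 numeric(1))
  data.frame(bin = levels(bin), n = n, n_ac = n_ac,
             ac_fraction = ifelse(n > 0, n_ac / n, NA_real_),
             empty = n == 0)
}
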