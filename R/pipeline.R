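#' Pipeline configuration
#'
#' Collects the tunable parameters of the two-layer pipeline with their
#' defaults. K-mer ranges are `c(k_min, k_max)`; the PROMOTER default of
#' 3-6 is the smallest of the studied multi-k combinations (3-6 up to
#' 3-9) and keeps the count matrices tractable; larger maxima trade
#' memory/time for accuracy. PseKNC uses lambda = 4 correlation tiers and
#' weight w = 0.2, with the tuple size k chosen per region by internal
#' CV. The auto-cross covariance lag is 4. The motif scan threshold is
#' the conventional 1e-4 exact p-value. SVM tuning is a small
#' cross-validated grid over cost and gamma (gamma expressed as multiples
#' of the 1/n_features heuristic).
#'
#' @param kmer_k_promoter,kmer_k_middle K ranges for the PROMOTER and
#'   MIDDLE count encodings.
#' @param pseknc_k_range Candidate PseKNC tuple sizes (per-region CV pick).
#' @param pseknc_lambda,pseknc_w PseKNC correlation tiers and weight.
#' @param acc_lag DACC/TACC maximum lag.
#' @param motif_p Motif-scan exact p-value threshold.
#' @param cgi_window,cgi_min_length,cgi_min_gc,cgi_min_oe CpG-island
#'   detection parameters (newcpgreport conventions).
#' @param alpha Fragment-selection t-test level.
#' @param fscore Apply Fisher-score selection (CV-chosen cutoff) to the
#'   count-based (k-mer / RevKmer / motif) models after the t-test
#'   filter, as LIBSVM's fselect does.
#' @param svm_cost,svm_gamma_mult SVM tuning grid.
#' @param tune_folds Internal CV folds for SVM tuning and k selection.
#' @param stack_folds Stacking folds generating out-of-fold meta-features
#'   for the second layer.
#' @param sel_folds CV folds inside incremental meta-feature selection.
#' @param n_boost LADTree boosting iterations.
#' @param mrmr_bins mRMR discretization bins.
#' @return A `timgo_config` list.
#' @export
timgo_config <- function(kmer_k_promoter = c(3L, 6L),
                         kmer_k_middle = c(3L, 5L),
                         pseknc_k_range = 2:6,
                         pseknc_lambda = 4L, pseknc_w = 0.2,
                         acc_lag = 4L, motif_p = 1e-4,
                         cgi_window = 100L, cgi_min_length = 200L,
                         cgi_min_gc = 50, cgi_min_oe = 0.6,
                         alpha = 0.05, fscore = TRUE,
                         svm_cost = c(1, 32),
                         svm_gamma_mult = 1,
                         tune_folds = 3L, stack_folds = 3L,
                         sel_folds = 5L, n_boost = 10L, mrmr_bins = 3L) {
  structure(list(kmer_k_promoter = as.integer(kmer_k_promoter),
                 kmer_k_middle = as.integer(kmer_k_middle),
                 pseknc_k_range = as.integer(pseknc_k_range),
                 pseknc_lambda = as.integer(pseknc_lambda),
                 pseknc_w = pseknc_w, acc_lag = as.integer(acc_lag),
                 motif_p = motif_p, cgi_window = as.integer(cgi_window),
                 cgi_min_length = as.integer(cgi_min_length),
                 cgi_min_gc = cgi_min_gc, cgi_min_oe = cgi_min_oe,
                 alpha = alpha, fscore = isTRUE(fscore),
                 svm_cost = svm_cost,
                 svm_gamma_mult = svm_gamma_mult,
                 tune_folds = as.integer(tune_folds),
                 stack_folds = as.integer(stack_folds),
                 sel_folds = as.integer(sel_folds),
                 n_boost = as.integer(n_boost),
                 mrmr_bins = as.integer(mrmr_bins)),
            class = "timgo_config")
}

#' Encode all nine features for every record
#'
#' Computes the label-independent feature matrices once over all records
#' (they are cached and reused across cross-validation folds; only the
#' label-dependent steps -- fragment filters, scaling, weighting, model
#' fits -- are refitted per fold). PseKNC is cached per candidate k.
#'
#' @param sequences [extract_sequences()] result (named `promoter` /
#'   `middle` character vectors).
#' @param config A [timgo_config()].
#' @param motif_lib Motif library (default: bundled plant library).
#' @param din_table,tri_table Property tables (default: bundled synthetic
#'   tables).
#' @param verbose Progress messages.
#' @return A `timgo_features` list: `features` (named matrices), `ids`,
#'   `n`, `config`.
#' @export
encode_features <- function(sequences, config = timgo_config(),
                            motif_lib = read_motif_library(),
                            din_table = read_property_table("dinucleotide"),
                            tri_table = read_property_table("trinucleotide"),
                            verbose = FALSE) {
  prom <- sequences$promoter
  midd <- sequences$middle
  stopifnot(length(prom) == length(midd),
            identical(names(prom), names(midd)))
  ids <- names(prom)
  say <- function(...) if (verbose) message(...)
  feats <- list()

  say("CGI features")
  feats$cgi_promoter <- cgi_feature_matrix(prom, config$cgi_window,
                                           config$cgi_min_length,
                                           config$cgi_min_gc,
                                           config$cgi_min_oe)
  feats$cgi_middle <- cgi_feature_matrix(midd, config$cgi_window,
                                         config$cgi_min_length,
                                         config$cgi_min_gc,
                                         config$cgi_min_oe)
  say("DNP / TNP")
  feats$dnp_promoter <- property_encode(prom, din_table)
  feats$dnp_middle <- property_encode(midd, din_table)
  feats$tnp_promoter <- property_encode(prom, tri_table)
  feats$tnp_middle <- property_encode(midd, tri_table)
  say("Kmer / RevKmer")
  kp <- config$kmer_k_promoter; km <- config$kmer_k_middle
  feats$kmer_promoter <- kmer_counts(prom, kmer_spec(kp[1], kp[2], FALSE))
  feats$revkmer_promoter <- kmer_counts(prom, kmer_spec(kp[1], kp[2], TRUE))
  feats$kmer_middle <- kmer_counts(midd, kmer_spec(km[1], km[2], FALSE))
  feats$revkmer_middle <- kmer_counts(midd, kmer_spec(km[1], km[2], TRUE))
  say("Motif scan")
  hits <- motif_scan(prom, motif_lib, p_threshold = config$motif_p)
  feats$motif_promoter <- motif_features(hits, motif_lib, ids,
                                         setNames(nchar(prom), ids))
  say("DACC / TACC")
  feats$dacc_promoter <- acc_encode(prom, din_table, config$acc_lag)
  feats$dacc_middle <- acc_encode(midd, din_table, config$acc_lag)
  feats$tacc_promoter <- acc_encode(prom, tri_table, config$acc_lag)
  feats$tacc_middle <- acc_encode(midd, tri_table, config$acc_lag)
  say("PseKNC")
  for (k in config$pseknc_k_range) {
    feats[[sprintf("pseknc_promoter_k%d", k)]] <-
      pseknc_encode(prom, k, config$pseknc_lambda, config$pseknc_w,
                    din_table)
    feats[[sprintf("pseknc_middle_k%d", k)]] <-
      pseknc_encode(midd, k, config$pseknc_lambda, config$pseknc_w,
                    din_table)
  }
  for (nm in names(feats)) rownames(feats[[nm]]) <- ids
  structure(list(features = feats, ids = ids, n = length(ids),
                 config = config, motif_hits = hits),
            class = "timgo_features")
}

#' Train the full two-layer model
#'
#' Fits the complete stack on a (balanced) training set: (1) the distance
#' logistic model; (2) out-of-fold meta-features from `stack_folds`
#' internal first-layer fits, so the second layer never sees a first-layer
#' prediction made on that record's own training fit; (3) mRMR ranking of
#' the 48 meta-features followed by incremental selection (smallest prefix
#' with maximal CV accuracy); (4) a LADTree on the selected meta-features;
#' (5) a final first layer refitted on the full training set, used when
#' predicting new records.
#'
#' @param fs [encode_features()] feature set covering the training rows.
#' @param labels `Ac`/`NAc` labels, one per training row.
#' @param distances Enhancer-TLS distances (bp).
#' @param config A [timgo_config()].
#' @param seed Integer seed.
#' @param rows Training record indices within `fs` (default all).
#' @return A `timgo_model`.
#' @export
train_timgo <- function(fs, labels, distances, config = timgo_config(),
                        seed = 1L, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(fs$n)
  labels <- factor(as.character(labels), levels = c("NAc", "Ac"))
  k <- config$stack_folds
  assign <- stratified_folds(as.character(labels), k, child_seed(seed, 7))
  meta <- matrix(NA_real_, nrow = length(rows), ncol = 48)
  for (fold in seq_len(k)) {
    tr <- assign != fold
    bundle_f <- train_first_layer(fs, labels[tr], distances[tr], config,
                                  child_seed(seed, 20 + fold),
                                  rows = rows[tr])
    mf <- meta_features(bundle_f, fs, rows[!tr], distances[!tr])
    if (fold == 1) colnames(meta) <- colnames(mf)
    meta[!tr, ] <- mf
  }
  rownames(meta) <- fs$ids[rows]

  rank <- mrmr_rank(meta, labels, bins = config$mrmr_bins)
  sel <- incremental_selection(meta, labels, rank$ranking,
                               folds = config$sel_folds,
                               seed = child_seed(seed, 31))
  lad <- ladtree_train(meta[, sel$selected, drop = FALSE], labels,
                       n_boost = config$n_boost)
  bundle <- train_first_layer(fs, labels, distances, config,
                              child_seed(seed, 50), rows = rows)
  structure(list(first_layer = bundle, mrmr = rank,
                 selection = sel, meta_columns = colnames(meta),
                 selected_columns = colnames(meta)[sel$selected],
                 ladtree = lad, config = config, seed = seed,
                 train_meta = meta,
                 version = as.character(utils::packageVersion("timgo"))),
            class = "timgo_model")
}

#' Predict activation for records with a trained two-layer model
#'
#' @param object A [train_timgo()] model.
#' @param fs Feature set containing the records (encoded with the same
#'   configuration).
#' @param rows Record indices within `fs`.
#' @param distances Enhancer-TLS distances (bp) for those records.
#' @param ... Unused.
#' @return data.frame with `id`, `pred` (`Ac`/`NAc`), `score` (LADTree
#'   margin), `prob` (activation probability), `distance_bp`.
#' @export
predict.timgo_model <- function(object, fs, rows = NULL, distances, ...) {
  if (is.null(rows)) rows <- seq_len(fs$n)
  meta <- meta_features(object$first_layer, fs, rows, distances)
  sel <- match(object$selected_columns, colnames(meta))
  x <- meta[, sel, drop = FALSE]
  score <- predict(object$ladtree, x, type = "score")
  data.frame(id = fs$ids[rows],
             pred = ifelse(score > 0, "Ac", "NAc"),
             score = score, prob = plogis(2 * score),
             distance_bp = distances,
             stringsAsFactors = FALSE)
}

#' Cross-validate the full two-layer pipeline
#'
#' Outer stratified k-fold CV of [train_timgo()]: all label-dependent
#' steps (fragment filters, distance weighting, scaling, SVM tuning,
#' meta-feature selection, LADTree) are refitted inside each training
#' fold; the shared [encode_features()] cache holds only label-independent
#' per-record encodings. Fold confusion matrices are pooled
#' (micro-averaged).
#'
#' @param fs Feature set over all records.
#' @param labels,distances Per-record labels and distances.
#' @param config A [timgo_config()].
#' @param k Outer folds (default 5).
#' @param seed Integer seed.
#' @param verbose Progress messages.
#' @return List: `confusion`, `metrics`, `predictions` (with distances),
#'   `distance_report`, `diagnostics` (per fold: retained fragments of
#'   the Kmer+Motif model, meta prefix size).
#' @export
timgo_cv <- function(fs, labels, distances, config = timgo_config(),
                     k = 5L, seed = 1L, verbose = FALSE) {
  lab <- as.character(labels)
  assign <- stratified_folds(lab, k, seed)
  pred <- character(length(lab))
  prob <- numeric(length(lab))
  diagnostics <- vector("list", k)
  for (fold in seq_len(k)) {
    if (verbose) message("outer fold ", fold, "/", k)
    tr <- which(assign != fold)
    te <- which(assign == fold)
    fit <- train_timgo(fs, lab[tr], distances[tr], config,
                       child_seed(seed, 300 + fold), rows = tr)
    out <- predict(fit, fs, te, distances[te])
    pred[te] <- out$pred
    prob[te] <- out$prob
    km <- fit$first_layer$models$kmer_motif_promoter
    diagnostics[[fold]] <- list(
      train_rows = tr,
      kmer_filter_retained = km$filter$retained,
      meta_prefix = fit$selection$best_size,
      selected_columns = fit$selected_columns)
  }
  cm <- confusion_matrix(lab, pred)
  list(confusion = cm, metrics = confusion_metrics(cm),
       predictions = data.frame(id = fs$ids, truth = lab, pred = pred,
                                prob = prob, distance_bp = distances,
                                fold = assign, stringsAsFactors = FALSE),
       distance_report = stratified_distance_report(distances, lab, pred),
       diagnostics = diagnostics)
}

#' Save / load a trained model bundle
#'
#' Serializes the versioned model archive with R's native serialization.
#'
#' @param model A `timgo_model`.
#' @param path File path (`.rds`).
#' @export
save_timgo <- function(model, path) {
  stopifnot(inherits(model, "timgo_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_timgo
#' @return `load_timgo`: the restored `timgo_model`.
#' @export
load_timgo <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "timgo_model")) stop("not a timgo model archive")
  model
}
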