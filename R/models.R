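#' Build a confusion matrix from truth and predictions
#'
#' @param truth,pred Vectors coercible to the same label set.
#' @param positive The positive-class label (default `"Ac"`).
#' @return Named integer vector `c(TP, FP, TN, FN)`, class
#'   `confusion_matrix`.
#' @export
confusion_matrix <- function(truth, pred, positive = "Ac") {
  truth_pos <- as.character(truth) == positive
  pred_pos <- as.character(pred) == positive
  structure(c(TP = sum(truth_pos & pred_pos),
              FP = sum(!truth_pos & pred_pos),
              TN = sum(!truth_pos & !pred_pos),
              FN = sum(truth_pos & !pred_pos)),
            class = "confusion_matrix")
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy, sensitivity, specificity, and the Matthews correlation
#' coefficient:
#' Acc = (TP+TN)/(TP+FP+TN+FN), Sn = TP/(TP+FN), Sp = TN/(TN+FP),
#' MCC = (TP*TN - FN*FP) / sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN)).
#' All four are reported as percentages (MCC x 100, in [-100, 100]). Any
#' metric whose denominator is zero is reported as 0 and flagged in
#' `undefined`.
#'
#' @param cm A [confusion_matrix()] or a vector/list with elements
#'   `TP`, `FP`, `TN`, `FN`.
#' @return A `metrics_report` list: `Acc`, `Sn`, `Sp`, `MCC` (percent),
#'   `n`, and `undefined` (character vector of zero-denominator metrics).
#' @export
confusion_metrics <- function(cm) {
  tp <- as.numeric(cm[["TP"]]); fp <- as.numeric(cm[["FP"]])
  tn <- as.numeric(cm[["TN"]]); fn <- as.numeric(cm[["FN"]])
  undefined <- character(0)
  total <- tp + fp + tn + fn
  guard <- function(num, den, name) {
    if (den <= 0) {
      undefined <<- c(undefined, name)
      0
    } else num / den
  }
  acc <- guard(tp + tn, total, "Acc")
  sn <- guard(tp, tp + fn, "Sn")
  sp <- guard(tn, tn + fp, "Sp")
  mcc_den2 <- (tp + fn) * (tn + fp) * (tp + fp) * (tn + fn)
  mcc <- guard(tp * tn - fn * fp, sqrt(mcc_den2), "MCC")
  structure(list(Acc = 100 * acc, Sn = 100 * sn, Sp = 100 * sp,
                 MCC = 100 * mcc, n = total, undefined = undefined),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("n=%d  Acc=%.1f%%  Sn=%.1f%%  Sp=%.1f%%  MCC=%.1f%%\n",
              x$n, x$Acc, x$Sn, x$Sp, x$MCC))
  if (length(x$undefined) > 0) {
    cat("undefined (zero denominator):", paste(x$undefined, collapse = ", "),
        "\n")
  }
  invisible(x)
}

# --- SVM helpers ------------------------------------------------------------

# Grid-search an RBF SVM by internal cross-validation accuracy, then fit
# the winning (cost, gamma) with probability outputs. Gamma candidates are
# multiples of the 1/ncol heuristic. Deterministic under `seed`.
tune_rbf_svm <- function(x, y, costs, gamma_mults, tune_folds, seed) {
  y <- factor(y, levels = c("NAc", "Ac"))
  gammas <- unique(gamma_mults / max(1, ncol(x)))
  grid <- expand.grid(cost = costs, gamma = gammas)
  best <- list(acc = -1)
  for (g in seq_len(nrow(grid))) {
    acc <- with_seed(child_seed(seed, g), {
      fit <- e1071::svm(x, y, kernel = "radial", cost = grid$cost[g],
                        gamma = grid$gamma[g], scale = FALSE,
                        cross = tune_folds)
      fit$tot.accuracy
    })
    if (acc > best$acc) best <- list(acc = acc, cost = grid$cost[g],
                                     gamma = grid$gamma[g])
  }
  fit <- with_seed(child_seed(seed, 1000), {
    e1071::svm(x, y, kernel = "radial", cost = best$cost,
               gamma = best$gamma, scale = FALSE, probability = TRUE)
  })
  list(fit = fit, cost = best$cost, gamma = best$gamma, cv_acc = best$acc)
}

# Predict label + class probabilities from a tuned SVM.
svm_predict_conf <- function(fit, x) {
  pr <- predict(fit, x, probability = TRUE)
  probs <- attr(pr, "probabilities")
  data.frame(pred = as.integer(as.character(pr) == "Ac"),
             conf_pos = probs[, "Ac"],
             conf_neg = probs[, "NAc"])
}

# --- first layer ------------------------------------------------------------

# The 16-model roster: feature-set entry, region, whether the t-test
# fragment filter applies, and whether the model is distance-weighted
# (all PROMOTER models are).
first_layer_roster <- function() {
  data.frame(
    name = c("cgi_promoter", "cgi_middle", "dnp_promoter", "dnp_middle",
             "tnp_promoter", "tnp_middle",
             "kmer_motif_promoter", "revkmer_motif_promoter",
             "kmer_middle", "revkmer_middle",
             "dacc_promoter", "dacc_middle", "tacc_promoter", "tacc_middle",
             "pseknc_promoter", "pseknc_middle"),
    region = c("promoter", "middle", "promoter", "middle", "promoter",
               "middle", "promoter", "promoter", "middle", "middle",
               "promoter", "middle", "promoter", "middle", "promoter",
               "middle"),
    filtered = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE,
                 TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

# Assemble the raw (unfiltered, unscaled) feature matrix for one roster
# entry, fitting the fragment filter on the training rows when the model
# is count-based. Returns list(x = matrix over `rows`, filter).
model_matrix <- function(fs, model_name, rows, fit_rows = rows,
                         labels = NULL, alpha = 0.05, pseknc_k = NULL) {
  feats <- fs$features
  fit_filter <- function(counts) {
    stopifnot(!is.null(labels))
    y <- as_binary_labels(labels)
    significant_fragments(counts[fit_rows[y == 1], , drop = FALSE],
                          counts[fit_rows[y == 0], , drop = FALSE],
                          alpha = alpha)
  }
  filtered_counts <- function(counts) {
    filt <- fit_filter(counts)
    list(x = apply_fragment_filter(filt, counts[rows, , drop = FALSE]),
         filter = filt)
  }
  switch(model_name,
    cgi_promoter = list(x = feats$cgi_promoter[rows, , drop = FALSE]),
    cgi_middle = list(x = feats$cgi_middle[rows, , drop = FALSE]),
    dnp_promoter = list(x = feats$dnp_promoter[rows, , drop = FALSE]),
    dnp_middle = list(x = feats$dnp_middle[rows, , drop = FALSE]),
    tnp_promoter = list(x = feats$tnp_promoter[rows, , drop = FALSE]),
    tnp_middle = list(x = feats$tnp_middle[rows, , drop = FALSE]),
    dacc_promoter = list(x = feats$dacc_promoter[rows, , drop = FALSE]),
    dacc_middle = list(x = feats$dacc_middle[rows, , drop = FALSE]),
    tacc_promoter = list(x = feats$tacc_promoter[rows, , drop = FALSE]),
    tacc_middle = list(x = feats$tacc_middle[rows, , drop = FALSE]),
    kmer_middle = filtered_counts(feats$kmer_middle),
    revkmer_middle = filtered_counts(feats$revkmer_middle),
    kmer_motif_promoter = ,
    revkmer_motif_promoter = {
      counts <- if (model_name == "kmer_motif_promoter")
        feats$kmer_promoter else feats$revkmer_promoter
      kf <- filtered_counts(counts)
      mf <- motif_block(fs, rows, fit_rows, labels, alpha)
      list(x = cbind(kf$x, mf$x), filter = kf$filter,
           motif_filter = mf$filter)
    },
    pseknc_promoter = ,
    pseknc_middle = {
      region <- sub("pseknc_", "", model_name)
      k <- if (is.null(pseknc_k)) fs$config$pseknc_k_range[1] else pseknc_k
      key <- sprintf("pseknc_%s_k%d", region, k)
      if (is.null(feats[[key]])) stop("missing feature cache entry ", key)
      list(x = feats[[key]][rows, , drop = FALSE], pseknc_k = k)
    },
    stop("unknown model ", model_name))
}

# Motif feature block restricted to motifs whose hit-count column passes
# the t-test filter on the training rows; all 4 features of a significant
# motif are kept.
motif_block <- function(fs, rows, fit_rows, labels, alpha) {
  mf <- fs$features$motif_promoter
  number_cols <- grep("_number$", colnames(mf))
  counts <- mf[, number_cols, drop = FALSE]
  y <- as_binary_labels(labels)
  filt <- significant_fragments(counts[fit_rows[y == 1], , drop = FALSE],
                                counts[fit_rows[y == 0], , drop = FALSE],
                                alpha = alpha)
  motifs <- sub("_number$", "", filt$retained)
  keep_cols <- as.vector(t(outer(motifs,
                                 c("number", "conserve", "orientation",
                                   "dis"), paste, sep = "_")))
  keep_cols <- intersect(keep_cols, colnames(mf))
  list(x = mf[rows, keep_cols, drop = FALSE], filter = filt)
}

#' Train the 16 first-layer SVM models
#'
#' One RBF SVM per (encoder, region) roster entry. Per model: the t-test
#' fragment filter is fitted on the training records (k-mer, RevKmer and
#' motif models), features are min-max scaled to \[-1, 1\], PROMOTER-model
#' features are weighted by the distance-activation logistic probability,
#' and (cost, gamma) are grid-searched by internal cross-validation. The
#' PseKNC tuple size k is chosen per region by internal CV accuracy over
#' `config$pseknc_k_range`.
#'
#' @param fs A [encode_features()] feature set.
#' @param labels Training labels (`Ac`/`NAc`), one per training row.
#' @param distances Enhancer-TLS distances in bp, one per training row.
#' @param config A [timgo_config()].
#' @param seed Integer seed (internal CV, SVM tuning).
#' @param rows Integer indices of the training records within `fs`
#'   (default: all).
#' @return A `first_layer_bundle` with 16 trained models and the fitted
#'   distance model.
#' @export
train_first_layer <- function(fs, labels, distances, config = timgo_config(),
                              seed = 1L, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(fs$n)
  stopifnot(length(labels) == length(rows),
            length(distances) == length(rows))
  roster <- first_layer_roster()
  dist_model <- fit_distance_logistic(distances, labels)
  y <- factor(as.character(labels), levels = c("NAc", "Ac"))

  models <- vector("list", nrow(roster))
  names(models) <- roster$name
  for (mi in seq_len(nrow(roster))) {
    name <- roster$name[mi]
    pseknc_k <- NULL
    if (name %in% c("pseknc_promoter", "pseknc_middle")) {
      pseknc_k <- select_pseknc_k(fs, name, rows, y, distances, dist_model,
                                  config, child_seed(seed, 100 + mi))
    }
    mm <- model_matrix(fs, name, rows, fit_rows = rows, labels = y,
                       alpha = config$alpha, pseknc_k = pseknc_k)
    x <- mm$x
    if (roster$filtered[mi] && config$fscore && ncol(x) > 8) {
      fsel <- fscore_select(x, y, folds = config$tune_folds,
                            seed = child_seed(seed, 400 + mi))
      x <- x[, sort(fsel$selected), drop = FALSE]
    }
    if (all(apply(x, 2, function(v) length(unique(v)) == 1))) {
      # Degenerate encoder on this training set (e.g. no CpG island in any
      # MIDDLE window): keep the 16-model roster intact with a class-prior
      # stub so meta-features stay well-defined.
      warning("model ", name, ": all-constant feature matrix; ",
              "fitting a class-prior stub")
      models[[mi]] <- list(name = name, stub = TRUE,
                           prior_pos = mean(y == "Ac"),
                           pseknc_k = mm$pseknc_k, filter = mm$filter,
                           weighted = FALSE, columns = colnames(x))
      next
    }
    scaler <- fit_scaler(x)
    xs <- apply_scaler(scaler, x)
    weighted <- roster$region[mi] == "promoter"
    if (weighted) xs <- weight_promoter_features(xs, dist_model, distances)
    tuned <- tune_rbf_svm(xs, y, config$svm_cost, config$svm_gamma_mult,
                          config$tune_folds, child_seed(seed, mi))
    models[[mi]] <- list(name = name, filter = mm$filter,
                         motif_filter = mm$motif_filter,
                         pseknc_k = mm$pseknc_k, scaler = scaler,
                         weighted = weighted, svm = tuned$fit,
                         cost = tuned$cost, gamma = tuned$gamma,
                         cv_acc = tuned$cv_acc,
                         columns = colnames(x))
  }
  structure(list(models = models, dist_model = dist_model,
                 roster = roster, config = config, train_rows = rows),
            class = "first_layer_bundle")
}

# Choose the PseKNC tuple size for one region by internal CV accuracy
# with default SVM parameters (scaled + weighted as in the final model).
select_pseknc_k <- function(fs, name, rows, y, distances, dist_model,
                            config, seed) {
  region <- sub("pseknc_", "", name)
  ks <- config$pseknc_k_range
  if (length(ks) == 1) return(ks)
  accs <- vapply(ks, function(k) {
    xm <- fs$features[[sprintf("pseknc_%s_k%d", region, k)]][rows, ,
                                                             drop = FALSE]
    xs <- apply_scaler(fit_scaler(xm), xm)
    if (region == "promoter") {
      xs <- weight_promoter_features(xs, dist_model, distances)
    }
    svm_cv_accuracy(xs, as.integer(y == "Ac"), folds = config$tune_folds,
                    seed = seed)
  }, numeric(1))
  ks[which.max(accs)]
}

# Transform feature rows for one trained submodel (filter columns, scale,
# weight) and predict label + confidences.
predict_submodel <- function(bundle, model, fs, rows, distances) {
  if (isTRUE(model$stub)) {
    p <- model$prior_pos
    return(data.frame(pred = rep(as.integer(p > 0.5), length(rows)),
                      conf_pos = rep(p, length(rows)),
                      conf_neg = rep(1 - p, length(rows))))
  }
  mm_cols <- model$columns
  # rebuild the raw matrix from the cache using the stored column set
  name <- model$name
  feats <- fs$features
  raw <- switch(name,
    kmer_motif_promoter = cbind(feats$kmer_promoter,
                                feats$motif_promoter)[rows, , drop = FALSE],
    revkmer_motif_promoter = cbind(feats$revkmer_promoter,
                                   feats$motif_promoter)[rows, ,
                                                         drop = FALSE],
    pseknc_promoter = feats[[sprintf("pseknc_promoter_k%d",
                                     model$pseknc_k)]][rows, , drop = FALSE],
    pseknc_middle = feats[[sprintf("pseknc_middle_k%d",
                                   model$pseknc_k)]][rows, , drop = FALSE],
    feats[[name]][rows, , drop = FALSE])
  x <- raw[, mm_cols, drop = FALSE]
  xs <- apply_scaler(model$scaler, x)
  if (model$weighted) {
    xs <- weight_promoter_features(xs, bundle$dist_model, distances)
  }
  svm_predict_conf(model$svm, xs)
}

#' Meta-feature matrix from the first layer
#'
#' For each of the 16 first-layer models, three meta-features: the
#' predicted label (0/1), the positive-class confidence, and the
#' negative-class confidence (summing to 1 per model) -- 48 columns in the
#' fixed roster order, named `<model>_pred`, `<model>_conf_pos`,
#' `<model>_conf_neg`.
#'
#' @param bundle A [train_first_layer()] bundle.
#' @param fs The feature set the records live in.
#' @param rows Record indices to predict.
#' @param distances Enhancer-TLS distances (bp) for those records.
#' @return Numeric matrix `length(rows) x 48`.
#' @export
meta_features <- function(bundle, fs, rows, distances) {
  stopifnot(inherits(bundle, "first_layer_bundle"))
  blocks <- lapply(bundle$models, function(model) {
    pr <- predict_submodel(bundle, model, fs, rows, distances)
    m <- as.matrix(pr)
    colnames(m) <- paste(model$name, c("pred", "conf_pos", "conf_neg"),
                         sep = "_")
    m
  })
  out <- do.call(cbind, blocks)
  rownames(out) <- fs$ids[rows]
  out
}

# --- generic CV utilities ---------------------------------------------------

#' Stratified k-fold cross-validation driver
#'
#' Splits records into stratified folds, calls `trainer` on each training
#' fold and `predictor` on the held-out fold, and pools the per-fold
#' confusion matrices (micro-averaging). All model fitting -- including
#' any feature selection or weighting inside `trainer` -- sees only the
#' training-fold indices, so fold-level selection cannot leak.
#'
#' @param labels Full label vector (`Ac`/`NAc` or binary).
#' @param trainer Function `(train_idx)` returning a fitted object.
#' @param predictor Function `(fit, test_idx)` returning predicted labels
#'   on the same label scale as `labels`.
#' @param k Number of folds (default 5).
#' @param seed Fold-assignment seed.
#' @return List: `confusion` (pooled), `metrics`, `fold_assign`,
#'   `predictions` (per-record), `fits` (if `keep_fits`).
#' @param keep_fits Keep the per-fold fitted objects (default FALSE).
#' @export
kfold_cv <- function(labels, trainer, predictor, k = 5L, seed = 1L,
                     keep_fits = FALSE) {
  lab <- as.character(labels)
  assign <- stratified_folds(lab, k, seed)
  pred <- character(length(lab))
  fits <- if (keep_fits) vector("list", k) else NULL
  for (fold in seq_len(k)) {
    tr <- which(assign != fold)
    te <- which(assign == fold)
    fit <- trainer(tr)
    pred[te] <- as.character(predictor(fit, te))
    if (keep_fits) fits[[fold]] <- fit
  }
  cm <- confusion_matrix(lab, pred)
  list(confusion = cm, metrics = confusion_metrics(cm),
       fold_assign = assign,
       predictions = data.frame(truth = lab, pred = pred,
                                fold = assign),
       fits = fits)
}

#' Per-distance-bin prediction accuracy
#'
#' Groups records by the enhancer-TLS distance into half-open `(lo, hi]`
#' kb bins and reports the prediction accuracy within each bin; a record
#' at exactly 2 kb falls in the 0-2 bin. Empty bins are flagged with `NA`
#' accuracy rather than interpolated.
#'
#' @param distance_bp Distances in bp.
#' @param truth,pred Label vectors.
#' @param edges_kb Bin edges in kb (default `c(0, 2, 5, 10, 15, 20, 25,
#'   Inf)`).
#' @return data.frame with `bin`, `n`, `n_correct`, `accuracy` (percent,
#'   `NA` for empty bins), `empty`.
#' @export
stratified_distance_report <- function(distance_bp, truth, pred,
                                       edges_kb = c(0, 2, 5, 10, 15, 20,
                                                    25, Inf)) {
  kb <- distance_bp / 1000
  bin <- cut(kb, edges_kb, include.lowest = FALSE, right = TRUE)
  correct <- as.character(truth) == as.character(pred)
  out <- data.frame(bin = levels(bin),
                    n = as.vector(table(bin)))
  out$n_correct <- vapply(levels(bin), function(b) {
    sum(correct[!is.na(bin) & bin == b])
  }, numeric(1))
  out$accuracy <- ifelse(out$n > 0, 100 * out$n_correct / out$n, NA_real_)
  out$empty <- out$n == 0
  out
}
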