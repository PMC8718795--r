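#' Select class-discriminating sequence fragments by t-test
#'
#' Per vocabulary fragment (k-mer, reverse-complement k-mer class, or
#' motif), a Welch two-sample two-sided t-test compares occurrence counts
#' between the activated (positive) and nonactivated (negative) groups;
#' fragments with p below `alpha` are retained. No multiple-testing
#' correction is applied: the raw per-fragment level is the selection
#' rule. Fragments with zero variance in both groups are dropped.
#'
#' @param counts_pos,counts_neg Count matrices (records x fragments) with
#'   identical column sets; each must have at least 2 rows.
#' @param alpha Per-fragment significance level (default 0.05).
#' @return A `fragment_filter`: list with `table` (fragment, statistic,
#'   p_value, keep; sorted by p), `retained` (character vector), `alpha`.
#' @export
significant_fragments <- function(counts_pos, counts_neg, alpha = 0.05) {
  if (!identical(colnames(counts_pos), colnames(counts_neg))) {
    stop("count matrices must share the same fragment columns")
  }
  n1 <- nrow(counts_pos); n2 <- nrow(counts_neg)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 records")
  m1 <- colMeans(counts_pos); m2 <- colMeans(counts_neg)
  v1 <- apply(counts_pos, 2, var); v2 <- apply(counts_neg, 2, var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  degenerate <- v1 == 0 & v2 == 0
  tab <- data.frame(fragment = colnames(counts_pos), statistic = tstat,
                    p_value = p, stringsAsFactors = FALSE)
  tab <- tab[!degenerate, , drop = FALSE]
  tab$keep <- !is.na(tab$p_value) & tab$p_value < alpha
  tab <- tab[order(tab$p_value), ]
  rownames(tab) <- NULL
  structure(list(table = tab, retained = tab$fragment[tab$keep],
                 alpha = alpha),
            class = "fragment_filter")
}

#' Apply a fragment filter to a count matrix
#' @param filter A [significant_fragments()] result.
#' @param counts Count matrix whose columns include the retained fragments.
#' @param min_keep If the filter retains nothing, fall back to the
#'   `min_keep` smallest-p fragments (with a warning) so downstream models
#'   still have input; set to 0 to disable.
#' @return The column subset of `counts`.
#' @export
apply_fragment_filter <- function(filter, counts, min_keep = 10L) {
  stopifnot(inherits(filter, "fragment_filter"))
  keep <- filter$retained
  if (length(keep) == 0 && min_keep > 0) {
    warning("no fragment passed the t-test filter; keeping the ",
            min_keep, " smallest-p fragments")
    keep <- head(filter$table$fragment, min_keep)
  }
  counts[, intersect(keep, colnames(counts)), drop = FALSE]
}

#' Serialize a fragment filter to TSV
#' @param filter A `fragment_filter`.
#' @param path Output path.
#' @export
write_fragment_filter <- function(filter, path) {
  write.table(filter$table, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Fit the distance-activation logistic model
#'
#' Maximum-likelihood logistic regression of activation status on the
#' enhancer-TLS distance: P(activation) = plogis(beta0 + beta1 * d).
#' On panels where activation falls off with distance the fitted slope is
#' negative; the fitted probability then decreases monotonically in d.
#'
#' @param distances Numeric vector of enhancer-TLS distances in bp.
#' @param labels Binary labels: 0/1, logical, or a factor whose last level
#'   is the positive (activated) class.
#' @return A `distance_model`: list with `intercept`, `slope`, `fitted`
#'   (per-record probabilities), and the underlying `glm` coefficients'
#'   standard errors.
#' @export
fit_distance_logistic <- function(distances, labels) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) {
    stop("labels contain a single class; cannot fit a logistic model")
  }
  fit <- glm(y ~ distances, family = binomial())
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  structure(list(intercept = unname(cf[1]), slope = unname(cf[2]),
                 se = unname(se), fitted = unname(fitted(fit))),
            class = "distance_model")
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) {
    as.integer(labels == levels(labels)[nlevels(labels)])
  } else if (is.logical(labels)) {
    as.integer(labels)
  } else if (all(labels %in% c(0, 1))) {
    as.integer(labels)
  } else if (all(labels %in% c("Ac", "NAc"))) {
    as.integer(labels == "Ac")
  } else {
    stop("labels must be binary (0/1, logical, factor, or Ac/NAc)")
  }
}

#' Predicted activation probability at a distance
#' @param model A [fit_distance_logistic()] model.
#' @param distance_bp Distances in bp.
#' @return Probabilities in (0, 1).
#' @export
predict_activation <- function(model, distance_bp) {
  stopifnot(inherits(model, "distance_model"))
  plogis(model$intercept + model$slope * distance_bp)
}

#' Weight promoter features by the distance-activation probability
#'
#' Scales a promoter feature vector (or each row of a matrix) by the
#' fitted activation probability at the record's enhancer-TLS distance.
#' Records sharing one promoter but observed under different insertion
#' events thus receive distinct feature vectors, resolving otherwise
#' contradictory duplicated training rows. Direction is preserved; only
#' the norm changes, by a factor in (0, 1).
#'
#' @param x Feature vector, or matrix with one row per record.
#' @param model A [fit_distance_logistic()] model.
#' @param distance_bp Distance(s) in bp, one per record.
#' @return Weighted vector/matrix of the same shape.
#' @export
weight_promoter_features <- function(x, model, distance_bp) {
  p <- predict_activation(model, distance_bp)
  if (is.matrix(x)) {
    stopifnot(length(p) == nrow(x))
    x * p
  } else {
    stopifnot(length(p) == 1)
    x * p
  }
}

#' Fisher-score feature ranking and selection
#'
#' Computes the LIBSVM fselect-style Fisher score per column,
#' F = ((m+ - m)^2 + (m- - m)^2) / (var+ + var-), ranks columns by it, and
#' (optionally) picks a cutoff by cross-validated SVM accuracy over a
#' grid of candidate subset sizes.
#'
#' @param features Numeric matrix (records x features).
#' @param labels Binary labels (see [fit_distance_logistic()]).
#' @param top_n Keep the `top_n` best columns (skips the CV search).
#' @param cv_sizes Candidate subset sizes for the CV search (default:
#'   halving grid from all columns down to 2).
#' @param folds,seed CV folds / seed for the cutoff search.
#' @return List with `scores` (named, input order), `ranking` (column
#'   indices, best first), and `selected` (column indices kept).
#' @export
fscore_select <- function(features, labels, top_n = NULL, cv_sizes = NULL,
                          folds = 3L, seed = 1L) {
  y <- as_binary_labels(labels)
  pos <- features[y == 1, , drop = FALSE]
  neg <- features[y == 0, , drop = FALSE]
  m <- colMeans(features); mp <- colMeans(pos); mn <- colMeans(neg)
  vp <- apply(pos, 2, var); vn <- apply(neg, 2, var)
  denom <- vp + vn
  num <- (mp - m)^2 + (mn - m)^2
  # zero within-group variance with distinct means separates perfectly
  scores <- ifelse(denom > 0, num / denom, ifelse(num > 0, Inf, 0))
  ranking <- order(scores, decreasing = TRUE)
  if (!is.null(top_n)) {
    selected <- ranking[seq_len(min(top_n, length(ranking)))]
  } else {
    if (is.null(cv_sizes)) {
      cv_sizes <- unique(pmax(2, floor(ncol(features) / 2^(0:6))))
    }
    accs <- vapply(cv_sizes, function(sz) {
      cols <- ranking[seq_len(sz)]
      svm_cv_accuracy(features[, cols, drop = FALSE], y, folds, seed)
    }, numeric(1))
    selected <- ranking[seq_len(cv_sizes[which.max(accs)])]
  }
  list(scores = scores, ranking = ranking, selected = selected)
}

# Plain k-fold SVM accuracy used by selection searches (default params).
svm_cv_accuracy <- function(x, y, folds = 3L, seed = 1L) {
  f <- factor(y)
  if (nlevels(f) < 2) return(0)
  assign <- stratified_folds(as.integer(f), folds, seed)
  correct <- 0
  for (k in seq_len(folds)) {
    tr <- assign != k
    if (length(unique(f[tr])) < 2) next
    fit <- with_seed(child_seed(seed, k),
                     e1071::svm(x[tr, , drop = FALSE], f[tr],
                                kernel = "radial", scale = FALSE))
    correct <- correct + sum(predict(fit, x[!tr, , drop = FALSE]) == f[!tr])
  }
  correct / length(y)
}

# Mutual information of two discrete vectors (natural log).
mutual_information <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  pxy <- tab / n
  px <- rowSums(pxy); py <- colSums(pxy)
  nz <- pxy > 0
  sum(pxy[nz] * log(pxy[nz] / outer(px, py)[nz]))
}

# Equal-frequency discretization into `bins` bins; vectors with at most
# `bins` distinct values (e.g. predicted 0/1 labels) are left as is.
discretize_ef <- function(x, bins = 3L) {
  ux <- unique(x)
  if (length(ux) <= bins) return(match(x, sort(ux)))
  qs <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1)))
  if (length(qs) < 3) return(match(x, sort(ux)))
  as.integer(cut(x, qs, include.lowest = TRUE))
}

#' Greedy mRMR feature ranking (MID variant)
#'
#' Ranks columns by minimum-redundancy-maximum-relevance: the first pick
#' maximizes mutual information with the label; each later pick maximizes
#' I(column; label) minus the mean mutual information with the columns
#' already selected. Continuous columns are discretized into equal-
#' frequency bins first. Ties break deterministically toward the lower
#' column index.
#'
#' @param features Numeric matrix (records x features).
#' @param labels Binary labels.
#' @param bins Discretization bins (default 3).
#' @return List with `ranking` (column indices, best first), `relevance`
#'   (MI with the label, input order), and `scores` (the mRMR objective at
#'   each pick).
#' @export
mrmr_rank <- function(features, labels, bins = 3L) {
  y <- as_binary_labels(labels)
  n <- ncol(features)
  disc <- lapply(seq_len(n), function(j) discretize_ef(features[, j], bins))
  relevance <- vapply(disc, mutual_information, numeric(1), b = y)
  mi_cache <- matrix(NA_real_, n, n)
  selected <- integer(0)
  scores <- numeric(0)
  remaining <- seq_len(n)
  while (length(remaining) > 0) {
    obj <- vapply(remaining, function(j) {
      if (length(selected) == 0) return(relevance[j])
      red <- vapply(selected, function(s) {
        if (is.na(mi_cache[j, s])) {
          mi_cache[j, s] <<- mi_cache[s, j] <<-
            mutual_information(disc[[j]], disc[[s]])
        }
        mi_cache[j, s]
      }, numeric(1))
      relevance[j] - mean(red)
    }, numeric(1))
    pick <- remaining[which.max(obj)]  # which.max takes the first = lowest index
    selected <- c(selected, pick)
    scores <- c(scores, max(obj))
    remaining <- setdiff(remaining, pick)
  }
  list(ranking = selected, relevance = relevance, scores = scores)
}

#' Incremental feature selection over a ranked column list
#'
#' Evaluates the prefixes 1..N of a feature ranking by stratified k-fold
#' cross-validation accuracy of a learner and returns the smallest prefix
#' attaining the maximum accuracy ("highest accuracy, fewest features").
#'
#' @param features Numeric matrix.
#' @param labels Binary labels.
#' @param ranking Column indices, best first (e.g. `mrmr_rank()$ranking`).
#' @param learner Function `(x_train, y_train)` returning a model with a
#'   working `predict(model, x_new)` method; default: RBF SVM.
#' @param folds,seed CV configuration.
#' @param max_prefix Cap on the number of prefixes evaluated.
#' @return List with `best_size`, `accuracies` (one per prefix), and
#'   `selected` (the winning column subset).
#' @export
incremental_selection <- function(features, labels, ranking,
                                  learner = NULL, folds = 5L, seed = 1L,
                                  max_prefix = length(ranking)) {
  y <- as_binary_labels(labels)
  n_pref <- min(max_prefix, length(ranking))
  if (is.null(learner)) {
    accuracies <- vapply(seq_len(n_pref), function(p) {
      svm_cv_accuracy(features[, ranking[seq_len(p)], drop = FALSE],
                      y, folds, seed)
    }, numeric(1))
  } else {
    assign <- stratified_folds(y, folds, seed)
    accuracies <- vapply(seq_len(n_pref), function(p) {
      cols <- ranking[seq_len(p)]
      correct <- 0
      for (k in seq_len(folds)) {
        tr <- assign != k
        fit <- learner(features[tr, cols, drop = FALSE], y[tr])
        pred <- predict(fit, features[!tr, cols, drop = FALSE])
        correct <- correct + sum(pred == y[!tr])
      }
      correct / length(y)
    }, numeric(1))
  }
  best <- which.max(accuracies)  # first max = smallest prefix
  list(best_size = best, accuracies = accuracies,
       selected = ranking[seq_len(best)])
}
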