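#' Train a LogitBoost alternating decision tree (LADTree)
#'
#' An alternating decision tree grown by LogitBoost. The tree interleaves
#' prediction nodes (additive real-valued contributions) and splitter
#' nodes (single-feature threshold tests). At each boosting iteration the
#' working response and weights of LogitBoost are computed from the
#' current margins, and the single best (precondition, feature, threshold)
#' regression stump -- over all existing prediction nodes as preconditions
#' -- is attached under its precondition node with two new prediction
#' nodes. A record's score is the sum of the prediction-node values along
#' every root-to-leaf path it satisfies; the predicted class is the sign
#' of the score.
#'
#' @param x Numeric matrix (records x features).
#' @param y Binary labels: 0/1, logical, or a two-level factor whose last
#'   level is the positive class.
#' @param n_boost Number of boosting iterations, i.e. splitter nodes
#'   (default 10).
#' @param max_thresholds Per feature, candidate thresholds are midpoints
#'   between consecutive unique values, thinned to at most this many by
#'   quantiles (default 20).
#' @param shrinkage Optional multiplier on each prediction-node value
#'   (learning rate; default 1, the plain LogitBoost step).
#' @return A `ladtree` model.
#' @export
ladtree_train <- function(x, y, n_boost = 10L, max_thresholds = 20L,
                          shrinkage = 1) {
  x <- as.matrix(x)
  yb <- as_binary_labels(y)
  if (length(unique(yb)) < 2) stop("labels contain a single class")
  n <- nrow(x)
  stopifnot(length(yb) == n)

  # candidate thresholds per feature
  cand <- lapply(seq_len(ncol(x)), function(j) {
    u <- sort(unique(x[, j]))
    if (length(u) < 2) return(numeric(0))
    mids <- (u[-1] + u[-length(u)]) / 2
    if (length(mids) > max_thresholds) {
      mids <- unique(quantile(mids, probs = seq(0, 1,
                                                length.out = max_thresholds)))
    }
    mids
  })

  # node tables; node 1 is the root prediction node (precondition: all)
  pred_value <- 0.5 * log((sum(yb == 1) + 1) / (sum(yb == 0) + 1))
  pred_nodes <- data.frame(id = 1L, parent_split = 0L, side = NA,
                           value = pred_value)
  split_nodes <- data.frame(id = integer(0), precond = integer(0),
                            feature = integer(0), threshold = numeric(0))
  # which records satisfy the path down to each prediction node
  membership <- list(rep(TRUE, n))
  F <- rep(pred_value, n)

  for (it in seq_len(n_boost)) {
    p <- 1 / (1 + exp(-2 * F))
    w <- pmax(p * (1 - p), 1e-10)
    z <- pmin(pmax((yb - p) / w, -4), 4)  # clipped working response

    best <- NULL
    for (pc in seq_len(nrow(pred_nodes))) {
      mask <- membership[[pc]]
      if (sum(mask) < 4) next
      wi <- w[mask]; zi <- z[mask]; xi <- x[mask, , drop = FALSE]
      for (j in seq_len(ncol(x))) {
        for (t in cand[[j]]) {
          left <- xi[, j] <= t
          wl <- sum(wi[left]); wr <- sum(wi[!left])
          if (wl <= 0 || wr <= 0) next
          sl <- sum(wi[left] * zi[left]); sr <- sum(wi[!left] * zi[!left])
          # global weighted-SSE reduction of fitting two constants on this
          # precondition's subset (records outside it are unaffected), so
          # candidates are comparable across preconditions
          gain <- sl^2 / wl + sr^2 / wr
          if (is.null(best) || gain > best$gain + 1e-12) {
            best <- list(gain = gain, pc = pc, feature = j, threshold = t,
                         vl = shrinkage * 0.5 * sl / wl,
                         vr = shrinkage * 0.5 * sr / wr)
          }
        }
      }
    }
    if (is.null(best)) break

    sid <- nrow(split_nodes) + 1L
    split_nodes[sid, ] <- list(sid, best$pc, best$feature, best$threshold)
    mask <- membership[[best$pc]]
    left_mask <- mask & x[, best$feature] <= best$threshold
    right_mask <- mask & !(x[, best$feature] <= best$threshold)
    for (side in c("L", "R")) {
      m2 <- if (side == "L") left_mask else right_mask
      v <- if (side == "L") best$vl else best$vr
      pred_nodes[nrow(pred_nodes) + 1L, ] <-
        list(nrow(pred_nodes) + 1L, sid, side, v)
      membership[[length(membership) + 1L]] <- m2
      F[m2] <- F[m2] + v
    }
  }

  structure(list(pred_nodes = pred_nodes, split_nodes = split_nodes,
                 n_features = ncol(x), feature_names = colnames(x),
                 levels = label_levels(y)),
            class = "ladtree")
}

label_levels <- function(y) {
  if (is.factor(y)) {
    levels(y)
  } else if (is.character(y) && all(y %in% c("Ac", "NAc"))) {
    c("NAc", "Ac")
  } else {
    c("0", "1")
  }
}

#' Predict from a LADTree model
#'
#' @param object A [ladtree_train()] model.
#' @param newdata Numeric matrix with the training feature columns.
#' @param type `"class"` (default), `"score"` (additive margin), or
#'   `"prob"` (positive-class probability `plogis(2 * score)`).
#' @param ... Unused.
#' @return Vector of predictions, one per row of `newdata`.
#' @export
predict.ladtree <- function(object, newdata, type = c("class", "score",
                                                      "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  stopifnot(ncol(newdata) == object$n_features)
  n <- nrow(newdata)
  score <- numeric(n)
  mask_of <- vector("list", nrow(object$pred_nodes))
  for (pn in seq_len(nrow(object$pred_nodes))) {
    row <- object$pred_nodes[pn, ]
    if (row$parent_split == 0L) {
      mask <- rep(TRUE, n)
    } else {
      sp <- object$split_nodes[row$parent_split, ]
      parent_mask <- mask_of[[sp$precond]]
      test <- newdata[, sp$feature] <= sp$threshold
      mask <- if (row$side == "L") parent_mask & test else
        parent_mask & !test
    }
    mask_of[[pn]] <- mask
    score[mask] <- score[mask] + row$value
  }
  switch(type,
         score = score,
         prob = plogis(2 * score),
         class = {
           lv <- object$levels
           factor(ifelse(score > 0, lv[length(lv)], lv[1]), levels = lv)
         })
}
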