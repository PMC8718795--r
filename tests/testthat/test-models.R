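test_that("confusion metrics implement the four formulas with guards", {
  m <- confusion_metrics(c(TP = 10, FP = 0, TN = 10, FN = 0))
  expect_equal(c(m$Acc, m$Sn, m$Sp, m$MCC), c(100, 100, 100, 100))

  m2 <- confusion_metrics(c(TP = 3, FP = 1, TN = 4, FN = 2))
  expect_equal(m2$Acc, 100 * 7 / 10)
  expect_equal(m2$Sn, 100 * 3 / 5)
  expect_equal(m2$Sp, 100 * 4 / 5)
  expect_equal(m2$MCC, 100 * (3 * 4 - 2 * 1) / sqrt(5 * 5 * 4 * 6))
  expect_true(m2$MCC >= -100 && m2$MCC <= 100)

  # MCC = 100 iff FP = FN = 0 with both classes present
  expect_lt(confusion_metrics(c(TP = 9, FP = 1, TN = 10, FN = 0))$MCC, 100)

  # zero-denominator guard: no negatives at all
  g <- confusion_metrics(c(TP = 5, FP = 0, TN = 0, FN = 0))
  expect_equal(g$Sp, 0)
  expect_true("Sp" %in% g$undefined)

  cm <- confusion_matrix(c("Ac", "Ac", "NAc"), c("Ac", "NAc", "NAc"))
  expect_equal(unname(cm[c("TP", "FP", "TN", "FN")]), c(1, 0, 1, 1))
})

test_that("LADTree separates separable data and predicts deterministically", {
  set.seed(10)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  x <- cbind(f1 = y * 2 + runif(n, 0, 0.5), f2 = rnorm(n))
  fit <- ladtree_train(x, y, n_boost = 10)
  pred <- predict(fit, x)
  expect_equal(mean(pred == as.character(y)), 1)    # separable
  expect_identical(predict(fit, x, type = "score"),
                   predict(fit, x, type = "score"))
  pr <- predict(fit, x, type = "prob")
  expect_true(all(pr >= 0 & pr <= 1))
  expect_true(all((pr > 0.5) == (pred == "1")))
  expect_error(ladtree_train(x, rep(1, n)), "single class")
})

test_that("LADTree boosting improves fit on noisy XOR-ish structure", {
  set.seed(3)
  n <- 200
  x <- matrix(runif(n * 2), ncol = 2)
  y <- as.integer(xor(x[, 1] > 0.5, x[, 2] > 0.5))  # needs >1 split
  fit1 <- ladtree_train(x, y, n_boost = 1)
  fit10 <- ladtree_train(x, y, n_boost = 12)
  acc <- function(f) mean(predict(f, x) == as.character(y))
  expect_gt(acc(fit10), acc(fit1))
  expect_gt(acc(fit10), 0.85)
})

test_that("stratified folds are balanced and seeded", {
  y <- rep(c("Ac", "NAc"), each = 150)
  cv <- kfold_cv(y,
                 trainer = function(tr) table(y[tr]),
                 predictor = function(fit, te) rep("Ac", length(te)),
                 k = 5, seed = 3)
  folds <- cv$fold_assign
  expect_equal(as.vector(table(folds)), rep(60, 5))  # folds of 60
  for (f in 1:5) {
    expect_equal(as.vector(table(y[folds == f])), c(30, 30))
  }
  cv2 <- kfold_cv(y, function(tr) NULL,
                  function(fit, te) rep("Ac", length(te)), k = 5, seed = 3)
  expect_identical(folds, cv2$fold_assign)
})

test_that("cross-validation trains only on training-fold indices", {
  y <- rep(c("Ac", "NAc"), each = 20)
  seen <- list()
  cv <- kfold_cv(y,
                 trainer = function(tr) { seen[[length(seen) + 1]] <<- tr; tr },
                 predictor = function(fit, te) {
                   expect_length(intersect(fit, te), 0)  # disjointness
                   rep("Ac", length(te))
                 },
                 k = 4, seed = 1)
  expect_length(seen, 4)
  expect_equal(sort(unique(unlist(seen))), 1:40)
})

test_that("distance-stratified report uses half-open (lo, hi] kb bins", {
  rep1 <- stratified_distance_report(c(1000, 22000), c("Ac", "Ac"),
                                     c("Ac", "NAc"))
  expect_equal(rep1$accuracy[rep1$bin == "(0,2]"], 100)
  expect_equal(rep1$accuracy[rep1$bin == "(20,25]"], 0)
  expect_true(rep1$empty[rep1$bin == "(5,10]"])
  expect_true(is.na(rep1$accuracy[rep1$bin == "(5,10]"]))

  # boundary: exactly 2.0 kb falls in the 0-2 bin
  rep2 <- stratified_distance_report(2000, "Ac", "Ac")
  expect_equal(rep2$n[rep2$bin == "(0,2]"], 1)
  expect_equal(rep2$n[rep2$bin == "(2,5]"], 0)
  # oracle: explicit interval arithmetic for a grid of distances
  d <- c(500, 2000, 2001, 5000, 10000, 25000, 25001)
  rep3 <- stratified_distance_report(d, rep("Ac", 7), rep("Ac", 7))
  expect_equal(rep3$n, c(2, 2, 1, 0, 0, 1, 1))
  expect_equal(sum(rep3$n), 7)

  # all predictions correct -> every occupied bin at 100%
  expect_true(all(rep3$accuracy[!rep3$empty] == 100))
})

test_that("first layer trains 16 models whose meta-features are
           well-formed", {
  fx <- shared_sim()
  conf <- shared_conf()
  fs <- shared_fs()
  bundle <- suppressWarnings(
    train_first_layer(fs, fx$ds$label, fx$ds$distance_bp, conf, seed = 3))
  expect_s3_class(bundle, "first_layer_bundle")
  expect_length(bundle$models, 16)
  expect_setequal(names(bundle$models), first_layer_roster()$name)

  mf <- meta_features(bundle, fs, seq_len(fs$n), fx$ds$distance_bp)
  expect_equal(dim(mf), c(fs$n, 48))
  pred_cols <- grep("_pred$", colnames(mf))
  expect_true(all(mf[, pred_cols] %in% c(0, 1)))
  cp <- grep("_conf_pos$", colnames(mf)); cn <- grep("_conf_neg$",
                                                     colnames(mf))
  expect_true(all(abs(mf[, cp] + mf[, cn] - 1) < 1e-9))
  expect_true(all(mf[, cp] >= 0 & mf[, cp] <= 1))

  # determinism: same seed twice gives identical meta-features
  bundle2 <- suppressWarnings(
    train_first_layer(fs, fx$ds$label, fx$ds$distance_bp, conf, seed = 3))
  mf2 <- meta_features(bundle2, fs, seq_len(fs$n), fx$ds$distance_bp)
  expect_equal(mf, mf2)

  # planted-signal ordering: Kmer+Motif promoter beats the CGI models
  accs <- vapply(bundle$models, function(m)
    if (is.null(m$cv_acc)) 50 else m$cv_acc, numeric(1))
  expect_gt(accs[["kmer_motif_promoter"]], 70)
  expect_gt(accs[["kmer_motif_promoter"]], accs[["cgi_promoter"]])
})

test_that("fragment filters inside CV folds are fitted on fold-train
           rows only", {
  fx <- shared_sim()
  conf <- timgo_config(pseknc_k_range = 2L, stack_folds = 2L,
                       svm_cost = 1, svm_gamma_mult = 1, fscore = FALSE)
  fs <- shared_fs()
  lab <- as.character(fx$ds$label)
  k <- 3
  assign <- timgo:::stratified_folds(lab, k, 5L)
  tr <- which(assign != 1)
  te <- which(assign == 1)

  bundle <- suppressWarnings(
    train_first_layer(fs, lab[tr], fx$ds$distance_bp[tr], conf, seed = 2,
                      rows = tr))
  got <- bundle$models$kmer_middle$filter

  # oracle: the filter recomputed from fold-train counts alone
  counts <- fs$features$kmer_middle
  y <- lab[tr] == "Ac"
  want <- significant_fragments(counts[tr[y], , drop = FALSE],
                                counts[tr[!y], , drop = FALSE])
  expect_identical(got$retained, want$retained)

  # injecting a discriminative fragment into held-out rows only must not
  # change the fold-train filter
  fs2 <- fs
  fs2$features$kmer_middle[te, "AAAAA"] <-
    fs2$features$kmer_middle[te, "AAAAA"] + ifelse(lab[te] == "Ac", 50, 0)
  bundle2 <- suppressWarnings(
    train_first_layer(fs2, lab[tr], fx$ds$distance_bp[tr], conf, seed = 2,
                      rows = tr))
  expect_identical(bundle2$models$kmer_middle$filter$retained,
                   got$retained)
  # ... while injecting it into the training rows does change it
  fs3 <- fs
  fs3$features$kmer_middle[tr, "AAAAA"] <-
    fs3$features$kmer_middle[tr, "AAAAA"] + ifelse(lab[tr] == "Ac", 50, 0)
  bundle3 <- suppressWarnings(
    train_first_layer(fs3, lab[tr], fx$ds$distance_bp[tr], conf, seed = 2,
                      rows = tr))
  expect_true("AAAAA" %in% bundle3$models$kmer_middle$filter$retained)
})
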