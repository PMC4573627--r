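# A linearly separable toy problem: class is decided by the first feature.
separable_pm <- function(n_per_class = 30, p = 4, seed = 2) {
  with_seed(seed, {
    X <- matrix(rnorm(2 * n_per_class * p, sd = 0.3), ncol = p)
    X[1:n_per_class, 1] <- X[1:n_per_class, 1] + 5
    y <- c(rep(1, n_per_class), rep(-1, n_per_class))
    anchors <- data.frame(id = paste0("a", seq_len(2 * n_per_class)),
                          chrom = "chr1", pos = 0, strand = "+",
                          stringsAsFactors = FALSE)
    structure(list(X = X, y = y, anchors = anchors, marks = "M",
                   k = p / 2, bin_size = 100), class = "profile_matrix")
  })
}

test_that("stratified half-split preserves class balance", {
  pm <- separable_pm(70)  # 70 + 70
  pm$y <- c(rep(1, 100), rep(-1, 40))
  sp <- split_half(pm, seed = 4)
  expect_equal(sum(sp$train$y == 1), 50)
  expect_equal(sum(sp$train$y == -1), 20)
  expect_equal(nrow(sp$train$X) + nrow(sp$test$X), 140)
  expect_equal(length(intersect(sp$train$anchors$id, sp$test$anchors$id)), 0)
  # odd class size floors: 11 positives -> 5 in train
  pm2 <- separable_pm(30)
  pm2$y <- c(rep(1, 11), rep(-1, 49))
  sp2 <- split_half(pm2, seed = 4)
  expect_equal(sum(sp2$train$y == 1), 5)
  # seeded: identical repeat
  expect_identical(split_half(pm, seed = 4)$train$anchors$id,
                   sp$train$anchors$id)
  expect_error(split_half(structure(pm[names(pm) != "y"],
                                    class = "profile_matrix"), 1), "labels")
})

test_that("the SVM separates a separable toy problem perfectly", {
  pm <- separable_pm()
  sp <- split_half(pm, seed = 1)
  model <- train_svm(sp$train, tiny_svm_config())
  sc <- predict_scores(model, sp$test)
  acc <- mean(sign(sc$score) == sp$test$y)
  expect_equal(acc, 1.0)
  expect_equal(roc_auc(sc$score, sp$test$y)$auc, 1.0)
  # scores and probabilities agree in orientation
  expect_true(mean(sc$probability[sp$test$y == 1]) >
              mean(sc$probability[sp$test$y == -1]))
  expect_true(all(sc$probability >= 0 & sc$probability <= 1))
})

test_that("a single-cell grid skips cross-validation", {
  pm <- separable_pm()
  cfg <- svm_config(C_grid = 1, gamma_grid = 0.01, cv_folds = 3)
  model <- train_svm(pm, cfg)
  expect_equal(model$C, 1)
  expect_equal(model$gamma, 0.01)
  expect_true(is.na(model$cv_accuracy))
})

test_that("grid selection is deterministic and reports the chosen cell", {
  pm <- separable_pm(40)
  m1 <- train_svm(pm, tiny_svm_config(seed = 11))
  m2 <- train_svm(pm, tiny_svm_config(seed = 11))
  expect_equal(m1$C, m2$C)
  expect_equal(m1$gamma, m2$gamma)
  expect_equal(m1$cv_accuracy, m2$cv_accuracy)
  expect_true(m1$C %in% c(1, 10))
  expect_true(m1$gamma %in% c(1e-3, 1e-2))
})

test_that("prediction is deterministic and row-order equivariant", {
  pm <- separable_pm()
  model <- train_svm(pm, tiny_svm_config())
  s1 <- predict_scores(model, pm)
  s2 <- predict_scores(model, pm)
  expect_identical(s1, s2)
  perm <- rev(seq_len(nrow(pm$X)))
  s3 <- predict_scores(model, pm$X[perm, ])
  expect_equal(s3$score, s1$score[perm])
  expect_error(predict_scores(model, pm$X[, 1:2]), "width")
  expect_equal(nrow(predict_scores(model, pm$X[0, , drop = FALSE])), 0)
})

test_that("classifiers survive a save/load round trip", {
  pm <- separable_pm()
  model <- train_svm(pm, tiny_svm_config())
  p <- tempfile(fileext = ".rds")
  save_classifier(model, p)
  back <- load_classifier(p)
  expect_equal(predict_scores(back, pm), predict_scores(model, pm))
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(format = "other"), bad)
  expect_error(load_classifier(bad), "classifier file")
})

test_that("roc_auc matches hand-computed values", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(-1, -1, 1, 1))$auc, 1.0)
  expect_equal(roc_auc(c(4, 3, 2, 1), c(1, 1, -1, -1))$auc, 1.0)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(1, 1, -1, -1))$auc, 0.0)
  expect_equal(roc_auc(c(1, 1, 1, 1), c(1, -1, 1, -1))$auc, 0.5)
  # 3 concordant pairs of 4: scores (3,1) pos vs (2,0) neg
  expect_equal(roc_auc(c(3, 1, 2, 0), c(1, 1, -1, -1))$auc, 0.75)
  # 0/1 and logical labels are accepted
  expect_equal(roc_auc(c(3, 1, 2, 0), c(1, 1, 0, 0))$auc, 0.75)
  expect_equal(roc_auc(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE))$auc, 0.75)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
  # curve starts at (0, 0) and ends at (1, 1)
  r <- roc_auc(c(3, 1, 2, 0), c(1, 1, -1, -1))
  expect_equal(r$curve$tpr[1], 0)
  expect_equal(r$curve$fpr[1], 0)
  expect_equal(r$curve$tpr[nrow(r$curve)], 1)
  expect_equal(r$curve$fpr[nrow(r$curve)], 1)
})

test_that("roc_auc agrees with a brute-force pair-counting oracle", {
  brute_auc <- function(s, l) {
    ps <- s[l == 1]; ns <- s[l == -1]
    total <- 0
    for (a in ps) for (b in ns)
      total <- total + (a > b) + 0.5 * (a == b)
    total / (length(ps) * length(ns))
  }
  set.seed(31)
  for (i in 1:50) {
    n <- sample(5:60, 1)
    s <- sample(round(rnorm(n), 1))  # rounding forces ties
    l <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(l)) < 2) l[1:2] <- c(-1, 1)
    expect_equal(roc_auc(s, l)$auc, brute_auc(s, l))
  }
})

test_that("roc_auc cross-checks against pROC and obeys invariances", {
  set.seed(17)
  s <- rnorm(200)
  l <- ifelse(runif(200) < plogis(2 * s), 1, -1)
  ours <- roc_auc(s, l)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = l, predictor = s,
                                        levels = c(-1, 1),
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
  # invariance under strictly monotone transforms
  expect_equal(roc_auc(exp(s), l)$auc, ours)
  expect_equal(roc_auc(rank(s), l)$auc, ours)
  # label-flip / negation symmetry
  expect_equal(roc_auc(-s, l)$auc, 1 - ours)
})

test_that("conflicting duplicate points give chance-level AUC", {
  s <- rep(c(1, 2), each = 2)
  l <- c(1, -1, 1, -1)
  expect_equal(roc_auc(s, l)$auc, 0.5)
})

test_that("evaluate_windows returns one row per subset-k cell", {
  st <- tiny_study(seed = 13, genome = c(chr1 = 6e5), n_genes = 80,
                   n_mirnas = 4)
  pos <- anchors_from_transcripts(st$ann$genes)
  neg <- sample_random_anchors(st$cfg$genome, nrow(pos), seed = 5,
                               id_prefix = "neg")
  tab <- evaluate_windows(st$tracks, pos, neg,
                          marks_subsets = list(H3K4me3 = "H3K4me3"),
                          k_list = c(5, 10), seed = 3,
                          config = tiny_svm_config(3))
  expect_equal(nrow(tab), 2)
  expect_setequal(tab$k, c(5, 10))
  expect_true(all(tab$auc >= 0 & tab$auc <= 1))
  expect_true(all(tab$subset == "H3K4me3"))
})
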