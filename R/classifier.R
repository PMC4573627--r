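# RBF-kernel SVM separating TSS profiles from random-region profiles,
# with grid-searched (C, gamma), feature standardization, a monotone
# score->probability map, and ROC/AUC evaluation.

#' SVM training configuration
#'
#' @param C_grid penalty values for the grid search.
#' @param gamma_grid RBF kernel widths for the grid search.
#' @param cv_folds cross-validation folds used to select (C, gamma).
#' @param seed integer seed controlling fold assignment.
#' @param class_weighting \code{"none"} or \code{"balanced"}.
#' @param scaling \code{"standardize"} (default; zero mean, unit variance
#'   fitted on the training data) or \code{"none"}.
#' @return list of class \code{svm_config}.
#' @export
svm_config <- function(C_grid = c(0.1, 1, 10, 100),
                       gamma_grid = c(1e-4, 1e-3, 1e-2, 1e-1),
                       cv_folds = 5, seed = 1,
                       class_weighting = c("none", "balanced"),
                       scaling = c("standardize", "none")) {
  if (length(C_grid) == 0 || length(gamma_grid) == 0) stop("empty grid")
  if (cv_folds < 2) stop("cv_folds must be >= 2")
  structure(list(C_grid = sort(C_grid), gamma_grid = sort(gamma_grid),
                 cv_folds = as.integer(cv_folds), seed = seed,
                 class_weighting = match.arg(class_weighting),
                 scaling = match.arg(scaling)),
            class = "svm_config")
}

#' Stratified 50/50 split of a profile matrix
#'
#' Half of each class (floor on the training side) goes to training, the
#' rest to testing; reproducible under the seed.
#'
#' @param matrix a \code{profile_matrix} with labels.
#' @param seed integer seed.
#' @return list(train, test) of \code{profile_matrix} objects.
#' @export
split_half <- function(matrix, seed = 1) {
  y <- matrix$y
  if (is.null(y)) stop("split_half requires labels")
  if (any(table(y) < 2) || length(unique(y)) < 2)
    stop("each class needs at least 2 members")
  with_seed(seed, {
    train_idx <- unlist(lapply(unique(y), function(cl) {
      idx <- which(y == cl)
      sample(idx, floor(length(idx) / 2))
    }))
  })
  train_idx <- sort(train_idx)
  subset_pm <- function(rows) {
    structure(list(X = matrix$X[rows, , drop = FALSE], y = matrix$y[rows],
                   anchors = matrix$anchors[rows, , drop = FALSE],
                   marks = matrix$marks, k = matrix$k,
                   bin_size = matrix$bin_size), class = "profile_matrix")
  }
  list(train = subset_pm(train_idx),
       test = subset_pm(setdiff(seq_along(y), train_idx)))
}

scale_features <- function(X, center, scale) {
  sweep(sweep(X, 2, center, "-"), 2, scale, "/")
}

fit_raw_svm <- function(X, yf, C, gamma, class_weights = NULL) {
  e1071::svm(x = X, y = yf, type = "C-classification", kernel = "radial",
             cost = C, gamma = gamma, scale = FALSE,
             class.weights = class_weights)
}

decision_values <- function(fit, X, flip = 1) {
  p <- predict(fit, X, decision.values = TRUE)
  as.numeric(attr(p, "decision.values")) * flip
}

#' Train the RBF-SVM TSS classifier
#'
#' (C, gamma) are selected by cross-validated accuracy on the training data
#' only (ties broken toward the smallest C, then the smallest gamma); the
#' final model is refit on all training rows. Features are standardized
#' with training-set means/SDs, and a monotone sigmoid mapping decision
#' scores to probabilities is fitted on the training decision scores.
#'
#' @param train a \code{profile_matrix} with labels in \{-1, +1\}.
#' @param config an [svm_config()].
#' @return list of class \code{trained_classifier}.
#' @export
train_svm <- function(train, config = svm_config()) {
  X <- train$X
  y <- train$y
  if (length(unique(y)) < 2) stop("training data must contain both classes")
  if (any(!is.finite(X))) stop("non-finite feature values")
  if (config$scaling == "standardize") {
    center <- colMeans(X)
    scl <- apply(X, 2, sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
  } else {
    center <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  }
  Xs <- scale_features(X, center, scl)
  yf <- factor(y, levels = c(1, -1))
  cw <- if (config$class_weighting == "balanced") {
    tab <- table(yf)
    setNames(as.numeric(sum(tab) / (2 * tab)), names(tab))
  } else NULL

  grid <- expand.grid(gamma = config$gamma_grid, C = config$C_grid)
  if (nrow(grid) > 1) {
    folds <- with_seed(config$seed, {
      f <- integer(length(y))
      for (cl in unique(y)) {
        idx <- which(y == cl)
        f[idx] <- sample(rep_len(seq_len(config$cv_folds), length(idx)))
      }
      f
    })
    acc <- vapply(seq_len(nrow(grid)), function(g) {
      correct <- 0
      for (fold in seq_len(config$cv_folds)) {
        tr <- folds != fold
        if (length(unique(y[tr])) < 2 || !any(!tr)) next
        fit <- fit_raw_svm(Xs[tr, , drop = FALSE], yf[tr],
                           grid$C[g], grid$gamma[g], cw)
        pred <- predict(fit, Xs[!tr, , drop = FALSE])
        correct <- correct + sum(as.character(pred) == as.character(yf[!tr]))
      }
      correct / length(y)
    }, numeric(1))
    # tie-break: smallest C, then smallest gamma
    ord <- order(-acc, grid$C, grid$gamma)
    best <- ord[1]
    cv_accuracy <- acc[best]
  } else {
    best <- 1
    cv_accuracy <- NA_real_
  }
  C_sel <- grid$C[best]; gamma_sel <- grid$gamma[best]
  fit <- fit_raw_svm(Xs, yf, C_sel, gamma_sel, cw)
  dec <- decision_values(fit, Xs)
  # orient decision scores so larger means more TSS-like (+1 class)
  flip <- if (mean(dec[y == 1]) >= mean(dec[y == -1])) 1 else -1
  dec <- dec * flip
  platt <- fit_platt(dec, y)
  structure(list(fit = fit, C = C_sel, gamma = gamma_sel,
                 cv_accuracy = cv_accuracy, center = center, scale = scl,
                 flip = flip, platt = platt, marks = train$marks,
                 k = train$k, n_features = ncol(X), config = config),
            class = "trained_classifier")
}

# Monotone sigmoid calibration of decision scores (Platt scaling). The
# slope is constrained positive so probability is strictly increasing in
# the decision score.
fit_platt <- function(dec, y) {
  t01 <- as.numeric(y == 1)
  fit <- tryCatch(
    suppressWarnings(glm(t01 ~ dec, family = binomial())),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(coef(fit)[2]) || coef(fit)[2] <= 0) {
    c(a = 0, b = 1)
  } else {
    c(a = unname(coef(fit)[1]), b = unname(coef(fit)[2]))
  }
}

#' @export
print.trained_classifier <- function(x, ...) {
  cat(sprintf(paste0("RBF-SVM TSS classifier: C = %g, gamma = %g, ",
                     "%d features (%d marks, k = %d)\n"),
              x$C, x$gamma, x$n_features, length(x$marks), x$k))
  invisible(x)
}

#' Decision scores and probabilities for new profiles
#'
#' @param model a \code{trained_classifier}.
#' @param matrix a \code{profile_matrix} or bare feature matrix with the
#'   training feature width.
#' @return data.frame(score, probability), one row per input row.
#' @export
predict_scores <- function(model, matrix) {
  X <- if (inherits(matrix, "profile_matrix")) matrix$X else matrix
  if (ncol(X) != model$n_features)
    stop(sprintf("feature width %d does not match training width %d",
                 ncol(X), model$n_features))
  if (nrow(X) == 0) return(data.frame(score = numeric(), probability = numeric()))
  Xs <- scale_features(X, model$center, model$scale)
  dec <- decision_values(model$fit, Xs, model$flip)
  data.frame(score = dec,
             probability = plogis(model$platt["a"] + model$platt["b"] * dec))
}

#' Save / load a trained classifier
#'
#' The serialized file bundles the fitted SVM, scaling and calibration
#' parameters, the selected grid point, mark order, window size and the
#' training seed, plus a format version tag.
#'
#' @param model a \code{trained_classifier}.
#' @param path file path.
#' @return \code{load_classifier} returns the model.
#' @export
save_classifier <- function(model, path) {
  saveRDS(list(format = "mirpromoter_classifier", version = 1L,
               model = model), path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "mirpromoter_classifier"))
    stop("not a mirpromoter classifier file")
  obj$model
}

#' ROC curve and AUC
#'
#' AUC is the rank statistic P(score+ > score-) + 0.5 P(tie), identical to
#' the trapezoidal integral of the threshold-swept curve.
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels labels in \{-1, +1\} (or logical/0-1).
#' @return list(auc, curve = data.frame(threshold, tpr, fpr)) of class
#'   \code{roc_result}.
#' @export
roc_auc <- function(scores, labels) {
  lab <- normalize_labels(labels)
  npos <- sum(lab == 1); nneg <- sum(lab == -1)
  if (npos == 0 || nneg == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[lab == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- lab[ord]
  tp <- cumsum(l == 1); fp <- cumsum(l == -1)
  last <- c(s[-1] != s[-length(s)], TRUE)   # one point per distinct threshold
  curve <- data.frame(threshold = s[last],
                      tpr = tp[last] / npos, fpr = fp[last] / nneg)
  curve <- rbind(data.frame(threshold = Inf, tpr = 0, fpr = 0), curve)
  structure(list(auc = auc, curve = curve), class = "roc_result")
}

normalize_labels <- function(labels) {
  if (is.logical(labels)) return(ifelse(labels, 1, -1))
  l <- as.numeric(labels)
  if (all(l %in% c(0, 1))) return(ifelse(l == 1, 1, -1))
  if (!all(l %in% c(-1, 1))) stop("labels must be in {-1, +1}")
  l
}

#' AUC table across mark subsets and window sizes
#'
#' For each mark subset and each half-window k, features are extracted,
#' the pooled positive/negative matrix is split 50/50 (stratified), the SVM
#' is trained on one half and the held-out AUC is computed on the other,
#' reproducing the window-size comparison experiment.
#'
#' @param tracks named list of binned tracks.
#' @param pos_anchors,neg_anchors anchor data.frames (TSSs and random
#'   positions).
#' @param marks_subsets named list of character vectors of mark labels.
#' @param k_list half-window sizes in bins.
#' @param seed integer seed (split and CV folds).
#' @param config an [svm_config()].
#' @return data.frame(subset, k, auc, C, gamma).
#' @export
evaluate_windows <- function(tracks, pos_anchors, neg_anchors,
                             marks_subsets, k_list = c(20, 15, 10, 5),
                             seed = 1, config = svm_config(seed = seed)) {
  if (nrow(pos_anchors) == 0 || nrow(neg_anchors) == 0)
    stop("anchors must be non-empty")
  anchors <- rbind(pos_anchors, neg_anchors)
  labels <- c(rep(1, nrow(pos_anchors)), rep(-1, nrow(neg_anchors)))
  kmax <- max(k_list)
  res <- list()
  for (sname in names(marks_subsets)) {
    marks <- marks_subsets[[sname]]
    full <- build_matrix(tracks, anchors, labels, k = kmax, marks = marks)
    for (k in k_list) {
      pm <- shrink_window(full, k)
      sp <- split_half(pm, seed = seed)
      model <- train_svm(sp$train, config)
      sc <- predict_scores(model, sp$test)
      roc <- roc_auc(sc$score, sp$test$y)
      res[[length(res) + 1]] <- data.frame(
        subset = sname, k = k, auc = roc$auc, C = model$C,
        gamma = model$gamma, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

# Restrict a profile_matrix built at window K to a smaller window k by
# selecting the inner columns of each mark block.
shrink_window <- function(pm, k) {
  K <- pm$k
  if (k > K) stop("k exceeds the extracted window")
  if (k == K) return(pm)
  inner <- (K - k + 1):(K + k)
  cols <- as.vector(vapply(seq_along(pm$marks) - 1,
                           function(mi) mi * 2 * K + inner,
                           numeric(2 * k)))
  structure(list(X = pm$X[, cols, drop = FALSE], y = pm$y,
                 anchors = pm$anchors, marks = pm$marks, k = k,
                 bin_size = pm$bin_size), class = "profile_matrix")
}

#' Write an AUC table / ROC points as TSV
#' @param x data.frame (AUC table or ROC curve points).
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
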