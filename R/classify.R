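#' Assemble the feature matrix from screened coupling profiles
#'
#' Columns are the features flagged significant in a [coupling_group_screen()]
#' result, in the screen's (atlas) order; rows are subjects, group A first.
#' This mirrors a select-then-classify workflow in which features are picked
#' on the full sample before cross-validation — convenient but optimistic;
#' see `nested` in [loocv_classify()] for the leakage-free alternative.
#'
#' @inheritParams coupling_group_screen
#' @param screen result of [coupling_group_screen()] on the same subjects.
#' @return list `x` (subjects x features matrix), `y` (factor with levels
#'   `control`, `patient`; positive class `patient`), `features`.
#' @export
select_features <- function(profilesA, profilesB, screen,
                            scale = c("node", "within", "between", "global")) {
  scale <- match.arg(scale)
  keep <- screen$feature[screen$significant]
  if (!length(keep)) {
    stop("no significant features at this scale; ",
         "lower the screen alpha or choose another scale")
  }
  field <- switch(scale, node = "node", within = "within_network",
                  between = "between_network", global = "global_network")
  matA <- t(vapply(profilesA, `[[`, profilesA[[1]][[field]], field))
  matB <- t(vapply(profilesB, `[[`, profilesB[[1]][[field]], field))
  x <- rbind(matA[, keep, drop = FALSE], matB[, keep, drop = FALSE])
  complete <- colSums(is.na(x)) == 0
  if (!all(complete)) {
    warning("dropping feature(s) undefined for some subject: ",
            paste(keep[!complete], collapse = ", "))
    x <- x[, complete, drop = FALSE]
    keep <- keep[complete]
    if (!length(keep)) stop("no complete significant features remain")
  }
  y <- factor(c(rep("patient", nrow(matA)), rep("control", nrow(matB))),
              levels = c("control", "patient"))
  rownames(x) <- c(vapply(profilesA, `[[`, "", "id"),
                   vapply(profilesB, `[[`, "", "id"))
  list(x = x, y = y, features = keep)
}

#' Leave-one-out cross-validated classification
#'
#' Per fold: standardize features on the training subjects only (constant
#' training features are dropped for that fold), fit the backend classifier,
#' predict the held-out subject.  Accuracy, sensitivity (patients correctly
#' predicted) and specificity (controls correctly predicted) are aggregated
#' over folds; they are recomputable exactly from the returned per-subject
#' predictions.
#'
#' @param x subjects x features numeric matrix.
#' @param y factor of labels; the level `"patient"` is the positive class
#'   (any two-level factor works; the second level is treated as positive).
#' @param backend `"svm"` (linear kernel), `"lda"` or `"bagged_trees"`.
#' @param C SVM cost parameter.
#' @param seed RNG seed (only the bagged-trees backend is stochastic).
#' @param nested optional function `(x_train, y_train) -> column indices`
#'   performing feature selection inside each training fold.
#' @return object of class `nc_classifier`: `accuracy`, `sensitivity`,
#'   `specificity`, `predictions` (data.frame subject/truth/predicted),
#'   `backend`, `seed`.
#' @export
loocv_classify <- function(x, y, backend = c("svm", "lda", "bagged_trees"),
                           C = 1, seed = 1, nested = NULL) {
  backend <- match.arg(backend)
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) stop("labels must have exactly two levels")
  if (min(table(y)) < 3) stop("need at least 3 subjects per class")
  n <- nrow(x)
  pred <- character(n)
  set.seed(seed)
  fold_seeds <- sample.int(.Machine$integer.max, n)
  for (i in seq_len(n)) {
    xtr <- x[-i, , drop = FALSE]
    ytr <- y[-i]
    if (!is.null(nested)) {
      keep_cols <- nested(xtr, ytr)
      if (!length(keep_cols)) keep_cols <- seq_len(ncol(xtr))
      xtr <- xtr[, keep_cols, drop = FALSE]
      xte <- x[i, keep_cols, drop = FALSE]
    } else {
      xte <- x[i, , drop = FALSE]
    }
    mu <- colMeans(xtr)
    sds <- apply(xtr, 2, stats::sd)
    ok <- sds > 0
    if (!any(ok)) stop("all features constant in a training fold")
    xtr <- scale(xtr[, ok, drop = FALSE], center = mu[ok], scale = sds[ok])
    xte <- scale(xte[, ok, drop = FALSE], center = mu[ok], scale = sds[ok])
    set.seed(fold_seeds[i])
    pred[i] <- switch(backend,
      svm = {
        fit <- e1071::svm(xtr, ytr, kernel = "linear", cost = C,
                          scale = FALSE)
        as.character(predict(fit, xte))
      },
      lda = {
        fit <- MASS::lda(xtr, grouping = ytr)
        as.character(predict(fit, xte)$class)
      },
      bagged_trees = {
        if (!requireNamespace("randomForest", quietly = TRUE)) {
          stop("the bagged_trees backend needs the randomForest package")
        }
        # bagging = random forest with mtry = all features
        fit <- randomForest::randomForest(xtr, ytr, mtry = ncol(xtr),
                                          ntree = 100)
        as.character(predict(fit, xte))
      })
  }
  pos <- levels(y)[2]
  neg <- levels(y)[1]
  truth <- as.character(y)
  acc <- mean(pred == truth)
  sens <- mean(pred[truth == pos] == pos)
  spec <- mean(pred[truth == neg] == neg)
  preds <- data.frame(subject = rownames(x) %||% as.character(seq_len(n)),
                      truth = truth, predicted = pred,
                      stringsAsFactors = FALSE)
  structure(list(accuracy = acc, sensitivity = sens, specificity = spec,
                 predictions = preds, backend = backend, C = C, seed = seed),
            class = "nc_classifier")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Label-permutation significance of the LOOCV accuracy
#'
#' Permutes the subject labels, reruns the full LOOCV, and reports
#' p = (1 + #\{permuted accuracy >= observed\}) / (1 + n_perm).
#'
#' @inheritParams loocv_classify
#' @param n_perm number of label permutations (>= 1).
#' @param observed optionally a precomputed `nc_classifier` for (x, y).
#' @return list `p`, `observed_accuracy`, `null_accuracy` (vector),
#'   `n_perm`, `seed`.
#' @export
permutation_test_classifier <- function(x, y, n_perm = 5000, seed = 1,
                                        backend = "svm", C = 1,
                                        observed = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (is.null(observed)) {
    observed <- loocv_classify(x, y, backend = backend, C = C, seed = seed)
  }
  set.seed(seed)
  perm_seeds <- sample.int(.Machine$integer.max, n_perm)
  null_acc <- vapply(seq_len(n_perm), function(b) {
    set.seed(perm_seeds[b])
    yp <- sample(y)
    loocv_classify(x, yp, backend = backend, C = C,
                   seed = perm_seeds[b])$accuracy
  }, numeric(1))
  p <- (1 + sum(null_acc >= observed$accuracy)) / (1 + n_perm)
  list(p = p, observed_accuracy = observed$accuracy,
       null_accuracy = null_acc, n_perm = n_perm, seed = seed)
}
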