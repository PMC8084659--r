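#' Assemble a labeled dataset from feature matrices
#'
#' @param X M x N numeric feature matrix (N = 25 for this pipeline).
#' @param labels Character/factor vector of M class labels drawn from
#'   NORMAL, RBBB, AF.
#' @param provenance Optional record ids.
#' @return List of class `labeled_dataset` with `X`, `y` (factor with the
#'   fixed class order NORMAL, RBBB, AF) and `provenance`.
#' @export
labeled_dataset <- function(X, labels, provenance = NULL) {
  X <- as.matrix(X)
  stopifnot(nrow(X) > 0, !anyNA(X), length(labels) == nrow(X))
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  labs <- as.character(labels)
  bad <- setdiff(unique(labs), CLASS_LEVELS)
  if (length(bad) > 0) {
    stop("unknown class label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(X = X, y = factor(labs, levels = CLASS_LEVELS),
                 provenance = provenance),
            class = "labeled_dataset")
}

#' Expected beat count from raw sample totals
#'
#' Dataset bookkeeping for fixed-width segmentation: with 200 samples per
#' beat, per-class raw sample counts translate into training/test tuple
#' counts by integer division.
#'
#' @param sample_counts Numeric vector of per-class raw sample counts.
#' @param beat_samples Samples per beat (default 200).
#' @return List with `total_samples` and `n_beats`.
#' @export
dataset_arithmetic <- function(sample_counts, beat_samples = 200L) {
  total <- sum(sample_counts)
  list(total_samples = total, n_beats = total %/% beat_samples)
}

#' Train a multiclass beat classifier
#'
#' Three candidate model families are supported: a single decision tree
#' (`rpart`), multinomial (softmax) logistic regression (`nnet::multinom`)
#' and a random forest with a default of 10 trees (`randomForest`). All
#' training is deterministic given `seed`.
#'
#' @param dataset A [labeled_dataset].
#' @param kind One of `"decision_tree"`, `"logistic_regression"`,
#'   `"random_forest"`.
#' @param seed Integer training seed.
#' @param n_trees Number of trees for the random forest.
#' @return Object of class `ecg_model` with the fitted state, `kind`,
#'   `class_order`, `seed` and hyperparameters.
#' @export
train_classifier <- function(dataset,
                             kind = c("random_forest", "decision_tree",
                                      "logistic_regression"),
                             seed = 1L, n_trees = 10L) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  kind <- match.arg(kind)
  if (nlevels(droplevels(dataset$y)) < 2) {
    stop("degenerate training set: only one class present", call. = FALSE)
  }
  df <- as.data.frame(dataset$X)
  df$.y <- dataset$y
  fit <- withr::with_seed(as.integer(seed), switch(
    kind,
    decision_tree = rpart::rpart(.y ~ ., data = df, method = "class"),
    logistic_regression = nnet::multinom(.y ~ ., data = df, trace = FALSE,
                                         maxit = 300, MaxNWts = 5000),
    random_forest = randomForest::randomForest(
      x = dataset$X, y = dataset$y, ntree = n_trees)
  ))
  structure(list(kind = kind, fit = fit, class_order = CLASS_LEVELS,
                 seed = as.integer(seed),
                 hyperparams = if (kind == "random_forest")
                   list(n_trees = as.integer(n_trees)) else list(),
                 n_features = ncol(dataset$X)),
            class = "ecg_model")
}

#' Predict beat classes (and per-class scores)
#'
#' For the random forest the label is the majority vote over trees and the
#' scores are the vote fractions (summing to 1 per beat); ties are broken
#' deterministically toward the earliest class in `class_order`. For the
#' other families the scores are fitted class probabilities.
#'
#' @param model An `ecg_model`.
#' @param X Feature matrix with the training feature width (25).
#' @return List with `label` (factor) and `scores` (matrix, one column per
#'   class in `class_order`).
#' @export
predict_beats <- function(model, X) {
  stopifnot(inherits(model, "ecg_model"))
  X <- as.matrix(X)
  if (ncol(X) != model$n_features) {
    stop(sprintf("feature width %d does not match model width %d",
                 ncol(X), model$n_features), call. = FALSE)
  }
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  df <- as.data.frame(X)
  scores <- switch(
    model$kind,
    decision_tree = predict(model$fit, df, type = "prob"),
    logistic_regression = {
      p <- predict(model$fit, df, type = "probs")
      if (is.null(dim(p))) p <- rbind(p)  # single-row edge case
      p
    },
    random_forest = {
      v <- predict(model$fit, X, type = "vote", norm.votes = TRUE)
      unclass(v)
    })
  # fixed column order, tolerate models fitted on a class subset
  S <- matrix(0, nrow = nrow(X), ncol = length(model$class_order),
              dimnames = list(NULL, model$class_order))
  for (cl in intersect(colnames(scores), model$class_order)) {
    S[, cl] <- scores[, cl]
  }
  list(label = vote_to_label(S, model$class_order), scores = S)
}

# Deterministic argmax over per-class scores: on a tie (e.g. a 5-vs-5 tree
# vote split) the earliest class in class_order wins.
vote_to_label <- function(scores, class_order) {
  lab <- class_order[apply(scores[, class_order, drop = FALSE], 1, which.max)]
  factor(lab, levels = class_order)
}

#' Multiclass metric suite (one-vs-rest, macro averaged)
#'
#' Builds the per-class one-vs-rest confusion counts and reports, per class
#' and macro-averaged: sensitivity = TP/(TP+FN) x 100, specificity =
#' TN/(TN+FP) x 100, precision, F1 and the false positive rate
#' FP/(FP+TN) (a fraction). Overall accuracy is correct/M x 100. When
#' per-class scores are supplied, a macro one-vs-rest ROC AUC is computed.
#' The identity specificity = (1 - FPR) x 100 holds exactly, per class and
#' in the macro average.
#'
#' @param truth True labels.
#' @param pred Predicted labels.
#' @param scores Optional score matrix with one named column per class.
#' @return Object of class `metric_report`: `per_class` data.frame and
#'   scalars `accuracy`, `sensitivity`, `specificity`, `precision`, `f1`,
#'   `auc` (all percent), `fpr` (fraction).
#' @export
evaluate_predictions <- function(truth, pred, scores = NULL) {
  if (length(truth) != length(pred)) {
    stop("truth and pred lengths differ", call. = FALSE)
  }
  lv <- CLASS_LEVELS[CLASS_LEVELS %in% unique(as.character(truth))]
  if (length(lv) < 2) stop("need >= 2 classes in truth", call. = FALSE)
  truth <- factor(as.character(truth), levels = CLASS_LEVELS)
  pred <- factor(as.character(pred), levels = CLASS_LEVELS)
  m <- length(truth)
  per <- do.call(rbind, lapply(CLASS_LEVELS, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    tn <- m - tp - fp - fn
    sens <- if (tp + fn > 0) tp / (tp + fn) * 100 else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) * 100 else NA_real_
    prec <- if (tp + fp > 0) tp / (tp + fp) * 100 else NA_real_
    f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0)
      2 * prec * sens / (prec + sens) else NA_real_
    fpr <- if (fp + tn > 0) fp / (fp + tn) else NA_real_
    data.frame(class = cl, TP = tp, FP = fp, TN = tn, FN = fn,
               sensitivity = sens, specificity = spec, precision = prec,
               f1 = f1, fpr = fpr, stringsAsFactors = FALSE)
  }))
  present <- per$class %in% lv
  auc <- NA_real_
  if (!is.null(scores)) {
    aucs <- vapply(lv, function(cl) {
      resp <- as.integer(truth == cl)
      if (length(unique(resp)) < 2) return(NA_real_)
      as.numeric(pROC::auc(pROC::roc(resp, scores[, cl], quiet = TRUE,
                                     direction = "<")))
    }, numeric(1))
    auc <- mean(aucs, na.rm = TRUE) * 100
  }
  structure(list(
    per_class = per,
    accuracy = sum(truth == pred) / m * 100,
    sensitivity = mean(per$sensitivity[present]),
    specificity = mean(per$specificity[present]),
    precision = mean(per$precision[present], na.rm = TRUE),
    f1 = mean(per$f1[present], na.rm = TRUE),
    auc = auc,
    fpr = mean(per$fpr[present]),
    n = m), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Multiclass metrics (macro one-vs-rest, n = ", x$n, ")\n", sep = "")
  vals <- c(Accuracy = x$accuracy, Sensitivity = x$sensitivity,
            Specificity = x$specificity, `F1-score` = x$f1,
            Precision = x$precision, `AUC score` = x$auc)
  vals <- vals[!is.na(vals)]
  cat(sprintf("  %-12s %6.2f %%\n", names(vals), vals), sep = "")
  cat(sprintf("  %-12s %6.4f\n", "FPR", x$fpr))
  invisible(x)
}

#' Select the best model on a validation set
#'
#' Candidates are compared by macro F1; ties broken by higher accuracy,
#' then by declaration order. A comparison table is attached to the result.
#'
#' @param candidates Named list of `ecg_model` objects (>= 2).
#' @param validation A [labeled_dataset].
#' @return List with `best` (an `ecg_model`), `best_name` and `comparison`
#'   (data.frame of macro F1/accuracy per candidate).
#' @export
model_select <- function(candidates, validation) {
  stopifnot(length(candidates) >= 2, inherits(validation, "labeled_dataset"))
  if (nrow(validation$X) == 0) stop("empty validation set", call. = FALSE)
  if (is.null(names(candidates))) {
    names(candidates) <- vapply(candidates, `[[`, "", "kind")
  }
  comp <- do.call(rbind, lapply(seq_along(candidates), function(i) {
    p <- predict_beats(candidates[[i]], validation$X)
    r <- evaluate_predictions(validation$y, p$label, p$scores)
    data.frame(model = names(candidates)[i], kind = candidates[[i]]$kind,
               f1 = r$f1, accuracy = r$accuracy, auc = r$auc,
               stringsAsFactors = FALSE)
  }))
  ord <- order(-comp$f1, -comp$accuracy, seq_len(nrow(comp)))
  best_i <- ord[1]
  list(best = candidates[[best_i]], best_name = comp$model[best_i],
       comparison = comp)
}

MODEL_FORMAT <- "ecgstream-model"
MODEL_VERSION <- 1L

#' Persist / load a trained model
#'
#' The artifact embeds a header (format tag, version, kind, hyperparameters,
#' class order, training seed, feature width) next to the fitted state; a
#' reloaded model yields identical predictions. A file that is not a model
#' artifact, or carries an unknown version, raises a load error rather than
#' silently falling back.
#'
#' @param model An `ecg_model`.
#' @param path Artifact path.
#' @return `save_model`: `path`, invisibly. `load_model`: the `ecg_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ecg_model"))
  obj <- list(header = list(format = MODEL_FORMAT, version = MODEL_VERSION,
                            kind = model$kind,
                            hyperparams = model$hyperparams,
                            class_order = model$class_order,
                            seed = model$seed,
                            n_features = model$n_features),
              model = model)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("cannot load model artifact: ", conditionMessage(e), call. = FALSE)
  })
  if (!is.list(obj) || is.null(obj$header) ||
      !identical(obj$header$format, MODEL_FORMAT)) {
    stop("not an ecgstream model artifact: ", path, call. = FALSE)
  }
  if (!identical(obj$header$version, MODEL_VERSION)) {
    stop("model artifact version mismatch (got ", obj$header$version, ")",
         call. = FALSE)
  }
  obj$model
}
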