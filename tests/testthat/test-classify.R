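separable_dataset <- function(n_per = 30, sd = 0.05, seed = 1) {
  withr::with_seed(seed, {
    centers <- list(NORMAL = c(rep(3, 5), rep(0, 20)),
                    RBBB = c(rep(0, 5), rep(3, 5), rep(0, 15)),
                    AF = c(rep(0, 10), rep(3, 5), rep(0, 10)))
    X <- do.call(rbind, lapply(centers, function(mu) {
      matrix(rnorm(n_per * 25, sd = sd), ncol = 25) +
        matrix(mu, n_per, 25, byrow = TRUE)
    }))
    labeled_dataset(X, rep(names(centers), each = n_per))
  })
}

test_that("all three model families separate well-separated clusters", {
  ds <- separable_dataset()
  for (kind in c("decision_tree", "logistic_regression", "random_forest")) {
    m <- train_classifier(ds, kind, seed = 2)
    p <- predict_beats(m, ds$X)
    expect_equal(mean(p$label == ds$y), 1,
                 info = paste("training accuracy for", kind))
  }
})

test_that("training is deterministic given the seed and rejects degenerate input", {
  ds <- separable_dataset()
  probe <- separable_dataset(seed = 9)$X
  m1 <- train_classifier(ds, "random_forest", seed = 7)
  m2 <- train_classifier(ds, "random_forest", seed = 7)
  expect_identical(predict_beats(m1, probe)$label,
                   predict_beats(m2, probe)$label)
  one_class <- labeled_dataset(matrix(rnorm(100), ncol = 25),
                               rep("NORMAL", 4))
  expect_error(train_classifier(one_class, "random_forest"), "degenerate")
})

test_that("prediction scores are normalized and shape errors are caught", {
  ds <- separable_dataset()
  m <- train_classifier(ds, "random_forest", seed = 2)
  p <- predict_beats(m, ds$X)
  expect_equal(unname(rowSums(p$scores)), rep(1, nrow(ds$X)),
               tolerance = 1e-12)
  expect_error(predict_beats(m, ds$X[, 1:10]), "feature width")
})

test_that("tied votes break deterministically toward the earliest class", {
  classes <- c("NORMAL", "RBBB", "AF")
  # constructed 5-vs-5 tree-vote tie between RBBB and AF
  S <- matrix(c(0, 0.5, 0.5), 1, 3, dimnames = list(NULL, classes))
  expect_equal(as.character(ecgstream:::vote_to_label(S, classes)), "RBBB")
  # unanimity returns that class
  S2 <- matrix(c(0, 0, 1), 1, 3, dimnames = list(NULL, classes))
  expect_equal(as.character(ecgstream:::vote_to_label(S2, classes)), "AF")
  # three-way tie: first class in class_order
  S3 <- matrix(1 / 3, 1, 3, dimnames = list(NULL, classes))
  expect_equal(as.character(ecgstream:::vote_to_label(S3, classes)), "NORMAL")
})

test_that("metric suite matches hand-counted confusion arithmetic", {
  # truth -> pred counts: A:[5,0,0], B:[1,4,0], C:[0,0,5]
  truth <- c(rep("NORMAL", 5), rep("RBBB", 5), rep("AF", 5))
  pred <- c(rep("NORMAL", 5), "NORMAL", rep("RBBB", 4), rep("AF", 5))
  r <- evaluate_predictions(truth, pred)
  expect_equal(r$accuracy, 14 / 15 * 100, tolerance = 1e-12)
  expect_equal(r$sensitivity, (100 + 80 + 100) / 3, tolerance = 1e-12)

  # perfect predictions
  rp <- evaluate_predictions(truth, truth)
  expect_equal(rp$accuracy, 100)
  expect_equal(rp$sensitivity, 100)
  expect_equal(rp$specificity, 100)
  expect_equal(rp$fpr, 0)

  # constant predictor on balanced truth
  rc <- evaluate_predictions(truth, rep("NORMAL", 15))
  expect_equal(rc$accuracy, 100 / 3, tolerance = 1e-12)
  expect_equal(rc$per_class$specificity[rc$per_class$class == "NORMAL"], 0)
})

test_that("evaluate matches brute-force counting on random label vectors", {
  withr::with_seed(42, {
    for (i in 1:25) {
      n <- sample(10:1000, 1)
      truth <- sample(c("NORMAL", "RBBB", "AF"), n, replace = TRUE)
      pred <- sample(c("NORMAL", "RBBB", "AF"), n, replace = TRUE)
      if (length(unique(truth)) < 2) next
      r <- evaluate_predictions(truth, pred)
      bf <- brute_force_metrics(truth, pred)
      for (cl in names(bf)) {
        row <- r$per_class[r$per_class$class == cl, ]
        expect_equal(unlist(row[c("TP", "FP", "TN", "FN")]),
                     bf[[cl]][c("TP", "FP", "TN", "FN")],
                     ignore_attr = TRUE)
        expect_equal(row$TP + row$FP + row$TN + row$FN, n)
        # exact complement identity, per class
        expect_equal(row$specificity, (1 - row$fpr) * 100, tolerance = 1e-12)
      }
      expect_equal(r$specificity, (1 - r$fpr) * 100, tolerance = 1e-10)
    }
  })
})

test_that("mismatched or single-class inputs raise shape errors", {
  expect_error(evaluate_predictions(c("NORMAL", "RBBB"), "NORMAL"),
               "lengths differ")
  expect_error(evaluate_predictions(rep("NORMAL", 5), rep("NORMAL", 5)),
               ">= 2 classes")
})

test_that("AUC from scores is 100 for a perfect scorer", {
  truth <- c(rep("NORMAL", 5), rep("RBBB", 5), rep("AF", 5))
  S <- matrix(0, 15, 3, dimnames = list(NULL, c("NORMAL", "RBBB", "AF")))
  S[cbind(seq_len(15), match(truth, colnames(S)))] <- 1
  r <- evaluate_predictions(truth, truth, S)
  expect_equal(r$auc, 100)
})

test_that("model_select prefers F1, then accuracy, then declaration order", {
  ds <- separable_dataset()
  good <- train_classifier(ds, "random_forest", seed = 2)
  bad <- train_classifier(labeled_dataset(ds$X + rnorm(length(ds$X), sd = 5),
                                          ds$y), "decision_tree", seed = 2)
  sel <- model_select(list(noisy = bad, clean = good), ds)
  expect_equal(sel$best_name, "clean")
  expect_equal(nrow(sel$comparison), 2)

  # equal candidates: first declared wins
  sel2 <- model_select(list(first = good, second = good), ds)
  expect_equal(sel2$best_name, "first")
  expect_error(model_select(list(good), ds), "length")
})

test_that("model artifacts round-trip exactly and refuse corrupt files", {
  td <- withr::local_tempdir()
  ds <- separable_dataset()
  probe <- separable_dataset(seed = 30)$X
  m <- train_classifier(ds, "random_forest", seed = 4)
  p <- file.path(td, "m.rds")
  save_model(m, p)
  m2 <- load_model(p)
  expect_identical(predict_beats(m, probe)$label,
                   predict_beats(m2, probe)$label)
  expect_identical(predict_beats(m, probe)$scores,
                   predict_beats(m2, probe)$scores)

  bad <- file.path(td, "bad.rds")
  writeLines("this is not a model", bad)
  expect_error(load_model(bad), "cannot load")
  notmodel <- file.path(td, "nm.rds")
  saveRDS(list(a = 1), notmodel)
  expect_error(load_model(notmodel), "not an ecgstream model")
})

test_that("held-out F1 does not decrease as class separation grows", {
  f1_at <- function(sep) {
    mk <- function(seed) withr::with_seed(seed, {
      centers <- list(NORMAL = c(rep(sep, 5), rep(0, 20)),
                      RBBB = c(rep(0, 5), rep(sep, 5), rep(0, 15)),
                      AF = c(rep(0, 10), rep(sep, 5), rep(0, 10)))
      X <- do.call(rbind, lapply(centers, function(mu) {
        matrix(rnorm(40 * 25, sd = 1), ncol = 25) +
          matrix(mu, 40, 25, byrow = TRUE)
      }))
      labeled_dataset(X, rep(names(centers), each = 40))
    })
    tr <- mk(100); te <- mk(200)
    m <- train_classifier(tr, "random_forest", seed = 5)
    p <- predict_beats(m, te$X)
    evaluate_predictions(te$y, p$label)$f1
  }
  f1s <- vapply(c(0.2, 1, 3), f1_at, numeric(1))
  expect_true(all(diff(f1s) >= 0))
})
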