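# Brute-force oracle: best training accuracy achievable with one
# axis-aligned threshold split (majority vote in each half).
best_single_split_accuracy <- function(X, y) {
  n <- length(y)
  best <- max(table(y)) / n          # no split at all
  for (f in seq_len(ncol(X))) {
    for (thr in unique(X[, f])) {
      left <- X[, f] <= thr
      if (!any(left) || all(left)) next
      acc <- (max(table(y[left])) + max(table(y[!left]))) / n
      best <- max(best, acc)
    }
  }
  best
}

toy_features <- function(n, seed) {
  set.seed(seed)
  data.frame(variability = runif(n, 0, 0.2), normality = runif(n),
             mean_rr = runif(n, 0.4, 1.2))
}

test_that("a one-threshold-separable set is solved by a single split", {
  d <- toy_features(60, 1)
  d$label <- ifelse(d$variability > 0.1, "AF", "non-AF")
  fit <- mesc_tree(label ~ variability + normality + mean_rr, d,
                   max_splits = 30)
  expect_equal(fit$n_splits, 1L)
  expect_equal(fit$training_accuracy, 1.0)
  expect_equal(predict(fit, d), d$label)
  expect_equal(fit$nodes$feature[1], 1L)   # split on variability
})

test_that("XOR geometry defeats a single split", {
  d <- data.frame(variability = c(0, 0, 1, 1), normality = c(0, 1, 0, 1),
                  mean_rr = 0.8,
                  label = c("A", "B", "B", "A"))
  fit <- mesc_tree(label ~ variability + normality + mean_rr, d,
                   max_splits = 1)
  expect_lte(fit$training_accuracy, 0.75)
  expect_lte(fit$training_accuracy,
             best_single_split_accuracy(as.matrix(d[, 1:3]), d$label))
})

test_that("single-split trees never beat the enumeration oracle", {
  for (seed in 1:10) {
    d <- toy_features(40, seed)
    d$label <- ifelse(d$normality + rnorm(40, 0, 0.3) > 0.5, "AF", "non-AF")
    if (length(unique(d$label)) < 2) next
    fit <- mesc_tree(label ~ variability + normality + mean_rr, d,
                     max_splits = 1)
    expect_lte(fit$training_accuracy,
               best_single_split_accuracy(as.matrix(d[, 1:3]), d$label) + 1e-12)
  }
})

test_that("the split cap bounds the number of internal nodes", {
  set.seed(99)
  d <- toy_features(400, 99)
  d$label <- sample(c("AF", "non-AF"), 400, replace = TRUE)  # noise: deep tree
  for (cap in c(1, 5, 30)) {
    fit <- mesc_tree(label ~ variability + normality + mean_rr, d,
                     max_splits = cap)
    expect_lte(fit$n_splits, cap)
    expect_lte(sum(!is.na(fit$nodes$feature)), cap)
  }
  expect_error(mesc_tree(label ~ variability, transform(d, label = "AF")),
               "2 classes")
})

test_that("prediction is deterministic and faithful to training labels", {
  d <- toy_features(120, 3)
  d$label <- ifelse(d$variability > 0.06 & d$normality > 0.5, "AF", "non-AF")
  fit1 <- mesc_tree(label ~ variability + normality + mean_rr, d, 30)
  fit2 <- mesc_tree(label ~ variability + normality + mean_rr, d, 30)
  expect_identical(fit1$nodes, fit2$nodes)             # determinism
  expect_equal(predict(fit1, d), d$label)              # pure tree recalls
  expect_identical(predict(fit1, d), predict(fit1, d))
  # out-of-range points route by threshold comparison without error
  far <- data.frame(variability = c(-5, 50), normality = c(-2, 7),
                    mean_rr = c(0, 100))
  expect_length(predict(fit1, far), 2)
  expect_error(predict(fit1, d[, c("variability", "mean_rr")]),
               "lacks feature")
})

test_that("tree agrees with rpart on a cleanly separable problem", {
  d <- toy_features(200, 17)
  d$label <- ifelse(d$variability > 0.1, "AF", "non-AF")
  fit <- mesc_tree(label ~ variability + normality + mean_rr, d, 30)
  rp <- rpart::rpart(label ~ variability + normality + mean_rr, d,
                     method = "class",
                     control = rpart::rpart.control(cp = 0, minsplit = 2))
  expect_equal(predict(fit, d),
               as.character(predict(rp, d, type = "class")))
})

test_that("trees survive a JSON round trip", {
  d <- toy_features(150, 23)
  d$label <- ifelse(d$normality > 0.6, "AF", "non-AF")
  fit <- mesc_tree(label ~ variability + normality + mean_rr, d, 10)
  f <- withr::local_tempfile(fileext = ".json")
  write_tree_json(fit, f)
  back <- read_tree_json(f)
  expect_equal(predict(back, d), predict(fit, d))
  expect_equal(back$max_splits, fit$max_splits)
  expect_equal(back$features, fit$features)
})

test_that("clinical metrics match their formulas exactly", {
  mk <- function(TP, FN, TN, FP) {
    truth <- c(rep("AF", TP + FN), rep("non-AF", TN + FP))
    pred <- c(rep("AF", TP), rep("non-AF", FN), rep("non-AF", TN),
              rep("AF", FP))
    evaluate_detection(pred, truth)
  }
  m <- mk(9, 1, 8, 2)
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$ppv, 9 / 11)
  expect_equal(m$npv, 8 / 9)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$f1, 18 / 21)

  perfect <- mk(5, 0, 5, 0)
  expect_equal(unlist(perfect[c("sensitivity", "specificity", "ppv", "npv",
                                "accuracy", "f1")]),
               rep(1, 6), ignore_attr = TRUE)

  # enumerated confusion tables: integer-exact metric identities
  for (TP in 0:3) for (FN in 0:3) for (TN in 0:3) for (FP in 0:3) {
    if (TP + FN + TN + FP == 0) next
    m <- mk(TP, FN, TN, FP)
    expect_identical(c(m$TP, m$FN, m$TN, m$FP), c(TP, FN, TN, FP))
    P <- TP + FN; N <- TN + FP
    if (P > 0 && N > 0) {
      expect_equal(m$accuracy,
                   (m$sensitivity * P + m$specificity * N) / (P + N))
    }
  }
})

test_that("all-negative sets report only specificity and accuracy", {
  m <- evaluate_detection(rep("non-AF", 10), rep("non-AF", 10))
  expect_true(is.na(m$sensitivity) && is.na(m$ppv) && is.na(m$f1))
  expect_equal(m$specificity, 1)
  expect_equal(m$accuracy, m$specificity)
  expect_error(evaluate_detection("AF", c("AF", "AF")), "equal-length")
})

cv_records <- local({
  cohort <- gen_cohort(8, af_burden_range = c(0.2, 0.8), seed = 77,
                       beats_per_record = 1600)
  lapply(cohort, function(r) list(rr = r$rr, segments = r$segments))
})

test_that("cross-validation assigns whole records to folds and picks the argmax", {
  cv <- cross_validate(cv_records, orders = 1, window_lengths = c(70, 150),
                       folds = 4, seed = 5, stride = 35)
  expect_length(cv$fold_of, length(cv_records))        # record-level folds
  expect_setequal(unique(cv$fold_of), 1:4)
  expect_equal(cv$best, which.max(cv$grid$mean_accuracy))
  expect_true(is.na(cv$grid$p_value[cv$best]))
  others <- cv$grid$p_value[-cv$best]
  expect_true(all(others > 0 & others <= 1))

  # duplicated cells are statistically indistinguishable from the best
  cv2 <- cross_validate(cv_records, orders = 1,
                        window_lengths = c(150, 150), folds = 4, seed = 5,
                        stride = 35)
  expect_equal(cv2$grid$mean_accuracy[1], cv2$grid$mean_accuracy[2])
  expect_equal(cv2$grid$p_value[-cv2$best], 0.5)
  expect_error(cross_validate(cv_records[1:3], folds = 4), "more records")
})

test_that("patient-to-self skips single-class records and accepts the cap list", {
  tabs <- lapply(cv_records[1:5], function(r)
    compute_indices(r$rr, r$segments, index_config(window_length = 150,
                                                   stride = 35)))
  nsr <- single_rhythm_record("NSR", n_beats = 1500, seed = 50)
  tabs$nsr_only <- compute_indices(nsr$rr, nsr$segments,
                                   index_config(stride = 35))
  res <- patient_to_self(tabs, split_caps = c(2, 3, 4, 10, 20, 30, 50, 100))
  expect_true("NSR50" %in% res$skipped)   # short records may also be skipped
  expect_equal(dim(res$accuracy), c(6L, 8L))
  expect_length(res$mean_accuracy, 8L)
  expect_true(all(res$mean_accuracy >= 0 & res$mean_accuracy <= 1))
})

test_that("cross-database training enforces disjoint ids and flags the train set", {
  tabs <- lapply(cv_records, function(r)
    compute_indices(r$rr, r$segments, index_config(stride = 35)))
  train <- do.call(rbind, tabs[1:4])
  test_b <- do.call(rbind, tabs[5:8])
  res <- cross_database(train, list(B = test_b))
  expect_true(isTRUE(attr(res$reports$train, "optimistic")))
  expect_gte(res$reports$train$accuracy, res$reports$B$accuracy - 0.05)
  expect_error(cross_database(train, list(bad = train)), "shared")

  # NSR-only test set: only Sp and ACC are defined
  nsr <- single_rhythm_record("NSR", n_beats = 1500, seed = 51)
  t_nsr <- compute_indices(nsr$rr, nsr$segments, index_config(stride = 35))
  rep_nsr <- cross_database(train, list(nsr = t_nsr))$reports$nsr
  expect_true(is.na(rep_nsr$sensitivity))       # no positives in the truth
  expect_false(is.na(rep_nsr$specificity))
  expect_false(is.na(rep_nsr$accuracy))
  if (rep_nsr$FP == 0) expect_true(is.na(rep_nsr$ppv) && is.na(rep_nsr$f1))
})
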