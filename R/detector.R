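# The explainable split-capped decision-tree AF detector and the evaluation
# protocols built around it.

# --------------------------------------------------------------------------
# Tree growing: best-first axis-aligned CART on Gini impurity.  The number of
# internal split nodes is capped (`max_splits`); ties on impurity gain break
# deterministically to the lowest feature index, then the lowest threshold,
# then the lowest (oldest) leaf id.

#' Gini impurity of a class-count vector
#' @noRd
.gini <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

#' Best single split of one leaf: list(gain, feature, threshold) or NULL
#' @noRd
.best_split <- function(X, yint, idx, n_classes, eps = 1e-12) {
  n <- length(idx)
  if (n < 2L) return(NULL)
  parent_counts <- tabulate(yint[idx], n_classes)
  g_parent <- .gini(parent_counts)
  if (g_parent <= eps) return(NULL)
  best <- NULL
  for (f in seq_len(ncol(X))) {
    x <- X[idx, f]
    o <- order(x, method = "radix")
    xs <- x[o]
    ys <- yint[idx][o]
    # cumulative class counts on the left of each cut position
    cut_ok <- which(diff(xs) > 0)        # split between positions i and i+1
    if (length(cut_ok) == 0L) next
    # n_classes x n matrix of cumulative class counts left of each position
    left_cum <- t(vapply(seq_len(n_classes), function(k) cumsum(ys == k),
                         numeric(n)))
    nl <- cut_ok
    nr <- n - nl
    gl <- 1 - colSums((left_cum[, cut_ok, drop = FALSE] / rep(nl, each = n_classes))^2)
    right_counts <- parent_counts - left_cum[, cut_ok, drop = FALSE]
    gr <- 1 - colSums((right_counts / rep(nr, each = n_classes))^2)
    gain <- g_parent - (nl * gl + nr * gr) / n
    bi <- which.max(gain)                # first max = lowest threshold
    if (gain[bi] > eps &&
        (is.null(best) || gain[bi] > best$gain + eps)) {
      best <- list(gain = gain[bi], feature = f,
                   threshold = (xs[cut_ok[bi]] + xs[cut_ok[bi] + 1L]) / 2)
    }
  }
  best
}

#' Fit a split-capped decision tree over the irregularity indices
#'
#' Best-first recursive axis-aligned splitting that minimizes Gini impurity,
#' grown until all leaves are pure or the cap on the number of internal
#' split nodes is reached.  The cap (default 30) is the guard against
#' overfitting; the fit is fully deterministic.
#'
#' @param formula model formula, e.g.
#'   `label ~ variability + normality + mean_rr`.
#' @param data data.frame holding the response and features.
#' @param max_splits maximum number of internal split nodes (>= 1).
#' @return object of class `mesc_tree` with `print`, `summary` and `predict`
#'   methods.
#' @examples
#' d <- data.frame(variability = c(0.01, 0.02, 0.1, 0.12),
#'                 normality = c(0.5, 0.6, 0.95, 0.9),
#'                 mean_rr = c(0.9, 0.85, 0.5, 0.55),
#'                 label = c("non-AF", "non-AF", "AF", "AF"))
#' fit <- mesc_tree(label ~ variability + normality + mean_rr, d)
#' predict(fit, d)
#' @export
mesc_tree <- function(formula, data, max_splits = 30L) {
  max_splits <- as.integer(max_splits)
  if (max_splits < 1L) stop("max_splits must be >= 1", call. = FALSE)
  mf <- stats::model.frame(formula, data)
  y <- factor(mf[[1L]])
  if (nlevels(y) < 2L) {
    stop("training data must contain at least 2 classes", call. = FALSE)
  }
  X <- as.matrix(mf[, -1L, drop = FALSE])
  if (!is.numeric(X)) stop("all features must be numeric", call. = FALSE)
  fit <- .grow_tree(X, as.integer(y), nlevels(y), max_splits)
  nodes <- fit$nodes
  nodes$label <- ifelse(is.na(nodes$class), NA_character_,
                        levels(y)[nodes$class])
  obj <- structure(list(
    nodes = nodes,
    features = colnames(X),
    classes = levels(y),
    max_splits = max_splits,
    n_splits = sum(!is.na(nodes$feature)),
    n = nrow(X),
    call = match.call()), class = "mesc_tree")
  obj$training_accuracy <- mean(predict(obj, as.data.frame(X)) == as.character(y))
  obj
}

#' Workhorse: grow the capped tree
#' @noRd
.grow_tree <- function(X, yint, n_classes, max_splits) {
  # node table; feature NA => leaf.  class = majority class (ties: lowest id)
  nodes <- data.frame(id = 1L, feature = NA_integer_, threshold = NA_real_,
                      left = NA_integer_, right = NA_integer_,
                      class = NA_integer_, n = nrow(X))
  members <- list(seq_len(nrow(X)))
  cand <- list(.best_split(X, yint, members[[1L]], n_classes))
  majority <- function(idx) which.max(tabulate(yint[idx], n_classes))
  nodes$class[1L] <- majority(members[[1L]])
  n_split <- 0L
  while (n_split < max_splits) {
    gains <- vapply(cand, function(c) if (is.null(c)) -Inf else c$gain,
                    numeric(1))
    leaf_open <- is.na(nodes$feature) & gains > -Inf
    if (!any(leaf_open)) break
    # strictly-greatest gain wins; ties go to the lowest (oldest) node id
    b <- which(leaf_open)[which.max(gains[leaf_open])]
    sp <- cand[[b]]
    idx <- members[[b]]
    go_left <- X[idx, sp$feature] <= sp$threshold
    lid <- nrow(nodes) + 1L
    rid <- nrow(nodes) + 2L
    nodes[lid, ] <- list(lid, NA_integer_, NA_real_, NA_integer_, NA_integer_,
                         majority(idx[go_left]), sum(go_left))
    nodes[rid, ] <- list(rid, NA_integer_, NA_real_, NA_integer_, NA_integer_,
                         majority(idx[!go_left]), sum(!go_left))
    nodes$feature[b] <- sp$feature
    nodes$threshold[b] <- sp$threshold
    nodes$left[b] <- lid
    nodes$right[b] <- rid
    nodes$class[b] <- NA_integer_
    members[[b]] <- integer(0)
    members[[lid]] <- idx[go_left]
    members[[rid]] <- idx[!go_left]
    cand[b] <- list(NULL)       # node b is internal now; never re-split
    cand[lid] <- list(.best_split(X, yint, members[[lid]], n_classes))
    cand[rid] <- list(.best_split(X, yint, members[[rid]], n_classes))
    n_split <- n_split + 1L
  }
  list(nodes = nodes)
}

#' Predict rhythm labels with a fitted tree
#'
#' @param object a `mesc_tree`.
#' @param newdata data.frame containing the training feature columns.
#' @param ... unused.
#' @return character vector of predicted labels.
#' @export
predict.mesc_tree <- function(object, newdata, ...) {
  stopifnot(is.data.frame(newdata) || is.matrix(newdata))
  newdata <- as.data.frame(newdata)
  missing_f <- setdiff(object$features, names(newdata))
  if (length(missing_f) > 0L) {
    stop("newdata lacks feature(s): ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  nodes <- object$nodes
  node <- rep(1L, nrow(X))
  repeat {
    is_leaf <- is.na(nodes$feature[node])
    if (all(is_leaf)) break
    act <- which(!is_leaf)
    f <- nodes$feature[node[act]]
    thr <- nodes$threshold[node[act]]
    xv <- X[cbind(act, f)]
    node[act] <- ifelse(xv <= thr, nodes$left[node[act]],
                        nodes$right[node[act]])
  }
  nodes$label[node]
}

#' @export
print.mesc_tree <- function(x, ...) {
  cat(sprintf("Split-capped decision tree: %d split(s) (cap %d), %d training windows\n",
              x$n_splits, x$max_splits, x$n))
  cat(sprintf("Training accuracy: %.4f\n", x$training_accuracy))
  .print_node <- function(id, depth) {
    pad <- strrep("  ", depth)
    nd <- x$nodes[id, ]
    if (is.na(nd$feature)) {
      cat(sprintf("%s* predict '%s' (n=%d)\n", pad, nd$label, nd$n))
    } else {
      cat(sprintf("%s%s <= %.6g (n=%d)\n", pad, x$features[nd$feature],
                  nd$threshold, nd$n))
      .print_node(nd$left, depth + 1L)
      cat(sprintf("%s%s >  %.6g\n", pad, x$features[nd$feature], nd$threshold))
      .print_node(nd$right, depth + 1L)
    }
  }
  .print_node(1L, 0L)
  invisible(x)
}

#' @export
summary.mesc_tree <- function(object, ...) {
  used <- unique(object$features[stats::na.omit(object$nodes$feature)])
  cat(sprintf("mesc_tree: %d splits (cap %d), %d leaves\n", object$n_splits,
              object$max_splits, sum(is.na(object$nodes$feature))))
  cat("Features used:", if (length(used)) paste(used, collapse = ", ") else "none", "\n")
  cat(sprintf("Training: n = %d, accuracy = %.4f\n", object$n,
              object$training_accuracy))
  invisible(object)
}

# --------------------------------------------------------------------------
# Tree serialization (JSON split-tree: feature, threshold, children, label)

#' Serialize a fitted tree to JSON
#' @param model a `mesc_tree`.
#' @param path output path.
#' @export
write_tree_json <- function(model, path) {
  stopifnot(inherits(model, "mesc_tree"))
  payload <- list(
    features = model$features,
    classes = model$classes,
    max_splits = model$max_splits,
    n = model$n,
    training_accuracy = model$training_accuracy,
    nodes = model$nodes)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}

#' Read a tree serialized by [write_tree_json]
#' @param path JSON path.
#' @return a `mesc_tree`.
#' @export
read_tree_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as.data.frame(p$nodes)
  nodes$feature <- as.integer(nodes$feature)
  nodes$left <- as.integer(nodes$left)
  nodes$right <- as.integer(nodes$right)
  nodes$class <- as.integer(nodes$class)
  structure(list(nodes = nodes, features = p$features, classes = p$classes,
                 max_splits = as.integer(p$max_splits),
                 n_splits = sum(!is.na(nodes$feature)),
                 n = as.integer(p$n),
                 training_accuracy = p$training_accuracy,
                 call = NULL), class = "mesc_tree")
}

# --------------------------------------------------------------------------
# Clinical performance metrics

#' Confusion counts and clinical detection metrics
#'
#' Tallies TP/FP/TN/FN with `positive` as the positive class and derives
#' sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, PPV `TP/(TP+FP)`,
#' NPV `TN/(TN+FN)`, accuracy `(TP+TN)/total` and F1 `2TP/(2TP+FP+FN)`.
#' Ratios with a zero denominator are reported as `NA` (absent), as happens
#' for all-negative rhythm sets where only specificity and accuracy are
#' defined.
#'
#' @param pred_labels predicted labels.
#' @param true_labels reference labels, same length.
#' @param positive the positive-class label (default `"AF"`).
#' @return object of class `af_metrics`: list of counts and the six metrics.
#' @export
evaluate_detection <- function(pred_labels, true_labels, positive = "AF") {
  pred_labels <- as.character(pred_labels)
  true_labels <- as.character(true_labels)
  if (length(pred_labels) != length(true_labels) || length(pred_labels) == 0L) {
    stop("pred_labels and true_labels must be equal-length, non-empty",
         call. = FALSE)
  }
  p <- pred_labels == positive
  t <- true_labels == positive
  TP <- sum(p & t); FP <- sum(p & !t); TN <- sum(!p & !t); FN <- sum(!p & t)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(
    TP = TP, FP = FP, TN = TN, FN = FN,
    sensitivity = ratio(TP, TP + FN),
    specificity = ratio(TN, TN + FP),
    ppv = ratio(TP, TP + FP),
    npv = ratio(TN, TN + FN),
    accuracy = (TP + TN) / (TP + TN + FP + FN),
    f1 = ratio(2 * TP, 2 * TP + FP + FN),
    positive = positive), class = "af_metrics")
}

#' @export
print.af_metrics <- function(x, digits = 3L, ...) {
  cat(sprintf("Detection metrics (positive = '%s')\n", x$positive))
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$TP, x$FP, x$TN, x$FN))
  m <- c(Se = x$sensitivity, Sp = x$specificity, PPV = x$ppv, NPV = x$npv,
         ACC = x$accuracy, F1 = x$f1)
  for (nm in names(m)) {
    cat(sprintf("  %-4s %s\n", nm,
                if (is.na(m[[nm]])) "-" else formatC(m[[nm]], digits = digits,
                                                     format = "f")))
  }
  invisible(x)
}

#' @export
as.data.frame.af_metrics <- function(x, ...) {
  data.frame(TP = x$TP, FP = x$FP, TN = x$TN, FN = x$FN,
             sensitivity = x$sensitivity, specificity = x$specificity,
             ppv = x$ppv, npv = x$npv, accuracy = x$accuracy, f1 = x$f1)
}

# --------------------------------------------------------------------------
# Hyperparameter selection: record-level cross-validation over a
# (MESC order x window length) grid.

#' One-tailed unpaired (pooled-variance) t-test p-value: mean(a) > mean(b)?
#' @noRd
.one_tailed_p <- function(best, other) {
  sp2 <- (sum((best - mean(best))^2) + sum((other - mean(other))^2)) /
    (length(best) + length(other) - 2)
  if (sp2 <= 0) {
    d <- mean(best) - mean(other)
    return(if (d > 0) .Machine$double.eps else 0.5)
  }
  tt <- stats::t.test(best, other, alternative = "greater", var.equal = TRUE)
  unname(tt$p.value)
}

#' Record-level cross-validation over the hyperparameter grid
#'
#' For every (MESC order, window length) cell the per-record index tables
#' are recomputed, records (never individual windows) are assigned to folds
#' to prevent leakage, and a capped tree is trained on the training folds
#' and scored on the validation fold.  The best cell (highest mean
#' validation accuracy) is compared with every other cell by a one-tailed
#' unpaired t-test over the fold accuracies (significance at p < 0.05).
#'
#' @param records list of records, each a list with elements `rr`
#'   ([rr_series]) and `segments` (`rhythm_segments`).
#' @param orders MESC orders to try.
#' @param window_lengths window lengths (beats) to try.
#' @param folds number of folds (>= 2; must be < number of records).
#' @param seed integer seed for the fold assignment.
#' @param max_splits tree split cap.
#' @param stride window stride in beats.
#' @return object of class `mesc_cv`: `grid` data.frame (order,
#'   window_length, mean_accuracy, p_value), `best` row index,
#'   `fold_accuracy` matrix, `fold_of` record-fold assignment.
#' @export
cross_validate <- function(records, orders = c(1L, 2L),
                           window_lengths = c(70L, 150L), folds = 5L,
                           seed = 1L, max_splits = 30L, stride = 30L) {
  folds <- as.integer(folds)
  n_rec <- length(records)
  if (folds < 2L) stop("folds must be >= 2", call. = FALSE)
  if (n_rec <= folds) stop("need more records than folds", call. = FALSE)
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(folds), n_rec))
  grid <- expand.grid(order = as.integer(orders),
                      window_length = as.integer(window_lengths))
  acc <- matrix(NA_real_, nrow(grid), folds)
  form <- label ~ variability + normality + mean_rr
  for (g in seq_len(nrow(grid))) {
    cfg <- index_config(mesc_order = grid$order[g],
                        window_length = grid$window_length[g],
                        stride = min(stride, grid$window_length[g]))
    tabs <- lapply(records, function(r) compute_indices(r$rr, r$segments, cfg))
    for (k in seq_len(folds)) {
      train <- do.call(rbind, tabs[fold_of != k])
      valid <- do.call(rbind, tabs[fold_of == k])
      if (length(unique(train$label)) < 2L || nrow(valid) == 0L) {
        stop("degenerate fold: training fold lacks both classes", call. = FALSE)
      }
      fit <- mesc_tree(form, train, max_splits = max_splits)
      acc[g, k] <- mean(predict(fit, valid) == valid$label)
    }
  }
  grid$mean_accuracy <- rowMeans(acc)
  best <- which.max(grid$mean_accuracy)
  grid$p_value <- vapply(seq_len(nrow(grid)), function(g) {
    if (g == best) NA_real_ else .one_tailed_p(acc[best, ], acc[g, ])
  }, numeric(1))
  structure(list(grid = grid, best = best, fold_accuracy = acc,
                 fold_of = fold_of, folds = folds, seed = seed),
            class = "mesc_cv")
}

#' @export
print.mesc_cv <- function(x, ...) {
  cat(sprintf("Hyperparameter cross-validation (%d folds, record-level)\n",
              x$folds))
  g <- x$grid
  g$best <- ifelse(seq_len(nrow(g)) == x$best, "*", "")
  print(g, row.names = FALSE)
  invisible(x)
}

# --------------------------------------------------------------------------
# Patient-to-self protocol: train and test within each record.

#' Patient-to-self evaluation across tree-complexity caps
#'
#' For each record the windows are split chronologically into a training
#' part and a holdout part; a tree is trained at every split cap and scored
#' on the holdout.  Records whose training part lacks both classes (e.g.
#' single-rhythm records) are skipped and reported.
#'
#' @param record_tables list of per-record window-index data.frames.
#' @param split_caps integer vector of split caps (e.g.
#'   `c(2, 3, 4, 10, 20, 30, 50, 100)`).
#' @param holdout_fraction fraction of each record's windows held out
#'   (chronologically last).
#' @return object of class `patient_to_self`: `accuracy` matrix (record x
#'   cap), `mean_accuracy` per cap, `skipped` record ids.
#' @export
patient_to_self <- function(record_tables,
                            split_caps = c(2L, 3L, 4L, 10L, 20L, 30L, 50L, 100L),
                            holdout_fraction = 0.3) {
  stopifnot(holdout_fraction > 0, holdout_fraction < 1)
  split_caps <- as.integer(split_caps)
  form <- label ~ variability + normality + mean_rr
  ids <- vapply(record_tables, function(tb) tb$record_id[1L], character(1))
  acc <- matrix(NA_real_, length(record_tables), length(split_caps),
                dimnames = list(ids, as.character(split_caps)))
  skipped <- character(0)
  for (i in seq_along(record_tables)) {
    tb <- record_tables[[i]]
    tb <- tb[order(tb$window_start_beat), , drop = FALSE]
    n <- nrow(tb)
    n_train <- floor((1 - holdout_fraction) * n)
    train <- tb[seq_len(n_train), , drop = FALSE]
    test <- tb[setdiff(seq_len(n), seq_len(n_train)), , drop = FALSE]
    if (n_train < 2L || nrow(test) == 0L ||
        length(unique(train$label)) < 2L) {
      skipped <- c(skipped, ids[i])
      next
    }
    for (j in seq_along(split_caps)) {
      fit <- mesc_tree(form, train, max_splits = split_caps[j])
      acc[i, j] <- mean(predict(fit, test) == test$label)
    }
  }
  keep <- !ids %in% skipped
  structure(list(accuracy = acc,
                 mean_accuracy = colMeans(acc[keep, , drop = FALSE]),
                 split_caps = split_caps, skipped = unname(skipped)),
            class = "patient_to_self")
}

#' @export
print.patient_to_self <- function(x, ...) {
  cat("Patient-to-self mean holdout accuracy by split cap:\n")
  print(round(x$mean_accuracy, 4))
  if (length(x$skipped) > 0L) {
    cat("Skipped (single-class training part):",
        paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}

# --------------------------------------------------------------------------
# Cross-database protocol: final training on one collection, testing on
# disjoint collections.

#' Train on one window-index collection, test on disjoint collections
#'
#' A single capped tree is trained on all training windows and evaluated on
#' each named test collection; metrics on the training collection itself are
#' included, flagged optimistic.  Record ids must be disjoint between the
#' training and every test collection.
#'
#' @param train_table window-index data.frame (all training records).
#' @param test_tables named list of window-index data.frames.
#' @param max_splits tree split cap.
#' @return object of class `cross_database`: `model`, `reports` (named list
#'   of [evaluate_detection] results; entry `"train"` carries attribute
#'   `optimistic = TRUE`).
#' @export
cross_database <- function(train_table, test_tables, max_splits = 30L) {
  stopifnot(is.data.frame(train_table), is.list(test_tables))
  train_ids <- unique(train_table$record_id)
  for (nm in names(test_tables)) {
    overlap <- intersect(train_ids, unique(test_tables[[nm]]$record_id))
    if (length(overlap) > 0L) {
      stop(sprintf("record id(s) shared between train and test set '%s': %s",
                   nm, paste(overlap, collapse = ", ")), call. = FALSE)
    }
  }
  fit <- mesc_tree(label ~ variability + normality + mean_rr, train_table,
                   max_splits = max_splits)
  reports <- lapply(test_tables, function(tb) {
    evaluate_detection(predict(fit, tb), tb$label)
  })
  train_report <- evaluate_detection(predict(fit, train_table),
                                     train_table$label)
  attr(train_report, "optimistic") <- TRUE
  reports$train <- train_report
  structure(list(model = fit, reports = reports), class = "cross_database")
}

#' @export
print.cross_database <- function(x, ...) {
  for (nm in names(x$reports)) {
    r <- x$reports[[nm]]
    flag <- if (isTRUE(attr(r, "optimistic"))) " (optimistic: training set)" else ""
    cat(sprintf("== %s%s ==\n", nm, flag))
    print(r)
  }
  invisible(x)
}
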