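#' Classical classifiers on fused features, and the metric suite
#'
#' The fused representation (pooled network channels + handcrafted texture
#' vector) is handed to classical classifiers — RBF SVM, k-nearest
#' neighbours, decision tree — and evaluated with the full multi-class
#' suite: confusion matrix, per-class and macro sensitivity (recall),
#' specificity, precision, F1, accuracy, and one-vs-rest ROC AUC.
#'
#' @name fusion_eval
NULL

feature_cols <- function(features) {
  setdiff(names(features), c("id", "label", "split"))
}

#' Fit a classical classifier on a feature table
#'
#' Defaults: RBF SVM with `C = 1`; KNN with `k = 5`; CART decision tree.
#' Features are standardised with train-set mean/sd before SVM and KNN
#' (scale-sensitive); the tree sees raw features. Fitting is seeded.
#'
#' @param features tibble with columns `id`, `label`, optional `split`,
#'   and numeric feature columns (e.g. from [extract_fused_features()]).
#' @param kind `"svm"`, `"knn"` or `"tree"`.
#' @param seed integer seed.
#' @param k KNN neighbour count; @param cost SVM cost parameter.
#' @return object of class `fused_classifier` with a [predict] method
#'   returning `list(class, prob)`.
#' @export
fit_classifier <- function(features, kind = c("svm", "knn", "tree"),
                           seed = 1L, k = 5L, cost = 1) {
  kind <- match.arg(kind)
  X <- as.matrix(features[, feature_cols(features)])
  if (any(!is.finite(X))) abort("feature rows must be finite")
  y <- factor(features$label)
  if (nlevels(y) < 2L) abort("need at least 2 classes to fit a classifier")
  center <- colMeans(X)
  scale <- apply(X, 2, sd)
  scale[scale < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, `/`)
  fit <- with_seed_(seed, switch(kind,
    svm = e1071::svm(Xs, y, kernel = "radial", cost = cost,
                     probability = TRUE, scale = FALSE),
    knn = caret::knn3(Xs, y, k = k),
    tree = rpart::rpart(label ~ ., method = "class",
                        data = data.frame(label = y, X, check.names = FALSE))
  ))
  structure(list(kind = kind, fit = fit, center = center, scale = scale,
                 levels = levels(y), seed = seed),
            class = "fused_classifier")
}

#' @export
print.fused_classifier <- function(x, ...) {
  cat(sprintf("<fused_classifier> %s over %d classes (%s)\n",
              x$kind, length(x$levels), paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' Predict classes and class probabilities
#' @param object a `fused_classifier`; @param features feature tibble;
#'   @param ... unused.
#' @return list with `class` (factor) and `prob` (matrix, one column per
#'   class in `object$levels`).
#' @export
predict.fused_classifier <- function(object, features, ...) {
  X <- as.matrix(features[, feature_cols(features)])
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, `/`)
  prob <- switch(object$kind,
    svm = {
      pr <- predict(object$fit, Xs, probability = TRUE)
      attr(pr, "probabilities")[, object$levels, drop = FALSE]
    },
    knn = predict(object$fit, Xs, type = "prob")[, object$levels, drop = FALSE],
    tree = predict(object$fit,
                   data.frame(X, check.names = FALSE),
                   type = "prob")[, object$levels, drop = FALSE]
  )
  cls <- factor(object$levels[max.col(prob, ties.method = "first")],
                levels = object$levels)
  list(class = cls, prob = prob)
}

## ---- metrics ---------------------------------------------------------------

#' One-vs-rest trapezoidal ROC AUC
#'
#' Thresholds sweep the score; the area under the (FPR, TPR) curve is
#' accumulated by the trapezoidal rule. Equivalent to the Mann-Whitney
#' pairwise-concordance statistic.
#'
#' @param scores numeric scores for the positive class.
#' @param positive logical (or 0/1) vector marking positive samples.
#' @return AUC in `[0, 1]`, or `NA` when either class is absent.
#' @export
roc_auc <- function(scores, positive) {
  positive <- as.logical(positive)
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- positive[ord]
  # group tied scores so ties contribute trapezoids, not steps
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / n_pos); fpr <- c(0, fp[last] / n_neg)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

#' Evaluate a classifier: confusion matrix and the full metric suite
#'
#' Per class (one-vs-rest): sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, precision `TP/(TP+FP)`, `F1 = 2PR/(P+R)`, AUC from the
#' class-probability scores. Macro values are unweighted means over the
#' classes present in the labels; classes absent from `labels` are kept in
#' the table with `NA` rates and excluded from the macro mean.
#'
#' @param classifier a `fused_classifier`.
#' @param features feature tibble to score.
#' @param labels true labels (defaults to `features$label`).
#' @return object of class `eval_report`: `confusion` (true rows x
#'   predicted columns), `per_class` tibble, `accuracy`, `macro` tibble.
#' @export
evaluate_classifier <- function(classifier, features, labels = features$label) {
  pred <- predict(classifier, features)
  eval_report(truth = factor(labels, levels = classifier$levels),
              predicted = pred$class, prob = pred$prob)
}

#' Build an evaluation report from predictions
#'
#' @param truth factor of true labels; @param predicted factor of predicted
#'   labels (same levels); @param prob optional score matrix (columns =
#'   levels) for AUC.
#' @return an `eval_report`.
#' @export
eval_report <- function(truth, predicted, prob = NULL) {
  lev <- levels(truth)
  confusion <- table(truth = truth, predicted = factor(predicted, levels = lev))
  total <- sum(confusion)
  per_class <- purrr::map_dfr(lev, function(cl) {
    tp <- confusion[cl, cl]
    fn <- sum(confusion[cl, ]) - tp
    fp <- sum(confusion[, cl]) - tp
    tn <- total - tp - fn - fp
    support <- tp + fn
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    prec <- if (tp + fp > 0) tp / (tp + fp) else if (support > 0) 0 else NA_real_
    f1 <- if (!is.na(sens) && !is.na(prec) && sens + prec > 0) {
      2 * prec * sens / (prec + sens)
    } else if (support > 0) 0 else NA_real_
    auc <- if (!is.null(prob)) roc_auc(prob[, cl], truth == cl) else NA_real_
    tibble::tibble(class = cl, support = as.integer(support),
                   sensitivity = sens, specificity = spec,
                   precision = prec, f1 = f1, auc = auc)
  })
  present <- per_class$support > 0
  macro <- tibble::tibble(
    accuracy = sum(diag(confusion)) / total,
    sensitivity = mean(per_class$sensitivity[present]),
    specificity = mean(per_class$specificity[present]),
    precision = mean(per_class$precision[present]),
    f1 = mean(per_class$f1[present]),
    auc = mean(per_class$auc[present], na.rm = TRUE),
    n = as.integer(total)
  )
  structure(list(confusion = confusion, per_class = per_class,
                 accuracy = macro$accuracy, macro = macro),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.3f, macro F1 %.3f (n = %d)\n",
              x$accuracy, x$macro$f1, x$macro$n))
  print(x$confusion)
  invisible(x)
}

#' @describeIn eval_report `tidy()` returns the per-class metric tibble.
#' @param x an `eval_report`; @param ... unused.
#' @export
tidy.eval_report <- function(x, ...) x$per_class

#' @describeIn eval_report `glance()` returns the one-row macro summary.
#' @export
glance.eval_report <- function(x, ...) x$macro

#' Serialize an evaluation report to JSON (lossless round trip)
#' @param report an `eval_report`; @param path JSON path.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  jsonlite::write_json(list(
    levels = rownames(report$confusion),
    confusion = unname(as.matrix(unclass(report$confusion))),
    per_class = report$per_class,
    macro = report$macro
  ), path, digits = NA, auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_eval_report
#' @export
read_eval_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lev <- obj$levels
  conf <- matrix(as.numeric(obj$confusion), nrow = length(lev), byrow = FALSE)
  confusion <- as.table(conf)
  dimnames(confusion) <- list(truth = lev, predicted = lev)
  names(dimnames(confusion)) <- c("truth", "predicted")
  per_class <- tibble::as_tibble(obj$per_class)
  per_class$support <- as.integer(per_class$support)
  macro <- tibble::as_tibble(obj$macro)
  macro$n <- as.integer(macro$n)
  structure(list(confusion = confusion, per_class = per_class,
                 accuracy = macro$accuracy, macro = macro),
            class = "eval_report")
}

#' Confusion-matrix heatmap
#' @param object an `eval_report`; @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- tibble::as_tibble(as.data.frame(object$confusion))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$Freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::scale_y_discrete(limits = rev(rownames(object$confusion))) +
    ggplot2::labs(x = "predicted", y = "true", fill = "count") +
    ggplot2::theme_minimal()
}

## ---- ablation --------------------------------------------------------------

#' Ablation: network-only vs texture-only vs fused features
#'
#' Trains the network once (with grafting), then fits and evaluates the
#' chosen classifier three times — on the pooled network channels alone, on
#' the handcrafted texture vector alone, and on the fused table — using
#' identical splits, the same seed, and identical row order across
#' configurations. Metrics are reported on both the validation and test
#' splits.
#'
#' @param tiles a [tile_set] with splits assigned.
#' @param glpp_cfg a [glpp_config()]; @param net_spec a [network_spec()]
#'   (its `glpp_dim` is overridden to match the descriptor length);
#' @param train_cfg a [train_config()].
#' @param classifier `"svm"`, `"knn"` or `"tree"`.
#' @param normalize_first when `TRUE`, stain-normalize all tiles to the
#'   first training tile's profile before featurization.
#' @return list with `table` (tibble: configuration x split metric rows),
#'   `reports` (named list of `eval_report`s), `model`, `features`.
#' @export
ablation_compare <- function(tiles, glpp_cfg = glpp_config(),
                             net_spec = NULL, train_cfg = train_config(),
                             classifier = "svm", normalize_first = FALSE) {
  if (dplyr::n_distinct(tiles$manifest$label) < 3L) {
    abort("ablation requires at least 3 classes")
  }
  if (normalize_first) {
    ref <- estimate_stain_profile(tiles$tiles[[which(tiles$manifest$split == "train")[1]]])
    tiles$tiles <- purrr::map(tiles$tiles, normalize_to_reference, ref_profile = ref)
  }
  glpp_tbl <- glpp_feature_table(tiles, glpp_cfg)
  d <- length(feature_cols(glpp_tbl))
  if (is.null(net_spec)) {
    net_spec <- network_spec(
      input_size = c(dim(tiles$tiles[[1]])[1:2], 3),
      glpp_dim = d,
      n_classes = dplyr::n_distinct(tiles$manifest$label)
    )
  } else {
    net_spec$glpp_dim <- d
    net_spec <- network_spec(net_spec$input_size, net_spec$blocks,
                             net_spec$graft_after_block, d, net_spec$n_classes)
  }
  model <- train_network(net_spec, tiles, glpp_tbl, train_cfg)
  fused <- extract_fused_features(model, tiles, glpp_tbl)
  cnn_only <- fused[, c("id", "label", "split",
                        grep("^cnn_", names(fused), value = TRUE))]
  glpp_only <- fused[, c("id", "label", "split",
                         grep("^glpp_", names(fused), value = TRUE))]
  feats <- list(cnn_only = cnn_only, glpp_only = glpp_only, fused = fused)

  reports <- list()
  rows <- list()
  for (cfg in names(feats)) {
    tr <- dplyr::filter(feats[[cfg]], .data$split == "train")
    clf <- fit_classifier(tr, kind = classifier, seed = train_cfg$seed)
    for (sp in c("val", "test")) {
      sub <- dplyr::filter(feats[[cfg]], .data$split == sp)
      if (!nrow(sub)) next
      rep <- evaluate_classifier(clf, sub)
      reports[[paste(cfg, sp, sep = "_")]] <- rep
      rows[[paste(cfg, sp, sep = "_")]] <-
        dplyr::bind_cols(tibble::tibble(configuration = cfg, split = sp),
                         glance(rep))
    }
  }
  list(table = dplyr::bind_rows(rows), reports = reports,
       model = model, features = feats)
}
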