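# Stratified fold assignment: within each class, shuffled samples are dealt
# round-robin to folds.
stratified_folds <- function(y, folds) {
  out <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    out[idx] <- rep_len(seq_len(folds), length(idx))
  }
  out
}

prep_xy <- function(features, labels) {
  if (inherits(features, "feature_matrix")) {
    X <- t(features$features)
    if (is.null(labels) && !is.null(features$labels)) {
      labels <- features$labels$class
    }
  } else {
    X <- as.matrix(features)
  }
  if (is.null(labels)) {
    abort("labels are required.", class = "salnet_error_validation")
  }
  y <- droplevels(as.factor(labels))
  if (nlevels(y) < 2L) {
    abort("labels contain a single class.", class = "salnet_error_validation")
  }
  if (length(y) != nrow(X)) {
    abort("label count does not match the sample count.",
          class = "salnet_error_validation")
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  list(X = X, y = y)
}

#' Wrapper-based Random-Forest feature selection
#'
#' Repeated rounds of stratified k-fold cross-validation: in each round a
#' Random Forest (`trees` trees, `sqrt(f)` variables per split) is grown on
#' every training split, permutation importances (mean accuracy decrease on
#' out-of-bag data) are averaged over the round's splits, and the features
#' above the third quartile of that round's importance distribution are
#' recorded. A feature is finally selected when its occurrence frequency
#' across rounds reaches the stability threshold `pi_thr` (default 0.9, in
#' the spirit of stability selection): because the cohort is fixed across
#' rounds, per-round passes of a spuriously label-correlated feature are
#' strongly dependent, so only a near-unanimous occurrence frequency — not a
#' binomial-null count — separates genuinely informative features from the
#' stable spurious background.
#'
#' @param features A [feature_matrix()] or a numeric matrix (features x
#'   samples when a `feature_matrix`, otherwise samples x features).
#' @param labels Class label per sample (taken from the `feature_matrix`
#'   labels when omitted).
#' @param rounds Number of cross-validation rounds (paper protocol: 1000).
#' @param folds Folds per round.
#' @param trees Trees per forest.
#' @param importance_quantile Per-round importance cut (default 0.75 = Q3).
#' @param pi_thr Stability threshold: minimum occurrence frequency across
#'   rounds for a feature to be selected.
#' @param seed Integer seed; the whole procedure is reproducible from it.
#' @return An object of class `selection_result`: `rounds`, `occurrence`
#'   tibble (`feature`, `count`, `frequency`, `selected`), `selected`,
#'   `occurrence_threshold`, and the rule parameters.
#' @export
wrapper_select <- function(features, labels = NULL, rounds = 1000, folds = 5,
                           trees = 500, importance_quantile = 0.75,
                           pi_thr = 0.9, seed = 1L) {
  xy <- prep_xy(features, labels)
  X <- xy$X
  y <- xy$y
  if (min(table(y)) < folds) {
    abort("each class needs at least `folds` samples.",
          class = "salnet_error_validation")
  }
  counts <- setNames(integer(ncol(X)), colnames(X))
  if (rounds > 0) {
    fit_seeds <- matrix(derive_seeds(seed, rounds * folds), nrow = rounds)
    with_local_seed(seed, {
      for (r in seq_len(rounds)) {
        fold_of <- stratified_folds(y, folds)
        imp <- matrix(0, ncol(X), folds)
        for (f in seq_len(folds)) {
          tr <- fold_of != f
          fit <- ranger::ranger(
            x = X[tr, , drop = FALSE], y = y[tr],
            num.trees = trees, mtry = floor(sqrt(ncol(X))),
            importance = "permutation", num.threads = 1,
            seed = fit_seeds[r, f]
          )
          v <- fit$variable.importance[colnames(X)]
          v[is.na(v)] <- 0  # no evaluable out-of-bag case for this feature
          imp[, f] <- v
        }
        rimp <- rowMeans(imp)
        cut <- quantile(rimp, importance_quantile, type = 7, names = FALSE)
        counts[rimp > cut] <- counts[rimp > cut] + 1L
      }
    })
  }
  thr <- ceiling(pi_thr * rounds)
  occurrence <- tibble(
    feature = names(counts), count = as.integer(counts),
    frequency = if (rounds > 0) counts / rounds else 0,
    selected = rounds > 0 & counts >= thr
  )
  structure(
    list(rounds = rounds, occurrence = occurrence,
         selected = occurrence$feature[occurrence$selected],
         occurrence_threshold = thr,
         params = list(folds = folds, trees = trees,
                       importance_quantile = importance_quantile,
                       pi_thr = pi_thr, seed = seed)),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d of %d features selected (%d rounds, count >= %d)\n",
              length(x$selected), nrow(x$occurrence), x$rounds,
              x$occurrence_threshold))
  invisible(x)
}

#' @method tidy selection_result
#' @export
tidy.selection_result <- function(x, ...) x$occurrence

#' @method glance selection_result
#' @export
glance.selection_result <- function(x, ...) {
  tibble(rounds = x$rounds, n_selected = length(x$selected),
         occurrence_threshold = x$occurrence_threshold)
}

#' Combine selected feature sets
#'
#' Order-stable, de-duplicated union of the features selected by two runs
#' (e.g. skeleton-multiplex and original-multiplex selections).
#'
#' @param a,b [wrapper_select()] results, or character vectors of feature
#'   names.
#' @return Character vector of feature names.
#' @export
combine_feature_sets <- function(a, b) {
  nm <- function(x) if (inherits(x, "selection_result")) x$selected else as.character(x)
  unique(c(nm(a), nm(b)))
}

#' Cross-validated Random-Forest evaluation
#'
#' Repeated stratified k-fold cross-validation of a probability Random Forest
#' on the selected features. Out-of-fold class probabilities give, per
#' repetition, the held-out accuracy, AUC, sensitivity and specificity
#' (positive class = disease group); the report carries each metric's mean and
#' standard error across repetitions, plus pooled confusion counts.
#'
#' @param features,labels As in [wrapper_select()].
#' @param selected Character vector of feature names to use (non-empty).
#' @param folds,trees Cross-validation folds and trees per forest.
#' @param repetitions Number of CV repetitions.
#' @param positive Positive (disease) class; default: the last factor level.
#' @param task Task name carried into the report.
#' @param seed Integer seed.
#' @return An object of class `classification_report` with `metrics` (tibble
#'   of metric, mean, se), `confusion` counts, and the run parameters.
#' @export
train_eval <- function(features, labels = NULL, selected, folds = 5,
                       trees = 500, repetitions = 10, positive = NULL,
                       task = "group-vs-group", seed = 1L) {
  xy <- prep_xy(features, labels)
  selected <- as.character(selected)
  if (length(selected) == 0L) {
    abort("`selected` must name at least one feature.",
          class = "salnet_error_validation")
  }
  missing <- setdiff(selected, colnames(xy$X))
  if (length(missing)) {
    abort(sprintf("unknown feature(s): %s", paste(head(missing, 3), collapse = ", ")),
          class = "salnet_error_validation")
  }
  X <- xy$X[, selected, drop = FALSE]
  y <- xy$y
  if (min(table(y)) < folds) {
    abort("each class needs at least one sample per fold.",
          class = "salnet_error_validation")
  }
  positive <- positive %||% levels(y)[nlevels(y)]
  stopifnot(positive %in% levels(y))
  negative <- setdiff(levels(y), positive)[1]
  fit_seeds <- matrix(derive_seeds(seed, repetitions * folds),
                      nrow = repetitions)
  conf <- c(tp = 0, tn = 0, fp = 0, fn = 0)
  per_rep <- with_local_seed(seed, {
    purrr::map(seq_len(repetitions), function(r) {
      fold_of <- stratified_folds(y, folds)
      prob <- numeric(length(y))
      for (f in seq_len(folds)) {
        te <- fold_of == f
        fit <- ranger::ranger(
          x = X[!te, , drop = FALSE], y = y[!te],
          num.trees = trees, mtry = max(1L, floor(sqrt(ncol(X)))),
          probability = TRUE, num.threads = 1, seed = fit_seeds[r, f]
        )
        prob[te] <- predict(fit, X[te, , drop = FALSE],
                            num.threads = 1)$predictions[, positive]
      }
      pred <- ifelse(prob > 0.5, positive, negative)
      tp <- sum(pred == positive & y == positive)
      tn <- sum(pred == negative & y != positive)
      fp <- sum(pred == positive & y != positive)
      fn <- sum(pred == negative & y == positive)
      conf <<- conf + c(tp = tp, tn = tn, fp = fp, fn = fn)
      auc <- as.numeric(pROC::auc(pROC::roc(
        response = y == positive, predictor = prob, quiet = TRUE,
        direction = "<", levels = c(FALSE, TRUE)
      )))
      c(accuracy = (tp + tn) / length(y), auc = auc,
        sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
    })
  })
  m <- do.call(rbind, per_rep)
  metrics <- tibble(
    metric = colnames(m),
    mean = colMeans(m),
    se = apply(m, 2, function(v) sd(v) / sqrt(length(v)))
  )
  structure(
    list(task = task, metrics = metrics, per_repetition = as_tibble(m),
         confusion = conf, positive = positive,
         params = list(folds = folds, trees = trees,
                       repetitions = repetitions, n_features = ncol(X),
                       seed = seed)),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report '%s'> (%d features, %d-fold x %d reps)\n",
              x$task, x$params$n_features, x$params$folds,
              x$params$repetitions))
  for (k in seq_len(nrow(x$metrics))) {
    cat(sprintf("  %-12s %.3f +/- %.3f\n", x$metrics$metric[k],
                x$metrics$mean[k], x$metrics$se[k]))
  }
  invisible(x)
}

#' @method tidy classification_report
#' @export
tidy.classification_report <- function(x, ...) x$metrics

#' @method glance classification_report
#' @export
glance.classification_report <- function(x, ...) {
  out <- as.list(setNames(x$metrics$mean, x$metrics$metric))
  as_tibble(c(list(task = x$task), out,
              list(n_features = x$params$n_features)))
}

#' @method autoplot classification_report
#' @export
autoplot.classification_report <- function(object, ...) {
  ggplot2::ggplot(object$metrics,
                  ggplot2::aes(x = .data$metric, y = .data$mean)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.2) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "held-out value", title = object$task)
}
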