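#' Random 70/30 train/test split
#'
#' @param n Number of observations (>= 10).
#' @param seed Optional integer seed (sets the RNG).
#' @param train_fraction Training fraction (default 0.7).
#' @return List with disjoint, covering `train` and `test` index vectors;
#'   `length(train) == round(train_fraction * n)`.
#' @export
split_70_30 <- function(n, seed = NULL, train_fraction = 0.7) {
  if (n < 10) stop("need at least 10 observations", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  perm <- sample(n)
  ntr <- round(train_fraction * n)
  list(train = sort(perm[seq_len(ntr)]), test = sort(perm[-seq_len(ntr)]))
}

#' k-fold cross-validation indices
#'
#' @param n Number of observations (>= k).
#' @param k Number of folds (default 10).
#' @param seed Optional integer seed.
#' @return List of k disjoint index vectors covering `1:n`, with sizes
#'   differing by at most one.
#' @export
kfold_indices <- function(n, k = 10, seed = NULL) {
  if (n < k) stop("need at least k observations", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  split(seq_len(n), fold)
}

#' Leave-one-source-out folds
#'
#' One fold per recording: the fold's test set is every window of that
#' source. Sources with zero windows are skipped with a warning.
#'
#' @param source_id Per-window source identifiers.
#' @return Named list of test-index vectors, one per source.
#' @export
leave_one_source_out <- function(source_id) {
  if (length(unique(source_id)) < 2)
    stop("need at least 2 sources", call. = FALSE)
  split(seq_along(source_id), source_id)
}

#' Confusion matrix and accuracies
#'
#' Counts matrix with actual classes in rows and predicted classes in
#' columns, in the fixed `class_order`. Overall accuracy is
#' 100 * trace / total; per-class accuracy is the per-row recall,
#' 100 * diagonal / row total.
#'
#' @param predicted,actual Equal-length label vectors.
#' @param class_order Fixed class ordering; labels outside it are an
#'   error.
#' @return List with `confusion`, `overall` (%), `per_class` (%).
#' @export
confusion_and_accuracy <- function(predicted, actual,
                                   class_order = activity_classes()) {
  predicted <- as.character(predicted)
  actual <- as.character(actual)
  if (length(predicted) != length(actual))
    stop("length mismatch", call. = FALSE)
  if (!all(c(predicted, actual) %in% class_order))
    stop("label outside class_order", call. = FALSE)
  keep <- class_order[class_order %in% c(predicted, actual)]
  cm <- table(factor(actual, levels = keep),
              factor(predicted, levels = keep))
  cm <- matrix(cm, nrow = length(keep),
               dimnames = list(actual = keep, predicted = keep))
  list(confusion = cm,
       overall = 100 * sum(diag(cm)) / sum(cm),
       per_class = 100 * diag(cm) / pmax(rowSums(cm), 1))
}

#' Default experiment options
#'
#' @param knn_k Neighbours for k-NN (default 10).
#' @param svm_cost Soft-margin penalty (default 1).
#' @param svm_train_cap Seeded training-subsample cap for the SVM
#'   (libsvm is superquadratic in n); `NULL` disables.
#' @param dt_train_cap Optional seeded training-subsample cap for the
#'   decision tree; `NULL` (default) trains on all rows.
#' @param standardize,pca_k,nca_threshold,nca_epochs,nca_step,nca_ref_cap
#'   Feature-set options (see [build_feature_set()]).
#' @return Named list.
#' @export
experiment_options <- function(knn_k = 10, svm_cost = 1,
                               svm_train_cap = 10000, dt_train_cap = NULL,
                               standardize = TRUE,
                               pca_k = 3, nca_threshold = 0.2,
                               nca_epochs = 50, nca_step = 0.01,
                               nca_ref_cap = 1000) {
  as.list(environment())
}

# Task labels + rows in scope: binary uses only stage 1-8 windows with
# the protocol-wide Standing/Walking rule; tertiary uses all windows
# with the per-recording jogging labels carried by the window metadata.
.task_rows <- function(ft, task) {
  if (task == "binary") {
    rows <- which(ft$meta$stage <= 8)
    labels <- ifelse(ft$meta$stage[rows] == 1, "Standing", "Walking")
  } else {
    rows <- seq_len(nrow(ft$meta))
    labels <- ft$meta$class[rows]
  }
  list(rows = rows, labels = labels)
}

# One train/test evaluation of (set, model) on rows of a feature table.
.eval_split <- function(ft, set_id, model_id, train_rows, test_rows,
                        labels_all, opts) {
  reg <- model_registry()[[model_id]]
  if (is.null(reg)) stop("unknown model: ", model_id, call. = FALSE)
  fsres <- build_feature_set(ft, set_id, train_rows, test_rows,
                             labels = labels_all, options = opts)
  fit <- reg$fit(fsres$train, labels_all[fsres$train_idx], opts)
  pred <- reg$predict(fit, fsres$test, opts)
  list(predicted = pred, actual = labels_all[fsres$test_idx],
       test_idx = fsres$test_idx, state = fsres$state)
}

#' Evaluate feature sets x models under the 70/30 protocol
#'
#' @param ft A `feature_table`.
#' @param task `"binary"` or `"tertiary"`.
#' @param sets Feature-set identifiers.
#' @param models Model identifiers (see [model_registry()]).
#' @param seed Integer seed governing the split and stochastic fits.
#' @param opts [experiment_options()].
#' @return data.frame with one row per (set, model): accuracy (%), and
#'   the number of data points (windows) entering that set.
#' @export
run_grid_70_30 <- function(ft, task = "binary",
                           sets = names(feature_set_defs()),
                           models = names(model_registry()),
                           seed = 1, opts = experiment_options()) {
  tk <- .task_rows(ft, task)
  labels_all <- rep(NA_character_, nrow(ft$meta))
  labels_all[tk$rows] <- tk$labels
  out <- list()
  for (set_id in sets) {
    rows <- tk$rows
    if (set_requires_valid(set_id)) rows <- rows[ft$meta$valid[rows]]
    sp <- split_70_30(length(rows), seed = seed)
    for (model_id in models) {
      set.seed(seed + 1)  # stochastic fits (NCA subsample, SVM cap)
      res <- .eval_split(ft, set_id, model_id, rows[sp$train],
                         rows[sp$test], labels_all, opts)
      acc <- confusion_and_accuracy(res$predicted, res$actual)
      out[[length(out) + 1]] <- data.frame(
        task = task, set_id = set_id, model_id = model_id,
        n_points = length(rows), accuracy = acc$overall)
    }
  }
  do.call(rbind, out)
}

#' Evaluate feature sets x models under 10-fold cross-validation
#'
#' Transforms and models are refitted inside every fold (no leakage);
#' the reported accuracy is the mean over folds, and the pooled
#' confusion matrix is returned per (set, model).
#'
#' @inheritParams run_grid_70_30
#' @param k Number of folds.
#' @return List: `table` (data.frame of mean accuracies) and
#'   `confusions` (named list of pooled confusion matrices).
#' @export
run_grid_kfold <- function(ft, task = "binary", sets = c("A", "C1", "E"),
                           models = names(model_registry()), k = 10,
                           seed = 1, opts = experiment_options()) {
  tk <- .task_rows(ft, task)
  labels_all <- rep(NA_character_, nrow(ft$meta))
  labels_all[tk$rows] <- tk$labels
  tab <- list()
  confusions <- list()
  for (set_id in sets) {
    rows <- tk$rows
    if (set_requires_valid(set_id)) rows <- rows[ft$meta$valid[rows]]
    folds <- kfold_indices(length(rows), k = k, seed = seed)
    for (model_id in models) {
      fold_acc <- numeric(k)
      pred_all <- actual_all <- character(0)
      for (f in seq_len(k)) {
        set.seed(seed + f)
        res <- .eval_split(ft, set_id, model_id,
                           rows[-folds[[f]]], rows[folds[[f]]],
                           labels_all, opts)
        fold_acc[f] <- confusion_and_accuracy(res$predicted,
                                              res$actual)$overall
        pred_all <- c(pred_all, res$predicted)
        actual_all <- c(actual_all, res$actual)
      }
      tab[[length(tab) + 1]] <- data.frame(
        task = task, set_id = set_id, model_id = model_id,
        n_points = length(rows), accuracy = mean(fold_acc))
      confusions[[paste(set_id, model_id, sep = ".")]] <-
        confusion_and_accuracy(pred_all, actual_all)$confusion
    }
  }
  list(table = do.call(rbind, tab), confusions = confusions)
}

#' Leave-one-source-out evaluation of one feature set
#'
#' Holds out all windows of each recording in turn, refitting
#' transforms and models on the remaining sources. Reports per-source
#' accuracies with their mean, SD, min and max, plus the pooled
#' confusion matrix and per-class accuracies.
#'
#' @inheritParams run_grid_70_30
#' @param set_id Single feature-set identifier.
#' @param model_id Single model identifier.
#' @return List of class `loso_result`: `per_source` (data.frame),
#'   `mean`, `sd`, `min`, `max`, `overall`, `confusion`, `per_class`.
#' @export
run_loso <- function(ft, set_id, model_id, task = "binary", seed = 1,
                     opts = experiment_options()) {
  tk <- .task_rows(ft, task)
  labels_all <- rep(NA_character_, nrow(ft$meta))
  labels_all[tk$rows] <- tk$labels
  rows <- tk$rows
  if (set_requires_valid(set_id)) rows <- rows[ft$meta$valid[rows]]
  folds <- leave_one_source_out(ft$meta$source_id[rows])
  empty <- vapply(folds, length, 0L) == 0
  if (any(empty)) {
    warning("skipping sources with zero windows: ",
            paste(names(folds)[empty], collapse = ", "))
    folds <- folds[!empty]
  }
  per_source <- data.frame(source_id = names(folds),
                           n_windows = vapply(folds, length, 0L),
                           accuracy = NA_real_)
  pred_all <- actual_all <- character(0)
  for (f in seq_along(folds)) {
    set.seed(seed + f)
    res <- .eval_split(ft, set_id, model_id,
                       rows[-folds[[f]]], rows[folds[[f]]],
                       labels_all, opts)
    per_source$accuracy[f] <- confusion_and_accuracy(res$predicted,
                                                     res$actual)$overall
    pred_all <- c(pred_all, res$predicted)
    actual_all <- c(actual_all, res$actual)
  }
  pooled <- confusion_and_accuracy(pred_all, actual_all)
  structure(list(
    task = task, set_id = set_id, model_id = model_id,
    per_source = per_source,
    mean = mean(per_source$accuracy), sd = stats::sd(per_source$accuracy),
    min = min(per_source$accuracy), max = max(per_source$accuracy),
    overall = pooled$overall, confusion = pooled$confusion,
    per_class = pooled$per_class), class = "loso_result")
}

#' @export
print.loso_result <- function(x, ...) {
  cat(sprintf("<loso %s / set %s / %s: mean %.2f%% (SD %.2f, min %.2f, max %.2f) over %d sources>\n",
              x$task, x$set_id, x$model_id, x$mean, x$sd, x$min, x$max,
              nrow(x$per_source)))
  invisible(x)
}

#' Accuracy grid in the wide report shape
#'
#' Pivots the long (set, model, accuracy) table into sets x models with
#' MEAN row and column (arithmetic means of the grid).
#'
#' @param tab data.frame from [run_grid_70_30()] or
#'   [run_grid_kfold()]`$table`.
#' @return data.frame, one row per feature set plus a MEAN row.
#' @export
accuracy_grid <- function(tab) {
  sets <- unique(tab$set_id)
  models <- unique(tab$model_id)
  wide <- data.frame(set_id = sets,
                     n_points = tab$n_points[match(sets, tab$set_id)])
  for (m in models)
    wide[[m]] <- tab$accuracy[tab$model_id == m][
      match(sets, tab$set_id[tab$model_id == m])]
  wide$MEAN <- rowMeans(wide[, models, drop = FALSE])
  mean_row <- data.frame(set_id = "MEAN", n_points = NA)
  for (m in models) mean_row[[m]] <- mean(wide[[m]])
  mean_row$MEAN <- NA
  rbind(wide, mean_row)
}
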