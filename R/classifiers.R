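#' Manhattan and Euclidean distances
#'
#' @param p,q Numeric vectors of equal length.
#' @return The distance.
#' @export
manhattan_distance <- function(p, q) sum(abs(q - p))

#' @rdname manhattan_distance
#' @export
euclidean_distance <- function(p, q) sqrt(sum((q - p)^2))

#' k-nearest-neighbour classification
#'
#' Brute-force k-NN under the Manhattan or Euclidean metric (default
#' k = 10). Each test row receives the majority label among its k
#' nearest training rows. Vote ties are broken by the smaller mean
#' distance among the tied classes, then by class-name order; distance
#' ties at the k-th neighbour keep the earlier training row (stable row
#' order), so predictions are deterministic and invariant to permuting
#' the training rows.
#'
#' @param train_x Training matrix (rows = observations).
#' @param train_y Training labels.
#' @param test_x Test matrix with the same column count.
#' @param k Number of neighbours (1 <= k <= nrow(train_x)).
#' @param metric `"manhattan"` or `"euclidean"`.
#' @return Character vector of predicted labels.
#' @export
knn_predict <- function(train_x, train_y, test_x, k = 10,
                        metric = c("manhattan", "euclidean")) {
  metric <- match.arg(metric)
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  if (nrow(train_x) == 0) stop("empty training set", call. = FALSE)
  if (ncol(train_x) != ncol(test_x))
    stop("train and test must share column count", call. = FALSE)
  if (k < 1 || k > nrow(train_x))
    stop("k must lie in [1, nrow(train_x)]", call. = FALSE)
  train_y <- as.character(train_y)
  nn <- .knn_kneighbors(t(train_x), t(test_x), as.integer(k),
                        if (metric == "manhattan") 0L else 1L)
  lab_mat <- matrix(train_y[nn$idx], nrow = nrow(nn$idx))
  classes <- sort(unique(train_y))
  cnt <- vapply(classes, function(cl) rowSums(lab_mat == cl),
                numeric(nrow(lab_mat)))
  cnt <- matrix(cnt, ncol = length(classes))
  mmax <- cnt[, 1]
  if (length(classes) > 1)
    for (j in 2:length(classes)) mmax <- pmax(mmax, cnt[, j])
  out <- classes[max.col(cnt, ties.method = "first")]
  tied <- which(rowSums(cnt == mmax) > 1)
  for (q in tied) {
    labs <- lab_mat[q, ]
    winners <- classes[cnt[q, ] == mmax[q]]
    md <- vapply(winners, function(cl) mean(nn$dist[q, labs == cl]), 0)
    out[q] <- sort(winners[md == min(md)])[1]
  }
  out
}

#' CART decision-tree classification
#'
#' Classification tree with greedy binary axis-aligned splits minimising
#' Gini impurity, fitted with `rpart`: minimum leaf size 5, no maximum
#' depth beyond rpart's limit of 30, no pruning (complexity parameter
#' 0). Pure training sets yield a depth-0 tree predicting the single
#' class.
#'
#' @param train_x Training matrix.
#' @param train_y Training labels.
#' @param min_leaf Minimum observations in any leaf.
#' @return List of class `cart_model`.
#' @export
dt_train <- function(train_x, train_y, min_leaf = 5) {
  if (nrow(as.matrix(train_x)) < 1) stop("empty training set", call. = FALSE)
  if (length(unique(train_y)) == 1) {
    # pure training set: depth-0 tree predicting the single class
    return(structure(list(fit = NULL, constant = as.character(train_y[1]),
                          classes = as.character(train_y[1]),
                          columns = colnames(as.data.frame(train_x))),
                     class = "cart_model"))
  }
  df <- data.frame(.y = factor(train_y), as.data.frame(train_x))
  fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                      control = rpart::rpart.control(
                        minsplit = 2 * min_leaf, minbucket = min_leaf,
                        cp = 0, xval = 0, maxdepth = 30))
  structure(list(fit = fit, classes = levels(df$.y),
                 columns = colnames(as.data.frame(train_x))),
            class = "cart_model")
}

#' @rdname dt_train
#' @param model A `cart_model`.
#' @param test_x Test matrix.
#' @return Character vector of predicted labels.
#' @export
dt_predict <- function(model, test_x) {
  if (!is.null(model$constant))
    return(rep(model$constant, nrow(as.matrix(test_x))))
  df <- as.data.frame(test_x)
  colnames(df) <- model$columns
  as.character(predict(model$fit, df, type = "class"))
}

#' Linear support-vector-machine classification
#'
#' Soft-margin SVM with a linear decision function
#' `y = sum_i x_i w_i + b` and classes coded -1/+1, fitted with
#' `e1071::svm` (libsvm). Multi-class problems are split one-versus-one
#' (3 pairwise machines for 3 classes) and combined by vote. Inputs are
#' expected already standardized, so internal scaling is off.
#'
#' @param train_x Training matrix.
#' @param train_y Training labels (>= 2 classes).
#' @param cost Soft-margin penalty C.
#' @return List of class `svm_model`.
#' @export
svm_train <- function(train_x, train_y, cost = 1) {
  y <- factor(train_y)
  if (nlevels(y) < 2) stop("SVM needs at least 2 classes", call. = FALSE)
  fit <- e1071::svm(x = as.matrix(train_x), y = y, kernel = "linear",
                    cost = cost, scale = FALSE)
  structure(list(fit = fit, classes = levels(y)), class = "svm_model")
}

#' @rdname svm_train
#' @param model An `svm_model`.
#' @param test_x Test matrix.
#' @return Character vector of predicted labels.
#' @export
svm_predict <- function(model, test_x) {
  as.character(predict(model$fit, as.matrix(test_x)))
}

#' Weights and bias of a fitted binary linear SVM
#'
#' Recovers the primal parameters (w, b) of each pairwise machine so the
#' decision value at a point is `x %*% w - b`.
#'
#' @param model An `svm_model`.
#' @return List with `w` (matrix, one column per pairwise machine) and
#'   `rho` (bias terms).
#' @export
svm_weights <- function(model) {
  fit <- model$fit
  list(w = crossprod(fit$SV, fit$coefs), rho = fit$rho)
}

#' Model registry used by the evaluation drivers
#'
#' Maps the four model identifiers to fit/predict closures:
#' `knn_manhattan`, `knn_euclidean`, `cart`, `svm_linear`
#' (models 1-4 in the result tables).
#'
#' @return Named list of `list(fit, predict)` pairs.
#' @export
model_registry <- function() {
  list(
    knn_manhattan = list(
      fit = function(x, y, opts) list(x = x, y = y, k = opts$knn_k),
      predict = function(m, x, opts)
        knn_predict(m$x, m$y, x, k = m$k, metric = "manhattan")),
    knn_euclidean = list(
      fit = function(x, y, opts) list(x = x, y = y, k = opts$knn_k),
      predict = function(m, x, opts)
        knn_predict(m$x, m$y, x, k = m$k, metric = "euclidean")),
    cart = list(
      fit = function(x, y, opts) {
        cap <- opts$dt_train_cap
        if (!is.null(cap) && nrow(x) > cap) {
          keep <- sample(nrow(x), cap)
          x <- x[keep, , drop = FALSE]
          y <- y[keep]
        }
        dt_train(x, y)
      },
      predict = function(m, x, opts) dt_predict(m, x)),
    svm_linear = list(
      fit = function(x, y, opts) {
        cap <- opts$svm_train_cap
        if (!is.null(cap) && nrow(x) > cap) {
          keep <- sample(nrow(x), cap)
          x <- x[keep, , drop = FALSE]
          y <- y[keep]
        }
        svm_train(x, y, cost = opts$svm_cost)
      },
      predict = function(m, x, opts) svm_predict(m, x))
  )
}
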