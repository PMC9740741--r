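#' Feature-set definitions
#'
#' The nine feature sets built from the 18 per-axis identifiers:
#' \describe{
#'   \item{A}{all 18 features (54 columns)}
#'   \item{B}{3-component PCA reduction of A}
#'   \item{C1}{NCA-selected features, lambda = default (1/n train)}
#'   \item{C2}{NCA-selected features, lambda = 0}
#'   \item{D}{3-component PCA reduction of C2}
#'   \item{E}{basic statistics, identifiers 1-5 (15 columns)}
#'   \item{F}{frequency domain, identifiers 8-9 (6 columns)}
#'   \item{G}{nonlinear features, identifiers 10-12 (9 columns)}
#'   \item{H}{wavelet energies, identifiers 13-18 (18 columns)}
#' }
#'
#' @return Named list mapping set id to base identifier vector.
#' @export
feature_set_defs <- function() {
  list(A = 1:18, B = 1:18, C1 = 1:18, C2 = 1:18, D = 1:18,
       E = 1:5, F = 8:9, G = 10:12, H = 13:18)
}

#' Does a feature set require nonlinear-valid windows?
#'
#' Sets whose base features include identifiers 10-12 (Lempel-Ziv, CTM,
#' correlation dimension) must drop windows whose nonlinear features
#' failed; sets E, F and H keep all windows.
#'
#' @param set_id One of A, B, C1, C2, D, E, F, G, H.
#' @return Logical.
#' @export
set_requires_valid <- function(set_id) {
  ids <- feature_set_defs()[[set_id]]
  if (is.null(ids)) stop("unknown feature set: ", set_id, call. = FALSE)
  any(10:12 %in% ids)
}

#' Select the base columns of a feature set
#'
#' @param features Windows x 54 feature matrix with [feature_columns()]
#'   names.
#' @param set_id Feature-set identifier.
#' @return Sub-matrix with the selected identifiers across all three axes.
#' @export
select_base <- function(features, set_id) {
  ids <- feature_set_defs()[[set_id]]
  if (is.null(ids)) stop("unknown feature set: ", set_id, call. = FALSE)
  keep <- as.vector(t(outer(c("x", "y", "z"), feature_names()[ids],
                            paste, sep = "_")))
  features[, keep, drop = FALSE]
}

#' Fit / apply a column standardizer
#'
#' Z-scores each column using training means and standard deviations;
#' constant columns get sd = 1 so they map to zero without division
#' errors. Applying a fitted state to new data always uses the training
#' statistics (no leakage).
#'
#' @param train Training matrix.
#' @return List with `means` and `sds`.
#' @export
fit_standardizer <- function(train) {
  means <- colMeans(train)
  sds <- apply(train, 2, stats::sd)
  sds[!is.finite(sds) | sds == 0] <- 1
  list(means = means, sds = sds)
}

#' @rdname fit_standardizer
#' @param x Matrix to standardize.
#' @param state Fitted standardizer.
#' @export
apply_standardizer <- function(x, state) {
  scale(x, center = state$means, scale = state$sds)[, , drop = FALSE]
}

#' Fit / apply a PCA reduction
#'
#' Principal components via eigendecomposition of the covariance matrix
#' of the (already standardized) training data; keeps the top `k`
#' components.
#'
#' @param train Standardized training matrix (rows >= k).
#' @param k Number of components (default 3).
#' @return List with `center`, `rotation` (columns orthonormal) and
#'   `explained` (variance fractions, non-increasing).
#' @export
fit_pca <- function(train, k = 3) {
  if (k > ncol(train)) stop("k exceeds the number of columns", call. = FALSE)
  if (nrow(train) < k) stop("need at least k rows", call. = FALSE)
  pr <- stats::prcomp(train, center = TRUE, scale. = FALSE)
  list(center = pr$center,
       rotation = pr$rotation[, seq_len(k), drop = FALSE],
       explained = (pr$sdev^2 / sum(pr$sdev^2))[seq_len(k)])
}

#' @rdname fit_pca
#' @param x Matrix to project.
#' @param state Fitted PCA.
#' @export
apply_pca <- function(x, state) {
  sweep(x, 2, state$center) %*% state$rotation
}

#' NCA feature-weight selection
#'
#' Neighbourhood component analysis for feature selection: learns
#' non-negative per-feature weights maximising the expected
#' leave-one-out classification accuracy under a soft nearest-neighbour
#' rule, with an L2 penalty `lambda` on the weights. The weighted
#' distance between rows i and j is `sum_r w_r^2 |x_ir - x_jr|`, the
#' neighbour kernel is `exp(-d / sigma)` with a self-normalising width:
#' for each reference sample, `sigma` is the mean weighted distance to
#' the other rows at the current weights, which keeps the neighbour
#' probabilities usefully spread as the weights grow or shrink.
#' Optimisation is stochastic gradient ascent (fixed epochs and step
#' size) with weights projected to be non-negative after each update.
#' Features with weight strictly greater than `threshold` are selected.
#'
#' For computational tractability on large window sets the optimiser
#' works on a seeded subsample of at most `ref_cap` training rows (default 1000); the
#' subsample is drawn with the ambient RNG, so seed the caller for
#' reproducibility.
#'
#' @param train Standardized training matrix.
#' @param labels Class labels (>= 2 classes).
#' @param lambda Regularisation; `"default"` means 1/n (n = rows used).
#' @param threshold Selection threshold on the weights (strict >).
#' @param epochs,step SGD passes and step size.
#' @param ref_cap Maximum number of rows used for fitting.
#' @return List with `weights` (named), `selected` (column indices with
#'   weight > threshold) and `lambda`.
#' @export
nca_select <- function(train, labels, lambda = "default", threshold = 0.2,
                       epochs = 50, step = 0.05, ref_cap = 1000) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2)
    stop("NCA needs at least 2 classes", call. = FALSE)
  n_all <- nrow(train)
  if (n_all > ref_cap) {
    keep <- sample(n_all, ref_cap)
    train <- train[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  n <- nrow(train)
  d <- ncol(train)
  if (identical(lambda, "default")) lambda <- 1 / n
  w <- rep(1, d)
  tr_t <- t(train)
  for (ep in seq_len(epochs)) {
    for (i in sample(n)) {
      ad <- abs(tr_t - train[i, ])          # d x n absolute differences
      dist_w <- colSums(ad * w^2)
      sigma <- mean(dist_w[-i])             # self-normalising width
      if (sigma <= 0) next
      k <- exp(-dist_w / sigma)
      k[i] <- 0
      denom <- sum(k)
      if (denom <= 0) next
      p <- k / denom
      same <- labels == labels[i]
      p_i <- sum(p[same])
      grad <- (2 * w / sigma) *
        (p_i * as.vector(ad %*% p) - as.vector(ad %*% (p * same))) -
        2 * lambda * w
      w <- pmax(w + step * grad, 0)
    }
  }
  names(w) <- colnames(train)
  list(weights = w, selected = which(w > threshold), lambda = lambda)
}

#' Assemble one feature set from training and test rows
#'
#' Selects the base identifiers, drops invalid rows for sets containing
#' the nonlinear features, standardizes with training statistics, and
#' applies the set's transform (PCA for B and D, NCA selection for C1,
#' C2 and D). Every fitted state is a pure function of the training
#' rows.
#'
#' @param ft A `feature_table`.
#' @param set_id Feature-set identifier.
#' @param train_idx,test_idx Row indices into `ft$features`.
#' @param options List: `standardize` (default TRUE), `pca_k` (3),
#'   `nca_threshold` (0.2), `nca_epochs`, `nca_step`, `nca_ref_cap`.
#' @param labels Class labels for all rows of `ft` (needed by NCA sets).
#' @return List `train`, `test` (transformed matrices), `train_idx`,
#'   `test_idx` (after validity filtering), `state` (fitted transforms).
#' @export
build_feature_set <- function(ft, set_id, train_idx, test_idx,
                              labels = NULL, options = list()) {
  o <- utils::modifyList(list(standardize = TRUE, pca_k = 3,
                              nca_threshold = 0.2, nca_epochs = 50,
                              nca_step = 0.01, nca_ref_cap = 1000),
                         options)
  if (set_requires_valid(set_id)) {
    train_idx <- train_idx[ft$meta$valid[train_idx]]
    test_idx <- test_idx[ft$meta$valid[test_idx]]
  }
  base <- select_base(ft$features, set_id)
  tr <- base[train_idx, , drop = FALSE]
  te <- base[test_idx, , drop = FALSE]
  state <- list(set_id = set_id)
  if (o$standardize) {
    state$standardizer <- fit_standardizer(tr)
    tr <- apply_standardizer(tr, state$standardizer)
    te <- apply_standardizer(te, state$standardizer)
  }
  if (set_id %in% c("C1", "C2", "D")) {
    lam <- if (set_id == "C1") "default" else 0
    state$nca <- nca_select(tr, labels[train_idx], lambda = lam,
                            threshold = o$nca_threshold,
                            epochs = o$nca_epochs, step = o$nca_step,
                            ref_cap = o$nca_ref_cap)
    sel <- state$nca$selected
    if (length(sel) == 0) sel <- order(state$nca$weights,
                                       decreasing = TRUE)[1]
    tr <- tr[, sel, drop = FALSE]
    te <- te[, sel, drop = FALSE]
  }
  if (set_id %in% c("B", "D")) {
    k <- min(o$pca_k, ncol(tr))
    state$pca <- fit_pca(tr, k)
    tr <- apply_pca(tr, state$pca)
    te <- apply_pca(te, state$pca)
  }
  list(train = tr, test = te, train_idx = train_idx, test_idx = test_idx,
       state = state)
}
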