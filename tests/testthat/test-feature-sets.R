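# simulated feature matrix: one informative column tracking the class,
# the rest pure noise
nca_sim <- function(n = 200, d = 10, seed = 1) {
  set.seed(seed)
  y <- rep(c("a", "b"), length.out = n)
  x <- matrix(stats::rnorm(n * d), n, d)
  x[, 1] <- ifelse(y == "a", -1, 1) + stats::rnorm(n, 0, 0.1)
  colnames(x) <- paste0("f", seq_len(d))
  list(x = apply_standardizer(x, fit_standardizer(x)), y = y)
}

test_that("base selection yields the documented dimensionalities", {
  m <- matrix(0, 4, 54, dimnames = list(NULL, feature_columns()))
  expect_equal(ncol(select_base(m, "A")), 54)
  expect_equal(ncol(select_base(m, "E")), 15)
  expect_equal(ncol(select_base(m, "F")), 6)
  expect_equal(ncol(select_base(m, "G")), 9)
  expect_equal(ncol(select_base(m, "H")), 18)
  expect_error(select_base(m, "Z"), "unknown")
  expect_true(set_requires_valid("A"))
  expect_true(set_requires_valid("G"))
  expect_false(set_requires_valid("E"))
})

test_that("standardizer centres and scales on training statistics only", {
  tr <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  st <- fit_standardizer(tr)
  z <- apply_standardizer(tr, st)
  expect_equal(z[, "a"], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(z[, "b"], c(0, 0, 0), ignore_attr = TRUE)  # constant column
  te <- cbind(a = c(4, 6), b = c(5, 7))
  zt <- apply_standardizer(te, st)
  expect_equal(zt[, "a"], c(2, 4), ignore_attr = TRUE)  # train mean/sd reused
})

test_that("PCA keeps orthonormal axes ordered by explained variance", {
  set.seed(8)
  dir1 <- c(1, 2, 3) / sqrt(14)
  x <- outer(stats::rnorm(200), dir1) +
    matrix(stats::rnorm(600, 0, 1e-4), 200, 3)
  st <- fit_pca(x, k = 3)
  expect_gt(st$explained[1], 0.999)
  expect_true(all(diff(st$explained) <= 1e-12))
  expect_equal(unname(crossprod(st$rotation)), diag(3), tolerance = 1e-9)
  expect_equal(ncol(apply_pca(x, st)), 3)
  expect_error(fit_pca(x, k = 5), "exceeds")
})

test_that("NCA keeps the informative feature and discards noise", {
  hits <- 0
  for (rep in 1:20) {
    sim <- nca_sim(seed = rep)
    set.seed(rep)
    res <- nca_select(sim$x, sim$y, lambda = "default", epochs = 30)
    if (1 %in% res$selected && all(res$weights[-1] < 0.2)) hits <- hits + 1
  }
  expect_gte(hits, 18)  # across 20 replicates
})

test_that("lambda = 0 selects a superset of the default-lambda features", {
  for (rep in 1:5) {
    sim <- nca_sim(seed = 100 + rep)
    set.seed(rep)
    r_def <- nca_select(sim$x, sim$y, lambda = "default", epochs = 30)
    set.seed(rep)
    r_zero <- nca_select(sim$x, sim$y, lambda = 0, epochs = 30)
    expect_true(all(r_def$selected %in% r_zero$selected))
  }
})

test_that("selection threshold is a strict inequality", {
  sim <- nca_sim(seed = 3)
  set.seed(3)
  res <- nca_select(sim$x, sim$y, epochs = 5)
  w <- res$weights
  expect_identical(res$selected, which(w > 0.2))
  expect_false(any(w[setdiff(seq_along(w), res$selected)] > 0.2))
  expect_error(nca_select(sim$x, rep("a", nrow(sim$x))), "2 classes")
})

test_that("assembled dimensionalities match the design table", {
  ft <- tiny_feature_table()
  labels <- ft$meta$class
  n <- nrow(ft$features)
  tr <- which(seq_len(n) %% 3 != 0)
  te <- which(seq_len(n) %% 3 == 0)
  dims <- c(A = 54, B = 3, E = 15, F = 6, G = 9, H = 18)
  for (set_id in names(dims)) {
    set.seed(1)
    out <- build_feature_set(ft, set_id, tr, te, labels = labels)
    expect_equal(ncol(out$train), unname(dims[set_id]))
    expect_equal(ncol(out$test), unname(dims[set_id]))
  }
  # D: NCA selection (lambda = 0) then PCA to exactly 3 columns
  set.seed(1)
  d <- build_feature_set(ft, "D", tr, te, labels = labels,
                         options = list(nca_epochs = 3, nca_ref_cap = 300))
  expect_equal(ncol(d$train), 3)
  # validity rule: invalid rows excluded for nonlinear-bearing sets only
  set.seed(1)
  a <- build_feature_set(ft, "A", tr, te, labels = labels,
                         options = list(nca_epochs = 3))
  expect_equal(length(a$train_idx), sum(ft$meta$valid[tr]))
  e <- build_feature_set(ft, "E", tr, te, labels = labels)
  expect_equal(length(e$train_idx), length(tr))
})

test_that("fitted transforms never depend on test rows", {
  ft <- tiny_feature_table()
  labels <- ft$meta$class
  n <- nrow(ft$features)
  tr <- seq_len(floor(n / 2))
  te <- (floor(n / 2) + 1):n
  te_shuffled <- sample(te)
  for (set_id in c("E", "B", "C1")) {
    set.seed(42)
    s1 <- build_feature_set(ft, set_id, tr, te, labels = labels,
                            options = list(nca_epochs = 3,
                                           nca_ref_cap = 200))
    set.seed(42)
    s2 <- build_feature_set(ft, set_id, tr, te_shuffled, labels = labels,
                            options = list(nca_epochs = 3,
                                           nca_ref_cap = 200))
    expect_equal(s1$state, s2$state)
  }
})
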