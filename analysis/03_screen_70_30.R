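#!/usr/bin/env Rscript
# Step 3: screening pass.
#
# Every feature set (A, B, C1, C2, D, E, F, G, H) crossed with every
# model (k-NN Manhattan, k-NN Euclidean, CART, linear SVM) under the
# random 70/30 split, separately for the binary and tertiary tasks.
# The SVM is trained on a seeded 10k-row subsample inside each fit
# (libsvm is superquadratic in n); all other models train on the full
# 70% split. Writes the two accuracy grids (with MEAN row/column).

library(accelgait)

ft <- readRDS("scratch/features.rds")
seed <- 1
opts <- experiment_options()   # svm_train_cap = 10000

for (task in c("binary", "tertiary")) {
  message("70/30 grid, ", task, " task ...")
  t0 <- Sys.time()
  tab <- run_grid_70_30(ft, task = task, seed = seed, opts = opts)
  grid <- accuracy_grid(tab)
  out <- sprintf("results/%s_70_30_grid.csv", task)
  write.csv(grid, out, row.names = FALSE)
  message(sprintf("  %.1f min; wrote %s",
                  as.numeric(Sys.time() - t0, units = "mins"), out))
  best <- tab[which.max(tab$accuracy), ]
  message(sprintf("  best single pair: set %s + %s = %.2f%%",
                  best$set_id, best$model_id, best$accuracy))
  means <- aggregate(accuracy ~ set_id, tab, mean)
  top <- means$set_id[order(-means$accuracy)][1:3]
  message("  top-3 sets by mean accuracy: ", paste(top, collapse = ", "))
}
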