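#!/usr/bin/env Rscript
# Step 4: 10-fold cross-validation of the sets carried forward.
#
# The screening pass consistently ranks the all-features set (A), the
# NCA-selected set (C1) and one cheap specialist set highest, so those
# are re-evaluated with 10-fold cross-validation: basic statistics (E)
# join A and C1 for the binary task, wavelets (H) for the tertiary
# task. Transforms and models are refitted inside every fold. Writes
# the accuracy grids and the pooled confusion matrices of the top
# three (set, model) pairs.

library(accelgait)

ft <- readRDS("scratch/features.rds")
seed <- 1
opts <- experiment_options()

carried <- list(binary = c("A", "C1", "E"), tertiary = c("A", "C1", "H"))

for (task in names(carried)) {
  message("10-fold CV, ", task, " task: sets ",
          paste(carried[[task]], collapse = ", "), " ...")
  t0 <- Sys.time()
  res <- run_grid_kfold(ft, task = task, sets = carried[[task]],
                        k = 10, seed = seed, opts = opts)
  grid <- accuracy_grid(res$table)
  out <- sprintf("results/%s_10fold_grid.csv", task)
  write.csv(grid, out, row.names = FALSE)
  # pooled confusion matrices of the top three pairs
  tab <- res$table[order(-res$table$accuracy), ]
  cm_rows <- list()
  for (i in 1:3) {
    key <- paste(tab$set_id[i], tab$model_id[i], sep = ".")
    cm <- res$confusions[[key]]
    cm_rows[[i]] <- data.frame(pair = key, actual = rownames(cm),
                               as.data.frame.matrix(cm))
  }
  write.csv(do.call(rbind, cm_rows),
            sprintf("results/%s_10fold_top3_confusions.csv", task),
            row.names = FALSE)
  message(sprintf("  %.1f min; wrote %s",
                  as.numeric(Sys.time() - t0, units = "mins"), out))
  print(grid, digits = 4)
}
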