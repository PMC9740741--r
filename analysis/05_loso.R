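#!/usr/bin/env Rscript
# Step 5: leave-one-source-out validation of the chosen sets.
#
# The repeatability estimate: hold out all windows of one recording per
# fold. The binary task uses the basic-statistics set (E, the cheapest
# of the near-tied top sets); the tertiary task uses the all-features
# set (A, the most consistent across models). k-NN trains on every
# remaining window; the decision tree and SVM train on seeded
# subsamples (30k / 10k rows per fold) to keep 110 refits tractable,
# and the SVM is skipped for the tertiary task where its per-fold
# fitting time is prohibitive. Writes per-model summary rows
# (Mean/SD/Min/Max), per-source accuracies, and the pooled confusion
# matrix of the Manhattan k-NN.

library(accelgait)

ft <- readRDS("scratch/features.rds")
seed <- 1
opts <- experiment_options(dt_train_cap = 30000)

plans <- list(
  binary = list(set = "E", models = c("knn_manhattan", "knn_euclidean",
                                      "cart", "svm_linear")),
  tertiary = list(set = "A", models = c("knn_manhattan", "knn_euclidean",
                                        "cart"))
)

for (task in names(plans)) {
  plan <- plans[[task]]
  summary_rows <- list()
  per_source <- NULL
  for (model in plan$models) {
    message(sprintf("LOSO %s, set %s, %s ...", task, plan$set, model))
    t0 <- Sys.time()
    r <- run_loso(ft, plan$set, model, task = task, seed = seed,
                  opts = opts)
    message(sprintf("  mean %.2f%% (SD %.2f, min %.2f, max %.2f), %.1f min",
                    r$mean, r$sd, r$min, r$max,
                    as.numeric(Sys.time() - t0, units = "mins")))
    summary_rows[[model]] <- data.frame(
      model = model, mean = r$mean, sd = r$sd, min = r$min, max = r$max)
    acc <- r$per_source[, c("source_id", "n_windows", "accuracy")]
    names(acc)[2:3] <- paste0(model, c("_n", "_accuracy"))
    per_source <- if (is.null(per_source)) acc
                  else merge(per_source, acc, by = "source_id")
    if (model == "knn_manhattan") {
      cm <- r$confusion
      write.csv(data.frame(actual = rownames(cm),
                           as.data.frame.matrix(cm)),
                sprintf("results/%s_loso_confusion_knn_manhattan.csv",
                        task), row.names = FALSE)
      pc <- data.frame(class = names(r$per_class),
                       accuracy = as.numeric(r$per_class),
                       error = 100 - as.numeric(r$per_class))
      write.csv(pc, sprintf("results/%s_loso_per_class.csv", task),
                row.names = FALSE)
    }
  }
  write.csv(do.call(rbind, summary_rows),
            sprintf("results/%s_loso_summary.csv", task),
            row.names = FALSE)
  write.csv(per_source, sprintf("results/%s_loso_per_source.csv", task),
            row.names = FALSE)
  worst <- per_source$source_id[order(per_source$knn_manhattan_accuracy)][1:3]
  message(sprintf("  weakest sources (%s): %s", task,
                  paste(worst, collapse = ", ")))
}
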