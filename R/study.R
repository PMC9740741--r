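#' Generate, preprocess and featurize the default cohort
#'
#' Convenience driver: generates the default 110-recording synthetic
#' cohort, downsamples/filters/segments it, and extracts the full
#' 54-column feature table.
#'
#' @param seed Master integer seed.
#' @param config A [cohort_config()].
#' @return A `feature_table`.
#' @export
cohort_feature_table <- function(seed = 1, config = cohort_config()) {
  cohort <- generate_cohort(config, seed = seed)
  windows <- preprocess_cohort(cohort)
  extract_features(windows)
}

#' Reference leave-one-source-out evaluation
#'
#' The pipeline's headline computation: on a synthetic cohort, run
#' leave-one-source-out cross-validation with the Manhattan k-NN
#' classifier for the binary task on the basic-statistics set (E) and
#' for the tertiary task on the all-features set (A). Returns the
#' summary accuracies and the tertiary per-class accuracies.
#'
#' @param seed Master integer seed (cohort generation and fold fits).
#' @param config A [cohort_config()]; default is the full
#'   110-recording cohort.
#' @param ft Optionally, a precomputed `feature_table` (skips
#'   generation).
#' @return List with `binary` and `tertiary` `loso_result`s and the
#'   feature table's window counts.
#' @export
reference_loso_evaluation <- function(seed = 1, config = cohort_config(),
                                      ft = NULL) {
  if (is.null(ft)) ft <- cohort_feature_table(seed, config)
  binary <- run_loso(ft, set_id = "E", model_id = "knn_manhattan",
                     task = "binary", seed = seed)
  tertiary <- run_loso(ft, set_id = "A", model_id = "knn_manhattan",
                       task = "tertiary", seed = seed)
  list(binary = binary, tertiary = tertiary,
       n_windows = nrow(ft$meta), n_valid = sum(ft$meta$valid))
}
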