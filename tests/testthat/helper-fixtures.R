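# Small fixtures shared across test files. Everything is generated in
# code; the tiny cohort is cached per session because several files use
# it.

tiny_config <- function(n_track = 2, n_treadmill = 1, ...) {
  cohort_config(n_track = n_track, n_treadmill = n_treadmill, ...)
}

.fixture_env <- new.env()

tiny_cohort <- function(seed = 42) {
  key <- paste0("cohort_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_cohort(tiny_config(), seed = seed)
  .fixture_env[[key]]
}

tiny_feature_table <- function(seed = 42) {
  key <- paste0("ft_", seed)
  if (is.null(.fixture_env[[key]])) {
    ws <- preprocess_cohort(tiny_cohort(seed))
    .fixture_env[[key]] <- extract_features(ws)
  }
  .fixture_env[[key]]
}

# A single short synthetic recording (one standing + two walking stages)
# for preprocessing tests where full protocol length is unnecessary.
short_recording <- function(seed = 5, fs = 50) {
  set.seed(seed)
  cfg <- tiny_config()
  params <- draw_subject_params(cfg, "short", fs)
  sig1 <- synth_stage_signal(0, "Standing", 60, fs, params, "treadmill")
  sig2 <- synth_stage_signal(4.3, "Walking", 45, fs, params, "treadmill")
  sig3 <- synth_stage_signal(4.9, "Walking", 45, fs, params, "treadmill")
  n <- vapply(list(sig1, sig2, sig3), function(s) length(s$x), 0L)
  rec <- list(source_id = "short", test_type = "treadmill",
              sampling_rate = fs,
              x = c(sig1$x, sig2$x, sig3$x),
              y = c(sig1$y, sig2$y, sig3$y),
              z = c(sig1$z, sig2$z, sig3$z),
              stage = rep(c(1L, 5L, 6L), n),
              class = rep(c("Standing", "Walking", "Walking"), n),
              jog_onset_stage = 9L, max_stage = 6L)
  class(rec) <- "raw_recording"
  rec
}

# Brute-force exhaustive-history Lempel-Ziv 1976 parser: the next word
# extends until it is no longer a substring of all preceding text plus
# the word minus its last character; the final (possibly reproducible)
# word still counts. Independent of the scanning implementation.
lz76_oracle <- function(bits) {
  s <- paste(bits, collapse = "")
  n <- nchar(s)
  pos <- 1L
  c_count <- 0L
  while (pos <= n) {
    len <- 1L
    repeat {
      word <- substr(s, pos, pos + len - 1L)
      history <- substr(s, 1L, pos + len - 2L)
      if (!grepl(word, history, fixed = TRUE)) break  # new word
      if (pos + len - 1L >= n) break                  # ran off the end
      len <- len + 1L
    }
    c_count <- c_count + 1L
    pos <- pos + len
  }
  c_count
}

# exhaustive all-pairs distance oracle for k-NN, with the same tie
# rules applied independently of the compiled search
knn_oracle <- function(train_x, train_y, test_x, k, metric) {
  dfun <- if (metric == "manhattan") manhattan_distance
          else euclidean_distance
  out <- character(nrow(test_x))
  for (q in seq_len(nrow(test_x))) {
    d <- apply(train_x, 1, dfun, q = test_x[q, ])
    ord <- order(d)[seq_len(k)]  # order() is stable on ties
    labs <- train_y[ord]
    votes <- table(labs)
    winners <- names(votes)[votes == max(votes)]
    if (length(winners) > 1) {
      md <- vapply(winners, function(cl) mean(d[ord][labs == cl]), 0)
      winners <- sort(winners[md == min(md)])
    }
    out[q] <- winners[1]
  }
  out
}
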