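# Small programmatic fixtures shared across test files.

# A minimal scheme with n_mid midline and n_bil bilateral landmarks.
small_scheme <- function(n_mid = 3L, n_bil = 0L) {
  n <- n_mid + n_bil
  landmark_scheme(data.frame(
    landmark = seq_len(n),
    name = paste0("lm", seq_len(n)),
    position = c(rep("midline", n_mid), rep("bilateral", n_bil)),
    type = "I", stringsAsFactors = FALSE))
}

# Dataset of fully midline configurations built from a list of K x 3 blocks
# keyed by individual/method/replicate triples.
midline_dataset <- function(blocks, ids, methods, reps,
                            dscheme = NULL) {
  K <- nrow(blocks[[1]])
  sch <- small_scheme(n_mid = K)
  if (is.null(dscheme))
    dscheme <- distance_scheme(data.frame(
      distance = 1L, landmark_a = 1L, landmark_b = 2L, label = "d1",
      stringsAsFactors = FALSE), sch)
  cfs <- Map(function(b, i, m, r) landmark_config(i, m, r, b),
             blocks, ids, methods, reps)
  landmark_dataset(cfs, sch, dscheme)
}

# Long-format distance table built directly (bypasses coordinates) for the
# reliability/difference modules: one row per value.
manual_distance_table <- function(individual, method, replicate, distance,
                                  value_mm) {
  data.frame(individual = as.character(individual), method = method,
             replicate = replicate, distance = distance,
             value_mm = value_mm, single_side = FALSE,
             stringsAsFactors = FALSE)
}
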