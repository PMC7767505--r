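# Shared fixtures, all generated in code.

random_dna <- function(n, length = 81, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = "")
  }, "")
}

# A small architecture that trains in well under a second; used wherever a
# test only needs structural behavior, not benchmark-scale capacity.
tiny_arch <- function(...) {
  arch_config(conv1_filters = 4L, conv1_kernel = 3L, conv2_filters = 4L,
              conv2_kernel = 3L, dense1_units = 4L, ...)
}

tiny_train <- function(epochs = 3L, seed = 1L, ...) {
  train_config(epochs = epochs, seed = seed, ...)
}

# Balanced two-class promoter/background set.
promn_dataset <- function(n_each = 60, mutation_rate = 0, seed = 11) {
  generate_dataset(synth_config(
    n_per_class = c(NON_PROMOTER = n_each, S70 = n_each),
    mutation_rate = mutation_rate, seed = seed))
}

# Small seven-class set covering every cascade stage.
sevenway_dataset <- function(n_sigma = 25, n_non = 50, mutation_rate = 0,
                             seed = 17) {
  counts <- c(NON_PROMOTER = n_non,
              stats::setNames(rep(n_sigma, 6), sigma_labels()))
  generate_dataset(synth_config(n_per_class = counts,
                                mutation_rate = mutation_rate, seed = seed))
}

# Stub cascade with one fixed probability per stage.
stub_cascade <- function(probs) {
  stages <- cascade_stages()$stage
  stopifnot(length(probs) == length(stages))
  cascade_model(stats::setNames(
    lapply(seq_along(stages),
           function(i) stub_classifier(probs[i], stages[i])),
    stages))
}

write_fasta_lines <- function(lines) {
  path <- tempfile(fileext = ".fa")
  writeLines(lines, path)
  path
}
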