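# Fixtures are built in code: small phantom corpora, toy network configs
# and lightweight corpus stand-ins used to exercise split bookkeeping
# without rendering thousands of images.

tiny_flat_config <- function(...) {
  flatnet_config(dilation_rates = c(1L, 1L, 2L, 2L, 3L),
                 filters = c(f1 = 2L, f2 = 2L, f4 = 4L, f5 = 4L, f6 = 4L), ...)
}

tiny_phantom <- function(n_subjects = 2, n_classes = 3, size = 48,
                         seed = 42, ...) {
  generate_corpus(phantom_config(n_subjects, n_classes,
                                 image_size = c(size, size),
                                 rng_seed = seed, ...))
}

# corpus stand-in carrying provenance only (enough for split planning)
meta_corpus <- function(n_subjects, n_classes, tags = "orig") {
  out <- list()
  for (s in seq_len(n_subjects)) for (cl in seq_len(n_classes)) for (tg in tags) {
    out[[length(out) + 1L]] <- structure(
      list(subject_id = sprintf("S%02d", s), class_id = sprintf("C%02d", cl),
           augmentation_tag = tg,
           source_id = sprintf("S%02d:C%02d", s, cl)),
      class = "annotated_image")
  }
  out
}

aug_tags <- function() c("orig", vapply(standard_transforms(),
                                        function(t) t$name, character(1)))

# argmax of a plain matrix under the codec's tie-breaking rule (row, col 0-based)
brute_argmax <- function(ch) {
  m <- max(ch)
  idx <- which(ch == m, arr.ind = TRUE)
  best <- idx[order(idx[, 1], idx[, 2])[1], ]
  c(x = unname(best["col"]) - 1, y = unname(best["row"]) - 1)
}
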