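# End-to-end experiment orchestration:
# synthesize/load -> augment -> split -> train per fold -> predict -> report.

#' Experiment configuration
#'
#' Exactly one input source must be given: a [phantom_config()] for a
#' synthetic corpus, or `annotations`/`images_dir` paths for an external
#' one.
#'
#' @param phantom a [phantom_config()], or `NULL`.
#' @param annotations,images_dir external corpus paths, or `NULL`.
#' @param scheme evaluation protocol: `"LoSo"` or `"CV10"`.
#' @param network a [flatnet_config()].
#' @param control a [train_control()].
#' @param codec a [codec_config()].
#' @param seed global seed driving augmentation and (for CV) the fold
#'   permutation.
#' @param resolution_mm_per_px resolution used in px-to-cm conversions.
#' @param outdir optional output directory; when set, per-fold record
#'   files are written there and finished folds are skipped on re-runs.
#' @param folds optional integer vector restricting which folds to run
#'   (e.g. a single fold of a larger plan); default all.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(phantom = NULL, annotations = NULL,
                              images_dir = NULL,
                              scheme = c("LoSo", "CV10"),
                              network = flatnet_config(),
                              control = train_control(),
                              codec = codec_config(), seed = 1L,
                              resolution_mm_per_px = 1, outdir = NULL,
                              folds = NULL) {
  scheme <- match.arg(scheme)
  has_phantom <- !is.null(phantom)
  has_files <- !is.null(annotations) || !is.null(images_dir)
  if (has_phantom == has_files)
    stop("give exactly one input source: phantom config, or annotation/image paths")
  if (has_phantom) stopifnot(inherits(phantom, "phantom_config"))
  structure(list(phantom = phantom, annotations = annotations,
                 images_dir = images_dir, scheme = scheme, network = network,
                 control = control, codec = codec, seed = as.integer(seed),
                 resolution_mm_per_px = resolution_mm_per_px,
                 outdir = outdir, folds = folds),
            class = "experiment_config")
}

#' Run a full training/evaluation experiment
#'
#' Executes the configured pipeline: the corpus of originals is generated
#' (or read), expanded with the ten standard transforms, split according
#' to the chosen scheme, and a fresh localizer is trained per fold and
#' evaluated on that fold's test items. Under LoSo it is asserted at run
#' time that no fold's training data contains the fold's test subject.
#'
#' @param config an [experiment_config()].
#' @param verbose print progress.
#' @return An `evaluation_report` (with the fitted models of the last fold
#'   attached as attribute `"last_fit"`).
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  originals <- if (!is.null(config$phantom)) generate_corpus(config$phantom)
               else read_corpus(config$annotations, config$images_dir)
  augmented <- augment_corpus(originals, seed = config$seed)
  plan <- switch(config$scheme,
                 LoSo = make_loso_splits(augmented),
                 CV10 = make_cv_splits(augmented, 10L, seed = config$seed))
  meta <- corpus_meta(augmented)
  run_folds <- config$folds %||% seq_along(plan$folds)
  if (!is.null(config$outdir))
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  predictions <- list()
  last_fit <- NULL
  for (f in run_folds) {
    fold <- plan$folds[[f]]
    if (config$scheme == "LoSo") {
      test_subj <- unique(meta$subject[fold$test])
      if (any(meta$subject[fold$train] %in% test_subj))
        stop("internal error: LoSo fold ", f, " leaks its test subject")
    }
    fold_file <- if (!is.null(config$outdir))
      file.path(config$outdir, sprintf("fold_%02d_predictions.csv", f)) else NULL
    if (!is.null(fold_file) && file.exists(fold_file)) {
      if (verbose) message("fold ", f, ": reusing ", fold_file)
      prev <- read.csv(fold_file, stringsAsFactors = FALSE)
      for (id in unique(prev$id))
        predictions[[id]] <- prev[prev$id == id, c("abbrev", "x", "y")]
      next
    }
    if (verbose)
      message(sprintf("fold %d/%d: training on %d items, testing on %d",
                      f, length(plan$folds), length(fold$train),
                      length(fold$test)))
    fit <- flatnet_fit(augmented[fold$train], config = config$network,
                       control = config$control, codec = config$codec,
                       verbose = verbose)
    fold_rows <- list()
    for (i in fold$test) {
      pred <- predict(fit, augmented[[i]])
      predictions[[meta$id[i]]] <- pred
      fold_rows[[length(fold_rows) + 1L]] <- cbind(id = meta$id[i], pred)
    }
    if (!is.null(fold_file))
      write.csv(do.call(rbind, fold_rows), fold_file, row.names = FALSE)
    last_fit <- fit
  }
  sub_plan <- plan
  sub_plan$folds <- plan$folds[run_folds]
  report <- build_report(augmented, predictions, sub_plan,
                         config$resolution_mm_per_px)
  if (!is.null(config$outdir))
    write_report(report, file.path(config$outdir, "report"))
  attr(report, "last_fit") <- last_fit
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare evaluation reports from different methods
#'
#' Reports must share the same split manifest (same scheme and test
#' items). Produces a side-by-side table of overall metrics plus pairwise
#' paired t-tests on the matched per-(image, landmark) distance errors.
#'
#' @param reports named list of `evaluation_report` objects; names label
#'   the methods and fix row/column order.
#' @return list with `table` (one row per method, input order) and
#'   `p_values` / `t_values` (pairwise matrices).
#' @export
compare_methods <- function(reports) {
  stopifnot(is.list(reports), length(reports) >= 2)
  if (is.null(names(reports)) || any(names(reports) == ""))
    names(reports) <- paste0("method", seq_along(reports))
  keys <- lapply(reports, function(r)
    sort(paste(r$records$image, r$records$landmark)))
  manifests <- lapply(reports, function(r)
    r$manifest[c("scheme", "n_items", "fold_test_sizes")])
  for (i in seq_along(reports)[-1]) {
    if (!identical(manifests[[1]], manifests[[i]]) ||
        !identical(keys[[1]], keys[[i]]))
      stop("reports do not share the same split manifest / record keys")
  }
  tab <- do.call(rbind, lapply(names(reports), function(nm) {
    o <- reports[[nm]]$overall
    data.frame(method = nm, rmse_px = o$rmse_px, rmse_cm = o$rmse_cm,
               outlier_pct = o$outlier_pct, median_d = o$median_d,
               stringsAsFactors = FALSE)
  }))
  ds <- lapply(reports, function(r) {
    r$records$d[order(paste(r$records$image, r$records$landmark))]
  })
  k <- length(reports)
  p <- t_ <- matrix(NA_real_, k, k, dimnames = list(names(reports), names(reports)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    tt <- paired_ttest(ds[[i]], ds[[j]])
    p[i, j] <- tt$p_value; t_[i, j] <- tt$t
  }
  list(table = tab, p_values = p, t_values = t_)
}
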