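# Evaluation: per-landmark Euclidean distances, RMSE over coordinate-pair
# errors, the strict >5 px outlier rate, split protocols (randomized
# 10-fold CV and leave-one-subject-out) and report assembly.

#' Euclidean distance between ground-truth and predicted points
#'
#' @param gt,pred length-2 vectors `c(x, y)`, or data.frames/matrices with
#'   columns `x` and `y` (vectorized over rows).
#' @return Numeric distance(s) in pixels.
#' @examples
#' euclidean_distance(c(0, 0), c(3, 4))  # 5
#' @export
euclidean_distance <- function(gt, pred) {
  get_xy <- function(p) {
    if (is.data.frame(p) || (is.matrix(p) && !is.null(colnames(p))))
      cbind(p[, "x"], p[, "y"])
    else if (is.matrix(p)) p
    else matrix(as.numeric(p), ncol = 2)
  }
  g <- get_xy(gt); p <- get_xy(pred)
  stopifnot(all(is.finite(g)), all(is.finite(p)), all(dim(g) == dim(p)))
  sqrt((g[, 1] - p[, 1])^2 + (g[, 2] - p[, 2])^2)
}

#' Root mean squared error over coordinate-pair errors
#'
#' `sqrt((1/Q) * sum((x_g - x_p)^2 + (y_g - y_p)^2))` over the Q records —
#' the squared x and y errors of each element are summed before averaging,
#' which equals `sqrt(mean(d^2))` for the per-record Euclidean distances d.
#'
#' @param records either a numeric vector of distances `d`, or a
#'   data.frame with columns `x_g`, `y_g`, `x_p`, `y_p` (or a column `d`).
#' @return RMSE in pixels.
#' @examples
#' rmse(c(0, 5))  # sqrt(12.5)
#' @export
rmse <- function(records) {
  d2 <- squared_errors(records)
  if (length(d2) == 0L) stop("rmse of an empty record set")
  sqrt(mean(d2))
}

# internal: per-record squared coordinate-pair error
squared_errors <- function(records) {
  if (is.numeric(records)) return(records^2)
  stopifnot(is.data.frame(records))
  if (all(c("x_g", "y_g", "x_p", "y_p") %in% names(records)))
    (records$x_g - records$x_p)^2 + (records$y_g - records$y_p)^2
  else if ("d" %in% names(records)) records$d^2
  else stop("records must carry x_g/y_g/x_p/y_p columns, a d column, or be numeric")
}

#' Percentage of landmarks with distance error above a threshold
#'
#' Outliers are counted with a strict inequality: an error exactly equal
#' to the threshold is not an outlier.
#'
#' @param records numeric distances or a record data.frame (see [rmse()]).
#' @param threshold_px outlier threshold in pixels (default 5).
#' @return Percentage in \[0, 100\].
#' @examples
#' outlier_rate(c(5.1, 4.9, 5.0))  # 33.33...
#' @export
outlier_rate <- function(records, threshold_px = 5) {
  d <- sqrt(squared_errors(records))
  if (length(d) == 0L) stop("outlier rate of an empty record set")
  100 * mean(d > threshold_px)
}

#' Randomized k-fold cross-validation split
#'
#' Randomly partitions the (augmented) corpus into k near-equal groups
#' (sizes differing by at most 1); each group serves once as the test set.
#' Note that, by design of this protocol, folds may share augmented copies
#' of the same subject/articulation between train and test sides.
#'
#' @param corpus list of annotated images (or anything whose `length()` is
#'   the number of items).
#' @param k number of folds (default 10).
#' @param seed RNG seed for the permutation.
#' @return A `split_plan` with `scheme = "CV10"`-style folds of item
#'   indices.
#' @export
make_cv_splits <- function(corpus, k = 10L, seed = 1L) {
  n <- length(corpus)
  if (k < 2) stop("k must be at least 2")
  if (n < k) stop("corpus smaller than the number of folds")
  perm <- with_seed(seed, sample(n))
  base <- n %/% k; rem <- n %% k
  sizes <- c(rep(base + 1L, rem), rep(base, k - rem))
  ends <- cumsum(sizes)
  folds <- lapply(seq_len(k), function(i) {
    test <- sort(perm[(ends[i] - sizes[i] + 1L):ends[i]])
    list(test = test, train = sort(setdiff(seq_len(n), test)))
  })
  structure(list(scheme = sprintf("CV%d", k), folds = folds, seed = seed,
                 n_items = n),
            class = "split_plan")
}

#' Leave-one-subject-out split
#'
#' One fold per subject: the test set holds that subject's un-augmented
#' originals only; the training set holds all items (originals plus
#' augmented copies) of the remaining subjects. Train and test sides are
#' therefore subject-disjoint.
#'
#' @param corpus list of [annotated_image()] objects (typically augmented).
#' @return A `split_plan` with `scheme = "LoSo"`.
#' @export
make_loso_splits <- function(corpus) {
  meta <- corpus_meta(corpus)
  subjects <- unique(meta$subject)
  if (length(subjects) < 2) stop("LoSo needs at least 2 subjects")
  folds <- lapply(subjects, function(s) {
    list(test = which(meta$subject == s & meta$tag == "orig"),
         train = which(meta$subject != s))
  })
  names(folds) <- subjects
  structure(list(scheme = "LoSo", folds = folds, seed = NA_integer_,
                 n_items = nrow(meta)),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  sizes <- vapply(x$folds, function(f) length(f$test), integer(1))
  cat(sprintf("<split_plan> %s, %d folds over %d items; test sizes: %s\n",
              x$scheme, length(x$folds), x$n_items,
              paste(sizes, collapse = ", ")))
  invisible(x)
}

#' Two-sided paired t-test on matched distance errors
#'
#' @param errors_a,errors_b equal-length numeric vectors of distance
#'   errors, paired by (image, landmark).
#' @return list with `t`, `p_value`, `df`, `mean_diff`.
#' @details Zero variance of the paired differences (e.g. comparing a
#'   method against itself) is a degenerate input and raises an error
#'   rather than fabricating a p-value.
#' @export
paired_ttest <- function(errors_a, errors_b) {
  stopifnot(is.numeric(errors_a), is.numeric(errors_b))
  if (length(errors_a) != length(errors_b))
    stop("paired t-test needs equal-length, matched samples")
  if (length(errors_a) < 2) stop("paired t-test needs at least 2 pairs")
  d <- errors_a - errors_b
  if (sd(d) == 0)
    stop("degenerate input: paired differences have zero variance")
  tt <- t.test(errors_a, errors_b, paired = TRUE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_diff = unname(tt$estimate))
}

#' Assemble an evaluation report
#'
#' Collects one distance record per (test image, landmark) across all
#' folds of a split plan, and aggregates them into the per-landmark RMSE
#' and outlier-rate matrices, per-subject RMSEs, and overall RMSE in both
#' pixels and centimeters.
#'
#' @param corpus the item list the split plan indexes into.
#' @param predictions named list mapping test-item ids
#'   (`subject:class:tag`) to predicted landmark data.frames.
#' @param plan a `split_plan`; every test item must have a prediction.
#' @param resolution_mm_per_px image resolution for the px-to-cm
#'   conversion (default 1).
#' @return An object of class `evaluation_report`.
#' @export
build_report <- function(corpus, predictions, plan,
                         resolution_mm_per_px = 1) {
  stopifnot(inherits(plan, "split_plan"))
  meta <- corpus_meta(corpus)
  recs <- list()
  for (f in seq_along(plan$folds)) {
    for (i in plan$folds[[f]]$test) {
      id <- meta$id[i]
      pred <- predictions[[id]]
      if (is.null(pred)) stop("missing prediction for test item ", id)
      gt <- corpus[[i]]$landmarks
      stopifnot(identical(as.character(pred$abbrev), as.character(gt$abbrev)))
      recs[[length(recs) + 1L]] <- data.frame(
        image = id, subject = meta$subject[i], fold = f,
        landmark = gt$abbrev, x_g = gt$x, y_g = gt$y,
        x_p = pred$x, y_p = pred$y,
        d = euclidean_distance(gt, pred), stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, recs)
  per_landmark <- do.call(rbind, lapply(split(records, records$landmark), function(r)
    data.frame(landmark = r$landmark[1], n = nrow(r), rmse_px = rmse(r),
               rmse_cm = px_to_cm(rmse(r), resolution_mm_per_px),
               outlier_pct = outlier_rate(r), stringsAsFactors = FALSE)))
  schema <- landmark_schema()
  per_landmark <- per_landmark[match(schema$abbrev, per_landmark$landmark), ]
  rownames(per_landmark) <- NULL
  per_subject <- do.call(rbind, lapply(split(records, records$subject), function(r)
    data.frame(subject = r$subject[1], n = nrow(r), rmse_px = rmse(r),
               rmse_cm = px_to_cm(rmse(r), resolution_mm_per_px),
               outlier_pct = outlier_rate(r), stringsAsFactors = FALSE)))
  rownames(per_subject) <- NULL
  overall <- list(n = nrow(records), rmse_px = rmse(records),
                  rmse_cm = px_to_cm(rmse(records), resolution_mm_per_px),
                  outlier_pct = outlier_rate(records),
                  median_d = median(records$d), mean_d = mean(records$d))
  manifest <- list(scheme = plan$scheme, seed = plan$seed,
                   n_items = plan$n_items,
                   fold_test_sizes = vapply(plan$folds, function(f)
                     length(f$test), integer(1)),
                   resolution_mm_per_px = resolution_mm_per_px)
  structure(list(records = records, per_landmark = per_landmark,
                 per_subject = per_subject, overall = overall,
                 manifest = manifest),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s: %d records\n", x$manifest$scheme,
              x$overall$n))
  cat(sprintf("  overall RMSE %.2f px / %.2f cm; outliers (>5 px): %.1f%%; median distance %.2f px\n",
              x$overall$rmse_px, x$overall$rmse_cm, x$overall$outlier_pct,
              x$overall$median_d))
  invisible(x)
}

#' Serialize an evaluation report
#'
#' Writes `<prefix>.json` (full report incl. split manifest) and two CSV
#' matrices (`<prefix>_per_landmark.csv`, `<prefix>_records.csv`).
#'
#' @param report an `evaluation_report`.
#' @param prefix output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, prefix) {
  stopifnot(inherits(report, "evaluation_report"))
  paths <- c(json = paste0(prefix, ".json"),
             landmarks = paste0(prefix, "_per_landmark.csv"),
             records = paste0(prefix, "_records.csv"))
  jsonlite::write_json(list(overall = report$overall,
                            per_landmark = report$per_landmark,
                            per_subject = report$per_subject,
                            manifest = report$manifest),
                       paths["json"], auto_unbox = TRUE, digits = NA)
  write.csv(report$per_landmark, paths["landmarks"], row.names = FALSE)
  write.csv(report$records, paths["records"], row.names = FALSE)
  invisible(paths)
}
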