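test_that("Euclidean distances follow the coordinate metric", {
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean_distance(c(7, 2), c(7, 2)), 0)
  set.seed(2)
  a <- data.frame(x = runif(10, 0, 50), y = runif(10, 0, 50))
  b <- data.frame(x = runif(10, 0, 50), y = runif(10, 0, 50))
  expect_equal(euclidean_distance(a, b), euclidean_distance(b, a))
  expect_true(all(euclidean_distance(a, b) >= 0))
})

test_that("RMSE averages squared coordinate-pair errors", {
  expect_equal(rmse(c(0, 5)), sqrt(12.5))
  expect_equal(rmse(rep(0, 7)), 0)
  set.seed(3)
  rec <- data.frame(x_g = runif(30), y_g = runif(30),
                    x_p = runif(30), y_p = runif(30))
  d <- euclidean_distance(rec[, c("x_g", "y_g")] |>
                            setNames(c("x", "y")),
                          rec[, c("x_p", "y_p")] |> setNames(c("x", "y")))
  expect_equal(rmse(rec)^2, mean(d^2))                 # brute-force identity
  expect_equal(rmse(rec), rmse(d))                     # distance-vector form
  expect_equal(rmse(rec[sample(30), ]), rmse(rec))     # permutation invariant
  expect_gte(rmse(d), mean(d))                         # RMSE >= mean distance
  expect_error(rmse(numeric(0)), "empty")
})

test_that("the outlier rule uses a strict 5-pixel threshold", {
  expect_equal(outlier_rate(c(5.1, 4.9, 5.0)), 100 / 3)
  expect_equal(outlier_rate(rep(0, 4)), 0)
  expect_equal(outlier_rate(rep(5, 10)), 0)     # boundary: not outliers
  expect_equal(outlier_rate(rep(5 + 1e-9, 10)), 100)
  expect_equal(outlier_rate(c(1, 10), threshold_px = 2), 50)
  expect_error(outlier_rate(numeric(0)), "empty")
})

test_that("10-fold CV reproduces the reference fold arithmetic", {
  plan <- make_cv_splits(seq_len(6138), k = 10, seed = 1)
  sizes <- vapply(plan$folds, function(f) length(f$test), integer(1))
  expect_equal(min(sizes), 613L)               # smallest test fold
  expect_equal(sum(sizes), 6138L)
  expect_true(all(abs(sizes - 613.8) <= 1))    # near-equal, differ by <= 1
  smallest <- which.min(sizes)
  expect_equal(length(plan$folds[[smallest]]$train), 5525L)
  # folds partition the corpus
  all_test <- sort(unlist(lapply(plan$folds, function(f) f$test)))
  expect_identical(all_test, seq_len(6138))
  expect_error(make_cv_splits(seq_len(5), k = 10), "smaller")
  expect_error(make_cv_splits(seq_len(50), k = 1), "at least 2")
})

test_that("LoSo folds test originals of one subject against the rest's augmented pool", {
  corpus <- meta_corpus(9, 62, tags = aug_tags())   # 6138 provenance items
  plan <- make_loso_splits(corpus)
  expect_length(plan$folds, 9L)
  meta <- flatnet:::corpus_meta(corpus)
  for (s in seq_along(plan$folds)) {
    fold <- plan$folds[[s]]
    expect_length(fold$test, 62L)
    expect_length(fold$train, 8L * 62L * 11L)  # 5456
    expect_true(all(meta$tag[fold$test] == "orig"))
    test_subject <- unique(meta$subject[fold$test])
    expect_length(test_subject, 1L)
    expect_false(test_subject %in% meta$subject[fold$train])
  }
  # each subject is tested exactly once
  tested <- vapply(plan$folds, function(f)
    unique(meta$subject[f$test]), character(1))
  expect_setequal(tested, unique(meta$subject))
  expect_error(make_loso_splits(meta_corpus(1, 5)), "at least 2 subjects")
})

test_that("the paired t-test matches the closed-form oracle", {
  set.seed(4)
  a <- rnorm(40, 3, 1); b <- a + rnorm(40, 0.5, 0.7)
  res <- paired_ttest(a, b)
  d <- a - b
  t_oracle <- mean(d) / (sd(d) / sqrt(length(d)))
  p_oracle <- 2 * stats::pt(-abs(t_oracle), length(d) - 1)
  expect_equal(res$t, t_oracle, tolerance = 1e-10)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-10)
  expect_equal(res$df, length(d) - 1)

  # a systematic shift with tiny jitter drives p toward 0
  x <- rnorm(500, 5, 1); y <- x + 1 + rnorm(500, 0, 0.01)
  expect_lt(paired_ttest(x, y)$p_value, 1e-100)

  expect_error(paired_ttest(a, a), "degenerate")
  expect_error(paired_ttest(a, b[1:10]), "equal-length")
  expect_error(paired_ttest(1, 2), "at least 2")
})

test_that("the paired t-test holds its nominal type-I error under the null", {
  set.seed(6)
  p <- replicate(200, {
    base <- rnorm(1000, 4, 1)
    paired_ttest(base + rnorm(1000, 0, 0.5),
                 base + rnorm(1000, 0, 0.5))$p_value
  })
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.045)
  expect_gt(mean(p > 0.5), 0.3)   # roughly uniform under the null
})

test_that("reports aggregate records exactly and convert px to cm", {
  corpus <- meta_corpus(3, 4)
  sch <- landmark_schema()
  set.seed(8)
  for (i in seq_along(corpus)) {
    corpus[[i]]$image <- matrix(0, 64, 64)
    corpus[[i]]$landmarks <- data.frame(abbrev = sch$abbrev,
                                        x = runif(21, 5, 58),
                                        y = runif(21, 5, 58), outside = FALSE)
  }
  plan <- make_loso_splits(corpus)
  meta <- flatnet:::corpus_meta(corpus)

  perfect <- setNames(lapply(corpus, function(it)
    it$landmarks[, c("abbrev", "x", "y")]), meta$id)
  rep0 <- build_report(corpus, perfect, plan, resolution_mm_per_px = 1)
  expect_equal(rep0$overall$rmse_px, 0)
  expect_true(all(rep0$per_landmark$rmse_px == 0))
  expect_true(all(rep0$per_landmark$outlier_pct == 0))

  shifted <- lapply(perfect, function(p) { p$x <- p$x + 3; p$y <- p$y + 4; p })
  rep1 <- build_report(corpus, shifted, plan, resolution_mm_per_px = 1)
  expect_equal(rep1$overall$rmse_px, 5, tolerance = 1e-12)
  expect_equal(rep1$overall$rmse_cm, 0.5, tolerance = 1e-12)  # 1 mm/px
  expect_equal(rep1$overall$outlier_pct, 0)   # exactly 5 px: strict rule

  # independent re-aggregation from the raw records
  recs <- rep1$records
  expect_equal(rep1$overall$rmse_px,
               sqrt(mean((recs$x_g - recs$x_p)^2 + (recs$y_g - recs$y_p)^2)))
  expect_equal(rep1$overall$rmse_px^2 * nrow(recs),
               sum((recs$x_g - recs$x_p)^2 + (recs$y_g - recs$y_p)^2))
  one <- rep1$per_landmark[rep1$per_landmark$landmark == "TT", ]
  expect_equal(one$rmse_px, rmse(recs[recs$landmark == "TT", ]))

  expect_error(build_report(corpus, perfect[-1], plan), "missing prediction")

  paths <- write_report(rep1, file.path(withr::local_tempdir(), "rep"))
  expect_true(all(file.exists(paths)))
  js <- jsonlite::read_json(paths[["json"]])
  expect_equal(js$overall$rmse_px, 5, tolerance = 1e-9)
})
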