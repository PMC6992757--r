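test_that("the ten standard transforms carry the canonical parameters", {
  tr <- standard_transforms()
  expect_length(tr, 10L)
  expect_equal(anyDuplicated(vapply(tr, function(t) t$name, character(1))), 0L)

  expect_equal(tr[[1]]$noise_variance, 12.75)
  # photometric-only: identity geometry
  expect_equal(tr[[1]]$rotation_deg, 0)
  expect_equal(tr[[1]]$translation_px, c(0, 0))
  expect_equal(tr[[1]]$zoom_scale, 1)

  expect_equal(tr[[2]]$blur_sigma, 5)
  expect_equal(tr[[3]]$rotation_deg, 10)
  expect_equal(tr[[4]]$rotation_deg, -5)
  expect_equal(tr[[5]]$translation_px, c(30, 10))
  expect_equal(tr[[6]]$translation_px, c(40, -10))
  expect_equal(tr[[7]]$rotation_deg, -5)
  expect_equal(tr[[7]]$translation_px, c(30, 10))
  # zoom-out spec has no other active component
  expect_equal(tr[[8]]$zoom_scale, 0.8)
  expect_equal(tr[[8]]$rotation_deg, 0)
  expect_equal(tr[[8]]$translation_px, c(0, 0))
  expect_equal(tr[[8]]$noise_variance, 0)
  expect_equal(tr[[8]]$blur_sigma, 0)
  expect_equal(tr[[9]]$translation_px, c(30, 10))
  expect_equal(tr[[9]]$zoom_scale, 1.2)
  expect_equal(tr[[10]]$translation_px, c(40, 20))
  expect_equal(tr[[10]]$zoom_scale, 0.9)
  expect_equal(tr[[10]]$blur_sigma, 3)

  expect_error(transform_spec("bad", zoom_scale = 0), "positive")
})

test_that("landmarks map exactly through the affine components", {
  corpus <- tiny_phantom(1, 1, size = 48)
  it <- corpus[[1]]
  it$image <- matrix(128, 256, 256)
  lms <- it$landmarks
  lms$x <- seq(60, 160, length.out = 21); lms$y <- seq(50, 150, length.out = 21)
  it <- annotated_image(it$image, lms[, c("abbrev", "x", "y")], "S1", "C1")

  tr <- standard_transforms()
  moved <- apply_transform(it, tr[[5]], 1)    # translation (+30, +10)
  expect_equal(moved$landmarks$x, lms$x + 30)
  expect_equal(moved$landmarks$y, lms$y + 10)
  expect_identical(moved$augmentation_tag, tr[[5]]$name)
  expect_identical(moved$source_id, it$source_id)

  # the image center is a fixed point of pure rotation
  ctr <- c(127.5, 127.5)
  aff <- transform_affine(tr[[3]], c(256, 256))
  p <- apply_affine(data.frame(x = ctr[1], y = ctr[2]), aff)
  expect_equal(c(p$x, p$y), ctr, tolerance = 1e-12)

  # positive rotation is counter-clockwise in the (x right, y down) frame:
  # a point to the right of center moves up (smaller y)
  q <- apply_affine(data.frame(x = ctr[1] + 50, y = ctr[2]), aff)
  expect_lt(q$y, ctr[2])

  # zoom out pulls points toward the center
  az <- transform_affine(tr[[8]], c(256, 256))
  z <- apply_affine(data.frame(x = ctr[1] + 100, y = ctr[2]), az)
  expect_equal(z$x, ctr[1] + 80, tolerance = 1e-12)
})

test_that("rotation-translation composition equals one exact affine", {
  rot <- transform_spec("r", rotation_deg = -5)
  tra <- transform_spec("t", translation_px = c(30, 10))
  both <- transform_spec("rt", rotation_deg = -5, translation_px = c(30, 10))
  size <- c(256, 256)
  pts <- data.frame(x = c(0, 50, 200.5, 17.3), y = c(0, 100, 30.2, 255))
  step1 <- apply_affine(pts, transform_affine(rot, size))
  step2 <- apply_affine(step1, transform_affine(tra, size))
  once <- apply_affine(pts, transform_affine(both, size))
  expect_equal(once, step2, tolerance = 1e-12)
})

test_that("seeded noise leaves landmarks bit-identical and has the stated scale", {
  img <- matrix(128, 256, 256)   # mid-gray: no clipping of the noise
  sch <- landmark_schema()
  lms <- data.frame(abbrev = sch$abbrev, x = rep(50, 21), y = rep(60, 21))
  it <- annotated_image(img, lms, "S1", "C1")
  noisy <- apply_transform(it, standard_transforms()[[1]], rng_seed = 99)
  expect_identical(noisy$landmarks$x, it$landmarks$x)
  expect_identical(noisy$landmarks$y, it$landmarks$y)
  delta <- noisy$image - img
  expect_equal(sd(delta), sqrt(12.75), tolerance = 0.02)     # ~3.571
  expect_equal(mean(delta), 0, tolerance = 0.05)
  # same seed reproduces the realization; different seed does not
  again <- apply_transform(it, standard_transforms()[[1]], rng_seed = 99)
  expect_identical(again$image, noisy$image)
  other <- apply_transform(it, standard_transforms()[[1]], rng_seed = 100)
  expect_false(identical(other$image, noisy$image))
})

test_that("image content and landmarks stay consistent under geometric warps", {
  # a bright spot at a landmark must land (argmax) within 1 px of the
  # analytically transformed landmark for every geometric transform
  img <- matrix(0, 64, 64)
  spot <- c(x = 12, y = 20)
  img[spot["y"] + 1, spot["x"] + 1] <- 255
  sch <- landmark_schema()
  lms <- data.frame(abbrev = sch$abbrev, x = rep(spot["x"], 21),
                    y = rep(spot["y"], 21))
  it <- annotated_image(img, lms, "S1", "C1")
  for (tr in standard_transforms()[3:9]) {
    out <- apply_transform(it, tr, 1)
    mapped <- c(out$landmarks$x[1], out$landmarks$y[1])
    if (any(mapped < 1) || any(mapped > 62)) next  # spot left the frame
    got <- brute_argmax(out$image)
    expect_lt(sqrt(sum((got - mapped)^2)), 1 + 1e-9)
  }
})

test_that("blur preserves total geometry and softens edges", {
  corpus <- tiny_phantom(1, 1, size = 64)
  it <- corpus[[1]]
  blurred <- apply_transform(it, standard_transforms()[[2]], 1)
  expect_identical(blurred$landmarks$x, it$landmarks$x)
  expect_lt(sd(blurred$image), sd(it$image))   # contrast reduced
  expect_true(all(blurred$image >= 0 & blurred$image <= 255))
})

test_that("corpus expansion is x11, provenance-complete and deterministic", {
  corpus <- tiny_phantom(2, 3, size = 48)
  aug <- augment_corpus(corpus, seed = 5)
  expect_length(aug, 66L)
  expect_equal(attr(aug, "expansion_factor"), 11L)

  tags <- vapply(aug, function(it) it$augmentation_tag, character(1))
  src <- vapply(aug, function(it) it$source_id, character(1))
  expect_setequal(unique(tags), aug_tags())
  # per-original group size is 11 with all tags distinct
  for (s in unique(src)) {
    expect_length(tags[src == s], 11L)
    expect_equal(anyDuplicated(tags[src == s]), 0L)
  }
  # every source maps to exactly one input original
  expect_setequal(unique(src), vapply(corpus, function(it) it$source_id,
                                      character(1)))

  aug2 <- augment_corpus(corpus, seed = 5)
  expect_identical(aug, aug2)
  aug3 <- augment_corpus(corpus, seed = 6)
  expect_false(identical(aug, aug3))

  expect_error(augment_corpus(aug), "originals only")
  expect_error(augment_corpus(list()), "non-empty")

  # single original expands to 11 distinct items
  one <- augment_corpus(corpus[1], seed = 1)
  expect_length(one, 11L)
  expect_equal(anyDuplicated(vapply(one, flatnet:::item_id, character(1))), 0L)
})
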