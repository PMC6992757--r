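test_that("encoded channels are peak-1 Gaussian hats", {
  lms <- data.frame(abbrev = "TT", x = 100, y = 120)
  hm <- encode_heatmaps(lms, c(256, 256), codec_config(sigma_px = 10))
  expect_equal(dim(hm$values), c(256L, 256L, 1L))
  # peak exactly 1 at (row 120, col 100), 0-based
  expect_equal(hm$values[121, 101, 1], 1.0, tolerance = 1e-12)
  expect_equal(max(hm$values), 1.0, tolerance = 1e-12)
  # value at Euclidean distance exactly sigma
  expect_equal(hm$values[121, 111, 1], exp(-0.5), tolerance = 1e-12)
  expect_equal(hm$values[131, 101, 1], exp(-0.5), tolerance = 1e-12)
  # untruncated: strictly positive everywhere
  expect_true(all(hm$values > 0))
})

test_that("multi-landmark stacks have one unimodal channel per landmark", {
  lms <- data.frame(abbrev = c("TT", "VT", "EG"),
                    x = c(20, 40, 10), y = c(30, 5, 50))
  hm <- encode_heatmaps(lms, c(64, 64), codec_config(sigma_px = 5))
  expect_equal(dim(hm$values)[3], 3L)
  expect_identical(hm$channels, c("TT", "VT", "EG"))
  for (l in 1:3) {
    ch <- hm$values[, , l]
    expect_equal(sum(ch == max(ch)), 1L)  # single global maximum
    expect_equal(brute_argmax(ch), c(x = lms$x[l], y = lms$y[l]))
  }
})

test_that("channel values decay monotonically with distance from the landmark", {
  hm <- encode_heatmaps(data.frame(abbrev = "N", x = 30, y = 30), c(64, 64),
                        codec_config(sigma_px = 7))
  ch <- hm$values[, , 1]
  ray_right <- ch[31, 31:64]    # along +x
  ray_down <- ch[31:64, 31]     # along +y
  diag_ray <- ch[cbind(31:60, 31:60)]
  expect_true(all(diff(ray_right) < 0))
  expect_true(all(diff(ray_down) < 0))
  expect_true(all(diff(diag_ray) < 0))
})

test_that("decode recovers the argmax with deterministic tie-breaking", {
  ch <- matrix(0, 100, 100)
  ch[51, 61] <- 1   # (x, y) = (60, 50)
  st <- structure(list(values = array(ch, c(100, 100, 1)), channels = "TT"),
                  class = "heatmap_stack")
  dec <- decode_heatmaps(st)
  expect_equal(c(dec$x, dec$y), c(60, 50))
  expect_false(dec$degenerate)

  ch2 <- matrix(0, 256, 256)
  ch2[11, 11] <- 1; ch2[201, 201] <- 1  # ties at (10,10) and (200,200)
  st2 <- structure(list(values = array(ch2, c(256, 256, 1)), channels = "TT"),
                   class = "heatmap_stack")
  dec2 <- decode_heatmaps(st2)
  expect_equal(c(dec2$x, dec2$y), c(10, 10))  # smallest row, then column

  flat <- structure(list(values = array(0.5, c(8, 8, 1)), channels = "TT"),
                    class = "heatmap_stack")
  dec3 <- decode_heatmaps(flat)
  expect_true(dec3$degenerate)
  expect_equal(c(dec3$x, dec3$y), c(0, 0))
})

test_that("decode-encode is the identity on integer in-frame coordinates", {
  grid <- expand.grid(x = c(0, 3, 17, 31, 63), y = c(0, 9, 22, 63))
  for (sigma in c(1, 5, 10)) {
    lms <- data.frame(abbrev = sprintf("L%d", seq_len(nrow(grid))),
                      x = grid$x, y = grid$y)
    hm <- encode_heatmaps(lms, c(64, 64), codec_config(sigma_px = sigma))
    dec <- decode_heatmaps(hm)
    expect_equal(dec$x, grid$x)
    expect_equal(dec$y, grid$y)
  }
})

test_that("decode matches a brute-force scan on random stacks", {
  set.seed(7)
  for (rep in 1:10) {
    vals <- array(runif(16 * 16 * 3), c(16, 16, 3))
    st <- structure(list(values = vals, channels = c("A", "B", "C")),
                    class = "heatmap_stack")
    dec <- decode_heatmaps(st)
    for (l in 1:3) {
      ref <- brute_argmax(vals[, , l])
      expect_equal(c(dec$x[l], dec$y[l]), unname(ref))
    }
  }
})

test_that("sub-pixel landmarks encode at the true center and decode to the nearest pixel", {
  lms <- data.frame(abbrev = "TT", x = 20.4, y = 30.7)
  hm <- encode_heatmaps(lms, c(64, 64), codec_config(sigma_px = 5))
  expect_lt(max(hm$values), 1)   # no pixel sits exactly on the center
  dec <- decode_heatmaps(hm)
  expect_equal(c(dec$x, dec$y), c(20, 31))  # nearest pixel
})

test_that("out-of-frame landmarks are rejected unless the caller opts out", {
  lms <- data.frame(abbrev = c("TT", "VT"), x = c(10, -5), y = c(10, 10))
  expect_error(encode_heatmaps(lms, c(32, 32)), "VT")
  expect_warning(hm <- encode_heatmaps(lms, c(32, 32), on_outside = "warn_skip"),
                 "VT")
  expect_identical(hm$channels, "TT")
  hm2 <- encode_heatmaps(lms, c(32, 32), on_outside = "allow")
  expect_equal(dim(hm2$values)[3], 2L)
  expect_lt(max(hm2$values[, , 2]), 1)  # center out of frame
})
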