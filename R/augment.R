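# Keypoint-consistent data augmentation.
#
# Each transform is a recipe of geometric components (rotation, translation,
# zoom — composed in that fixed order, about the image center
# ((cols-1)/2, (rows-1)/2)) and photometric components (Gaussian blur, then
# additive Gaussian intensity noise). The image is resampled by bilinear
# interpolation with zero padding; landmark coordinates are mapped through
# the exact same affine map analytically, so they carry no resampling error.
# Positive rotation is counter-clockwise in the (x right, y down) frame;
# translation (+a, +b) means (dx = +a columns, dy = +b rows).

#' Define an augmentation transform
#'
#' @param name tag stored in `augmentation_tag` of the transformed items.
#' @param noise_variance variance of additive zero-mean Gaussian intensity
#'   noise, on the 0-255 intensity scale (squared units).
#' @param blur_sigma standard deviation (px) of a Gaussian blur; 0 = none.
#' @param rotation_deg rotation angle in degrees (counter-clockwise,
#'   x right / y down frame), about the image center.
#' @param translation_px numeric `c(dx, dy)` = (columns, rows) shift.
#' @param zoom_scale isotropic scale factor about the image center
#'   (`< 1` zooms out, `> 1` zooms in).
#' @return A list of class `transform_spec`.
#' @export
transform_spec <- function(name, noise_variance = 0, blur_sigma = 0,
                           rotation_deg = 0, translation_px = c(0, 0),
                           zoom_scale = 1) {
  stopifnot(is.character(name), length(name) == 1L,
            noise_variance >= 0, blur_sigma >= 0,
            length(translation_px) == 2L)
  if (zoom_scale <= 0) stop("zoom_scale must be positive")
  structure(list(name = name, noise_variance = noise_variance,
                 blur_sigma = blur_sigma, rotation_deg = rotation_deg,
                 translation_px = as.numeric(translation_px),
                 zoom_scale = zoom_scale),
            class = "transform_spec")
}

#' The ten standard augmentation transforms
#'
#' Returns the fixed list of ten transforms used for the x11 corpus
#' expansion, in canonical order:
#' (1) Gaussian intensity noise, mean 0, variance 12.75;
#' (2) Gaussian blur, sigma 5 px;
#' (3) rotation +10 deg; (4) rotation -5 deg;
#' (5) translation (+30, +10) px; (6) translation (+40, -10) px;
#' (7) rotation -5 deg then translation (+30, +10) px;
#' (8) zoom out, scale 0.8;
#' (9) translation (+30, +10) px then zoom in, scale 1.2;
#' (10) translation (+40, +20) px then zoom out, scale 0.9, then Gaussian
#' blur, sigma 3 px.
#'
#' The blur parameters are interpreted as standard deviations in pixels,
#' and the noise variance on the 0-255 intensity scale (sd about 3.57).
#'
#' @return List of 10 [transform_spec()] objects.
#' @export
standard_transforms <- function() {
  list(
    transform_spec("noise_v12.75", noise_variance = 12.75),
    transform_spec("blur_s5", blur_sigma = 5),
    transform_spec("rot_p10", rotation_deg = 10),
    transform_spec("rot_m5", rotation_deg = -5),
    transform_spec("trans_p30_p10", translation_px = c(30, 10)),
    transform_spec("trans_p40_m10", translation_px = c(40, -10)),
    transform_spec("rot_m5_trans_p30_p10", rotation_deg = -5,
                   translation_px = c(30, 10)),
    transform_spec("zoom_0.8", zoom_scale = 0.8),
    transform_spec("trans_p30_p10_zoom_1.2", translation_px = c(30, 10),
                   zoom_scale = 1.2),
    transform_spec("trans_p40_p20_zoom_0.9_blur_s3",
                   translation_px = c(40, 20), zoom_scale = 0.9,
                   blur_sigma = 3)
  )
}

#' Forward affine map of a transform's geometric components
#'
#' Composes rotation, then translation, then zoom (the fixed application
#' order) into a single affine map `p' = M p + v` on 0-based (x, y)
#' coordinates, about the image center.
#'
#' @param spec a [transform_spec()].
#' @param image_size `c(rows, cols)`.
#' @return list with `M` (2x2) and `v` (length 2).
#' @export
transform_affine <- function(spec, image_size) {
  rows <- image_size[1]; cols <- image_size[2]
  cx <- (cols - 1) / 2; cy <- (rows - 1) / 2
  th <- spec$rotation_deg * pi / 180
  # CCW in (x right, y down): (1,0) -> (cos, -sin)
  Rm <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  s <- spec$zoom_scale
  ctr <- c(cx, cy)
  M <- s * Rm
  v <- s * (ctr - Rm %*% ctr + spec$translation_px) + (1 - s) * ctr
  list(M = M, v = as.numeric(v))
}

#' Apply an affine map to (x, y) points
#'
#' @param points data.frame or matrix with columns `x`, `y`.
#' @param affine list with `M` and `v` as from [transform_affine()].
#' @return Object of the same shape with mapped coordinates.
#' @export
apply_affine <- function(points, affine) {
  xy <- cbind(points[, "x"], points[, "y"]) %*% t(affine$M)
  points[, "x"] <- xy[, 1] + affine$v[1]
  points[, "y"] <- xy[, 2] + affine$v[2]
  points
}

# internal: bilinear resampling of `img` under the *forward* affine map
# (output pixel p_out samples the input at A^{-1}(p_out)); zero padding.
warp_bilinear <- function(img, affine) {
  rows <- nrow(img); cols <- ncol(img)
  Minv <- solve(affine$M)
  xo <- rep(0:(cols - 1), each = rows)
  yo <- rep(0:(rows - 1), times = cols)
  xs <- xo - affine$v[1]; ys <- yo - affine$v[2]
  xi <- Minv[1, 1] * xs + Minv[1, 2] * ys
  yi <- Minv[2, 1] * xs + Minv[2, 2] * ys
  x0 <- floor(xi); y0 <- floor(yi)
  fx <- xi - x0; fy <- yi - y0
  samp <- function(yy, xx) {
    ok <- xx >= 0 & xx < cols & yy >= 0 & yy < rows
    idx <- pmin(pmax(yy, 0), rows - 1) + pmin(pmax(xx, 0), cols - 1) * rows + 1
    as.numeric(img)[idx] * ok
  }
  out <- (1 - fx) * (1 - fy) * samp(y0, x0) +
         fx * (1 - fy) * samp(y0, x0 + 1) +
         (1 - fx) * fy * samp(y0 + 1, x0) +
         fx * fy * samp(y0 + 1, x0 + 1)
  matrix(out, rows, cols)
}

# internal: separable Gaussian blur with zero padding, kernel cut at 4 sd
gaussian_blur <- function(img, sigma) {
  band <- function(n) {
    rad <- ceiling(4 * sigma)
    k <- exp(-(0:rad)^2 / (2 * sigma^2))
    k <- k / (k[1] + 2 * sum(k[-1]))
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    B <- matrix(0, n, n)
    keep <- d <= rad
    B[keep] <- k[d[keep] + 1]
    B
  }
  Br <- band(nrow(img))
  Bc <- if (ncol(img) == nrow(img)) Br else band(ncol(img))
  Br %*% img %*% Bc
}

# internal: run `expr` under a temporary RNG seed, restoring global state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Apply one augmentation transform to an annotated image
#'
#' Geometric components are applied to the image by bilinear resampling
#' with zero padding and to the landmarks analytically through the same
#' affine map; photometric components (blur, then seeded noise) leave the
#' landmarks untouched. Intensities are clipped to \[0, 255\]. Landmarks
#' pushed outside the frame are kept and flagged, never clamped.
#'
#' @param item an [annotated_image()].
#' @param spec a [transform_spec()].
#' @param rng_seed integer seed fixing the noise realization.
#' @return A new [annotated_image()] with `augmentation_tag = spec$name`.
#' @export
apply_transform <- function(item, spec, rng_seed = 1L) {
  stopifnot(inherits(item, "annotated_image"), inherits(spec, "transform_spec"))
  img <- item$image
  lms <- item$landmarks
  geometric <- spec$rotation_deg != 0 || any(spec$translation_px != 0) ||
    spec$zoom_scale != 1
  if (geometric) {
    aff <- transform_affine(spec, dim(img))
    img <- warp_bilinear(img, aff)
    lms <- apply_affine(lms, aff)
  }
  if (spec$blur_sigma > 0) img <- gaussian_blur(img, spec$blur_sigma)
  if (spec$noise_variance > 0)
    img <- img + with_seed(rng_seed,
      matrix(rnorm(length(img), 0, sqrt(spec$noise_variance)), nrow(img)))
  img <- pmin(pmax(img, 0), 255)
  annotated_image(img, lms[, c("abbrev", "x", "y")],
                  subject_id = item$subject_id, class_id = item$class_id,
                  augmentation_tag = spec$name, source_id = item$source_id)
}

#' Expand a corpus of originals with the ten standard transforms
#'
#' Every original contributes itself (tag `"orig"`) plus one copy per
#' standard transform: an 11-fold expansion (558 originals become 6138
#' items in the reference corpus shape). Deterministic for a fixed seed.
#'
#' @param corpus list of [annotated_image()] objects, all with tag
#'   `"orig"`.
#' @param seed integer seed for the noise realizations.
#' @param transforms list of [transform_spec()]; defaults to
#'   [standard_transforms()].
#' @return List of annotated images of length `(1 + length(transforms)) *
#'   length(corpus)`, grouped by original, with attribute
#'   `expansion_factor`.
#' @export
augment_corpus <- function(corpus, seed = 1L, transforms = standard_transforms()) {
  if (!is.list(corpus) || length(corpus) == 0L)
    stop("corpus must be a non-empty list of originals")
  tags <- vapply(corpus, function(it) it$augmentation_tag, character(1))
  if (any(tags != "orig"))
    stop("augment_corpus expects originals only (augmentation_tag \"orig\")")
  out <- vector("list", length(corpus) * (1L + length(transforms)))
  pos <- 1L
  for (i in seq_along(corpus)) {
    out[[pos]] <- corpus[[i]]; pos <- pos + 1L
    for (j in seq_along(transforms)) {
      item_seed <- as.integer((seed + 100 * i + j) %% 2147483647)
      out[[pos]] <- apply_transform(corpus[[i]], transforms[[j]], item_seed)
      pos <- pos + 1L
    }
  }
  attr(out, "expansion_factor") <- 1L + length(transforms)
  out
}
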