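# Heat-map codec: landmark coordinates <-> Gaussian heat-map channels.

#' Heat-map codec configuration
#'
#' Target heat-maps are untruncated Gaussian hats
#' \deqn{G(x, y) = \exp(-((x - x_l)^2 + (y - y_l)^2) / (2\sigma^2))}
#' with peak value 1 at each landmark location, evaluated at every pixel of
#' the frame (no truncation radius, so every channel value is strictly
#' positive).
#'
#' @param sigma_px Gaussian width in pixels (default 10).
#' @param peak_value peak intensity of each channel (fixed at 1 in the
#'   reference setting).
#' @return A list of class `codec_config`.
#' @export
codec_config <- function(sigma_px = 10, peak_value = 1) {
  stopifnot(is.numeric(sigma_px), length(sigma_px) == 1L, sigma_px > 0,
            is.numeric(peak_value), length(peak_value) == 1L)
  structure(list(sigma_px = sigma_px, peak_value = peak_value),
            class = "codec_config")
}

#' Encode landmarks as Gaussian heat-map channels
#'
#' One channel per landmark; channel order follows the row order of
#' `landmarks` (a subset of the schema is allowed, e.g. one partition
#' group). Sub-pixel landmark locations are honored: the Gaussian is
#' centered at the real-valued coordinate, so the discrete maximum is then
#' slightly below `peak_value`.
#'
#' @param landmarks data.frame with columns `abbrev`, `x`, `y` (0-based).
#' @param image_size integer vector `c(rows, cols)`.
#' @param config a [codec_config()].
#' @param on_outside what to do with landmarks outside the frame:
#'   `"error"` (default), `"warn_skip"` (drop the channel with a warning),
#'   or `"allow"` (encode the Gaussian centered at the true out-of-frame
#'   location; used for training targets of augmented items whose ground
#'   truth left the frame).
#' @return A list of class `heatmap_stack` with elements `values`
#'   (rows x cols x L array) and `channels` (character vector, length L).
#' @export
encode_heatmaps <- function(landmarks, image_size, config = codec_config(),
                            on_outside = c("error", "warn_skip", "allow")) {
  on_outside <- match.arg(on_outside)
  stopifnot(is.data.frame(landmarks), all(c("abbrev", "x", "y") %in% names(landmarks)),
            length(image_size) == 2L, all(image_size >= 1))
  rows <- as.integer(image_size[1]); cols <- as.integer(image_size[2])
  out <- outside_frame(landmarks, rows, cols)
  if (any(out) && on_outside != "allow") {
    who <- paste(landmarks$abbrev[out], collapse = ", ")
    if (on_outside == "error")
      stop("landmark(s) outside the frame: ", who,
           " (use on_outside = \"warn_skip\" or \"allow\")")
    warning("skipping out-of-frame landmark(s): ", who)
    landmarks <- landmarks[!out, , drop = FALSE]
  }
  L <- nrow(landmarks)
  if (L == 0L) stop("no landmarks to encode")
  s2 <- 2 * config$sigma_px^2
  yy <- seq_len(rows) - 1
  xx <- seq_len(cols) - 1
  vals <- vapply(seq_len(L), function(l) {
    config$peak_value *
      exp(-outer((yy - landmarks$y[l])^2, (xx - landmarks$x[l])^2, "+") / s2)
  }, matrix(0, rows, cols))
  structure(list(values = vals, channels = as.character(landmarks$abbrev)),
            class = "heatmap_stack")
}

#' Decode heat-map channels to coordinates by per-channel argmax
#'
#' The predicted location of landmark l is the pixel holding the global
#' maximum of channel l. Ties are broken deterministically: smallest row,
#' then smallest column. An all-constant channel yields the tie-break
#' winner (pixel (0, 0)) and is flagged as degenerate.
#'
#' @param stack a `heatmap_stack` (target or predicted).
#' @return data.frame with columns `abbrev`, `x`, `y` (0-based pixel
#'   coordinates) and `degenerate`.
#' @export
decode_heatmaps <- function(stack) {
  stopifnot(inherits(stack, "heatmap_stack") || (is.list(stack) &&
            !is.null(stack$values) && !is.null(stack$channels)))
  vals <- stack$values
  stopifnot(length(dim(vals)) == 3L, dim(vals)[3] == length(stack$channels))
  L <- dim(vals)[3]
  res <- lapply(seq_len(L), function(l) {
    ch <- vals[, , l]
    m <- max(ch)
    idx <- which(ch == m, arr.ind = TRUE)
    best <- idx[order(idx[, 1], idx[, 2])[1], , drop = TRUE]
    c(x = unname(best["col"]) - 1, y = unname(best["row"]) - 1,
      degenerate = as.numeric(m == min(ch)))
  })
  res <- do.call(rbind, res)
  data.frame(abbrev = stack$channels, x = res[, "x"], y = res[, "y"],
             degenerate = res[, "degenerate"] > 0, stringsAsFactors = FALSE)
}

#' @export
print.heatmap_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<heatmap_stack> %dx%d px, %d channel(s): %s\n", d[1], d[2], d[3],
              paste(x$channels, collapse = ", ")))
  invisible(x)
}
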