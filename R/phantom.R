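# Seeded synthetic phantom corpus.
#
# The phantom is a schematic midsagittal vocal tract (head facing left,
# x right / y down): smooth bright curves on a dark background stand in for
# the face profile, hard palate, velum, tongue, epiglottis, lips, pharynx
# wall and jaw/neck line. The 21 landmarks are placed analytically on the
# curves' control points (UT and LT are deliberately *off* the curves,
# placed as fixed offsets from the palate/jaw region, mimicking their
# not-directly-visible status on real images). Subjects differ by a drawn
# morphology (global scale/offset, palate curvature, jaw length);
# articulation classes differ by drawn articulation parameters (tongue
# shape, jaw opening, lips, velum, larynx). The phantom is schematic, not
# anatomically faithful: its job is to provide images with the statistical
# structure of the real corpus (subjects x classes grid, inter-subject
# morphology and intra-subject articulation variability, additive noise).

#' Phantom corpus configuration
#'
#' @param n_subjects,n_classes corpus grid (the reference corpus shape is
#'   9 subjects x 62 articulation classes).
#' @param image_size `c(rows, cols)` in pixels, default `c(256, 256)`.
#' @param rng_seed integer; the corpus is a deterministic function of the
#'   full configuration including this seed.
#' @param noise_sd additive Gaussian intensity noise sd (8-bit units).
#' @param morphology_spread scale (>= 0) of inter-subject variation; 1 is
#'   the nominal realistic level, 0 makes all subjects identical.
#' @param articulation_spread scale (>= 0) of intra-subject variation
#'   across classes; 0 makes all classes identical.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(n_subjects = 9, n_classes = 62,
                           image_size = c(256, 256), rng_seed = 1L,
                           noise_sd = 4, morphology_spread = 1,
                           articulation_spread = 1) {
  stopifnot(n_subjects >= 1, n_classes >= 1, length(image_size) == 2L,
            all(image_size >= 32), noise_sd >= 0,
            morphology_spread >= 0, articulation_spread >= 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_classes = as.integer(n_classes),
                 image_size = as.integer(image_size),
                 rng_seed = as.integer(rng_seed), noise_sd = noise_sd,
                 morphology_spread = morphology_spread,
                 articulation_spread = articulation_spread),
            class = "phantom_config")
}

# internal: one subject's morphology draw (uniform, bounded so that all
# landmarks stay in-frame at the nominal spread)
draw_morphology <- function(spread) {
  list(scale = 1 + spread * runif(1, -0.06, 0.06),
       offset_x = spread * runif(1, -0.03, 0.03),
       offset_y = spread * runif(1, -0.03, 0.03),
       palate_curv = 0.035 * (1 + spread * runif(1, -0.4, 0.4)),
       jaw_len = 1 + spread * runif(1, -0.06, 0.06))
}

# internal: one (subject, class) articulation draw
draw_articulation <- function(spread) {
  list(tongue_height = 0.04 + spread * runif(1, -0.035, 0.045),
       tongue_advance = spread * runif(1, -1, 1),
       tongue_tip_elev = spread * runif(1, -0.04, 0.05),
       jaw_open = spread * runif(1, 0, 0.05),
       lip_protrusion = spread * runif(1, -0.005, 0.02),
       lip_aperture = spread * runif(1, 0, 0.025),
       velum_angle = spread * runif(1, -1, 1),
       larynx_height = spread * runif(1, -0.025, 0.025),
       epiglottis_tilt_x = spread * runif(1, -0.02, 0.02),
       epiglottis_tilt_y = spread * runif(1, -0.02, 0.02))
}

#' Neutral phantom parameters
#'
#' Midpoint morphology and articulation parameter sets (the zero-spread
#' phantom), useful as a starting point for controlled geometry studies.
#' @return A list with elements `morphology` and `articulation`.
#' @export
phantom_neutral_params <- function() {
  list(morphology = list(scale = 1, offset_x = 0, offset_y = 0,
                         palate_curv = 0.035, jaw_len = 1),
       articulation = list(tongue_height = 0.04, tongue_advance = 0,
                           tongue_tip_elev = 0, jaw_open = 0,
                           lip_protrusion = 0, lip_aperture = 0,
                           velum_angle = 0, larynx_height = 0,
                           epiglottis_tilt_x = 0, epiglottis_tilt_y = 0))
}

#' Analytic phantom geometry
#'
#' Builds the landmark positions and rendered-curve control polylines for
#' one phantom image from explicit morphology and articulation parameters.
#' Increasing `articulation$tongue_tip_elev` strictly raises the tongue
#' tip (decreases the TT y coordinate), and similarly each articulation
#' parameter moves its structure monotonically.
#'
#' @param morphology,articulation parameter lists as in
#'   [phantom_neutral_params()].
#' @param image_size `c(rows, cols)`.
#' @return List with `landmarks` (schema-ordered data.frame `abbrev, x, y`
#'   in 0-based pixels) and `curves` (list of control-point matrices).
#' @export
phantom_geometry <- function(morphology, articulation,
                             image_size = c(256, 256)) {
  a <- articulation; m <- morphology
  p <- a$lip_protrusion; ap <- a$lip_aperture; j <- a$jaw_open
  th <- a$tongue_height; adv <- 0.03 * a$tongue_advance
  vel <- a$velum_angle; lar <- a$larynx_height

  # landmark positions, normalized [0,1]^2, face pointing left
  L <- list(
    N    = c(0.160, 0.220),
    NP   = c(0.155, 0.300),
    ULPV = c(0.150 - p, 0.355),
    ULV  = c(0.175 - p, 0.400 - ap / 2),
    ANS  = c(0.235, 0.340),
    PNS  = c(0.520, 0.360),
    NPX  = c(0.600, 0.240),
    TT   = c(0.270 - adv, 0.500 - a$tongue_tip_elev),
    TS   = c(0.300, 0.575 + j),
    TJ   = c(0.275, 0.625 + j),
    TE   = c(0.580 + adv / 2, 0.625 + j / 2),
    ET   = c(0.615 + a$epiglottis_tilt_x, 0.555 + a$epiglottis_tilt_y),
    EG   = c(0.655, 0.770 + lar),
    PL   = c(0.715, 0.710 + lar),
    LLV  = c(0.175 - p, 0.460 + ap / 2 + j),
    LLSV = c(0.150 - p, 0.500 + j),
    LC   = c(0.160, 0.575 + j),
    NM   = c(0.380, 0.840 + j / 2),
    UT   = c(0.228, 0.405),
    LT   = c(0.228, 0.470 + j)
  )
  phi <- (62 + 22 * vel) * pi / 180   # velum hangs down-back from PNS
  L$VT <- L$PNS + 0.13 * c(cos(phi), sin(phi))

  # auxiliary (non-landmark) control points
  pal_mid <- c(0.380, (L$ANS[2] + L$PNS[2]) / 2 - m$palate_curv)
  vel_mid <- (L$PNS + L$VT) / 2 + c(0.018, 0)
  dors    <- c(0.420, 0.500 - th)                 # tongue dorsum apex
  A <- list(
    face = rbind(c(0.240, 0.040), c(0.150, 0.140), L$N, L$NP, L$ULPV),
    upper_lip = rbind(L$ULPV, L$ULV, c(0.215, 0.410)),
    lower_lip = rbind(L$LLSV, L$LLV, c(0.215, 0.460 + j)),
    lower_face = rbind(L$LLSV, L$LC, c(0.190, 0.660 + j),
                       c(0.250, 0.760 + j / 2), L$NM, c(0.405, 0.920),
                       c(0.420, 0.980)),
    palate = rbind(L$ANS, pal_mid, L$PNS),
    velum = rbind(L$PNS, vel_mid, L$VT),
    tongue = rbind(L$TJ, L$TS, L$TT,
                   c(0.310 - adv, 0.470 - th / 2), dors,
                   c(0.520 + adv / 2, 0.550 - th / 3), L$TE),
    epiglottis = rbind(L$TE, L$ET, L$EG),
    pharynx = rbind(L$NPX, c(0.690, 0.400), L$PL, c(0.700, 0.880 + lar))
  )

  ctr <- c(0.45, 0.5)
  morph_map <- function(pt) {
    pt <- ctr + m$scale * (pt - ctr) + c(m$offset_x, m$offset_y)
    # jaw length stretches the lower half horizontally about the lip line
    if (pt[2] > 0.55) pt[1] <- 0.15 + m$jaw_len * (pt[1] - 0.15)
    pt
  }
  to_px <- function(pt) c(pt[1] * (image_size[2] - 1), pt[2] * (image_size[1] - 1))
  map_all <- function(mat) t(apply(mat, 1, function(r) to_px(morph_map(r))))

  schema <- landmark_schema()
  lm_px <- t(vapply(schema$abbrev, function(ab) to_px(morph_map(L[[ab]])),
                    numeric(2)))
  landmarks <- data.frame(abbrev = schema$abbrev, x = lm_px[, 1],
                          y = lm_px[, 2], stringsAsFactors = FALSE)
  curves <- lapply(A, map_all)
  list(landmarks = landmarks, curves = curves)
}

# internal: densely sample a control polyline with a natural spline
sample_curve <- function(ctrl, per_px = 3) {
  d <- sqrt(diff(ctrl[, 1])^2 + diff(ctrl[, 2])^2)
  t0 <- c(0, cumsum(d))
  len <- max(t0)
  n <- max(20L, ceiling(per_px * len))
  if (nrow(ctrl) == 2L) {
    tt <- seq(0, len, length.out = n)
    return(cbind(x = ctrl[1, 1] + tt / len * diff(ctrl[, 1]),
                 y = ctrl[1, 2] + tt / len * diff(ctrl[, 2])))
  }
  sx <- spline(t0, ctrl[, 1], n = n, method = "natural")
  sy <- spline(t0, ctrl[, 2], n = n, method = "natural")
  cbind(x = sx$y, y = sy$y)
}

# internal: render one phantom image from its geometry
render_phantom <- function(geom, image_size, stroke = NULL,
                           background = 20, peak = 200) {
  rows <- image_size[1]; cols <- image_size[2]
  if (is.null(stroke)) stroke <- max(1, min(rows, cols) / 64)
  canvas <- matrix(background, rows, cols)
  for (cv in geom$curves) {
    s <- sample_curve(cv)
    canvas <- render_curves(canvas, s[, "x"], s[, "y"], stroke, peak)
  }
  canvas
}

#' Generate a seeded synthetic phantom corpus
#'
#' Produces `n_subjects * n_classes` original annotated images (tag
#' `"orig"`). Fully deterministic given the configuration: the same config
#' yields a byte-identical corpus.
#'
#' @param config a [phantom_config()].
#' @return List of [annotated_image()] objects, subjects varying slowest.
#' @examples
#' corpus <- generate_corpus(phantom_config(2, 3, image_size = c(64, 64)))
#' length(corpus)  # 6
#' @export
generate_corpus <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(config$rng_seed, {
    morphs <- replicate(config$n_subjects,
                        draw_morphology(config$morphology_spread),
                        simplify = FALSE)
    out <- vector("list", config$n_subjects * config$n_classes)
    pos <- 1L
    for (s in seq_len(config$n_subjects)) {
      for (cl in seq_len(config$n_classes)) {
        artic <- draw_articulation(config$articulation_spread)
        geom <- phantom_geometry(morphs[[s]], artic, config$image_size)
        img <- render_phantom(geom, config$image_size)
        if (config$noise_sd > 0)
          img <- pmin(pmax(img + matrix(rnorm(length(img), 0, config$noise_sd),
                                        nrow(img)), 0), 255)
        out[[pos]] <- annotated_image(img, geom$landmarks,
                                      subject_id = sprintf("S%02d", s),
                                      class_id = sprintf("C%02d", cl))
        pos <- pos + 1L
      }
    }
    out
  })
}

#' Per-landmark variability summary of a corpus
#'
#' Summarizes, for each landmark, the overall coordinate spread, the
#' between-subject spread (sd of per-subject mean positions) and the
#' within-subject spread (mean over subjects of the sd across classes).
#' Used to verify that a generated corpus carries both inter-subject
#' morphology variation and intra-subject articulation variation.
#'
#' @param corpus non-empty list of [annotated_image()] objects.
#' @return List of class `corpus_statistics` with `provenance` (one row
#'   per item) and `spread` (one row per landmark).
#' @export
corpus_statistics <- function(corpus) {
  stopifnot(is.list(corpus), length(corpus) > 0L)
  meta <- corpus_meta(corpus)
  schema <- landmark_schema()
  xs <- vapply(corpus, function(it) it$landmarks$x, numeric(nrow(schema)))
  ys <- vapply(corpus, function(it) it$landmarks$y, numeric(nrow(schema)))
  subj <- meta$subject
  sd0 <- function(v) if (length(v) > 1) sd(v) else 0
  per_lm <- lapply(seq_len(nrow(schema)), function(l) {
    mx <- tapply(xs[l, ], subj, mean); my <- tapply(ys[l, ], subj, mean)
    wx <- tapply(xs[l, ], subj, sd0);  wy <- tapply(ys[l, ], subj, sd0)
    data.frame(abbrev = schema$abbrev[l],
               sd_x = sd0(xs[l, ]), sd_y = sd0(ys[l, ]),
               between_subject = sd0(c(mx, recursive = TRUE)) + sd0(my),
               within_subject = mean(wx) + mean(wy),
               stringsAsFactors = FALSE)
  })
  structure(list(provenance = meta, spread = do.call(rbind, per_lm)),
            class = "corpus_statistics")
}

#' @export
print.corpus_statistics <- function(x, ...) {
  cat(sprintf("<corpus_statistics> %d items, %d subjects, %d classes\n",
              nrow(x$provenance), length(unique(x$provenance$subject)),
              length(unique(x$provenance$class))))
  print(x$spread, digits = 3)
  invisible(x)
}
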