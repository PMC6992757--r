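#' The 21-landmark vocal-tract schema
#'
#' Returns the fixed catalogue of the 21 anatomical landmarks of the
#' vocal-tract area, in canonical order (alphabetical by abbreviation).
#' This order is a package-wide contract: annotation CSV columns, heat-map
#' channels and report rows all follow it.
#'
#' @return A data frame of class `landmark_schema` with columns `abbrev`,
#'   `name`, `description` and 21 rows.
#' @examples
#' sch <- landmark_schema()
#' sch$abbrev
#' @export
landmark_schema <- function() {
  sch <- data.frame(
    abbrev = c("ANS", "EG", "ET", "LC", "LLSV", "LLV", "LT", "N", "NM", "NP",
               "NPX", "PL", "PNS", "TE", "TJ", "TS", "TT", "ULPV", "ULV",
               "UT", "VT"),
    name = c("Anterior Nasal Spine", "Epiglottis-Glottis", "Epiglottis Tip",
             "Lip-Chin", "Lower Lip Skin Vermillion", "Lower Lip Vermillion",
             "Lower Teeth", "Nose", "Neck-Mandible", "Nose-Philtrum",
             "Nasopharynx", "Pharynx-Larynx", "Posterior Nasal Spine",
             "Tongue-Epiglottis", "Tongue-Jaw", "Tongue Sub", "Tongue Tip",
             "Upper Lip Philtrum Vermillion", "Upper Lip Vermillion",
             "Upper Teeth", "Velum Tip"),
    description = c(
      "Anterior nasal spine",
      "Junction between the epiglottis and the glottis",
      "Tip of the epiglottis",
      "Labiomental groove",
      "Vermillon border of the lower lip",
      "Junction between the wet and dry vermillion of the lower lip",
      "Upper point of the lower incisors",
      "Most anterior point of the tip of the nose",
      "Junction between the horizontal submandibular line and vertical neck line",
      "Junction between the philtrum and the external nose",
      "Upper point of the nasopharynx",
      "Junction between the pharyngeal wall and the posterior supraglottic region",
      "Posterior nasal spine",
      "Junction between the tongue and the epiglottis",
      "Junction between the tongue and the jaw",
      "Most posterior point of the sublingual cavity",
      "Tip of the tongue",
      "Vermillon border of the upper lip",
      "Junction between the wet and dry vermillion of the upper lip",
      "Lower point of the upper incisors",
      "Tip of the velum"),
    stringsAsFactors = FALSE
  )
  class(sch) <- c("landmark_schema", "data.frame")
  sch
}

#' Convert a pixel distance to centimeters
#'
#' @param distance_px non-negative distance in pixels.
#' @param resolution_mm_per_px image resolution in millimeters per pixel
#'   (1.0 for the reference 256 x 256 mm field of view at 256 x 256 px).
#' @return Distance in centimeters: `distance_px * resolution_mm_per_px / 10`.
#' @examples
#' px_to_cm(3.6, 1)   # 0.36
#' @export
px_to_cm <- function(distance_px, resolution_mm_per_px = 1) {
  stopifnot(is.numeric(distance_px), is.numeric(resolution_mm_per_px),
            resolution_mm_per_px > 0)
  if (any(distance_px < 0)) stop("distance_px must be non-negative")
  distance_px * resolution_mm_per_px / 10
}

#' Replicate a grayscale image grid into three identical channels
#'
#' Grayscale inputs are converted to grayscale RGB by simple channel
#' repetition so they match the network's 3-channel input format.
#'
#' @param image numeric matrix (rows x cols), intensities in \[0, 255\].
#' @return A rows x cols x 3 array with all three slices identical.
#' @export
to_three_channel <- function(image) {
  stopifnot(is.matrix(image), is.numeric(image), all(is.finite(image)))
  array(rep(image, 3L), dim = c(nrow(image), ncol(image), 3L))
}

# internal: validate a landmark data.frame against the schema
check_landmarks <- function(landmarks, schema = landmark_schema()) {
  if (!is.data.frame(landmarks) || !all(c("abbrev", "x", "y") %in% names(landmarks)))
    stop("landmarks must be a data.frame with columns abbrev, x, y")
  if (nrow(landmarks) != nrow(schema) ||
      !identical(as.character(landmarks$abbrev), schema$abbrev))
    stop("landmarks must contain exactly the 21 schema landmarks in schema order")
  if (!all(is.finite(landmarks$x)) || !all(is.finite(landmarks$y)))
    stop("landmark coordinates must be finite")
  invisible(landmarks)
}

# internal: out-of-frame flag for 0-based coordinates on a rows x cols frame
outside_frame <- function(landmarks, rows, cols) {
  landmarks$x < 0 | landmarks$x >= cols | landmarks$y < 0 | landmarks$y >= rows
}

#' Construct an annotated image
#'
#' Bundles one grayscale image grid with its 21-landmark annotation and
#' provenance fields.
#'
#' @param image numeric matrix (rows x cols), intensities in \[0, 255\].
#' @param landmarks data.frame with columns `abbrev`, `x`, `y` (0-based
#'   pixel coordinates, x = column, y = row), rows in schema order.
#' @param subject_id,class_id subject and articulation-class identifiers.
#' @param augmentation_tag `"orig"` for un-augmented images, otherwise the
#'   name of the transform that produced the copy.
#' @param source_id identifier of the un-augmented original; defaults to
#'   `subject_id:class_id`.
#' @return A list of class `annotated_image`.
#' @export
annotated_image <- function(image, landmarks, subject_id, class_id,
                            augmentation_tag = "orig", source_id = NULL) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (!all(is.finite(image))) stop("image intensities must be finite")
  check_landmarks(landmarks)
  landmarks$outside <- outside_frame(landmarks, nrow(image), ncol(image))
  if (is.null(source_id)) source_id <- paste(subject_id, class_id, sep = ":")
  structure(list(image = image, landmarks = landmarks,
                 subject_id = as.character(subject_id),
                 class_id = as.character(class_id),
                 augmentation_tag = as.character(augmentation_tag),
                 source_id = as.character(source_id)),
            class = "annotated_image")
}

#' @export
print.annotated_image <- function(x, ...) {
  cat(sprintf("<annotated_image> %dx%d px, subject %s, class %s, tag %s\n",
              nrow(x$image), ncol(x$image), x$subject_id, x$class_id,
              x$augmentation_tag))
  invisible(x)
}

# internal: unique identifier of an item within a corpus
item_id <- function(item) {
  paste(item$subject_id, item$class_id, item$augmentation_tag, sep = ":")
}

# internal: metadata data.frame for a corpus
corpus_meta <- function(corpus) {
  data.frame(
    id = vapply(corpus, item_id, character(1)),
    subject = vapply(corpus, function(it) it$subject_id, character(1)),
    class = vapply(corpus, function(it) it$class_id, character(1)),
    tag = vapply(corpus, function(it) it$augmentation_tag, character(1)),
    source = vapply(corpus, function(it) it$source_id, character(1)),
    stringsAsFactors = FALSE
  )
}
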