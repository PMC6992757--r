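# Corpus I/O: PNG images (TIFF accepted on read) + one CSV annotation file.
# CSV dialect: one row per image with columns
#   image,subject,class,tag,source, then x_ANS,y_ANS, ..., x_VT,y_VT
# in schema order. Coordinates are written as floats (sub-pixel precision).

coord_columns <- function(schema = landmark_schema()) {
  as.vector(rbind(paste0("x_", schema$abbrev), paste0("y_", schema$abbrev)))
}

read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF images requires the 'tiff' package")
    img <- tiff::readTIFF(path)
  } else {
    img <- png::readPNG(path)
  }
  if (length(dim(img)) == 3L) img <- img[, , 1L]  # collapse RGB(A) to gray
  round(img * 255)
}

#' Read an annotated corpus from disk
#'
#' @param annotations_path path to the CSV annotation file (see package
#'   documentation for the column dialect).
#' @param images_dir directory holding the image files named in the CSV.
#' @return A list of [annotated_image()] objects, one per CSV row.
#' @seealso [write_corpus()]
#' @export
read_corpus <- function(annotations_path, images_dir) {
  if (!file.exists(annotations_path))
    stop("annotation file not found: ", annotations_path)
  schema <- landmark_schema()
  tab <- read.csv(annotations_path, stringsAsFactors = FALSE, check.names = FALSE)
  wanted <- c("image", "subject", "class", "tag", "source", coord_columns(schema))
  missing_cols <- setdiff(wanted, names(tab))
  if (length(missing_cols))
    stop("annotation file is missing columns (or has unknown landmark column order): ",
         paste(head(missing_cols, 5), collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    coords <- suppressWarnings(as.numeric(row[coord_columns(schema)]))
    if (length(coords) != 42L || any(is.na(coords)))
      stop("malformed coordinates in annotation row ", i, " (image ", row$image, ")")
    img_path <- file.path(images_dir, row$image)
    if (!file.exists(img_path))
      stop("image file not found for annotation row ", i, ": ", img_path)
    lms <- data.frame(abbrev = schema$abbrev,
                      x = coords[seq(1, 42, 2)],
                      y = coords[seq(2, 42, 2)],
                      stringsAsFactors = FALSE)
    annotated_image(read_image_file(img_path), lms,
                    subject_id = row$subject, class_id = row$class,
                    augmentation_tag = row$tag, source_id = row$source)
  })
}

#' Write an annotated corpus to disk
#'
#' Writes one 8-bit grayscale PNG per item plus a single CSV annotation
#' file. For integer-valued 8-bit images the round trip through
#' [read_corpus()] is lossless; coordinates round-trip exactly.
#'
#' @param corpus non-empty list of [annotated_image()] objects.
#' @param annotations_path output CSV path.
#' @param images_dir output directory for PNG files (created if needed).
#' @return Invisibly, the annotation data frame that was written.
#' @export
write_corpus <- function(corpus, annotations_path, images_dir) {
  if (!is.list(corpus) || length(corpus) == 0L)
    stop("corpus must be a non-empty list of annotated images")
  schema <- landmark_schema()
  dir.create(images_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(corpus), function(i) {
    it <- corpus[[i]]
    fname <- paste0(gsub("[^A-Za-z0-9_.-]", "_", item_id(it)), ".png")
    png::writePNG(pmin(pmax(it$image, 0), 255) / 255, file.path(images_dir, fname))
    # full 17-digit precision so the coordinate round trip is exact
    coords <- sprintf("%.17g", as.vector(rbind(it$landmarks$x, it$landmarks$y)))
    row <- data.frame(image = fname, subject = it$subject_id,
                      class = it$class_id, tag = it$augmentation_tag,
                      source = it$source_id, stringsAsFactors = FALSE)
    row[coord_columns(schema)] <- as.list(coords)
    row
  })
  tab <- do.call(rbind, rows)
  write.csv(tab, annotations_path, row.names = FALSE, quote = FALSE)
  invisible(tab)
}
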