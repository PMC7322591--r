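#' RGB fundus image container
#'
#' An `rgb_image` is a `height x width x 3` numeric array of intensities in
#' `[0, 255]` (red, green, blue planes), row-major with the origin at the
#' top-left. The constructor validates shape and range.
#'
#' @param x Numeric array with `dim = c(height, width, 3)`, values in
#'   `[0, 255]`.
#' @return An object of class `rgb_image`.
#' @export
as_rgb_image <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L)
    stop("an rgb_image needs a height x width x 3 array")
  if (anyNA(x) || min(x) < 0 || max(x) > 255)
    stop("intensities must lie in [0, 255]")
  structure(x, class = c("rgb_image", "array"))
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image %d x %d, intensity range [%g, %g]>\n",
              d[1], d[2], min(x), max(x)))
  invisible(x)
}

#' Load a colour raster image
#'
#' Reads an 8-bit PNG or JPEG file into an [as_rgb_image()] container with
#' intensities in `[0, 255]`. An alpha channel, if present, is dropped;
#' grayscale files are rejected because the pipeline needs the green plane.
#'
#' @param path Path to a PNG or JPEG file.
#' @return An `rgb_image`.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  a <- tryCatch({
    if (grepl("\\.png$", path, ignore.case = TRUE)) {
      png::readPNG(path)
    } else {
      # EBImage decodes JPEG (and others) but stores data x-major; transpose
      # back to row-major.
      img <- EBImage::readImage(path)
      d <- EBImage::imageData(img)
      if (length(dim(d)) == 2L) d else aperm(d, c(2L, 1L, 3L))
    }
  }, error = function(e) stop("could not decode image '", path, "': ",
                              conditionMessage(e)))
  if (length(dim(a)) == 2L || dim(a)[3] == 1L || dim(a)[3] == 2L)
    stop("image '", path, "' has no colour channels; 3-channel input required")
  if (dim(a)[3] == 4L) a <- a[, , 1:3, drop = FALSE]
  as_rgb_image(round(a * 255))
}

#' Write an RGB image to a PNG file
#'
#' @param image An `rgb_image`.
#' @param path Output path (PNG, lossless).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  image <- as_rgb_image(unclass(image))
  png::writePNG(unclass(image) / 255, target = path)
  invisible(path)
}

#' Resize an RGB image to a square side
#'
#' Bilinear resampling with anti-aliasing (via EBImage), the standard first
#' step that brings every fundus photograph to the common working resolution
#' (100 x 100 by default downstream). Output intensities are rounded back to
#' the 8-bit grid.
#'
#' @param image An `rgb_image`.
#' @param side Target side length in pixels, at least 8.
#' @return An `rgb_image` of dimension `side x side x 3`.
#' @export
resize_image <- function(image, side) {
  side <- as.integer(side)
  if (is.na(side) || side < 8L) stop("side must be at least 8 pixels")
  image <- as_rgb_image(unclass(image))
  if (all(dim(image)[1:2] == side)) return(image)
  a <- aperm(unclass(image), c(2L, 1L, 3L)) / 255   # EBImage is x-major
  out <- EBImage::resize(EBImage::Image(a, colormode = "Color"),
                         w = side, h = side, antialias = TRUE)
  b <- aperm(EBImage::imageData(out), c(2L, 1L, 3L)) * 255
  as_rgb_image(clip255(round_half_up(b)))
}

#' Extract the green component
#'
#' The green plane of a fundus photograph carries the strongest vessel and
#' lesion contrast (retinal pigments reflect green light preferentially), so
#' it is used directly as one of the two preprocessing paths.
#'
#' @param image An `rgb_image`.
#' @return A numeric matrix (gray plane) equal to the green plane.
#' @export
extract_green <- function(image) {
  image <- as_rgb_image(unclass(image))
  unclass(image)[, , 2L]
}

#' Convert an RGB image to luminance
#'
#' Standard Rec. 601 luminance, `0.299 R + 0.587 G + 0.114 B`, rounded
#' half-up to the nearest integer so downstream histograms operate on
#' discrete 8-bit intensities.
#'
#' @param image An `rgb_image`.
#' @return An integer-valued gray-plane matrix in `[0, 255]`.
#' @export
to_luminance <- function(image) {
  image <- unclass(as_rgb_image(unclass(image)))
  y <- 0.299 * image[, , 1L] + 0.587 * image[, , 2L] + 0.114 * image[, , 3L]
  clip255(round_half_up(y))
}

#' Read a label manifest
#'
#' The manifest is a CSV with header `image_id,path,grade`; grades are
#' integers 0 (no retinopathy) to 4 (proliferative). The referable flag
#' (grade >= 2) is derived, never stored.
#'
#' @param path Path to the CSV manifest.
#' @return A data frame with columns `image_id`, `path`, `grade`,
#'   `referable`.
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "path", "grade")
  if (!all(need %in% names(m)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  m$grade <- as.integer(m$grade)
  if (anyNA(m$grade) || any(m$grade < 0L | m$grade > 4L))
    stop("grades must be integers in 0..4")
  m$referable <- m$grade >= 2L
  m
}

#' Write a label manifest
#'
#' @param manifest Data frame with at least `image_id`, `path`, `grade`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  keep <- intersect(c("image_id", "path", "grade"), names(manifest))
  write.csv(manifest[keep], path, row.names = FALSE)
  invisible(path)
}
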