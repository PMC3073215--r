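#' RGB FISH image container
#'
#' Holds the three colour channels of a FISH image as raw integer matrices
#' together with the camera bit depth. In the two-probe HER2 assay the blue
#' channel carries the DAPI nuclear counterstain, the red channel the
#' HER2/neu probe signals and the green channel the CEP17 (centromere 17)
#' probe signals.
#'
#' @param red,green,blue Integer-valued matrices of identical dimensions with
#'   values in `[0, 2^bit_depth - 1]`.
#' @param bit_depth Either 8 or 16.
#'
#' @return An object of class `rgb_image` with fields `red`, `green`, `blue`
#'   (raw intensity matrices) and `bit_depth`.
#' @seealso [read_rgb()], [split_channels()]
#' @export
rgb_image <- function(red, green, blue, bit_depth = 8L) {
  if (!bit_depth %in% c(8L, 16L)) {
    stop("bit_depth must be 8 or 16, got ", bit_depth)
  }
  if (!all(dim(red) == dim(green)) || !all(dim(red) == dim(blue))) {
    stop("channel matrices must have identical dimensions")
  }
  maxval <- 2^bit_depth - 1
  for (ch in list(red, green, blue)) {
    if (min(ch) < 0 || max(ch) > maxval) {
      stop("raw intensities must lie in [0, ", maxval, "] for ",
           bit_depth, "-bit images")
    }
  }
  structure(
    list(red = red, green = green, blue = blue, bit_depth = as.integer(bit_depth)),
    class = "rgb_image"
  )
}

#' @export
print.rgb_image <- function(x, ...) {
  cat("rgb_image: ", nrow(x$red), " x ", ncol(x$red), " pixels, ",
      x$bit_depth, "-bit\n", sep = "")
  invisible(x)
}

#' Read an RGB FISH image from TIFF or PNG
#'
#' Decodes a 3-channel image, records its bit depth and returns the raw
#' integer channels in R, G, B order. RGBA images are accepted; the alpha
#' channel is dropped with a warning. Images with any other channel count
#' are rejected.
#'
#' @param path Path to a TIFF (8- or 16-bit) or PNG file.
#' @return An [rgb_image()].
#' @export
read_rgb <- function(path) {
  if (!file.exists(path)) stop("cannot read image: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(arr, "bits.per.sample")
    if (is.null(bits)) bits <- 8L
  } else if (ext == "png") {
    arr <- png::readPNG(path, info = TRUE)
    info <- attr(arr, "info")
    bits <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
  } else {
    stop("unsupported image format '", ext, "' (expected TIFF or PNG)")
  }
  bits <- as.integer(bits)
  if (!bits %in% c(8L, 16L)) {
    stop("unsupported bit depth ", bits, " (expected 8 or 16)")
  }
  d <- dim(arr)
  if (length(d) == 2L) {
    stop("expected a 3-channel RGB image, got 1 channel")
  }
  nch <- d[3]
  if (nch == 4L) {
    warning("RGBA input: dropping the alpha channel")
  } else if (nch != 3L) {
    stop("expected a 3-channel RGB image, got ", nch, " channels")
  }
  maxval <- 2^bits - 1
  raw <- function(i) round(matrix(arr[, , i], d[1], d[2]) * maxval)
  rgb_image(raw(1), raw(2), raw(3), bit_depth = bits)
}

#' Normalize raw intensities to the internal [0, 1] grayscale
#'
#' Divides raw integer intensities by `2^bit_depth - 1`. All downstream
#' analysis in the package operates on this bit-depth-agnostic scale.
#'
#' @param raw Numeric matrix of raw intensities.
#' @param bit_depth Either 8 or 16.
#' @return A numeric matrix with values in `[0, 1]`.
#' @export
normalize_intensity <- function(raw, bit_depth = 8L) {
  maxval <- 2^bit_depth - 1
  if (min(raw) < 0 || max(raw) > maxval) {
    stop("raw intensities out of range for ", bit_depth,
         "-bit data: expected [0, ", maxval, "], got [",
         min(raw), ", ", max(raw), "]")
  }
  raw / maxval
}

#' Split an RGB image into normalized grayscale channels
#'
#' @param img An [rgb_image()].
#' @return A named list `red`, `green`, `blue` of numeric matrices in
#'   `[0, 1]` (see [normalize_intensity()]).
#' @export
split_channels <- function(img) {
  stopifnot(inherits(img, "rgb_image"))
  list(
    red = normalize_intensity(img$red, img$bit_depth),
    green = normalize_intensity(img$green, img$bit_depth),
    blue = normalize_intensity(img$blue, img$bit_depth)
  )
}

#' Write an RGB image to TIFF
#'
#' Stores the raw channels at the image's own bit depth. Used by the
#' synthetic generator and the command-line `simulate` subcommand.
#'
#' @param img An [rgb_image()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_rgb <- function(img, path) {
  stopifnot(inherits(img, "rgb_image"))
  maxval <- 2^img$bit_depth - 1
  arr <- array(0, c(nrow(img$red), ncol(img$red), 3L))
  arr[, , 1] <- img$red / maxval
  arr[, , 2] <- img$green / maxval
  arr[, , 3] <- img$blue / maxval
  tiff::writeTIFF(arr, path, bits.per.sample = img$bit_depth)
  invisible(path)
}

# Debug helper: write a real-valued matrix as a 32-bit float TIFF, linearly
# rescaled to [0,1] when values fall outside that range.
write_float_tiff <- function(x, path) {
  rng <- range(x)
  if (rng[1] < 0 || rng[2] > 1) {
    span <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
    x <- (x - rng[1]) / span
  }
  tiff::writeTIFF(x, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}
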