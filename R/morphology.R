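#' Flat disk structuring element
#'
#' Binary disk mask of the pixels at Euclidean distance <= radius from the
#' centre; the neighbourhood that defines "small" for the top-hat/bottom-hat
#' enhancement. Radius 0 degenerates to a single pixel.
#'
#' @param radius Disk radius in pixels (non-negative integer).
#' @return An object of class `structuring_element` with fields `shape`,
#'   `radius` and `mask` (a `(2r+1) x (2r+1)` 0/1 matrix).
#' @export
disk_se <- function(radius = 5L) {
  radius <- as.integer(radius)
  if (radius < 0L) stop("radius must be non-negative")
  w <- 2L * radius + 1L
  d <- outer((-radius):radius, (-radius):radius, function(i, j) i * i + j * j)
  structure(
    list(shape = "disk", radius = radius,
         mask = matrix(as.numeric(d <= radius^2), w, w)),
    class = "structuring_element"
  )
}

check_se_fits <- function(I, se) {
  w <- 2L * se$radius + 1L
  if (w > nrow(I) || w > ncol(I)) {
    stop("structuring element (", w, "x", w, ") larger than image (",
         nrow(I), "x", ncol(I), ")")
  }
}

# Grayscale erosion/dilation under the package's symmetric border policy:
# the image is padded by 2*radius, the flat min/max filters run on the
# padded image, and the core is cropped back so EBImage's own edge handling
# never reaches the output.
morph_gray <- function(I, se, what = c("open", "close")) {
  what <- match.arg(what)
  r <- se$radius
  if (r == 0L) return(I)
  nr <- nrow(I); nc <- ncol(I)
  p <- pad_sym(I, 2L * r)
  k <- se$mask
  res <- if (what == "open") {
    EBImage::dilate(EBImage::erode(p, k), k)
  } else {
    EBImage::erode(EBImage::dilate(p, k), k)
  }
  res <- matrix(as.numeric(res), nrow(p), ncol(p))
  res[(2L * r + 1L):(2L * r + nr), (2L * r + 1L):(2L * r + nc), drop = FALSE]
}

#' Top-hat transform
#'
#' `TH = I - opening(I, se)`: extracts bright details smaller than the
#' structuring element from a non-uniform background. Non-negative
#' everywhere by the anti-extensivity of the opening.
#'
#' @param I Grayscale matrix in `[0, 1]`.
#' @param se A [disk_se()] structuring element.
#' @return Matrix of the same size, values >= 0.
#' @export
top_hat <- function(I, se = disk_se()) {
  validate_gray(I, "I")
  check_se_fits(I, se)
  I - morph_gray(I, se, "open")
}

#' Bottom-hat transform
#'
#' `BH = closing(I, se) - I`: extracts dark details smaller than the
#' structuring element. Non-negative everywhere by the extensivity of the
#' closing.
#'
#' @inheritParams top_hat
#' @return Matrix of the same size, values >= 0.
#' @export
bottom_hat <- function(I, se = disk_se()) {
  validate_gray(I, "I")
  check_se_fits(I, se)
  morph_gray(I, se, "close") - I
}

#' Combined top-hat/bottom-hat contrast enhancement
#'
#' `E = clip(I + TH - BH, 0, 1)`. The `TH - BH` difference pushes details
#' brighter than their surroundings and smaller than the structuring element
#' toward white while pulling the surrounding texture toward black; adding
#' the original image back reinforces the enhanced details and flattens
#' uneven background illumination.
#'
#' @inheritParams top_hat
#' @return Matrix of the same size in `[0, 1]`.
#' @export
enhance <- function(I, se = disk_se()) {
  validate_gray(I, "I")
  check_se_fits(I, se)
  op <- morph_gray(I, se, "open")
  cl <- morph_gray(I, se, "close")
  pmin(pmax(I + (I - op) - (cl - I), 0), 1)
}

#' Parameters for morphological dot detection
#'
#' @param se_radius Disk radius (pixels) of the enhancement structuring
#'   element; must exceed the expected dot radius.
#' @param threshold_mode How the enhanced image is binarised inside each
#'   nucleus: `"otsu_in_nucleus"` (Otsu on the in-nucleus enhanced values) or
#'   `"mean_plus_k_sigma"`.
#' @param k_sigma Multiplier for `"mean_plus_k_sigma"`.
#' @param min_dot_area,max_dot_area Connected-component area gates in pixels.
#'   `max_dot_area` defaults to `pi * se_radius^2`: a "dot" larger than the
#'   structuring element contradicts the enhancement premise.
#' @param min_contrast Minimum in-nucleus range of enhanced intensities for
#'   thresholding to be attempted; a nucleus flatter than this yields no dots.
#' @return A `mm_detect_params` list.
#' @export
mm_detect_params <- function(se_radius = 5L,
                             threshold_mode = c("otsu_in_nucleus", "mean_plus_k_sigma"),
                             k_sigma = 3,
                             min_dot_area = 2L,
                             max_dot_area = NULL,
                             min_contrast = 0.1) {
  threshold_mode <- match.arg(threshold_mode)
  se_radius <- as.integer(se_radius)
  if (is.null(max_dot_area)) max_dot_area <- round(pi * se_radius^2)
  if (min_dot_area >= max_dot_area) {
    stop("min_dot_area must be smaller than max_dot_area")
  }
  structure(
    list(se_radius = se_radius, threshold_mode = threshold_mode,
         k_sigma = k_sigma, min_dot_area = as.integer(min_dot_area),
         max_dot_area = as.integer(max_dot_area), min_contrast = min_contrast),
    class = "mm_detect_params"
  )
}

# Threshold the enhanced values of one nucleus. Returns a cutoff, or NA when
# the nucleus is too flat to contain signal.
nucleus_threshold <- function(vals, params) {
  rng <- range(vals)
  if (rng[2] - rng[1] < params$min_contrast) return(NA_real_)
  if (params$threshold_mode == "otsu_in_nucleus") {
    EBImage::otsu(matrix(vals, ncol = 1L), range = c(0, 1))
  } else {
    mean(vals) + params$k_sigma * sd(vals)
  }
}

#' Detect probe dots with the morphological engine
#'
#' Applies the combined top-hat/bottom-hat enhancement to a probe channel,
#' thresholds the enhanced image separately inside every segmented nucleus,
#' and turns area-gated connected components into dot records. Pixels
#' outside all nuclei are never reported as dots.
#'
#' @param channel Grayscale probe channel (red or green) in `[0, 1]`.
#' @param nuclei A [nucleus_map] from [segment_nuclei()].
#' @param params [mm_detect_params()].
#' @param channel_name `"red"` or `"green"`, recorded on each dot.
#' @return A data frame of dot records: `channel`, `row`, `col` (0-based
#'   centroid), `area`, `nucleus_id`, `est_count` (1 at detection time).
#' @export
detect_dots_mm <- function(channel, nuclei, params = mm_detect_params(),
                           channel_name = "red") {
  validate_gray(channel, "channel")
  stopifnot(inherits(nuclei, "nucleus_map"))
  if (!all(dim(channel) == dim(nuclei$labels))) {
    stop("channel and nucleus label map dimensions differ")
  }
  K <- nrow(nuclei$features)
  if (K == 0L) return(dot_records())
  E <- enhance(channel, disk_se(params$se_radius))
  labels <- nuclei$labels
  out <- vector("list", K)
  for (id in nuclei$features$label_id) {
    idx <- which(labels == id, arr.ind = TRUE)
    vals <- E[idx]
    thr <- nucleus_threshold(vals, params)
    if (is.na(thr)) next
    r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
    c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
    sub <- E[r0:r1, c0:c1, drop = FALSE]
    inmask <- labels[r0:r1, c0:c1, drop = FALSE] == id
    bin <- (sub > thr) & inmask
    out[[id]] <- components_to_dots(
      bin, channel_name, id,
      params$min_dot_area, params$max_dot_area,
      row_off = r0 - 1L, col_off = c0 - 1L
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(dot_records())
  do.call(rbind, out)
}
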