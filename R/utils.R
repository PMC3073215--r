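# Internal helpers shared across modules: padding, window reductions,
# labelled-region features, dot-record bookkeeping.

# Symmetric (edge-inclusive, mirror) padding by k pixels on every side.
# Requires k <= min(dim(x)); all morphological and windowed operators in the
# package use this border policy so that oracle tests can reproduce it.
pad_sym <- function(x, k) {
  if (k == 0L) return(x)
  nr <- nrow(x); nc <- ncol(x)
  if (k > nr || k > nc) {
    stop("padding width ", k, " exceeds image size ", nr, "x", nc)
  }
  ri <- c(k:1, seq_len(nr), nr:(nr - k + 1L))
  ci <- c(k:1, seq_len(nc), nc:(nc - k + 1L))
  x[ri, ci, drop = FALSE]
}

# Reduce over a (2k+1)x(2k+1) sliding window with symmetric padding.
# op is one of "sum", "max", "min". Implemented as shift-accumulate over the
# padded image; exact (no separable approximation).
window_reduce <- function(x, k, op = c("sum", "max", "min")) {
  op <- match.arg(op)
  if (k == 0L) return(x)
  nr <- nrow(x); nc <- ncol(x)
  p <- pad_sym(x, k)
  acc <- NULL
  for (di in -k:k) {
    for (dj in -k:k) {
      s <- p[(k + 1L + di):(k + nr + di), (k + 1L + dj):(k + nc + dj), drop = FALSE]
      acc <- if (is.null(acc)) {
        s
      } else {
        switch(op, sum = acc + s, max = pmax(acc, s), min = pmin(acc, s))
      }
    }
  }
  acc
}

# Even-odd (ray crossing) point-in-polygon test, vectorised over points.
# Polygon vertices (vx, vy) are taken in order and closed implicitly.
points_in_polygon <- function(px, py, vx, vy) {
  inside <- rep(FALSE, length(px))
  j <- length(vx)
  for (i in seq_along(vx)) {
    denom <- vy[j] - vy[i]
    if (denom != 0) {
      crosses <- ((vy[i] > py) != (vy[j] > py)) &
        (px < (vx[j] - vx[i]) * (py - vy[i]) / denom + vx[i])
      inside <- xor(inside, crosses)
    }
    j <- i
  }
  inside
}

# Solidity of a pixel region: area / area of the rasterised convex hull.
# The hull is the convex hull of pixel centres, inflated by a hair about its
# centroid so that boundary pixels test as inside; capped at 1.
region_solidity <- function(rows, cols) {
  n <- length(rows)
  if (n <= 3L) return(1)
  h <- grDevices::chull(cols, rows)
  if (length(h) <= 2L) return(1)
  vx <- cols[h]; vy <- rows[h]
  cx <- mean(vx); cy <- mean(vy)
  eps <- 1e-7
  vx <- cx + (vx - cx) * (1 + eps) + sign(vx - cx) * eps
  vy <- cy + (vy - cy) * (1 + eps) + sign(vy - cy) * eps
  rr <- seq(min(rows), max(rows))
  cc <- seq(min(cols), max(cols))
  grid <- expand.grid(row = rr, col = cc)
  hull_area <- sum(points_in_polygon(grid$col, grid$row, vx, vy))
  min(1, n / max(hull_area, n))
}

# Eccentricity from central second moments of the pixel coordinates,
# sqrt(1 - lambda_min/lambda_max) of the covariance eigenvalues; 0 for
# degenerate (single-pixel) regions.
region_eccentricity <- function(rows, cols) {
  rr <- rows - mean(rows)
  cc <- cols - mean(cols)
  mu20 <- mean(rr * rr)
  mu02 <- mean(cc * cc)
  mu11 <- mean(rr * cc)
  common <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- (mu20 + mu02) / 2 + common
  l2 <- (mu20 + mu02) / 2 - common
  if (l1 <= 0) return(0)
  sqrt(max(0, 1 - l2 / l1))
}

# Per-label region features for an integer label matrix. Centroids are
# 0-based (row, col) means of pixel indices.
region_features <- function(labels) {
  empty <- data.frame(
    label_id = integer(), area = integer(),
    centroid_row = numeric(), centroid_col = numeric(),
    solidity = numeric(), eccentricity = numeric(),
    touches_border = logical()
  )
  K <- max(labels)
  if (K < 1L) return(empty)
  idx <- which(labels > 0L, arr.ind = TRUE)
  lab <- labels[labels > 0L]
  nr <- nrow(labels); nc <- ncol(labels)
  feats <- lapply(sort(unique(lab)), function(id) {
    sel <- lab == id
    rows <- idx[sel, 1L]
    cols <- idx[sel, 2L]
    data.frame(
      label_id = id,
      area = length(rows),
      centroid_row = mean(rows) - 1,
      centroid_col = mean(cols) - 1,
      solidity = region_solidity(rows, cols),
      eccentricity = region_eccentricity(rows, cols),
      touches_border = any(rows == 1L | rows == nr | cols == 1L | cols == nc)
    )
  })
  do.call(rbind, feats)
}

# Canonical empty/constructed detected-dot table. Centroids 0-based.
dot_records <- function(channel = character(), row = numeric(),
                        col = numeric(), area = integer(),
                        nucleus_id = integer(), est_count = integer()) {
  data.frame(
    channel = as.character(channel),
    row = as.numeric(row),
    col = as.numeric(col),
    area = as.integer(area),
    nucleus_id = as.integer(nucleus_id),
    est_count = as.integer(est_count),
    stringsAsFactors = FALSE
  )
}

# Connected components (4-connectivity) of a logical matrix restricted to a
# single nucleus, returned as dot records after area gating.
components_to_dots <- function(mask, channel, nucleus_id,
                               min_area, max_area,
                               row_off = 0L, col_off = 0L) {
  if (!any(mask)) return(dot_records())
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow = nrow(mask))
  n <- max(lab)
  out <- vector("list", n)
  idx <- which(lab > 0L, arr.ind = TRUE)
  labv <- lab[lab > 0L]
  for (id in seq_len(n)) {
    sel <- labv == id
    a <- sum(sel)
    if (a < min_area || a > max_area) next
    rows <- idx[sel, 1L]; cols <- idx[sel, 2L]
    out[[id]] <- dot_records(
      channel = channel,
      row = mean(rows) - 1 + row_off,
      col = mean(cols) - 1 + col_off,
      area = a,
      nucleus_id = nucleus_id,
      est_count = 1L
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(dot_records())
  do.call(rbind, out)
}

# Validate a grayscale image matrix in [0, 1].
validate_gray <- function(x, arg = "image") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(arg, " must be a numeric matrix")
  }
  if (anyNA(x)) stop(arg, " contains missing values")
  if (min(x) < 0 || max(x) > 1) {
    stop(arg, " intensities must lie in [0, 1]; got range [",
         signif(min(x), 4), ", ", signif(max(x), 4), "]")
  }
  invisible(x)
}
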