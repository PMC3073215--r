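#' Specification of a synthetic two-probe FISH case
#'
#' Describes a seeded synthetic image that emulates the structure of a
#' DAPI/HER2/CEP17 FISH acquisition: elliptical textured nuclei on a dark
#' background in the blue channel, and small bright Gaussian probe dots
#' with additive noise in the red and green channels. Two failure modes can
#' be switched on: an acquisition without DAPI (`no_dapi`) and overlapping
#' red dots (`overlap_fraction`).
#'
#' @param image_size `(rows, cols)` in pixels.
#' @param n_nuclei Number of nuclei; placed without mutual overlap and away
#'   from the image border.
#' @param nucleus_radius_range Range of the major semi-axis in pixels; the
#'   axis ratio is sampled in `[1, 1.4]`.
#' @param red_per_nucleus,green_per_nucleus True dot counts per nucleus
#'   (scalar, recycled, or one value per nucleus).
#' @param dot_sigma Gaussian dot width (pixels).
#' @param dot_peak Dot peak amplitude above background.
#' @param background_level Probe-channel background intensity.
#' @param noise_sigma Standard deviation of the additive Gaussian noise.
#' @param overlap_fraction Fraction of red dots rendered overlapping an
#'   already-placed red dot (centre distance `1.5 * dot_sigma`), emulating
#'   merged HER2 signals.
#' @param no_dapi If TRUE the blue channel carries no nuclei (noise only),
#'   emulating an acquisition without counterstain.
#' @param seed Integer seed; the generator is bit-reproducible.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(image_size = c(600L, 600L),
                           n_nuclei = 20L,
                           nucleus_radius_range = c(24, 32),
                           red_per_nucleus = 4L,
                           green_per_nucleus = 2L,
                           dot_sigma = 1.5,
                           dot_peak = 0.8,
                           background_level = 0.1,
                           noise_sigma = 0.02,
                           overlap_fraction = 0,
                           no_dapi = FALSE,
                           seed = 1L) {
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    stop("overlap_fraction must lie in [0, 1]")
  }
  if (any(c(dot_peak, background_level) < 0) ||
      background_level + dot_peak > 1.5) {
    stop("dot_peak and background_level must be modest non-negative intensities")
  }
  structure(
    list(image_size = as.integer(image_size), n_nuclei = as.integer(n_nuclei),
         nucleus_radius_range = nucleus_radius_range,
         red_per_nucleus = as.integer(red_per_nucleus),
         green_per_nucleus = as.integer(green_per_nucleus),
         dot_sigma = dot_sigma, dot_peak = dot_peak,
         background_level = background_level, noise_sigma = noise_sigma,
         overlap_fraction = overlap_fraction, no_dapi = no_dapi,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Render one Gaussian probe dot onto a canvas
#'
#' Adds `peak * exp(-d^2 / (2 sigma^2))`, truncated at distance `4 sigma`
#' from the centre, to the canvas. Purely additive; the caller clips the
#' finished channel to `[0, 1]` once all dots and noise are in place.
#'
#' @param canvas Numeric matrix.
#' @param center 0-based `(row, col)` of the dot centre.
#' @param sigma Gaussian width (pixels).
#' @param peak Peak amplitude.
#' @return The updated canvas.
#' @export
render_dot <- function(canvas, center, sigma, peak) {
  r4 <- 4 * sigma
  nr <- nrow(canvas); nc <- ncol(canvas)
  cr <- center[1]; cc <- center[2]
  if (cr < 0 || cr > nr - 1 || cc < 0 || cc > nc - 1) {
    stop("dot centre outside canvas")
  }
  r0 <- max(1L, floor(cr - r4) + 1L); r1 <- min(nr, ceiling(cr + r4) + 1L)
  c0 <- max(1L, floor(cc - r4) + 1L); c1 <- min(nc, ceiling(cc + r4) + 1L)
  rows <- r0:r1; cols <- c0:c1
  d2 <- outer((rows - 1 - cr)^2, (cols - 1 - cc)^2, `+`)
  g <- peak * exp(-d2 / (2 * sigma^2))
  g[d2 > r4^2] <- 0
  canvas[rows, cols] <- canvas[rows, cols] + g
  canvas
}

# Sample a point uniformly inside the ellipse (centre, semiaxes a, b,
# rotation theta), shrunk by `margin` pixels on each semiaxis.
sample_in_ellipse <- function(center, a, b, theta, margin) {
  aa <- max(a - margin, 1); bb <- max(b - margin, 1)
  repeat {
    u <- runif(1, -1, 1); v <- runif(1, -1, 1)
    if (u * u + v * v <= 1) break
  }
  x <- u * aa; y <- v * bb
  c(center[1] + x * cos(theta) - y * sin(theta),
    center[2] + x * sin(theta) + y * cos(theta))
}

# Place n dot centres inside a nucleus with pairwise separation >= min_sep.
place_dots <- function(center, a, b, theta, n, margin, min_sep,
                       max_tries = 2000L) {
  pts <- matrix(numeric(0), ncol = 2)
  tries <- 0L
  while (nrow(pts) < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("could not place ", n, " dots with separation ", min_sep,
           " inside a nucleus of semi-axes ", round(a, 1), "/", round(b, 1))
    }
    p <- sample_in_ellipse(center, a, b, theta, margin)
    if (nrow(pts) == 0 ||
        all(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2) >= min_sep)) {
      pts <- rbind(pts, p)
    }
  }
  pts
}

# Rasterise an ellipse: 1-based pixel indices inside it.
ellipse_pixels <- function(nr, nc, center, a, b, theta) {
  r0 <- max(1L, floor(center[1] - a) + 1L)
  r1 <- min(nr, ceiling(center[1] + a) + 1L)
  c0 <- max(1L, floor(center[2] - a) + 1L)
  c1 <- min(nc, ceiling(center[2] + a) + 1L)
  rows <- r0:r1; cols <- c0:c1
  dr <- outer(rows - 1 - center[1], rep(1, length(cols)))
  dc <- outer(rep(1, length(rows)), cols - 1 - center[2])
  x <- dr * cos(theta) + dc * sin(theta)
  y <- -dr * sin(theta) + dc * cos(theta)
  inside <- (x / a)^2 + (y / b)^2 <= 1
  cbind(row = as.integer(row(inside)[inside]) + r0 - 1L,
        col = as.integer(col(inside)[inside]) + c0 - 1L)
}

#' Generate a synthetic FISH case with exact ground truth
#'
#' Places non-overlapping elliptical nuclei away from the border, fills the
#' blue channel with a textured nuclear stain (unless `no_dapi`), renders
#' the requested red and green Gaussian dots inside each nucleus, adds
#' Gaussian noise to every channel, clips to `[0, 1]` and quantises to a
#' 16-bit [rgb_image()]. Dots of the same channel are kept at least 9 px
#' apart (well separated at the default dot width) except for deliberately
#' overlapping red pairs controlled by `overlap_fraction`. Bit-identical
#' for a fixed spec; the caller's RNG state is left untouched.
#'
#' @param spec A [synthetic_spec()].
#' @return A list: `image` (an `rgb_image`) and `truth` with per-nucleus
#'   (`id`, `row`, `col`, `a`, `b`, `theta`, `true_red`, `true_green`) and
#'   per-dot (`channel`, `row`, `col`, `nucleus_id`) data frames.
#' @export
generate_case <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- get0(".Random.seed", globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(spec$seed)

  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  n <- spec$n_nuclei
  reds <- rep_len(spec$red_per_nucleus, n)
  greens <- rep_len(spec$green_per_nucleus, n)
  rlo <- spec$nucleus_radius_range[1]; rhi <- spec$nucleus_radius_range[2]

  # nucleus placement: rejection sampling, no mutual overlap, off-border
  nuc <- data.frame(id = integer(), row = numeric(), col = numeric(),
                    a = numeric(), b = numeric(), theta = numeric())
  tries <- 0L
  while (nrow(nuc) < n) {
    tries <- tries + 1L
    if (tries > 20000L) {
      stop("could not place ", n, " non-overlapping nuclei in a ",
           nr, "x", nc, " image; enlarge the image or reduce n_nuclei")
    }
    a <- runif(1, rlo, rhi)
    b <- a / runif(1, 1, 1.4)
    theta <- runif(1, 0, pi)
    margin <- a + 6
    if (2 * margin >= min(nr, nc)) {
      stop("nuclei too large for the image")
    }
    cr <- runif(1, margin, nr - 1 - margin)
    cc <- runif(1, margin, nc - 1 - margin)
    if (nrow(nuc) > 0) {
      d <- sqrt((nuc$row - cr)^2 + (nuc$col - cc)^2)
      if (any(d < nuc$a + a + 4)) next
    }
    nuc <- rbind(nuc, data.frame(id = nrow(nuc) + 1L, row = cr, col = cc,
                                 a = a, b = b, theta = theta))
  }

  blue <- matrix(0, nr, nc)
  if (!spec$no_dapi) {
    for (i in seq_len(n)) {
      px <- ellipse_pixels(nr, nc, c(nuc$row[i], nuc$col[i]),
                           nuc$a[i], nuc$b[i], nuc$theta[i])
      fill <- 0.7 * (1 + 0.12 * rnorm(nrow(px)))
      blue[px] <- pmin(pmax(fill, 0), 1)
    }
  }

  red <- matrix(spec$background_level, nr, nc)
  green <- matrix(spec$background_level, nr, nc)
  dots <- data.frame(channel = character(), row = numeric(),
                     col = numeric(), nucleus_id = integer())
  min_sep <- 9
  dot_margin <- 4
  for (i in seq_len(n)) {
    ctr <- c(nuc$row[i], nuc$col[i])
    geo <- list(a = nuc$a[i], b = nuc$b[i], th = nuc$theta[i])
    # green: always isolated single dots
    if (greens[i] > 0) {
      gp <- place_dots(ctr, geo$a, geo$b, geo$th, greens[i],
                       dot_margin, min_sep)
      for (j in seq_len(nrow(gp))) {
        green <- render_dot(green, gp[j, ], spec$dot_sigma, spec$dot_peak)
        dots <- rbind(dots, data.frame(channel = "green", row = gp[j, 1],
                                       col = gp[j, 2], nucleus_id = i))
      }
    }
    # red: a configurable share rendered overlapping an existing red dot
    if (reds[i] > 0) {
      n_ov <- round(spec$overlap_fraction * reds[i])
      n_ov <- min(n_ov, reds[i] - 1L)
      n_base <- reds[i] - n_ov
      rp <- place_dots(ctr, geo$a, geo$b, geo$th, n_base,
                       dot_margin, min_sep)
      for (j in seq_len(nrow(rp))) {
        red <- render_dot(red, rp[j, ], spec$dot_sigma, spec$dot_peak)
        dots <- rbind(dots, data.frame(channel = "red", row = rp[j, 1],
                                       col = rp[j, 2], nucleus_id = i))
      }
      if (n_ov > 0) {
        for (j in seq_len(n_ov)) {
          host <- rp[sample.int(nrow(rp), 1L), ]
          ang <- runif(1, 0, 2 * pi)
          p <- host + 1.5 * spec$dot_sigma * c(cos(ang), sin(ang))
          red <- render_dot(red, p, spec$dot_sigma, spec$dot_peak)
          dots <- rbind(dots, data.frame(channel = "red", row = p[1],
                                         col = p[2], nucleus_id = i))
        }
      }
    }
  }

  if (spec$noise_sigma > 0) {
    blue <- blue + matrix(rnorm(nr * nc, 0, spec$noise_sigma), nr, nc)
    red <- red + matrix(rnorm(nr * nc, 0, spec$noise_sigma), nr, nc)
    green <- green + matrix(rnorm(nr * nc, 0, spec$noise_sigma), nr, nc)
  }
  clip01 <- function(x) pmin(pmax(x, 0), 1)
  q16 <- function(x) round(clip01(x) * 65535)

  nuc$true_red <- reds
  nuc$true_green <- greens
  list(
    image = rgb_image(q16(red), q16(green), q16(blue), bit_depth = 16L),
    truth = list(nuclei = nuc, dots = dots)
  )
}
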