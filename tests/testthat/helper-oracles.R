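# Independent oracles and fixture builders used across the test files.
# The oracles reproduce the package's documented border policy (symmetric,
# edge-inclusive mirror padding) but share no code with the implementation.

# Mirror an out-of-range index back into 1..n (edge-inclusive reflection).
reflect_index <- function(i, n) {
  while (i < 1L || i > n) {
    if (i < 1L) i <- 1L - i
    if (i > n) i <- 2L * n + 1L - i
  }
  i
}

disk_offsets <- function(r) {
  g <- expand.grid(di = (-r):r, dj = (-r):r)
  g[g$di^2 + g$dj^2 <= r^2, , drop = FALSE]
}

# Fully naive sliding min/max over a disk: triple loop, used on tiny inputs
# to cross-check the faster shift oracle below.
naive_stage <- function(I, r, f) {
  off <- disk_offsets(r)
  nr <- nrow(I); nc <- ncol(I)
  out <- I
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      v <- numeric(nrow(off))
      for (o in seq_len(nrow(off))) {
        v[o] <- I[reflect_index(i + off$di[o], nr),
                  reflect_index(j + off$dj[o], nc)]
      }
      out[i, j] <- f(v)
    }
  }
  out
}

naive_open <- function(I, r) naive_stage(naive_stage(I, r, min), r, max)
naive_close <- function(I, r) naive_stage(naive_stage(I, r, max), r, min)

# Shift-accumulate sliding min/max over a disk with explicit reflected
# index vectors; fast enough for hundreds of images.
shift_stage <- function(I, r, f) {
  nr <- nrow(I); nc <- ncol(I)
  ridx <- vapply((1L - r):(nr + r), reflect_index, integer(1), n = nr)
  cidx <- vapply((1L - r):(nc + r), reflect_index, integer(1), n = nc)
  P <- I[ridx, cidx, drop = FALSE]
  off <- disk_offsets(r)
  acc <- NULL
  for (o in seq_len(nrow(off))) {
    s <- P[(r + 1L + off$di[o]):(r + nr + off$di[o]),
           (r + 1L + off$dj[o]):(r + nc + off$dj[o]), drop = FALSE]
    acc <- if (is.null(acc)) s else f(acc, s)
  }
  acc
}

oracle_open <- function(I, r) shift_stage(shift_stage(I, r, pmin), r, pmax)
oracle_close <- function(I, r) shift_stage(shift_stage(I, r, pmax), r, pmin)

# Brute-force windowed sum (rectangular window, symmetric padding).
oracle_window_sum <- function(I, k) {
  nr <- nrow(I); nc <- ncol(I)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      s <- 0
      for (di in (-k):k) {
        for (dj in (-k):k) {
          s <- s + I[reflect_index(i + di, nr), reflect_index(j + dj, nc)]
        }
      }
      out[i, j] <- s
    }
  }
  out
}

# Brute-force box-occupancy count: number of delta x delta grid boxes
# (origin-anchored, partial boxes included) holding at least one pixel of
# the given bin.
oracle_box_count <- function(bins, bin, delta) {
  idx <- which(bins == bin, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(0L)
  boxes <- unique(cbind((idx[, 1] - 1L) %/% delta, (idx[, 2] - 1L) %/% delta))
  nrow(boxes)
}

ls_slope <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * y) / sum(xc^2)
}

# Paint a filled disc of the given value onto a matrix (1-based centre).
draw_disc <- function(m, center, radius, value = 1) {
  nr <- nrow(m); nc <- ncol(m)
  for (i in max(1, floor(center[1] - radius)):min(nr, ceiling(center[1] + radius))) {
    for (j in max(1, floor(center[2] - radius)):min(nc, ceiling(center[2] + radius))) {
      if ((i - center[1])^2 + (j - center[2])^2 <= radius^2) m[i, j] <- value
    }
  }
  m
}

# A single-nucleus fixture: disc nucleus label map plus a probe channel
# with dots at the requested (1-based) centres.
single_nucleus_fixture <- function(size = 101L, nucleus_radius = 35,
                                   dot_centers = list(),
                                   background = 0.2, peak = 0.6,
                                   sigma = 1.5) {
  labels <- matrix(0L, size, size)
  ctr <- c((size + 1) / 2, (size + 1) / 2)
  labels <- draw_disc(labels, ctr, nucleus_radius, 1L)
  feats <- fishdots:::region_features(labels)
  nuclei <- fishdots:::new_nucleus_map(labels, feats)
  channel <- matrix(background, size, size)
  for (ct in dot_centers) {
    channel <- render_dot(channel, c(ct[1] - 1, ct[2] - 1), sigma, peak)
  }
  list(nuclei = nuclei, channel = pmin(channel, 1))
}
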