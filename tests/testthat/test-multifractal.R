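test_that("local measures match brute-force windowed statistics", {
  c0 <- matrix(0.3, 8, 8)
  expect_equal(local_measure(c0, 1, "sum"), matrix(9 * 0.3, 8, 8))
  expect_equal(local_measure(c0, 1, "max"), c0)
  expect_equal(local_measure(c0, 2, "min"), c0)

  set.seed(5)
  I <- matrix(runif(64), 8, 8)
  for (k in 1:2) {
    expect_equal(local_measure(I, k, "sum"), oracle_window_sum(I, k))
  }
  # floor guards against log(0)
  z <- matrix(0, 6, 6)
  expect_true(all(local_measure(z, 1, "sum", measure_floor = 1e-12) == 1e-12))
})

test_that("Hoelder exponents hit their analytic limits", {
  c0 <- matrix(0.37, 32, 32)
  a_sum <- holder_alpha(c0, mf_params(measure = "sum"))
  expect_lt(max(abs(a_sum$values - 2)), 1e-9) # mu ~ eps^2 for a constant

  a_max <- holder_alpha(c0, mf_params(measure = "max"))
  expect_lt(max(abs(a_max$values)), 1e-9) # mu constant in eps

  expect_error(mf_params(window_halfwidths = 2), "at least two")

  # an isolated bright spike has a lower exponent than the flat background
  sp <- matrix(0.1, 32, 32); sp[16, 16] <- 1
  a <- holder_alpha(sp, mf_params())
  expect_lt(a$values[16, 16], min(a$values[1:4, 1:4]))
  # direct slope at the spike: windowed sums computed by the oracle
  mus <- sapply(0:3, function(k) oracle_window_sum(sp, k)[16, 16])
  expect_equal(a$values[16, 16], ls_slope(log(2 * (0:3) + 1), log(mus)))
})

test_that("spectrum estimation matches box-counting oracles and conventions", {
  # full-support set: box dimension 2
  c0 <- matrix(0.5, 128, 128)
  s <- mf_spectrum(holder_alpha(c0), mf_params())
  expect_equal(length(s$f_per_bin), 1L) # degenerate alpha range -> single bin
  expect_lt(abs(s$f_per_bin[1] - 2), 0.1)
  expect_true(all(s$values == s$f_per_bin[1]))

  # 4 isolated marked pixels: N_delta = 4 at every delta -> f ~ 0
  sp <- matrix(0.1, 64, 64)
  for (ct in list(c(8, 8), c(8, 56), c(56, 8), c(56, 56))) sp[ct[1], ct[2]] <- 1
  a <- holder_alpha(sp)
  s2 <- mf_spectrum(a, mf_params())
  spike_bins <- unique(findInterval(
    a$values[cbind(c(8, 8, 56, 56), c(8, 56, 8, 56))],
    s2$bin_edges, rightmost.closed = TRUE
  ))
  expect_lt(max(abs(s2$f_per_bin[spike_bins])), 0.15)

  # exact agreement with a brute-force box-count oracle on a random 64x64 field
  set.seed(17)
  I <- matrix(runif(64 * 64), 64, 64)
  p <- mf_params(n_bins = 20)
  a2 <- holder_alpha(I, p)
  s3 <- mf_spectrum(a2, p)
  edges <- s3$bin_edges
  bins <- matrix(pmin(pmax(findInterval(a2$values, edges, rightmost.closed = TRUE), 1L), 20L), 64, 64)
  for (b in 1:20) {
    N <- sapply(p$box_sizes, function(d) oracle_box_count(bins, b, d))
    f_expected <- if (N[1] == 0) 0 else ls_slope(log(1 / p$box_sizes), log(N))
    expect_equal(s3$f_per_bin[b], f_expected)
  }
  # spectrum values never exceed the embedding dimension bound
  expect_lt(max(s3$f_per_bin), 2 + 0.1)
  expect_true(all(s3$values == s3$f_per_bin[bins]))
})

test_that("inverse selection honors tails, the f gate, and monotonicity", {
  set.seed(29)
  I <- matrix(runif(32 * 32), 32, 32)
  a <- holder_alpha(I)
  s <- mf_spectrum(a, mf_params())

  none <- inverse_select(a, s, mf_params(alpha_percentile = 0, alpha_tail = "low"))
  expect_false(any(none))

  all_sel <- inverse_select(a, s, mf_params(alpha_percentile = 0,
                                            alpha_tail = "high", f_max = Inf))
  expect_true(all(all_sel))

  # enlarging the low-tail percentile never shrinks the selection
  prev <- none
  for (pct in c(1, 5, 20, 50, 100)) {
    cur <- inverse_select(a, s, mf_params(alpha_percentile = pct,
                                          alpha_tail = "low", f_max = Inf))
    expect_true(all(cur[prev]))
    prev <- cur
  }

  # spike fixture: low tail at 5% with the f gate keeps the spike,
  # drops the background mode
  sp <- matrix(0.1, 64, 64); sp[32, 32] <- 1
  a2 <- holder_alpha(sp)
  s2 <- mf_spectrum(a2, mf_params())
  sel <- inverse_select(a2, s2, mf_params(alpha_percentile = 5, f_max = 1))
  expect_true(sel[32, 32])
  expect_false(any(sel[1:8, 1:8]))
})

test_that("IMF dot detection recovers planted dots inside nuclei only", {
  set.seed(41)
  fx <- single_nucleus_fixture(
    size = 151, nucleus_radius = 45,
    dot_centers = list(c(60, 60), c(90, 95)),
    background = 0.1, peak = 0.8
  )
  noisy <- pmin(pmax(fx$channel +
                       matrix(rnorm(151^2, 0, 0.02), 151, 151), 0), 1)
  dots <- detect_dots_imf(noisy, fx$nuclei, channel_name = "red")
  expect_equal(nrow(dots), 2L)
  expect_true(all(dots$nucleus_id == 1L))

  # flat nucleus: nothing selected, no error
  flat <- single_nucleus_fixture(size = 101, nucleus_radius = 35,
                                 background = 0.1)
  expect_equal(nrow(detect_dots_imf(flat$channel, flat$nuclei)), 0L)

  # dots outside every nucleus are excluded by the mask rule
  out <- single_nucleus_fixture(size = 151, nucleus_radius = 30,
                                dot_centers = list(c(10, 10)),
                                background = 0.1, peak = 0.8)
  expect_equal(nrow(detect_dots_imf(out$channel, out$nuclei)), 0L)
})
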