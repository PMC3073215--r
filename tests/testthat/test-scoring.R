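two_nucleus_map <- function() {
  labels <- matrix(0L, 60, 60)
  labels <- draw_disc(labels, c(20, 20), 10, 1L)
  labels <- draw_disc(labels, c(40, 45), 10, 2L)
  fishdots:::new_nucleus_map(labels, fishdots:::region_features(labels))
}

test_that("dots are assigned by centroid membership", {
  nuc <- two_nucleus_map()
  dots <- fishdots:::dot_records(
    channel = c("red", "red", "green", "red"),
    row = c(19, 21, 20, 2), col = c(19, 20, 21, 2),
    area = c(6L, 6L, 6L, 6L), nucleus_id = NA_integer_, est_count = 1L
  )
  out <- assign_dots(dots, nuc)
  expect_equal(out$nucleus_id[1:3], c(1L, 1L, 1L))
  expect_true(is.na(out$nucleus_id[4])) # background centroid -> none
  sc <- nucleus_scores(out, nuc)
  expect_equal(sc$red_count, c(2L, 0L))
  expect_equal(sc$green_count, c(1L, 0L))
  expect_error(
    assign_dots(fishdots:::dot_records("red", 500, 5, 4L, NA_integer_, 1L), nuc),
    "outside image"
  )
})

test_that("per-nucleus ratios follow the counting arithmetic and exclusion rule", {
  nuc <- two_nucleus_map()
  mk <- function(n_red1, n_green1, n_red2, n_green2) {
    fishdots:::dot_records(
      channel = c(rep("red", n_red1), rep("green", n_green1),
                  rep("red", n_red2), rep("green", n_green2)),
      row = c(rep(20, n_red1 + n_green1), rep(40, n_red2 + n_green2)),
      col = c(rep(20, n_red1 + n_green1), rep(45, n_red2 + n_green2)),
      area = 6L, nucleus_id = NA_integer_, est_count = 1L
    )
  }
  sc <- nucleus_scores(assign_dots(mk(4, 2, 2, 2), nuc), nuc)
  expect_equal(sc$ratio, c(2, 1))
  expect_false(any(sc$excluded))

  # no green signal -> ratio undefined, nucleus excluded
  sc2 <- nucleus_scores(assign_dots(mk(3, 0, 2, 1), nuc), nuc)
  expect_true(sc2$excluded[1])
  expect_true(is.na(sc2$ratio[1]))
  expect_equal(sc2$ratio[2], 2)

  # scale equivariance: doubling every count leaves ratios unchanged
  d <- assign_dots(mk(4, 2, 6, 2), nuc)
  d2 <- d; d2$est_count <- 2L
  expect_equal(nucleus_scores(d, nuc)$ratio, nucleus_scores(d2, nuc)$ratio)
})

test_that("case scoring averages ratios, truncates at max_cells, and errors when unscorable", {
  mk_scores <- function(ratios) {
    data.frame(nucleus_id = seq_along(ratios),
               red_count = as.integer(round(ratios * 2)),
               green_count = 2L, ratio = ratios, excluded = is.na(ratios))
  }
  cs <- case_score(mk_scores(c(2, 2, 2)))
  expect_equal(cs$mean_ratio, 2)
  expect_equal(cs$status, "equivocal")
  expect_equal(cs$n_nuclei_used, 3L)
  expect_match(cs$qc_warnings, "only 3 scorable")

  # identical ratios give that ratio exactly, any n
  for (n in c(1, 7, 60)) {
    expect_equal(case_score(mk_scores(rep(1.3, n)))$mean_ratio, 1.3)
  }

  # 70 nuclei, cap 60: first 60 in nucleus order are used
  cs70 <- case_score(mk_scores(c(rep(1, 60), rep(9, 10))), max_cells = 60)
  expect_equal(cs70$n_nuclei_used, 60L)
  expect_equal(cs70$mean_ratio, 1)

  # excluded nuclei are skipped, not averaged as zero
  cs_ex <- case_score(mk_scores(c(NA, 2.5, NA, 3.5)))
  expect_equal(cs_ex$mean_ratio, 3)

  expect_error(case_score(mk_scores(c(NA, NA))),
               class = "fishdots_unscorable")
  err <- tryCatch(case_score(mk_scores(NA_real_), qc_warnings = "img: no DAPI"),
                  fishdots_unscorable = function(e) e)
  expect_equal(err$qc_warnings, "img: no DAPI")

  # ratio of sums differs under heterogeneity and is available as a mode
  het <- data.frame(nucleus_id = 1:2, red_count = c(8L, 2L),
                    green_count = c(2L, 2L), ratio = c(4, 1),
                    excluded = FALSE)
  expect_equal(case_score(het)$mean_ratio, 2.5)
  expect_equal(case_score(het, mode = "ratio_of_sums")$mean_ratio, 10 / 4)
})

test_that("classification follows the 1.8/2.2 bands with an inclusive equivocal zone", {
  expect_equal(classify_ratio(2.5), "amplified")
  expect_equal(classify_ratio(1.0), "non_amplified")
  expect_equal(classify_ratio(2.0), "equivocal")
  expect_equal(classify_ratio(1.8), "equivocal") # boundaries are equivocal
  expect_equal(classify_ratio(2.2), "equivocal")
  expect_equal(classify_ratio(c(0, 1.79, 2.21)),
               c("non_amplified", "non_amplified", "amplified"))
  expect_error(classify_ratio(-0.1), "non-negative")
})

test_that("the naive area estimator rounds against a reference dot area", {
  expect_equal(estimate_count(10, 10), 1L)
  expect_equal(estimate_count(19, 10), 2L)
  expect_equal(estimate_count(4, 10), 1L) # floored at one copy
  expect_equal(estimate_count(c(10, 19, 35), 10), c(1L, 2L, 4L))
  expect_error(estimate_count(10, 0), "positive")
})
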