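test_that("group threshold applies the >=50% rule on the published series", {
  ss <- worked_sessions()
  expect_equal(group_threshold(ss$phenylethyl_acetate), 1.0)
  # exactly 10 of 20 qualifies at 1 mg/L
  expect_equal(group_threshold(ss$menthyl_acetate), 1.0)
  # rule never met: censored above the top concentration
  low <- panel_session(c(0, 0.1, 1, 10), counts = c(0, 1, 3, 6),
                       n_panelists = 20)
  thr <- group_threshold(low)
  expect_true(is.infinite(thr))
  expect_match(attr(thr, "censored"), "> 10")
})

test_that("monotone reconstruction is exact and round-trips the counts", {
  counts <- c(0, 6, 18, 20)
  D <- reconstruct_monotone(counts, 20)
  expect_equal(colSums(D), counts)
  expect_equal(dim(D), c(20L, 4L))
  # per-panelist monotone profiles
  expect_true(all(apply(D, 1, function(r) !is.unsorted(r))))
  expect_equal(reconstruct_monotone(c(0, 0, 0), 5), matrix(0L, 5, 3))
  expect_equal(colSums(reconstruct_monotone(c(0, 20), 20)), c(0, 20))
  expect_error(reconstruct_monotone(c(5, 3), 20), "decrease")
})

test_that("panelist bootstrap reproduces the published confidence intervals", {
  ss <- worked_sessions()
  b1 <- bootstrap_threshold_ci(ss$phenylethyl_acetate, B = 10000, seed = 42)
  expect_equal(b1$ci_low, 0.10)
  expect_equal(b1$ci_high, 1.0)
  expect_equal(b1$bootstrap_median, 1.0)
  b2 <- bootstrap_threshold_ci(ss$menthyl_acetate, B = 10000, seed = 42)
  expect_equal(b2$ci_low, 1.0)
  expect_equal(b2$ci_high, 10.0)
  expect_equal(b2$bootstrap_median, 1.0)
  expect_true(b1$reconstructed)
})

test_that("identical panelists give a degenerate bootstrap interval", {
  D <- matrix(rep(c(0L, 1L, 1L, 1L), each = 20), nrow = 20)
  s <- panel_session(c(0, 1, 10, 100), detection = D)
  b <- bootstrap_threshold_ci(s, B = 2000, seed = 1)
  expect_equal(b$ci_low, b$ci_high)
  expect_equal(b$ci_low, group_threshold(s))
})

test_that("flipping a detection from no to yes never raises the threshold", {
  set.seed(8)
  for (rep_i in 1:20) {
    counts <- sort(sample(0:20, 5, replace = TRUE))
    s <- panel_session(c(0, 0.1, 1, 10, 100), counts = c(0, counts[1:4]),
                       n_panelists = 20)
    t0 <- group_threshold(s)
    D <- s$detection
    zero <- which(D == 0 & col(D) > 1)
    if (!length(zero)) next
    D[sample(zero, 1)] <- 1L
    t1 <- group_threshold(panel_session(s$concentrations, detection = D))
    expect_lte(t1, t0)
  }
})

test_that("descriptor tallies and intensity summaries match their data", {
  ss <- worked_sessions()
  tly <- descriptor_tally(ss$phenylethyl_acetate)
  expect_equal(unname(tly[["1"]]["floral"]), 10L)
  expect_equal(unname(tly[["1"]]["sweet"]), 3L)
  s <- panel_session(c(0, 1), counts = c(0, 2), n_panelists = 3,
                     intensity = list(rep(0, 3), c(2, 3, 4)))
  isum <- intensity_summary(s)
  expect_equal(isum$mean, c(0, 3))
  expect_equal(isum$sd[2], 1)
  s1 <- panel_session(c(0, 1), counts = c(0, 1), n_panelists = 1,
                      intensity = list(0, 3))
  isum1 <- intensity_summary(s1)
  expect_equal(isum1$sd[2], 0)        # single rating: SD 0 by convention
  expect_false(isum1$sd_defined[2])
})

test_that("session IO round-trips both CSV dialects", {
  path <- withr::local_tempfile(fileext = ".csv")
  long <- expand.grid(panelist_id = 1:4, concentration_mg_L = c(0, 1, 10))
  long$detected <- as.integer(long$concentration_mg_L >= 1 &
                              long$panelist_id <= 3)
  write.csv(long, path, row.names = FALSE)
  s <- read_panel_session(path)
  expect_equal(colSums(s$detection), c(0, 3, 3))
  counts_path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(concentration_mg_L = c(0, 1, 10),
                       detected_count = c(0, 3, 3), n_panelists = 4),
            counts_path, row.names = FALSE)
  s2 <- read_panel_session(counts_path)
  expect_equal(colSums(s2$detection), colSums(s$detection))
})
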