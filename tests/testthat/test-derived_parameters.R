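test_that("mean MGS averages all scored cells and excludes missing ones", {
  expect_equal(mgs_mean(make_grimace(rep(0, 50), 10)), 0)
  expect_equal(mgs_mean(make_grimace(rep(2, 50), 10)), 2)

  set.seed(11)
  vals <- sample(0:2, 50, replace = TRUE)
  vals[c(3, 17, 41)] <- NA
  fix <- make_grimace(vals, 10)
  expect_equal(mgs_mean(fix), sum(vals, na.rm = TRUE) / 47)

  # bounded by the observed cells, invariant to image order
  expect_gte(mgs_mean(fix), min(vals, na.rm = TRUE))
  expect_lte(mgs_mean(fix), max(vals, na.rm = TRUE))
  expect_equal(mgs_mean(fix[sample(10), ]), mgs_mean(fix))

  expect_error(mgs_mean(make_grimace(rep(NA_real_, 10), 2)),
               "no assessable")
  expect_error(grimace_scores(make_grimace(rep(0, 55), 11)), "at most 10")
  expect_error(grimace_scores(make_grimace(rep(0.5, 10), 2)), "0, 1, 2")
})

test_that("sum MGS adds per-unit means, with and without whiskers", {
  expect_equal(mgs_sum(make_grimace(rep(0, 50), 10)), 0)
  expect_equal(mgs_sum(make_grimace(rep(0, 50), 10), include_whiskers = FALSE), 0)

  ones <- make_grimace(rep(1, 50), 10)
  expect_equal(mgs_sum(ones), 5)
  expect_equal(mgs_sum(ones, include_whiskers = FALSE), 4)

  set.seed(12)
  vals <- sample(0:2, 40, replace = TRUE)
  vals[c(2, 9, 33)] <- NA
  fix <- make_grimace(vals, 8)
  expect_equal(mgs_sum(fix), sum(colMeans(fix, na.rm = TRUE)))

  # whisker identity over random partially-missing fixtures
  for (i in 1:20) {
    v <- sample(c(0:2, NA), 50, replace = TRUE)
    if (all(is.na(v))) next
    f <- make_grimace(v, 10)
    if (all(is.na(f[, "whisker_change"]))) next
    expect_equal(mgs_sum(f) - mgs_sum(f, include_whiskers = FALSE),
                 mean(f[, "whisker_change"], na.rm = TRUE))
  }
})

test_that("body weight change is relative to the mean baseline weight", {
  expect_equal(body_weight_change(25, c(24, 25, 26)), 0)
  expect_equal(body_weight_change(27.5, 25), 10)

  baseline <- c(24.1, 24.6, 25.0, 25.3, 25.5)
  series <- c(24.0, 23.1, 22.8, 23.5, 24.2, 24.9)
  expect_equal(body_weight_change(series, baseline),
               100 * (series - mean(baseline)) / mean(baseline))
  # baseline points themselves average to exactly zero change
  expect_equal(mean(body_weight_change(baseline, baseline)), 0)

  expect_error(body_weight_change(-1, 25), "positive")
  expect_error(body_weight_change(25, numeric()), "empty")
})

test_that("burrowing latency applies both episode rules and censors", {
  empty <- burrowing_log(window = 72000)
  expect_equal(burrowing_latency(empty), list(latency = 72000, censored = TRUE))

  one <- burrowing_log(100, 115, window = 72000)
  expect_equal(burrowing_latency(one), list(latency = 100, censored = FALSE))

  # 8 s + 14 s bouts bridged by a 4 s break: 22 s total, starts at 50
  chain <- burrowing_log(c(50, 62), c(58, 76), window = 72000)
  expect_equal(burrowing_latency(chain), list(latency = 50, censored = FALSE))

  # break longer than 5 s separates episodes; second bout qualifies alone
  split <- burrowing_log(c(0, 14), c(8, 28), window = 72000)
  expect_equal(burrowing_latency(split), list(latency = 14, censored = FALSE))

  # thresholds are strict: exactly 10 s alone and exactly 20 s bridged fail
  expect_true(burrowing_latency(burrowing_log(5, 15, 600))$censored)
  expect_true(burrowing_latency(burrowing_log(c(0, 14), c(10, 24), 600))$censored)
  # a break of exactly 5 s still bridges
  expect_equal(
    burrowing_latency(burrowing_log(c(0, 13), c(8, 26.5), 600))$latency, 0)

  expect_error(burrowing_log(10, 5), "exceed")
  expect_error(burrowing_log(c(0, 5), c(6, 9)), "non-overlapping")
})

test_that("burrowing latency matches the exhaustive episode-scan oracle", {
  set.seed(77)
  for (i in 1:200) {
    log <- random_log()
    got <- burrowing_latency(log)
    want <- oracle_latency(log$starts, log$ends, log$window)
    expect_equal(got, want)
    expect_lte(got$latency, log$window)
    # dropping a bout can only delay (or preserve) the latency
    if (length(log$starts) > 1) {
      drop <- sample(length(log$starts), 1)
      thinned <- burrowing_log(log$starts[-drop], log$ends[-drop], log$window)
      expect_gte(burrowing_latency(thinned)$latency, got$latency)
    }
  }
})

test_that("delta burrowing latency is a plain difference", {
  expect_equal(delta_burrowing_latency(5000, 5000), 0)
  expect_equal(delta_burrowing_latency(72000, 300), 71700)
  post <- burrowing_latency(burrowing_log(window = 72000))
  base <- burrowing_latency(burrowing_log(100, 120, window = 72000))
  expect_equal(delta_burrowing_latency(post, base), 71900)
})

test_that("drinking water concentration follows dose, weight and intake", {
  expect_equal(drinking_water_concentration(0, 25, 5), 0)
  expect_equal(drinking_water_concentration(25, 26.36, 5.324),
               25 * 0.02636 / 5.324)
  expect_equal(drinking_water_concentration(25, 21.04, 4.201),
               25 * 0.02104 / 4.201)
  # drip correction reduces the effective intake
  expect_equal(drinking_water_concentration(25, 25, 5.5, drip_correction_g = 0.5),
               drinking_water_concentration(25, 25, 5))
  expect_error(drinking_water_concentration(25, 25, 0), "positive")
})
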