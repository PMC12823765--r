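test_that("bias-corrected filling recovers withheld truth exactly for a constant offset", {
  dates <- as.Date("2001-01-01") + 0:59
  set.seed(3)
  truth <- 5 + 5 * sin(seq(0, 2, length.out = 60)) + rnorm(60, 0, 2)
  for (c_off in c(-2.5, 0, 1.5)) {
    target <- make_daily(dates, truth, truth + 8)
    aux <- make_daily(dates, truth + c_off, truth + 8 + c_off, "AUX")
    withheld <- c(10, 31, 60)
    target$tmin[withheld] <- NA
    target$tmax[withheld] <- NA
    filled <- fill_gaps_bias_corrected(target, aux, window_days = 15)
    expect_equal(filled$tmin[withheld], truth[withheld], tolerance = 1e-9)
    expect_equal(filled$tmax[withheld], truth[withheld] + 8,
                 tolerance = 1e-9)
    expect_identical(unique(filled$tmin_src[withheld]), "aux-filled")
    qc <- attr(filled, "qc")
    expect_identical(nrow(qc), 6L)  # three gaps, two variables
    expect_equal(qc$bias, rep(c_off, 6), tolerance = 1e-9)
    expect_false(any(qc$flagged))
  }
})

test_that("filling is an identity on complete series and idempotent", {
  dates <- as.Date("2001-06-01") + 0:29
  target <- make_daily(dates, rnorm(30, 10), rnorm(30, 20))
  aux <- make_daily(dates, rnorm(30, 11), rnorm(30, 21), "AUX")
  out <- fill_gaps_bias_corrected(target, aux)
  expect_equal(out$tmin, target$tmin)
  expect_identical(nrow(attr(out, "qc")), 0L)
  # idempotence on a series with gaps
  target$tmin[5] <- NA
  once <- fill_gaps_bias_corrected(target, aux)
  twice <- fill_gaps_bias_corrected(once[names(target)], aux)
  expect_equal(twice$tmin, once$tmin)
})

test_that("filling flags large biases and unfillable gaps", {
  dates <- as.Date("2001-01-01") + 0:19
  target <- make_daily(dates, rep(0, 20), rep(10, 20))
  aux <- make_daily(dates, rep(5, 20), rep(15, 20), "AUX")  # bias +5
  target$tmin[10] <- NA
  filled <- fill_gaps_bias_corrected(target, aux)
  qc <- attr(filled, "qc")
  expect_true(qc$flagged[1])
  expect_equal(filled$tmin[10], 0)   # corrected despite the flag
  # no overlap in the window: gap stays missing
  aux2 <- aux
  aux2$tmin[1:20] <- NA
  target2 <- make_daily(dates, rep(0, 20), rep(10, 20))
  target2$tmin[10] <- NA
  filled2 <- fill_gaps_bias_corrected(target2, aux2)
  expect_true(is.na(filled2$tmin[10]))
  expect_true(attr(filled2, "qc")$flagged[1])
  expect_error(fill_gaps_bias_corrected(target, aux, window_days = 14),
               "odd")
})

test_that("the auxiliary station with most shared days wins", {
  dates <- as.Date("2001-01-01") + 0:14
  target <- make_daily(dates, rep(10, 15), rep(20, 15))
  target$tmin[8] <- NA
  sparse <- make_daily(dates, rep(12, 15), rep(22, 15), "SPARSE")
  sparse$tmin[c(1:5, 11:15)] <- NA      # 4 shared days, bias +2
  rich <- make_daily(dates, rep(17, 15), rep(27, 15), "RICH")  # bias +7
  filled <- fill_gaps_bias_corrected(target, list(sparse, rich))
  qc <- attr(filled, "qc")
  expect_identical(qc$aux_station, "RICH")
  expect_equal(filled$tmin[8], 10)
})

test_that("linear interpolation fills interior gaps only", {
  dates <- as.Date("2002-01-01") + 0:3
  s <- make_daily(dates, c(0, NA, NA, 9), c(4, NA, 8, 14))
  out <- interpolate_linear(s)
  expect_equal(out$tmin, c(0, 3, 6, 9))
  expect_equal(out$tmax, c(4, 6, 8, 14))
  expect_identical(out$tmin_src[2], "interpolated")
  # no gaps: identity
  s2 <- make_daily(dates, 1:4, 11:14)
  expect_equal(interpolate_linear(s2)$tmin, 1:4)
  # leading/trailing gaps stay missing and are reported
  s3 <- make_daily(dates, c(NA, 2, 3, NA), c(NA, 12, 13, NA))
  out3 <- interpolate_linear(s3)
  expect_true(is.na(out3$tmin[1]) && is.na(out3$tmin[4]))
  expect_length(attr(out3, "unfilled")$tmin, 2)
  s4 <- make_daily(dates, rep(NA_real_, 4), rep(NA_real_, 4))
  expect_error(interpolate_linear(s4), "unusable")
})

test_that("hourly conversion produces 24 values per day and preserves extremes", {
  dates <- as.Date("2003-01-01") + 0:9
  set.seed(5)
  tmin <- rnorm(10, 2, 1)
  tmax <- tmin + runif(10, 6, 10)
  hourly <- daily_to_hourly(make_daily(dates, tmin, tmax), latitude = 40)
  expect_identical(nrow(hourly), 240L)
  expect_false(anyNA(hourly$temp))
  for (d in 1:10) {
    day <- hourly$temp[hourly$date == dates[d]]
    expect_equal(max(day), tmax[d], tolerance = 1e-9)
    lo <- min(tmin[max(d - 1, 1):min(d + 1, 10)])
    expect_gte(min(day), lo - 1e-6)
  }
  # continuity across midnight: no jump exceeding a few degrees
  expect_lt(max(abs(diff(hourly$temp))), 5)
})

test_that("a flat day yields a flat hourly curve and errors name gaps", {
  dates <- as.Date("2003-06-01") + 0:4
  hourly <- daily_to_hourly(make_daily(dates, rep(10, 5), rep(10, 5)),
                            latitude = 50)
  expect_true(all(hourly$temp == 10))
  bad <- make_daily(dates, c(1, NA, 3, 4, 5), rep(12, 5))
  expect_error(daily_to_hourly(bad, 50), "2003-06-02")
  expect_error(daily_to_hourly(make_daily(dates, 1:5, 11:15), 100),
               "latitude")
})

test_that("daylight span from the solar equations is longer in summer", {
  # independent check of the sunrise equation at latitude 40
  oracle_daylength <- function(lat, doy) {
    decl <- -23.44 * pi / 180 * cos(2 * pi * (doy + 10) / 365)
    2 * acos(pmin(1, pmax(-1, -tan(lat * pi / 180) * tan(decl)))) * 12 / pi
  }
  midsummer <- as.integer(format(as.Date("2003-06-21"), "%j"))
  midwinter <- as.integer(format(as.Date("2003-12-21"), "%j"))
  dl <- bloomcast:::daylight_hours(40, c(midsummer, midwinter))
  expect_equal(dl, oracle_daylength(40, c(midsummer, midwinter)),
               tolerance = 1e-9)
  expect_gt(dl[1], 14)
  expect_lt(dl[2], 10)
  expect_gt(dl[1], dl[2])
})
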