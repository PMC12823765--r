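make_test_season <- function(temps, season = 2000) {
  start <- as.Date(sprintf("%d-09-01", season - 1))
  ndays <- length(temps) / 24
  hourly <- data.frame(date = rep(start + 0:(ndays - 1), each = 24),
                       hour = rep(0:23, ndays), temp = temps)
  season_series(hourly, season,
                window_end = format(start + ndays - 1, "%m-%d"))
}

test_that("heat effectiveness is a logistic gate centered at yc", {
  req <- cultivar_requirements(yc = 40, zc = 300, s1 = 1.2)
  expect_equal(heat_effectiveness(40, req), 0.5)
  expect_equal(heat_effectiveness(60, req), 1, tolerance = 1e-6)
  expect_lt(heat_effectiveness(0, req), 1e-6)
  y <- seq(25, 55, by = 0.5)  # inside the unsaturated band
  expect_true(all(diff(heat_effectiveness(y, req)) > 0))
  # shallower transitions leak more heat below the midpoint
  soft <- cultivar_requirements(yc = 40, zc = 300, s1 = 0.1)
  expect_gt(heat_effectiveness(35, soft), heat_effectiveness(35, req))
})

test_that("season construction validates coverage and maps the calendar", {
  temps <- rep(10, 24 * 303)
  s <- make_test_season(temps, season = 1999)  # 1998-09-01..1999-06-30
  expect_s3_class(s, "season_series")
  expect_length(s$temps, 24 * 303)
  expect_equal(s$doy[1], as.numeric(as.Date("1998-09-01") -
                                      as.Date("1999-01-01")) + 1)
  expect_equal(max(s$doy), 181)  # 30 June
  # missing hours are rejected
  hourly <- data.frame(date = rep(as.Date("1998-09-01") + 0:200, each = 24),
                       hour = rep(0:23, 201), temp = 10)
  expect_error(season_series(hourly, 1999), "incomplete")
})

test_that("season simulation predicts bloom like the reference loop", {
  set.seed(11)
  for (i in 1:8) {
    chill <- random_chill_params()
    heat <- random_heat_params()
    req <- cultivar_requirements(yc = runif(1, 10, 40),
                                 zc = runif(1, 100, 400),
                                 s1 = runif(1, 0.1, 1.2))
    temps <- random_season_temps(24 * 150)
    s <- make_test_season(temps)
    pred <- simulate_season(s, chill, heat, req)
    hr <- oracle_bloom_hour(temps, chill, heat, req)
    if (is.na(hr)) {
      expect_identical(pred$status, "no_bloom")
    } else {
      expect_identical(pred$status, "bloom")
      expect_equal(pred$bloom_doy, s$doy[hr])
    }
  }
})

test_that("no forcing means no bloom; bloom is monotone in zc", {
  chill <- default_chill_params()
  heat <- heat_params(Tb = 4, Tu = 26)
  cold <- make_test_season(rep(2, 24 * 200))  # never above Tb
  req <- cultivar_requirements(yc = 5, zc = 100, s1 = 0.5)
  expect_identical(simulate_season(cold, chill, heat, req)$status,
                   "no_bloom")
  # a warm post-chill season blooms earlier under a smaller requirement
  temps <- c(rep(5, 24 * 90), rep(15, 24 * 110))
  s <- make_test_season(temps)
  lo <- simulate_season(s, chill, heat,
                        cultivar_requirements(5, 100, 0.5))
  hi <- simulate_season(s, chill, heat,
                        cultivar_requirements(5, 700, 0.5))
  expect_identical(lo$status, "bloom")
  expect_true(hi$status == "no_bloom" || hi$bloom_doy > lo$bloom_doy)
  tiny_start <- as.Date("1999-12-20")
  tiny <- data.frame(date = rep(tiny_start + 0:19, each = 24),
                     hour = rep(0:23, 20), temp = 10)
  tiny_season <- season_series(tiny, 2000, window_start = "12-20",
                               window_end = "01-08")
  expect_error(simulate_season(tiny_season, chill, heat, req), "30 days")
})

test_that("steep transitions keep chill and heat phases sequential", {
  chill <- default_chill_params()
  heat <- heat_params(Tb = 4, Tu = 26)
  req <- cultivar_requirements(yc = 40, zc = 500, s1 = 1.2)
  # chill phase at 4 degC sits below Tb, so forcing is unavailable until
  # the transition; any pre-transition heat comes from the gate alone
  temps <- c(rep(4, 24 * 110), rep(18, 24 * 90))
  s <- make_test_season(temps)
  pred <- simulate_season(s, chill, heat, req, trajectories = TRUE)
  reach <- which(pred$chill >= req$yc)[1]
  expect_false(is.na(reach))
  expect_lte(pred$heat[reach], 0.02 * req$zc)
})

test_that("temperature response curves follow the fixed-grid contract", {
  chill <- default_chill_params()
  heat <- default_heat_params()
  rc <- temperature_response_curves(chill, heat, hours = 1200)
  expect_identical(nrow(rc), 551L)
  expect_equal(range(rc$temperature), c(-5, 50))
  expect_identical(max(rc$heat_response_normalized), 1)
  expect_equal(rc$heat_response_normalized[which.min(abs(rc$temperature - heat$Tb))], 0)
  expect_equal(rc$heat_response_normalized[which.min(abs(rc$temperature - heat$Tc))], 0)
  expect_true(all(rc$heat_response_normalized[rc$temperature > 36] == 0))
  # chill curve is unimodal for the default parameters
  # unimodal up to the discreteness of whole Chill Portions (the final
  # count steps by one conversion event, so the curve wiggles by less
  # than half a portion around its envelope)
  ch <- rc$chill_response
  peak <- which.max(ch)
  expect_true(all(diff(ch[1:peak]) > -0.5))
  expect_true(all(diff(ch[peak:length(ch)]) < 0.5))
  expect_gt(max(ch), 0)
  # the default submodel keeps a little sub-zero sensitivity; hot
  # temperatures accumulate nothing at all
  expect_lt(ch[1], 0.01)
  expect_identical(ch[length(ch)], 0)
})
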